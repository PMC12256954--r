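# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records every operation in creation order; backward() walks the tape
# in reverse and accumulates gradients into the leaves.  Only the operations
# the model needs are implemented; every backward rule is checked against
# finite differences in the test suite.  Scalars are 1x1 matrices.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), bw = NULL, req = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  nd$req <- req
  if (req) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ad_leaf <- function(tape, value) {
  ad_node(tape, value, req = TRUE)
}

ad_const <- function(tape, value) {
  ad_node(tape, value, req = FALSE)
}

ad_accum <- function(nd, g) {
  if (!nd$req) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Runs the backward pass from a scalar node; afterwards every leaf that
# requires gradients carries $grad.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$v) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (tape$n == 0L) return(invisible(NULL))
  for (k in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

ad_req <- function(...) {
  ps <- list(...)
  any(vapply(ps, function(p) isTRUE(p$req), logical(1)))
}

ad_mm <- function(tape, a, b) {
  v <- a$v %*% b$v
  ad_node(tape, v, list(a, b), req = ad_req(a, b), bw = function(g) {
    if (a$req) ad_accum(a, g %*% t(b$v))
    if (b$req) ad_accum(b, t(a$v) %*% g)
  })
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$v), list(a), req = a$req, bw = function(g) {
    ad_accum(a, t(g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$v + b$v, list(a, b), req = ad_req(a, b), bw = function(g) {
    if (a$req) ad_accum(a, g)
    if (b$req) ad_accum(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$v - b$v, list(a, b), req = ad_req(a, b), bw = function(g) {
    if (a$req) ad_accum(a, g)
    if (b$req) ad_accum(b, -g)
  })
}

# Adds a length-ncol row vector (bias) to every row of a matrix.
ad_add_bias <- function(tape, a, b) {
  v <- sweep(a$v, 2L, as.numeric(b$v), "+")
  ad_node(tape, v, list(a, b), req = ad_req(a, b), bw = function(g) {
    if (a$req) ad_accum(a, g)
    if (b$req) ad_accum(b, matrix(colSums(g), nrow(b$v), ncol(b$v)))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$v * b$v, list(a, b), req = ad_req(a, b), bw = function(g) {
    if (a$req) ad_accum(a, g * b$v)
    if (b$req) ad_accum(b, g * a$v)
  })
}

ad_div <- function(tape, a, b) {
  v <- a$v / b$v
  ad_node(tape, v, list(a, b), req = ad_req(a, b), bw = function(g) {
    if (a$req) ad_accum(a, g / b$v)
    if (b$req) ad_accum(b, -g * a$v / (b$v * b$v))
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$v * s, list(a), req = a$req, bw = function(g) {
    ad_accum(a, g * s)
  })
}

ad_exp <- function(tape, a) {
  v <- exp(a$v)
  ad_node(tape, v, list(a), req = a$req, bw = function(g) ad_accum(a, g * v))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$v), list(a), req = a$req, bw = function(g) {
    ad_accum(a, g / a$v)
  })
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

ad_softplus <- function(tape, a) {
  v <- softplus(a$v)
  ad_node(tape, v, list(a), req = a$req, bw = function(g) {
    ad_accum(a, g * stats::plogis(a$v))
  })
}

ad_elu <- function(tape, a, alpha = 1) {
  v <- ifelse(a$v > 0, a$v, alpha * (exp(pmin(a$v, 0)) - 1))
  ad_node(tape, v, list(a), req = a$req, bw = function(g) {
    ad_accum(a, g * ifelse(a$v > 0, 1, v + alpha))
  })
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  ad_node(tape, ifelse(a$v > 0, a$v, slope * a$v), list(a), req = a$req,
          bw = function(g) ad_accum(a, g * ifelse(a$v > 0, 1, slope)))
}

ad_abs <- function(tape, a) {
  ad_node(tape, abs(a$v), list(a), req = a$req, bw = function(g) {
    ad_accum(a, g * sign(a$v))
  })
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$v), 1L, 1L), list(a), req = a$req,
          bw = function(g) ad_accum(a, matrix(g[1L], nrow(a$v), ncol(a$v))))
}

ad_mean <- function(tape, a) {
  n <- length(a$v)
  ad_node(tape, matrix(mean(a$v), 1L, 1L), list(a), req = a$req,
          bw = function(g) ad_accum(a, matrix(g[1L] / n, nrow(a$v), ncol(a$v))))
}

# Outer sum: S[i, j] = f[i] + g[j] from two column vectors.
ad_outer_sum <- function(tape, f, g) {
  nf <- nrow(f$v); ng <- nrow(g$v)
  v <- matrix(f$v, nf, ng) + matrix(g$v, nf, ng, byrow = TRUE)
  ad_node(tape, v, list(f, g), req = ad_req(f, g), bw = function(gr) {
    if (f$req) ad_accum(f, matrix(rowSums(gr), nf, 1L))
    if (g$req) ad_accum(g, matrix(colSums(gr), ng, 1L))
  })
}

# Multiply a matrix node elementwise by a 1x1 scalar node.
ad_smul <- function(tape, a, s) {
  ad_node(tape, a$v * s$v[1L], list(a, s), req = ad_req(a, s), bw = function(g) {
    if (a$req) ad_accum(a, g * s$v[1L])
    if (s$req) ad_accum(s, matrix(sum(g * a$v), 1L, 1L))
  })
}

# Add a 1x1 scalar node to every entry of a matrix node.
ad_sadd <- function(tape, a, s) {
  ad_node(tape, a$v + s$v[1L], list(a, s), req = ad_req(a, s), bw = function(g) {
    if (a$req) ad_accum(a, g)
    if (s$req) ad_accum(s, matrix(sum(g), 1L, 1L))
  })
}

# Add a numeric constant to every entry (used for stable softmax shifts).
ad_shift <- function(tape, a, c) {
  ad_node(tape, a$v + c, list(a), req = a$req, bw = function(g) ad_accum(a, g))
}

# Multiply each column j of a matrix node by entry j of a 1 x ncol node.
ad_colmul <- function(tape, a, w) {
  wv <- as.numeric(w$v)
  v <- sweep(a$v, 2L, wv, "*")
  ad_node(tape, v, list(a, w), req = ad_req(a, w), bw = function(g) {
    if (a$req) ad_accum(a, sweep(g, 2L, wv, "*"))
    if (w$req) ad_accum(w, matrix(colSums(g * a$v), 1L))
  })
}

# Column-concatenate a list of matrix nodes.
ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(nd) ncol(nd$v), integer(1))
  v <- do.call(cbind, lapply(nodes, function(nd) nd$v))
  ad_node(tape, v, nodes, req = do.call(ad_req, nodes), bw = function(g) {
    at <- 0L
    for (nd in nodes) {
      w <- ncol(nd$v)
      if (nd$req) ad_accum(nd, g[, at + seq_len(w), drop = FALSE])
      at <- at + w
    }
  })
}

# Matrix inverse; d(X^-1) = -X^-1 dX X^-1  =>  grad_X = -X^-T G X^-T.
ad_solve <- function(tape, a) {
  inv <- solve(a$v)
  ad_node(tape, inv, list(a), req = a$req, bw = function(g) {
    ad_accum(a, -t(inv) %*% g %*% t(inv))
  })
}
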