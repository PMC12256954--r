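# The reverse-mode tape is the foundation of training: every backward rule
# is validated against central finite differences on composite graphs.

fd_grad <- function(f, x, h = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

test_that("gradients of a dense composite graph match finite differences", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 3, 2) * 0.5
  b <- matrix(rnorm(2), 1, 2) * 0.1
  A <- matrix(rnorm(4), 2, 2) * 0.2
  loss_fn <- function(W., b., A.) {
    tape <- hypergsem:::ad_tape()
    Wn <- hypergsem:::ad_leaf(tape, W.)
    bn <- hypergsem:::ad_leaf(tape, b.)
    An <- hypergsem:::ad_leaf(tape, A.)
    Xc <- hypergsem:::ad_const(tape, X)
    h1 <- hypergsem:::ad_elu(tape, hypergsem:::ad_add_bias(
      tape, hypergsem:::ad_mm(tape, Xc, Wn), bn))
    IA <- hypergsem:::ad_sub(tape, hypergsem:::ad_const(tape, diag(2)), An)
    h2 <- hypergsem:::ad_mm(tape, h1, hypergsem:::ad_solve(tape, IA))
    h3 <- hypergsem:::ad_softplus(tape, h2)
    out <- hypergsem:::ad_mean(tape, hypergsem:::ad_mul(tape, h3, h3))
    list(tape = tape, out = out, Wn = Wn, bn = bn, An = An)
  }
  g <- loss_fn(W, b, A)
  hypergsem:::ad_backward(g$tape, g$out)
  val <- function(W., b., A.) loss_fn(W., b., A.)$out$v[1]
  expect_rel_equal(g$Wn$grad, fd_grad(function(x) val(x, b, A), W), 1e-5)
  expect_rel_equal(g$bn$grad, fd_grad(function(x) val(W, x, A), b), 1e-5)
  expect_rel_equal(g$An$grad, fd_grad(function(x) val(W, b, x), A), 1e-5)
})

test_that("gradients of attention-style ops match finite differences", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  W <- matrix(rnorm(6), 3, 2) * 0.4
  a1 <- matrix(rnorm(2), 2, 1) * 0.4
  a2 <- matrix(rnorm(2), 2, 1) * 0.4
  B <- matrix(rbinom(20, 1, 0.6), 5, 4)
  B[1, ] <- 1                                # keep hyperedges non-empty
  loss_fn <- function(W., a1., a2.) {
    tape <- hypergsem:::ad_tape()
    Wn <- hypergsem:::ad_leaf(tape, W.)
    a1n <- hypergsem:::ad_leaf(tape, a1.)
    a2n <- hypergsem:::ad_leaf(tape, a2.)
    Xc <- hypergsem:::ad_const(tape, X)
    HW <- hypergsem:::ad_mm(tape, Xc, Wn)
    f <- hypergsem:::ad_mm(tape, HW, a1n)
    g <- hypergsem:::ad_mm(tape, HW, a2n)
    S <- hypergsem:::ad_leaky_relu(tape, hypergsem:::ad_outer_sum(tape, f, g),
                                   0.2)
    E <- hypergsem:::ad_exp(tape, S)
    D <- hypergsem:::ad_mm(tape, E, hypergsem:::ad_const(tape, B))
    Q <- hypergsem:::ad_div(tape, hypergsem:::ad_const(tape, B), D)
    Wagg <- hypergsem:::ad_mul(tape, E,
                               hypergsem:::ad_mm(tape, Q,
                                                 hypergsem:::ad_const(tape,
                                                                      t(B))))
    out <- hypergsem:::ad_mean(tape,
                               hypergsem:::ad_abs(tape,
                                                  hypergsem:::ad_mm(tape, Wagg,
                                                                    HW)))
    list(tape = tape, out = out, Wn = Wn, a1n = a1n, a2n = a2n)
  }
  g <- loss_fn(W, a1, a2)
  hypergsem:::ad_backward(g$tape, g$out)
  val <- function(W., a1., a2.) loss_fn(W., a1., a2.)$out$v[1]
  expect_rel_equal(g$Wn$grad, fd_grad(function(x) val(x, a1, a2), W), 1e-4)
  expect_rel_equal(g$a1n$grad, fd_grad(function(x) val(W, x, a2), a1), 1e-4)
  expect_rel_equal(g$a2n$grad, fd_grad(function(x) val(W, a1, x), a2), 1e-4)
})

test_that("scalar, column-scale and concatenation ops backpropagate correctly", {
  set.seed(3)
  X <- matrix(rnorm(8), 4, 2)
  s <- matrix(0.7, 1, 1)
  w <- matrix(rnorm(2), 1, 2)
  loss_fn <- function(s., w.) {
    tape <- hypergsem:::ad_tape()
    sn <- hypergsem:::ad_leaf(tape, s.)
    wn <- hypergsem:::ad_leaf(tape, w.)
    Xc <- hypergsem:::ad_const(tape, X)
    p1 <- hypergsem:::ad_sadd(tape, hypergsem:::ad_smul(tape, Xc, sn), sn)
    p2 <- hypergsem:::ad_colmul(tape, Xc, wn)
    cc <- hypergsem:::ad_cbind(tape, list(p1, p2))
    lg <- hypergsem:::ad_log(tape, hypergsem:::ad_softplus(tape, cc))
    out <- hypergsem:::ad_sum(tape, hypergsem:::ad_mul(tape, lg, lg))
    list(tape = tape, out = out, sn = sn, wn = wn)
  }
  g <- loss_fn(s, w)
  hypergsem:::ad_backward(g$tape, g$out)
  val <- function(s., w.) loss_fn(s., w.)$out$v[1]
  expect_rel_equal(g$sn$grad, fd_grad(function(x) val(x, w), s), 1e-5)
  expect_rel_equal(g$wn$grad, fd_grad(function(x) val(s, x), w), 1e-5)
})

test_that("the full model forward graph differentiates its parameters correctly", {
  hg <- tiny_hypergraph(n_genes = 5, n_cells = 8, seed = 4)
  cfg <- tiny_config()
  n <- length(hg$gene_ids); m <- length(hg$cell_ids)
  set.seed(4)
  params <- shrink_params(init_network_params(cfg, n, m))
  A <- init_causal_matrix(n, 0.01)$A * 0.3
  ctx <- hypergsem:::forward_context(hg)
  d <- cfg$latent_dim_gene
  set.seed(5)
  eps <- list(V = matrix(rnorm(n * d), n, d), E = matrix(rnorm(m * n), m, n),
              D = matrix(rnorm(m * n), m, n))
  run <- function(params., A.) {
    tape <- hypergsem:::ad_tape()
    pn <- hypergsem:::wrap_tree(tape, params., TRUE)
    pn$leaky_slope <- params.$leaky_slope
    An <- hypergsem:::ad_leaf(tape, A.)
    fw <- hypergsem:::forward_graph(tape, ctx, pn, An, eps, cfg)
    list(tape = tape, fw = fw, pn = pn, An = An)
  }
  g <- run(params, A)
  hypergsem:::ad_backward(g$tape, g$fw$total)
  # A gradient
  fdA <- fd_grad(function(x) run(params, x)$fw$total$v[1], A, h = 1e-6)
  expect_rel_equal(g$An$grad, fdA, 1e-4)
  # a couple of network parameters along different paths
  fe_w <- params$cell$fe$w1[[1]]
  fdfe <- fd_grad(function(x) {
    p <- params; p$cell$fe$w1[[1]] <- x; run(p, A)$fw$total$v[1]
  }, fe_w, h = 1e-6)
  expect_rel_equal(g$pn$cell$fe$w1[[1]]$grad, fdfe, 1e-4)
  Wsk <- params$gene$layers[[2]]$Wskip
  fdsk <- fd_grad(function(x) {
    p <- params; p$gene$layers[[2]]$Wskip <- x; run(p, A)$fw$total$v[1]
  }, Wsk, h = 1e-6)
  expect_rel_equal(g$pn$gene$layers[[2]]$Wskip$grad, fdsk, 1e-4)
})
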