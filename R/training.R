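# Parameter initialization and the two-phase alternating RMSprop loop.

#' Initialize the causal interaction matrix
#'
#' Diagonal set to zero; every off-diagonal entry drawn i.i.d. from
#' N(1/(n_genes - 1), epsilon^2). The small epsilon perturbation prevents
#' entrapment in local optima; with epsilon = 0 every off-diagonal entry is
#' exactly 1/(n_genes - 1).
#'
#' @param n_genes Number of genes (>= 2).
#' @param epsilon Standard deviation of the initialization (>= 0).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param gene_ids Optional identifiers.
#' @return An `hg_causal`.
#' @export
init_causal_matrix <- function(n_genes, epsilon = 1e-4, seed = NULL,
                               gene_ids = NULL) {
  if (n_genes < 2) stop("`n_genes` must be at least 2")
  if (epsilon < 0) stop("`epsilon` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(n_genes^2, mean = 1 / (n_genes - 1), sd = epsilon),
              n_genes, n_genes)
  diag(A) <- 0
  causal_matrix(A, gene_ids %||% paste0("g", seq_len(n_genes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

kaiming_uniform <- function(nr, nc, fan_in = nr) {
  b <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

xavier_uniform <- function(nr, nc, fan_in = nr, fan_out = nc) {
  b <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

#' Initialize all network parameters
#'
#' Attention projections and score vectors use Xavier-uniform
#' initialization; MLP and variational-head weights use kaiming-uniform;
#' all biases start at zero. Deterministic given the seed.
#'
#' @param config An `hg_config`.
#' @param n_genes,n_cells Data dimensions the architecture is bound to.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return An `hg_params` nested list (gene encoder, cell encoder, decoder).
#' @export
init_network_params <- function(config, n_genes, n_cells, seed = NULL) {
  stopifnot(inherits(config, "hg_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$layers
  in_w <- n_cells
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    out_w <- if (l < L) config$att_dim else config$att_out
    pooled_w <- if (l < L) out_w * config$heads else out_w
    layers[[l]] <- list(heads = lapply(seq_len(config$heads), function(h) {
      list(W = xavier_uniform(in_w, out_w),
           a1 = xavier_uniform(out_w, 1, fan_in = 2 * out_w, fan_out = 1),
           a2 = xavier_uniform(out_w, 1, fan_in = 2 * out_w, fan_out = 1))
    }),
    # linear skip term: keeps node identity when large hyperedges make the
    # attention aggregate nearly uniform (over-smoothing guard)
    Wskip = xavier_uniform(in_w, pooled_w))
    in_w <- pooled_w
  }
  d <- config$latent_dim_gene
  dp <- config$latent_dim_cell
  gene <- list(layers = layers,
               Wmu = kaiming_uniform(config$att_out, d),
               bmu = zeros(1, d),
               Wsig = kaiming_uniform(config$att_out, d),
               bsig = zeros(1, d))
  fe <- if (config$fe_style == "genewise") {
    K <- config$fe_channels
    list(style = "genewise",
         w1 = lapply(seq_len(K), function(k) kaiming_uniform(1, 1, fan_in = 1)),
         b1 = lapply(seq_len(K), function(k) zeros(1, 1)),
         w2 = lapply(seq_len(K), function(k) kaiming_uniform(1, 1, fan_in = K)),
         b2 = zeros(1, 1))
  } else {
    list(style = "dense",
         W1 = kaiming_uniform(n_genes, config$fe_hidden),
         b1 = zeros(1, config$fe_hidden),
         W2 = kaiming_uniform(config$fe_hidden, n_genes),
         b2 = zeros(1, n_genes))
  }
  cell <- if (config$head_style == "genewise") {
    # diagonal heads start at identity scale: a random per-gene sign/scale
    # would arbitrarily re-weight each gene's contribution to the KL
    list(fe = fe,
         wmu = matrix(1, 1, n_genes),
         bmu = zeros(1, n_genes),
         wsig = matrix(1, 1, n_genes),
         bsig = zeros(1, n_genes))
  } else {
    list(fe = fe,
         Wmu = kaiming_uniform(n_genes, dp), bmu = zeros(1, dp),
         Wsig = kaiming_uniform(n_genes, dp), bsig = zeros(1, dp))
  }
  dec_head <- if (config$head_style == "genewise") {
    # gene-indexed decoder: diagonal head plus a per-gene modulation gain
    # read out of the gene latent (v = 1 + ZV %*% wr at initialization)
    list(wmu = matrix(1, 1, n_genes),
         bmu = zeros(1, n_genes),
         wsig = matrix(1, 1, n_genes),
         bsig = zeros(1, n_genes),
         wr = xavier_uniform(d, 1),
         br = matrix(1, n_genes, 1))
  } else {
    list(Wmu = kaiming_uniform(n_genes, d), bmu = zeros(1, d),
         Wsig = kaiming_uniform(n_genes, d), bsig = zeros(1, d))
  }
  fd <- if (config$head_style == "genewise") {
    # gene-indexed cell latent: the decoder MLP is genewise as well
    K <- config$fe_channels
    list(style = "genewise",
         w1 = lapply(seq_len(K), function(k) kaiming_uniform(1, 1, fan_in = 1)),
         b1 = lapply(seq_len(K), function(k) zeros(1, 1)),
         w2 = lapply(seq_len(K), function(k) kaiming_uniform(1, 1, fan_in = K)),
         b2 = zeros(1, 1))
  } else {
    list(style = "dense",
         W1 = kaiming_uniform(dp, config$dec_hidden),
         b1 = zeros(1, config$dec_hidden),
         W2 = kaiming_uniform(config$dec_hidden, n_genes),
         b2 = zeros(1, n_genes))
  }
  dec <- c(list(fd = fd), dec_head)
  structure(list(gene = gene, cell = cell, dec = dec,
                 leaky_slope = config$leaky_slope),
            class = "hg_params")
}

# --- nested parameter-tree helpers -------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.matrix(a)) return(f(a, b))
  if (is.list(a)) {
    return(stats::setNames(lapply(seq_along(a),
                                  function(i) tree_map2(a[[i]], b[[i]], f)),
                           names(a)))
  }
  a
}

tree_map <- function(a, f) {
  if (is.matrix(a)) return(f(a))
  if (is.list(a)) {
    return(stats::setNames(lapply(a, tree_map, f = f), names(a)))
  }
  a
}

# Wrap every matrix in the tree as an autodiff leaf (trainable) or const.
wrap_tree <- function(tape, p, trainable) {
  tree_map(p, function(m) if (trainable) ad_leaf(tape, m) else ad_const(tape, m))
}

rmsprop_init <- function(p) tree_map(p, function(m) m * 0)

# One RMSprop update over a (params, grads, state) triple of trees.
rmsprop_step <- function(p, nodes, state, lr, rho = 0.99, eps = 1e-8) {
  newp <- p; news <- state
  rec <- function(path_p, path_n, path_s) {
    if (is.matrix(path_p)) {
      g <- path_n$grad
      if (is.null(g)) g <- path_p * 0
      s <- rho * path_s + (1 - rho) * g * g
      newp <- path_p - lr * g / (sqrt(s) + eps)
      dimnames(newp) <- dimnames(path_p)
      dimnames(s) <- dimnames(path_s)
      list(p = newp, s = s)
    } else if (is.list(path_p)) {
      out_p <- path_p; out_s <- path_s
      for (i in seq_along(path_p)) {
        if (is.matrix(path_p[[i]]) || is.list(path_p[[i]])) {
          r <- rec(path_p[[i]], path_n[[i]], path_s[[i]])
          out_p[[i]] <- r$p; out_s[[i]] <- r$s
        }
      }
      list(p = out_p, s = out_s)
    } else {
      list(p = path_p, s = path_s)
    }
  }
  rec(p, nodes, state)
}

#' Train the model with two-phase alternating RMSprop
#'
#' Repeats `cycles` times: (phase "net") RMSprop on all encoder/decoder
#' parameters with the causal matrix frozen, for `epochs_net` full-batch
#' epochs at `lr_net`; then (phase "A") RMSprop on the causal matrix alone
#' at `lr_A` for `epochs_A` epochs, with its diagonal re-zeroed after every
#' step. All randomness (initialization and reparameterization draws) flows
#' from `config$seed`.
#'
#' @param hg An `hg_hypergraph` built from the data (see
#'   [build_hypergraph()] / [preprocess()]).
#' @param config An `hg_config`.
#' @param verbose Print per-phase progress?
#' @return An `hg_model`: `params`, `A` (`hg_causal`), `config`, `loss_log`
#'   (one row per optimizer step), `n_genes`, `n_cells`.
#' @export
train <- function(hg, config = hg_config(), verbose = FALSE) {
  stopifnot(inherits(hg, "hg_hypergraph"), inherits(config, "hg_config"))
  H <- hg$hyperedge_features                  # cells x genes, normalized
  m <- nrow(H); n <- ncol(H)
  if (m < 1 || n < 2) stop("hypergraph is degenerate (need >= 2 genes)")
  set.seed(config$seed)
  A <- init_causal_matrix(n, config$epsilon_init, gene_ids = hg$gene_ids)$A
  # the 1/(n-1) off-diagonal init has spectral radius ~ 1, leaving
  # (I - t(A)) near-singular; rescale to a safe radius before optimization
  sr <- spectral_radius(t(A))
  if (sr > config$init_spectral_cap) A <- A * (config$init_spectral_cap / sr)
  params <- init_network_params(config, n, m)
  ctx <- forward_context(hg)
  st_net <- rmsprop_init(params)
  st_A <- A * 0
  d <- config$latent_dim_gene
  dpc <- if (config$head_style == "genewise") n else config$latent_dim_cell
  dD <- if (config$head_style == "genewise") n else d
  total_steps <- config$cycles * (config$epochs_net + config$epochs_A)
  log <- vector("list", total_steps)
  step <- 0L
  for (cycle in seq_len(config$cycles)) {
    for (phase in c("net", "A")) {
      n_ep <- if (phase == "net") config$epochs_net else config$epochs_A
      # with the network frozen, the attention path, f_E(H) and the gene KL
      # are A-independent constants for the whole phase
      a_det <- !isTRUE(config$a_phase_sampling)
      cache <- if (phase == "A" && a_det) {
        ge <- gene_encode(hg, params)
        list(ZV = ge$latent$mean, kl_gene = gaussian_kl(ge$latent),
             Fe = fe_forward(H, params$cell$fe))
      }
      if (phase == "A") { A_tail <- A * 0; n_tail <- 0L }
      for (ep in seq_len(n_ep)) {
        step <- step + 1L
        eps <- list(V = matrix(stats::rnorm(n * d), n, d),
                    E = matrix(stats::rnorm(m * dpc), m, dpc),
                    D = matrix(stats::rnorm(m * dD), m, dD))
        tape <- ad_tape()
        pn <- wrap_tree(tape, params, trainable = (phase == "net"))
        pn$leaky_slope <- params$leaky_slope
        An <- if (phase == "A") ad_leaf(tape, A) else ad_const(tape, A)
        # the causal-matrix phase optimizes a deterministic subproblem
        # (posterior means); the network phase trains the stochastic ELBO
        fw <- forward_graph(tape, ctx, pn, An, eps, config,
                            sample = (phase == "net") || !a_det,
                            cache = cache)
        comps <- c(reconstruction = fw$reconstruction, kl_gene = fw$kl_gene,
                   kl_cell = fw$kl_cell, sparsity = fw$sparsity,
                   total = fw$total$v[1L])
        if (any(!is.finite(comps))) {
          bad <- names(comps)[!is.finite(comps)][1L]
          stop(sprintf("non-finite loss at step %d (term `%s` = %s)",
                       step, bad, comps[[bad]]))
        }
        ad_backward(tape, fw$total)
        if (phase == "net") {
          r <- rmsprop_step(params, pn, st_net, config$lr_net)
          params <- r$p; st_net <- r$s
        } else {
          g <- An$grad %||% (A * 0)
          st_A <- 0.99 * st_A + 0.01 * g * g
          A <- A - config$lr_A * g / (sqrt(st_A) + 1e-8)
          diag(A) <- 0                        # re-zero after every step
          # tail-average the iterates over the second half of the phase:
          # the L1 subgradient makes uninformative entries oscillate around
          # zero at the step-size scale, and averaging removes that floor
          if (ep > n_ep / 2) {
            A_tail <- A_tail + A; n_tail <- n_tail + 1L
          }
        }
        log[[step]] <- data.frame(step = step, cycle = cycle, phase = phase,
                                  epoch = ep,
                                  reconstruction = comps[["reconstruction"]],
                                  kl_gene = comps[["kl_gene"]],
                                  kl_cell = comps[["kl_cell"]],
                                  sparsity = comps[["sparsity"]],
                                  total = comps[["total"]])
      }
      if (verbose) {
        message(sprintf("cycle %d phase %-3s total %.5f", cycle, phase,
                        log[[step]]$total))
      }
    }
  }
  A_final <- if (exists("n_tail") && n_tail > 0L) A_tail / n_tail else A
  structure(list(params = params, A = causal_matrix(A_final, hg$gene_ids),
                 config = config, loss_log = do.call(rbind, log),
                 n_genes = n, n_cells = m),
            class = "hg_model")
}

#' @export
print.hg_model <- function(x, ...) {
  ll <- x$loss_log
  cat(sprintf(paste0("<hg_model> %d genes x %d cells; %d optimizer steps; ",
                     "final total loss %.5f\n"),
              x$n_genes, x$n_cells, nrow(ll), ll$total[nrow(ll)]))
  invisible(x)
}

#' Cell latent means from a fitted model
#'
#' Runs the SEM cell encoder on a hypergraph and returns the posterior mean
#' (the deterministic embedding used for clustering and visualization).
#'
#' @param model An `hg_model`.
#' @param hg An `hg_hypergraph` with the gene set the model was trained on.
#' @return cells x latent_dim_cell matrix with cell ids as rownames.
#' @export
encode_cells <- function(model, hg) {
  stopifnot(inherits(model, "hg_model"), inherits(hg, "hg_hypergraph"))
  zt <- cell_encode_sem(hg$hyperedge_features, model$A, model$params)
  mu <- cell_variational_head(zt, model$params)$mean
  rownames(mu) <- hg$cell_ids
  mu
}

#' Gene latent means from a fitted model
#'
#' @inheritParams encode_cells
#' @return genes x latent_dim_gene matrix with gene ids as rownames.
#' @export
encode_genes <- function(model, hg) {
  stopifnot(inherits(model, "hg_model"), inherits(hg, "hg_hypergraph"))
  mu <- gene_encode(hg, model$params)$latent$mean
  rownames(mu) <- hg$gene_ids
  mu
}

#' Per-step loss breakdown of a fitted model
#' @param model An `hg_model`.
#' @return The `loss_log` data.frame.
#' @export
loss_log <- function(model) model$loss_log
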