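# Shared fixture builders; everything is generated in code.

tiny_expr <- function(values = matrix(c(0, 2, 1, 3, 0, 4), 2, 3),
                      stage = "raw") {
  expression_matrix(values,
                    cell_ids = paste0("c", seq_len(nrow(values))),
                    gene_ids = paste0("g", seq_len(ncol(values))),
                    stage = stage)
}

tiny_hypergraph <- function(n_genes = 6, n_cells = 12, seed = 1,
                            dropout = 0.3) {
  A <- simulate_grn(n_genes, density = 0.2, seed = seed)
  ds <- simulate_expression(A, n_cells, noise_sd = 1, dropout = dropout,
                            seed = seed)
  build_hypergraph(ds$expression, normalize_expression(ds$expression))
}

tiny_config <- function(...) {
  base <- list(att_dim = 3, att_out = 4, latent_dim_gene = 4,
               latent_dim_cell = 4, fe_channels = 2, dec_hidden = 3,
               cycles = 1, epochs_net = 2, epochs_A = 2)
  do.call(hg_config, utils::modifyList(base, list(...)))
}

# Parameters scaled down so losses are O(1) and finite differences are
# numerically meaningful.
shrink_params <- function(params, factor = 0.2) {
  hypergsem:::tree_map(params, function(m) m * factor)
}

random_latent <- function(nr = 4, nc = 3, seed = 1) {
  set.seed(seed)
  gaussian_latent(matrix(rnorm(nr * nc), nr, nc),
                  matrix(exp(rnorm(nr * nc, sd = 0.5)), nr, nc))
}

expect_rel_equal <- function(got, want, tol = 1e-6) {
  expect_lt(max(abs(got - want)) / max(1, max(abs(want))), tol)
}

# from-scratch contingency implementation (independent of the package code)
oracle_scores <- function(pred, ref) {
  N <- length(pred)
  tab <- table(pred, ref)
  H <- function(n) { p <- n[n > 0] / sum(n); -sum(p * log(p)) }
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) {
      mi <- mi + tab[i, j] / N * log(N * tab[i, j] / (a[i] * b[j]))
    }
  }
  hu <- H(a); hv <- H(b)
  hck <- 0                                   # H(ref | pred)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) hck <- hck - tab[i, j] / N * log(tab[i, j] / a[i])
  }
  hkc <- 0                                   # H(pred | ref)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) hkc <- hkc - tab[i, j] / N * log(tab[i, j] / b[j])
  }
  comb <- function(x) sum(x * (x - 1) / 2)
  idx <- comb(as.vector(tab)); ea <- comb(a) * comb(b) / (N * (N - 1) / 2)
  mx <- (comb(a) + comb(b)) / 2
  list(nmi = unname(if (hu + hv == 0) 1 else mi / ((hu + hv) / 2)),
       ari = unname(if (mx == ea) 1 else (idx - ea) / (mx - ea)),
       hom = unname(if (hv == 0) 1 else 1 - hck / hv),
       com = unname(if (hu == 0) 1 else 1 - hkc / hu))
}

# ranking-metric oracles (shared by the metric and acceptance tests)
all_pairs <- function(genes) {
  p <- expand.grid(regulator = genes, target = genes,
                   stringsAsFactors = FALSE)
  p[p$regulator != p$target, ]
}

ranked <- function(pairs, ord) {
  ed <- pairs[ord, ]
  ed$score <- seq(nrow(ed), 1)
  rownames(ed) <- NULL
  class(ed) <- c("hg_edges", "data.frame")
  ed
}

# definitional EPR and trapezoidal AUPRC, written independently of the
# package implementation
oracle_epr <- function(hits, K, P) (sum(hits[seq_len(K)]) / K) / (K / P)
oracle_auprc <- function(hits) {
  K <- sum(hits); P <- length(hits)
  tp <- cumsum(hits); prec <- tp / seq_len(P); rec <- tp / K
  rec0 <- c(0, rec[-P]); prec0 <- c(prec[1], prec[-P])
  sum((rec - rec0) * (prec + prec0) / 2)
}
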