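#' Simulate a ground-truth causal interaction matrix
#'
#' Off-diagonal entries are non-zero with probability `density`, with
#' magnitudes uniform in `weight_range` and random signs. The matrix is
#' rescaled so that the spectral radius of its transpose is at most
#' `spectral_cap`, which guarantees invertibility of (I - t(A)) in the
#' linear SEM and bounds the variance inflation of downstream expression.
#'
#' @param n_genes Number of genes (>= 2).
#' @param density Edge probability in (0, 1).
#' @param weight_range Length-2 positive vector (lo, hi) of edge magnitudes.
#' @param seed Integer seed.
#' @param spectral_cap Upper bound for the spectral radius (default 0.8).
#' @return An `hg_causal` object: list with `A` (n x n, zero diagonal) and
#'   `gene_ids`.
#' @export
simulate_grn <- function(n_genes, density = 0.05, weight_range = c(0.5, 1),
                         seed = 0, spectral_cap = 0.8) {
  if (n_genes < 2) stop("`n_genes` must be at least 2")
  if (density <= 0 || density >= 1) stop("`density` must be in (0, 1)")
  if (weight_range[1] <= 0 || weight_range[1] > weight_range[2]) {
    stop("`weight_range` must satisfy 0 < lo <= hi")
  }
  set.seed(seed)
  n <- n_genes
  A <- matrix(0, n, n)
  off <- which(row(A) != col(A))
  hit <- off[stats::runif(length(off)) < density]
  mag <- stats::runif(length(hit), weight_range[1], weight_range[2])
  sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
  A[hit] <- mag * sgn
  sr <- spectral_radius(t(A))
  if (!is.finite(sr)) stop("degenerate draw: spectral radius not finite")
  if (sr > spectral_cap) A <- A * (spectral_cap / sr)
  causal_matrix(A, paste0("g", seq_len(n)))
}

spectral_radius <- function(M) {
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Causal interaction matrix constructor
#'
#' @param A Square numeric matrix; the diagonal is forced to zero. Entry
#'   `A[i, j]` scores the influence of gene `i` (regulator) on gene `j`.
#' @param gene_ids Gene identifiers (default from dimnames).
#' @return An `hg_causal` object.
#' @export
causal_matrix <- function(A, gene_ids = rownames(A)) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(!is.finite(A))) stop("causal matrix contains non-finite entries")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(A)))
  diag(A) <- 0
  dimnames(A) <- list(gene_ids, gene_ids)
  structure(list(A = A, gene_ids = as.character(gene_ids)),
            class = "hg_causal")
}

#' @export
print.hg_causal <- function(x, ...) {
  cat(sprintf("<hg_causal> %d genes, %d non-zero links, spectral radius %.3f\n",
              nrow(x$A), sum(x$A != 0), spectral_radius(t(x$A))))
  invisible(x)
}

#' Simulate expression from a linear SEM
#'
#' Each cell is an independent draw of the linear structural equation model:
#' gene noise z ~ N(0, noise_sd^2) is propagated through the network as
#' h = solve(I - t(A)) z, so the cells x genes matrix is Z (I - A)^{-1}.
#' Values are mapped to the non-negative scale with softplus (preserving
#' rank information that the incidence construction relies on), then zeroed
#' independently with probability `dropout` to emulate single-cell dropout.
#'
#' @param A An `hg_causal` (spectral radius of t(A) must be < 1).
#' @param n_cells Number of cells to draw.
#' @param noise_sd Standard deviation of the SEM noise.
#' @param dropout Per-entry zeroing probability in [0, 1).
#' @param seed Integer seed.
#' @return An `hg_synthetic` list: `expression` (raw `hg_expr`), `truth_A`
#'   (`hg_causal`), `truth_edges` (`hg_truth` ground-truth network),
#'   `latent` (pre-softplus SEM values), `seed`.
#' @export
simulate_expression <- function(A, n_cells, noise_sd = 1, dropout = 0,
                                seed = 0) {
  stopifnot(inherits(A, "hg_causal"))
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  n <- nrow(A$A)
  if (spectral_radius(t(A$A)) >= 1) {
    stop("spectral radius of t(A) must be < 1 for the SEM to be stable")
  }
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_cells * n, 0, noise_sd), n_cells, n)
  H <- Z %*% solve(diag(n) - A$A)          # row-cell form of (I - t(A))^-1 z
  X <- softplus(H)
  if (dropout > 0) {
    X[matrix(stats::runif(length(X)), n_cells, n) < dropout] <- 0
  }
  expr <- expression_matrix(X, paste0("c", seq_len(n_cells)), A$gene_ids,
                            stage = "raw")
  structure(list(expression = expr, truth_A = A,
                 truth_edges = truth_from_causal(A),
                 latent = H, seed = seed),
            class = "hg_synthetic")
}

#' Ground-truth network from a causal matrix
#'
#' @param A An `hg_causal`; every non-zero off-diagonal entry becomes a
#'   directed edge regulator -> target.
#' @return An `hg_truth` object (see [ground_truth()]).
#' @export
truth_from_causal <- function(A) {
  stopifnot(inherits(A, "hg_causal"))
  idx <- which(A$A != 0, arr.ind = TRUE)
  ground_truth(data.frame(regulator = A$gene_ids[idx[, 1L]],
                          target = A$gene_ids[idx[, 2L]],
                          stringsAsFactors = FALSE),
               genes = A$gene_ids)
}

#' Simulate expression with cell-cluster and gene-module block structure
#'
#' Cells are split evenly into `k_clusters` groups and genes into
#' `k_modules` modules; cells of cluster c over-express the genes of module
#' ((c - 1) mod k_modules) + 1 by `effect_size` on top of standard Gaussian
#' noise. Values are softplus-mapped to the raw scale.
#'
#' @param n_cells,n_genes Dimensions.
#' @param k_clusters Number of cell clusters (>= 2).
#' @param k_modules Number of gene modules (>= 1).
#' @param effect_size Mean shift added to over-expressed blocks.
#' @param seed Integer seed.
#' @return An `hg_synthetic` list with `expression`, `cell_labels`,
#'   `gene_module_labels`, `seed`.
#' @export
simulate_clustered <- function(n_cells, n_genes, k_clusters = 2,
                               k_modules = k_clusters, effect_size = 10,
                               seed = 0) {
  if (k_clusters < 2) stop("`k_clusters` must be >= 2")
  if (k_modules < 1) stop("`k_modules` must be >= 1")
  if (k_clusters > n_cells) stop("more clusters than cells")
  if (k_modules > n_genes) stop("more modules than genes")
  set.seed(seed)
  cl <- rep(seq_len(k_clusters), length.out = n_cells)
  md <- rep(seq_len(k_modules), length.out = n_genes)
  X <- matrix(stats::rnorm(n_cells * n_genes), n_cells, n_genes)
  for (c in seq_len(k_clusters)) {
    m <- ((c - 1L) %% k_modules) + 1L
    X[cl == c, md == m] <- X[cl == c, md == m] + effect_size
  }
  expr <- expression_matrix(softplus(X), paste0("c", seq_len(n_cells)),
                            paste0("g", seq_len(n_genes)), stage = "raw")
  structure(list(expression = expr,
                 cell_labels = stats::setNames(cl, expr$cell_ids),
                 gene_module_labels = stats::setNames(md, expr$gene_ids),
                 seed = seed),
            class = "hg_synthetic")
}

#' @export
print.hg_synthetic <- function(x, ...) {
  cat("<hg_synthetic>\n")
  print(x$expression)
  if (!is.null(x$truth_edges)) {
    cat(sprintf("  ground truth: %d edges\n", nrow(x$truth_edges$edges)))
  }
  if (!is.null(x$cell_labels)) {
    cat(sprintf("  cell labels: %d clusters\n", length(unique(x$cell_labels))))
  }
  invisible(x)
}
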