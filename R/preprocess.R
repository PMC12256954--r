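#' Filter sparsely expressed genes and cells
#'
#' Keeps genes with non-zero expression in strictly more than `min_frac` of
#' cells, then cells with non-zero expression in strictly more than
#' `min_frac` of the remaining genes. The gene filter is applied first and
#' each filter is applied once.
#'
#' @param x An `hg_expr` at stage `"raw"`.
#' @param min_frac Fraction threshold (default 0.01, i.e. "over 1%").
#' @return A filtered `hg_expr` at stage `"filtered"`.
#' @export
filter_cells_genes <- function(x, min_frac = 0.01) {
  stopifnot(inherits(x, "hg_expr"))
  if (x$stage != "raw") stop("filter_cells_genes expects a raw-stage matrix")
  v <- x$values
  keep_g <- colMeans(v > 0) > min_frac
  if (!any(keep_g)) stop("no genes pass the expression filter (gene axis empty)")
  v <- v[, keep_g, drop = FALSE]
  keep_c <- rowMeans(v > 0) > min_frac
  if (!any(keep_c)) stop("no cells pass the expression filter (cell axis empty)")
  v <- v[keep_c, , drop = FALSE]
  expression_matrix(v, stage = "filtered")
}

per_gene_sd <- function(values) {
  # ranking statistic: per-gene sd of the log1p-transformed values
  lv <- log1p(values)
  mu <- colMeans(lv)
  sqrt(colMeans(lv^2) - mu^2)
}

#' Select the most variable genes
#'
#' Genes are ranked by the standard deviation of their log1p-transformed
#' expression across cells and the top `n_top` are retained (ties broken by
#' original column order). When `tf_list` is given, every TF present in the
#' matrix is force-included in addition to the `n_top` most-varying genes.
#'
#' @param x An `hg_expr` at stage `"raw"` or `"filtered"`.
#' @param n_top Number of genes to keep.
#' @param tf_list Optional character vector of TF symbols to force-include.
#' @return An `hg_expr` with the selected genes, stage unchanged.
#' @export
select_top_variable_genes <- function(x, n_top, tf_list = NULL) {
  stopifnot(inherits(x, "hg_expr"))
  if (x$stage == "normalized") stop("select genes before normalization")
  if (n_top <= 0) stop("`n_top` must be positive")
  n <- ncol(x$values)
  if (n_top >= n) {
    if (n_top > n) warning("`n_top` exceeds the number of genes; keeping all")
    return(x)
  }
  sds <- per_gene_sd(x$values)
  ord <- order(-sds, seq_len(n))            # stable: ties by column order
  keep <- sort(ord[seq_len(n_top)])
  if (!is.null(tf_list)) {
    keep <- sort(union(keep, which(x$gene_ids %in% tf_list)))
  }
  expression_matrix(x$values[, keep, drop = FALSE], stage = x$stage)
}

#' Log-transform and z-normalize an expression matrix
#'
#' Applies x -> log(1 + x) entrywise, then a per-gene z-score across cells
#' (population standard deviation). Genes constant after the log transform
#' map to all-zero columns.
#'
#' @param x An `hg_expr` at stage `"raw"` or `"filtered"`.
#' @return An `hg_expr` at stage `"normalized"`.
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "hg_expr"))
  if (x$stage == "normalized") stop("matrix is already normalized")
  if (any(x$values < 0)) stop("negative values cannot be log-transformed")
  lv <- log1p(x$values)
  mu <- colMeans(lv)
  sd <- sqrt(colMeans(lv^2) - mu^2)
  z <- sweep(lv, 2L, mu, "-")
  pos <- sd > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2L, sd[pos], "/")
  z[, !pos] <- 0
  expression_matrix(z, stage = "normalized")
}

#' Build the gene-cell hypergraph
#'
#' Genes are nodes and cells are hyperedges: the incidence matrix has entry
#' (cell, gene) = 1 exactly when the raw expression is positive. Node
#' features are the normalized expression profiles of genes (genes x cells);
#' hyperedge features are the transposed view (cells x genes). The hyperedge
#' weight matrix is the identity and is not stored explicitly.
#'
#' @param x_raw Raw/filtered-stage `hg_expr` (positivity defines incidence).
#' @param x_norm Normalized-stage `hg_expr` with identical identifiers.
#' @return An object of class `hg_hypergraph` with `incidence`
#'   (cells x genes, 0/1), `node_features` (genes x cells),
#'   `hyperedge_features` (cells x genes), `cell_ids`, `gene_ids`.
#' @export
build_hypergraph <- function(x_raw, x_norm) {
  stopifnot(inherits(x_raw, "hg_expr"), inherits(x_norm, "hg_expr"))
  if (!identical(dim(x_raw$values), dim(x_norm$values)) ||
      !identical(x_raw$cell_ids, x_norm$cell_ids) ||
      !identical(x_raw$gene_ids, x_norm$gene_ids)) {
    stop("raw and normalized matrices must share shape and identifiers")
  }
  inc <- (x_raw$values > 0) * 1
  structure(list(incidence = inc,
                 node_features = t(x_norm$values),
                 hyperedge_features = x_norm$values,
                 cell_ids = x_raw$cell_ids,
                 gene_ids = x_raw$gene_ids),
            class = "hg_hypergraph")
}

#' @export
print.hg_hypergraph <- function(x, ...) {
  cat(sprintf("<hg_hypergraph> %d gene nodes, %d cell hyperedges, fill %.3f\n",
              length(x$gene_ids), length(x$cell_ids), mean(x$incidence)))
  invisible(x)
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper: filter, optionally select variable genes, normalize,
#' and build the hypergraph.
#'
#' @param x Raw `hg_expr`.
#' @param min_frac Expression-filter fraction (see [filter_cells_genes()]).
#' @param n_top Optional number of variable genes to keep.
#' @param tf_list Optional TF symbols to force-include in the selection.
#' @return An `hg_hypergraph`.
#' @export
preprocess <- function(x, min_frac = 0.01, n_top = NULL, tf_list = NULL) {
  xf <- filter_cells_genes(x, min_frac)
  if (!is.null(n_top)) xf <- select_top_variable_genes(xf, n_top, tf_list)
  build_hypergraph(xf, normalize_expression(xf))
}
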