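#' Extract a ranked regulatory edge list from a causal matrix
#'
#' The absolute value of `A[i, j]` scores the directed link i -> j
#' (row = regulator, column = target, matching the SEM convention
#' H = t(A) H + Z on gene-indexed features). Self-edges are dropped; when a
#' TF list is given only edges originating from TFs are emitted. Edges are
#' sorted by decreasing score with ties broken by (regulator, target)
#' lexical order.
#'
#' @param A An `hg_causal` or a plain square matrix with gene dimnames.
#' @param tf_list Optional character vector restricting regulators.
#' @return An `hg_edges` data.frame with columns `regulator`, `target`,
#'   `score`.
#' @export
extract_edges <- function(A, tf_list = NULL) {
  if (is.matrix(A)) A <- causal_matrix(A)
  stopifnot(inherits(A, "hg_causal"))
  ids <- A$gene_ids
  if (!is.null(tf_list)) {
    tf_list <- intersect(tf_list, ids)
    if (length(tf_list) == 0) stop("TF list shares no genes with the matrix")
  } else {
    tf_list <- ids
  }
  ri <- match(tf_list, ids)
  reg <- rep(tf_list, each = length(ids))
  tgt <- rep(ids, times = length(tf_list))
  sc <- abs(as.numeric(t(A$A[ri, , drop = FALSE])))
  keep <- reg != tgt
  df <- data.frame(regulator = reg[keep], target = tgt[keep],
                   score = sc[keep], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$regulator, df$target), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hg_edges", "data.frame")
  df
}

#' Keep the top fraction of a ranked edge list
#'
#' Retains the `ceiling(fraction * n)` highest-scoring edges (the ranking is
#' the stored deterministic order).
#'
#' @param edges An `hg_edges`.
#' @param fraction Fraction in (0, 1]; the benchmark convention is 0.005
#'   (the top 0.5% of predicted pairs).
#' @return The truncated `hg_edges`.
#' @export
select_top_fraction <- function(edges, fraction = 0.005) {
  stopifnot(inherits(edges, "data.frame"))
  if (nrow(edges) == 0) stop("empty edge list")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  k <- ceiling(fraction * nrow(edges))
  out <- edges[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ranked edge list as TSV (regulator, target, score)
#' @param edges An `hg_edges`.
#' @param path Output path.
#' @param header Write a header line? Default `FALSE` (benchmark style).
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path, header = FALSE) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a ranked edge list TSV
#' @param path File path.
#' @param header Does the file carry a header line?
#' @return An `hg_edges` data.frame.
#' @export
read_edges <- function(path, header = FALSE) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("regulator", "target", "score")
  class(df) <- c("hg_edges", "data.frame")
  df
}
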