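#' Ground-truth regulatory network
#'
#' @param edges data.frame with columns `regulator` and `target` (self-edges
#'   are dropped).
#' @param genes Gene universe (default: union of ids seen in `edges`).
#' @param tfs TF universe (default: unique regulators in `edges`).
#' @return An `hg_truth` object with `edges`, `genes`, `tfs`.
#' @export
ground_truth <- function(edges, genes = NULL, tfs = NULL) {
  stopifnot(is.data.frame(edges), all(c("regulator", "target") %in% names(edges)))
  edges <- unique(edges[, c("regulator", "target")])
  edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(c(edges$regulator, edges$target)))
  if (is.null(tfs)) tfs <- sort(unique(edges$regulator))
  if (!all(edges$regulator %in% tfs) || !all(edges$target %in% genes)) {
    stop("truth edges fall outside the declared TF/gene universes")
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, genes = as.character(genes),
                 tfs = as.character(tfs)),
            class = "hg_truth")
}

#' Read a ground-truth edge list (TSV: regulator, target)
#' @param path File path; no header by default.
#' @param header Does the file carry a header line?
#' @inheritParams ground_truth
#' @return An `hg_truth`.
#' @export
read_ground_truth <- function(path, header = FALSE, genes = NULL, tfs = NULL) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("regulator", "target")
  ground_truth(df[, 1:2], genes = genes, tfs = tfs)
}

# Number of evaluable ordered pairs: TF x gene minus self-pairs.
n_possible_pairs <- function(truth) {
  length(truth$tfs) * length(truth$genes) - sum(truth$tfs %in% truth$genes)
}

edge_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

#' Early precision ratio (EPR)
#'
#' Odds ratio of the true-positive rate among the top-K predicted edges
#' against random predictions, with K the number of ground-truth edges:
#' EPR = (TP / K) / (K / P), where P is the number of evaluable ordered
#' (TF, gene) pairs excluding self-pairs. Ties at the K-th rank are broken
#' by the stored deterministic order of the edge list.
#'
#' @param predicted An `hg_edges` ranked edge list (see [extract_edges()]).
#' @param truth An `hg_truth`.
#' @return A single number; 1 is the random baseline.
#' @export
epr <- function(predicted, truth) {
  stopifnot(inherits(truth, "hg_truth"))
  ed <- as.data.frame(predicted)
  K <- nrow(truth$edges)
  if (K == 0) stop("empty ground truth")
  P <- n_possible_pairs(truth)
  keep <- ed$regulator %in% truth$tfs & ed$target %in% truth$genes
  ed <- ed[keep, , drop = FALSE]
  topk <- ed[seq_len(min(K, nrow(ed))), , drop = FALSE]
  tset <- edge_key(truth$edges$regulator, truth$edges$target)
  tp <- sum(edge_key(topk$regulator, topk$target) %in% tset)
  (tp / K) / (K / P)
}

# Precision-recall points of a ranked 0/1 hit vector; trapezoidal area.
auprc_from_hits <- function(hits, n_pos) {
  tp <- cumsum(hits)
  prec <- tp / seq_along(hits)
  rec <- tp / n_pos
  rec0 <- c(0, rec[-length(rec)])
  prec0 <- c(prec[1L], prec[-length(prec)])
  sum((rec - rec0) * (prec + prec0) / 2)
}

# Exact expectation of the trapezoidal AUPRC under a uniformly random
# ranking of P pairs containing K positives (hypergeometric identities:
# E[tp_i | hit at i] = 1 + (i-1)(K-1)/(P-1)).
expected_random_auprc <- function(K, P) {
  i <- seq_len(P)
  e_hit_prec <- (K / P) * (1 + (i - 1) * (K - 1) / (P - 1)) / i
  e_hit_prec_prev <- c((K / P), rep((K / P) * (K - 1) / (P - 1), P - 1))
  sum((e_hit_prec + e_hit_prec_prev) / 2) / K
}

#' AUPRC ratio
#'
#' Area under the precision-recall curve of the full ranking (trapezoidal
#' over the per-rank precision/recall points) divided by the expected AUPRC
#' of a uniformly random ranking of the same instance — the "random
#' predictions" baseline. For large instances the baseline approaches K/P,
#' so a perfect ranking approaches the ratio P/K.
#'
#' @inheritParams epr
#' @return A single number; 1 is the random baseline.
#' @export
auprc_ratio <- function(predicted, truth) {
  stopifnot(inherits(truth, "hg_truth"))
  ed <- as.data.frame(predicted)
  K <- nrow(truth$edges)
  if (K == 0) stop("empty ground truth")
  P <- n_possible_pairs(truth)
  keep <- ed$regulator %in% truth$tfs & ed$target %in% truth$genes
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed) < P) {
    stop(sprintf("ranking covers %d of %d evaluable pairs; score every pair",
                 nrow(ed), P))
  }
  tset <- edge_key(truth$edges$regulator, truth$edges$target)
  hits <- edge_key(ed$regulator, ed$target) %in% tset
  auprc_from_hits(hits, K) / expected_random_auprc(K, P)
}

#' Overlap coefficient between two sets
#'
#' O(A, B) = |intersect(A, B)| / min(|A|, |B|), in [0, 1]: 1 when one set is
#' contained in the other, 0 when they are disjoint.
#'
#' @param a,b Non-empty vectors treated as sets.
#' @return A single number in [0, 1].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap coefficient is undefined for empty sets")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

entropy_counts <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Clustering agreement scores
#'
#' Computes NMI (normalization: arithmetic mean of the two entropies), ARI,
#' homogeneity and completeness from the contingency table of two labelings
#' of the same entities. Predicted labels play the "cluster" role and
#' reference labels the "class" role for homogeneity/completeness.
#'
#' @param pred,ref Label vectors; if named, names are matched, otherwise
#'   positions are matched.
#' @return Named list with `nmi`, `ari`, `hom`, `com`.
#' @export
clustering_scores <- function(pred, ref) {
  if (!is.null(names(pred)) && !is.null(names(ref))) {
    if (!setequal(names(pred), names(ref))) {
      stop("pred and ref label different entity sets")
    }
    ref <- ref[names(pred)]
  } else if (length(pred) != length(ref)) {
    stop("pred and ref label different entity sets")
  }
  N <- length(pred)
  tab <- unclass(table(pred, ref))
  a <- rowSums(tab); b <- colSums(tab)
  # mutual information and entropies (natural log)
  p <- tab / N
  pa <- a / N; pb <- b / N
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (outer(pa, pb)[nz])))
  hu <- entropy_counts(a); hv <- entropy_counts(b)
  nmi <- if (hu + hv == 0) 1 else mi / ((hu + hv) / 2)
  # adjusted Rand index
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  exp_idx <- sum_comb(a) * sum_comb(b) / choose(N, 2)
  max_idx <- (sum_comb(a) + sum_comb(b)) / 2
  ari <- if (max_idx == exp_idx) 1 else (idx - exp_idx) / (max_idx - exp_idx)
  # conditional entropies: H(class | cluster) and H(cluster | class)
  h_ref_given_pred <- -sum(p[nz] * log((p / (pa[row(p)]))[nz] ))
  h_pred_given_ref <- -sum(p[nz] * log((p / matrix(pb, nrow(p), ncol(p),
                                                   byrow = TRUE))[nz]))
  hom <- if (hv == 0) 1 else 1 - h_ref_given_pred / hv
  com <- if (hu == 0) 1 else 1 - h_pred_given_ref / hu
  list(nmi = nmi, ari = ari, hom = hom, com = com)
}

#' Normalized enrichment score (NES)
#'
#' Z-score of a motif's AUC against the AUC distribution of all motifs,
#' using the sample standard deviation (denominator N - 1).
#'
#' @param auc_motif AUC of the motif of interest.
#' @param all_aucs Numeric vector of AUCs of all motifs (length >= 2).
#' @return A single number.
#' @export
nes <- function(auc_motif, all_aucs) {
  if (length(all_aucs) < 2) stop("need at least two AUCs")
  s <- stats::sd(all_aucs)
  if (s == 0) stop("zero standard deviation across AUCs")
  (auc_motif - mean(all_aucs)) / s
}

#' Cluster cells from a latent representation
#'
#' Mirrors the standard single-cell latent-clustering recipe: if the latent
#' dimension exceeds 10 the top 10 principal components are extracted, a
#' 30-nearest-neighbour graph (Euclidean) is built, and Louvain community
#' detection is run with its resolution parameter tuned by binary search on
#' [1e-3, 10] until the cluster count matches `n_target_clusters` (at most
#' `max_iter` halvings; if the interval collapses first, the closest count
#' is returned with a warning).
#'
#' @param latent Numeric matrix, cells x latent dimensions.
#' @param n_target_clusters Desired number of clusters.
#' @param seed Integer seed (Louvain uses R's RNG).
#' @param n_neighbors Neighbourhood size (default 30).
#' @param max_iter Binary-search iteration cap (default 30).
#' @return Integer cluster labels named by rownames of `latent` (if any).
#' @export
embed_and_cluster <- function(latent, n_target_clusters, seed = 0,
                              n_neighbors = 30, max_iter = 30) {
  stopifnot(is.matrix(latent), n_target_clusters >= 1)
  m <- nrow(latent)
  if (m <= n_target_clusters) stop("need more cells than target clusters")
  if (m < n_neighbors + 1) {
    stop(sprintf("need at least n_neighbors + 1 = %d cells, got %d",
                 n_neighbors + 1, m))
  }
  if (ncol(latent) > 10) {
    latent <- stats::prcomp(latent, center = TRUE, scale. = FALSE)$x[, 1:10,
                                                                    drop = FALSE]
  }
  d <- as.matrix(stats::dist(latent))
  diag(d) <- Inf
  adj <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    nb <- order(d[i, ])[seq_len(n_neighbors)]
    adj[i, nb] <- 1L
  }
  adj <- pmax(adj, t(adj))                   # mutualise: undirected kNN graph
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  run <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_louvain(g, resolution = res))
  }
  lo <- 1e-3; hi <- 10
  best <- NULL; best_gap <- Inf
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    lab <- run(mid)
    k <- length(unique(lab))
    gap <- abs(k - n_target_clusters)
    if (gap < best_gap) { best <- lab; best_gap <- gap }
    if (k == n_target_clusters) break
    if (k < n_target_clusters) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-6 && it < max_iter) {
      warning(sprintf(paste0("resolution search collapsed before reaching %d ",
                             "clusters; returning closest count"),
                      n_target_clusters))
      break
    }
  }
  if (best_gap > 0 && (hi - lo) >= 1e-6) {
    warning(sprintf("could not reach exactly %d clusters within %d iterations",
                    n_target_clusters, max_iter))
  }
  out <- as.integer(best)
  names(out) <- rownames(latent)
  out
}

#' Read a label file (entity<TAB>label)
#' @param path File path; no header expected.
#' @return Named vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}
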