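# Independent oracles used below: exhaustive enumeration for EPR/AUPRC on a
# tiny instance, a from-scratch contingency-table implementation for the
# clustering scores, and mclust's ARI as an external cross-check.


test_that("EPR and AUPRC ratio agree with exhaustive enumeration on 3 genes / 2 edges", {
  genes <- c("g1", "g2", "g3")
  pairs <- all_pairs(genes)                  # 6 ordered pairs
  truth <- ground_truth(data.frame(regulator = c("g1", "g2"),
                                   target = c("g2", "g3")),
                        genes = genes, tfs = genes)
  K <- 2; P <- 6
  tkey <- paste(truth$edges$regulator, truth$edges$target)
  idx <- seq_len(nrow(pairs))
  allperms <- as.matrix(expand.grid(rep(list(idx), 6)))
  allperms <- allperms[apply(allperms, 1, function(r) length(unique(r)) == 6), ]
  auprcs <- numeric(nrow(allperms))
  for (r in seq_len(nrow(allperms))) {
    ord <- allperms[r, ]
    ed <- ranked(pairs, ord)
    hits <- paste(ed$regulator, ed$target) %in% tkey
    expect_identical(epr(ed, truth), oracle_epr(hits, K, P))
    auprcs[r] <- oracle_auprc(hits)
  }
  # the random baseline equals the enumeration mean exactly, so the package
  # ratio must equal oracle AUPRC / mean(all AUPRCs) for every ranking
  base <- mean(auprcs)
  for (r in seq(1, nrow(allperms), by = 37)) {
    ed <- ranked(pairs, allperms[r, ])
    hits <- paste(ed$regulator, ed$target) %in% tkey
    expect_equal(auprc_ratio(ed, truth), oracle_auprc(hits) / base,
                 tolerance = 1e-12)
  }
})

test_that("EPR hits its closed-form extremes", {
  genes <- paste0("g", 1:6)
  pairs <- all_pairs(genes)
  set.seed(16)
  tsel <- sample(nrow(pairs), 7)
  truth <- ground_truth(pairs[tsel, ], genes = genes, tfs = genes)
  K <- 7; P <- 30
  # all true edges ranked on top -> EPR = P/K; none in top-K -> 0
  ord_best <- c(tsel, setdiff(seq_len(nrow(pairs)), tsel))
  expect_equal(epr(ranked(pairs, ord_best), truth), P / K)
  expect_equal(epr(ranked(pairs, rev(ord_best)), truth), 0)
  # perfect ranking has AUPRC exactly 1, so its ratio is 1 / E[random AUPRC]
  expect_equal(auprc_ratio(ranked(pairs, ord_best), truth),
               1 / hypergsem:::expected_random_auprc(K, P), tolerance = 1e-12)
  # reversed-perfect ranking scores below random
  expect_lt(auprc_ratio(ranked(pairs, rev(ord_best)), truth), 1)
  expect_error(epr(ranked(pairs, seq_len(nrow(pairs))),
                   ground_truth(pairs[0, ], genes = genes, tfs = genes)),
               "empty")
})

test_that("random rankings average to 1 for both ratio metrics", {
  genes <- paste0("g", 1:5)
  pairs <- all_pairs(genes)
  set.seed(17)
  truth <- ground_truth(pairs[sample(nrow(pairs), 5), ],
                        genes = genes, tfs = genes)
  reps <- 2000
  eprs <- auprs <- numeric(reps)
  for (r in seq_len(reps)) {
    ed <- ranked(pairs, sample(nrow(pairs)))
    eprs[r] <- epr(ed, truth)
    auprs[r] <- auprc_ratio(ed, truth)
  }
  expect_lt(abs(mean(eprs) - 1), 4 * sd(eprs) / sqrt(reps))
  expect_lt(abs(mean(auprs) - 1), 4 * sd(auprs) / sqrt(reps))
})

test_that("overlap coefficient matches its set-theoretic definition", {
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  # symmetry and containment
  set.seed(18)
  for (i in 1:20) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
  }
  expect_equal(overlap_coefficient(c("a", "b"), letters), 1)
  expect_error(overlap_coefficient(character(0), "a"), "empty")
})


test_that("clustering scores match an independent contingency implementation", {
  set.seed(19)
  for (r in 1:50) {
    pred <- sample(1:4, 30, replace = TRUE)
    ref <- sample(1:3, 30, replace = TRUE)
    got <- clustering_scores(pred, ref)
    want <- oracle_scores(pred, ref)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("clustering scores honour agreement, permutation and degenerate cases", {
  set.seed(20)
  ref <- sample(1:3, 40, replace = TRUE)
  perfect <- clustering_scores(ref, ref)
  expect_equal(unlist(perfect), c(nmi = 1, ari = 1, hom = 1, com = 1))
  # permuting the label names changes nothing
  relab <- c(2L, 3L, 1L)[ref]
  expect_equal(clustering_scores(relab, ref), perfect)
  # single-cluster prediction vs balanced 2-class reference
  ref2 <- rep(1:2, each = 10)
  deg <- clustering_scores(rep(1L, 20), ref2)
  expect_equal(deg$com, 1)
  expect_equal(deg$hom, 0)
  # external cross-check on ARI
  if (requireNamespace("mclust", quietly = TRUE)) {
    pred <- sample(1:4, 40, replace = TRUE)
    expect_equal(clustering_scores(pred, ref)$ari,
                 mclust::adjustedRandIndex(pred, ref), tolerance = 1e-12)
  }
  expect_error(clustering_scores(setNames(1:3, c("a", "b", "c")),
                                 setNames(1:3, c("a", "b", "x"))),
               "entity")
})

test_that("NES is the z-score against all motif AUCs with sample sd", {
  expect_equal(nes(0.2, c(0.1, 0.2, 0.3)), 0)
  expect_equal(nes(0.3, c(0.1, 0.2, 0.3)), 1)   # sample sd = 0.1
  # a motif one sample-sd above the mean scores exactly 1
  set.seed(21)
  aucs <- runif(50)
  expect_equal(nes(mean(aucs) + sd(aucs), aucs), 1, tolerance = 1e-12)
  # shift invariance
  expect_equal(nes(0.3 + 5, c(0.1, 0.2, 0.3) + 5), 1)
  expect_error(nes(0.5, c(0.2, 0.2)), "zero")
  expect_error(nes(0.5, 0.2), "at least two")
})

test_that("latent clustering recovers separated blobs and is seed-stable", {
  set.seed(22)
  lat <- rbind(matrix(rnorm(40 * 12, 0), 40, 12),
               matrix(rnorm(40 * 12, 8), 40, 12))
  rownames(lat) <- paste0("c", 1:80)
  lab <- embed_and_cluster(lat, 2, seed = 1)
  expect_equal(length(lab), 80L)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(clustering_scores(lab, rep(1:2, each = 40))$ari, 1)
  expect_identical(lab, embed_and_cluster(lat, 2, seed = 1))
  # low-dimensional input skips the PCA branch and still works
  lab2 <- embed_and_cluster(lat[, 1:2], 2, seed = 1)
  expect_equal(clustering_scores(lab2, rep(1:2, each = 40))$ari, 1)
  expect_error(embed_and_cluster(lat[1:10, ], 2, seed = 1), "n_neighbors")
})
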