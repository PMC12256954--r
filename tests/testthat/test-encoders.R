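make_params <- function(n_cells = 4, seed = 1, cfg = tiny_config()) {
  set.seed(seed)
  init_network_params(cfg, n_genes = 5, n_cells = n_cells)
}

test_that("attention score evaluates LeakyReLU(a^T [Wh_i || Wh_j])", {
  p <- make_params()
  # hand-built head: W = identity, a = e1 concatenated with zeros
  p$gene$layers[[1]]$heads[[1]]$W <- diag(4)
  p$gene$layers[[1]]$heads[[1]]$a1 <- matrix(c(1, 0, 0, 0), 4, 1)
  p$gene$layers[[1]]$heads[[1]]$a2 <- matrix(0, 4, 1)
  h <- c(0.7, -1, 2, 0)
  expect_equal(attention_score(h, rnorm(4), p), 0.7)
  # a = 0 gives score 0 for any pair
  p$gene$layers[[1]]$heads[[1]]$a1[] <- 0
  expect_equal(attention_score(h, h, p), 0)
  # negative pre-activation scaled by the leak slope
  p$gene$layers[[1]]$heads[[1]]$a1 <- matrix(c(1, 0, 0, 0), 4, 1)
  expect_equal(attention_score(c(-2, 0, 0, 0), h, p), -2 * p$leaky_slope)
  expect_error(attention_score(c(1, 2), h, p), "width")
})

test_that("attention coefficients are per-hyperedge softmaxes", {
  S <- matrix(0, 3, 3)
  # singleton hyperedge -> coefficient 1
  co <- attention_coefficients(S, list(2L))
  expect_equal(co[[1]][2, 2], 1)
  # equal scores -> 0.5 each
  co2 <- attention_coefficients(S, list(c(1L, 3L)))
  expect_equal(co2[[1]][1, c(1, 3)], c(0.5, 0.5))
  # scores {0, ln 3} -> {0.25, 0.75}
  S2 <- S; S2[1, 3] <- log(3)
  co3 <- attention_coefficients(S2, list(c(1L, 3L)))
  expect_equal(co3[[1]][1, c(1, 3)], c(0.25, 0.75))
  expect_error(attention_coefficients(S, list(integer(0))), "empty")
})

test_that("coefficient rows sum to 1 over members, are 0 elsewhere, and are shift-invariant", {
  set.seed(6)
  S <- matrix(rnorm(8 * 8), 8, 8)
  edges <- list(c(1L, 2L, 5L), c(3L, 4L), c(2L, 6L, 7L, 8L))
  co <- attention_coefficients(S, edges)
  for (k in seq_along(edges)) {
    mem <- edges[[k]]
    expect_equal(unname(rowSums(co[[k]][mem, , drop = FALSE])),
                 rep(1, length(mem)), tolerance = 1e-12)
    out <- setdiff(1:8, mem)
    expect_true(all(co[[k]][out, ] == 0) && all(co[[k]][, out] == 0))
  }
  co_shift <- attention_coefficients(S + 3.7, edges)
  expect_equal(co, co_shift, tolerance = 1e-12)
})

test_that("propagation reduces to (M Omega M^T h) W on a singleton hypergraph", {
  raw <- expression_matrix(matrix(2, 1, 1), "c1", "g1")
  hg <- build_hypergraph(raw, expression_matrix(matrix(1.3, 1, 1),
                                                "c1", "g1",
                                                stage = "normalized"))
  W <- matrix(c(2, -1), 1, 2)
  out <- propagate(matrix(1.3, 1, 1), hg, matrix(1, 1, 1), W,
                   activation = "identity")
  expect_equal(out, 1.3 %*% W)               # M Omega M^T = 1 here
  # doubling Omega doubles the pre-activation
  out2 <- propagate(matrix(1.3, 1, 1), hg, matrix(1, 1, 1), W,
                    omega = matrix(2, 1, 1), activation = "identity")
  expect_equal(out2, 2 * out)
  # zero features propagate to zero under ELU
  expect_equal(propagate(matrix(0, 1, 1), hg, matrix(1, 1, 1), W),
               matrix(0, 1, 2))
  expect_error(propagate(matrix(0, 2, 1), hg, matrix(1, 2, 2), W),
               "incidence")
})

test_that("variational heads map zero input to zero mean and softplus std", {
  p <- make_params()
  z <- matrix(0, 5, 4)
  lat <- gene_variational_head(z, p)
  expect_equal(lat$mean, matrix(0, 5, 4))
  expect_equal(lat$std, matrix(hypergsem:::softplus(0), 5, 4))
  # identity weights on a 1-dim input reproduce the input as the mean
  p1 <- p
  p1$gene$Wmu <- diag(4); p1$gene$bmu <- matrix(0, 1, 4)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(gene_variational_head(x, p1)$mean, x)
  # std is strictly positive even for very negative pre-activations
  p1$gene$bsig <- matrix(-30, 1, 4)
  expect_true(all(gene_variational_head(x, p1)$std > 0))
  # cell head has cell-axis shapes
  pc <- make_params(cfg = tiny_config(head_style = "dense"))
  latc <- cell_variational_head(matrix(0, 7, 5), pc)
  expect_equal(dim(latc$mean), c(7L, 4L))
  expect_true(all(latc$std > 0))
})

test_that("reparameterization is deterministic given a seed and matches moments", {
  lat <- random_latent(20, 5)
  z1 <- reparameterize(lat, seed = 42)
  z2 <- reparameterize(lat, seed = 42)
  expect_identical(z1, z2)
  # degenerate (vanishing) std returns the mean
  lat0 <- gaussian_latent(lat$mean, matrix(1e-300, 20, 5))
  expect_equal(reparameterize(lat0, seed = 1), lat$mean, tolerance = 1e-12)
  # sample mean over 1e5 independent draws is within 4 sd/sqrt(n) of mu
  big <- gaussian_latent(matrix(2, 1e5, 1), matrix(3, 1e5, 1))
  zs <- reparameterize(big, seed = 7)
  expect_lt(abs(mean(zs) - 2), 4 * 3 / sqrt(1e5))
  expect_error(gaussian_latent(matrix(0, 2, 2), matrix(0, 2, 2)), "positive")
})

test_that("the SEM cell encoder composes the MLP with (I - t(A)) gene-wise", {
  cfg <- tiny_config(fe_channels = 1)
  set.seed(7)
  p <- init_network_params(cfg, n_genes = 2, n_cells = 3)
  # single positive channel makes f_E explicit: w2*elu(x*w1 + b1) + b2
  p$cell$fe$w1[[1]][] <- 1; p$cell$fe$b1[[1]][] <- 0
  p$cell$fe$w2[[1]][] <- 1; p$cell$fe$b2[] <- 0
  H <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)     # positive -> elu is identity
  expect_equal(cell_encode_sem(H, matrix(0, 2, 2), p), H)
  # strictly upper-triangular A with A[1,2] = a reduces the second
  # component by a times the first
  a <- 0.6
  A <- matrix(c(0, 0, a, 0), 2, 2)
  out <- cell_encode_sem(H, A, p)
  expect_equal(out[, 1], H[, 1])
  expect_equal(out[, 2], H[, 2] - a * H[, 1])
  expect_error(cell_encode_sem(H, matrix(0, 3, 3), p), "genes")
  # dense f_E with A = 0 equals the bare MLP (independent evaluation)
  cfgd <- tiny_config(fe_style = "dense", head_style = "dense")
  set.seed(8)
  pd <- init_network_params(cfgd, n_genes = 4, n_cells = 3)
  Hd <- matrix(rnorm(12), 3, 4)
  mlp <- hypergsem:::elu(Hd %*% pd$cell$fe$W1 +
                           matrix(pd$cell$fe$b1, 3, cfgd$fe_hidden,
                                  byrow = TRUE)) %*% pd$cell$fe$W2 +
    matrix(pd$cell$fe$b2, 3, 4, byrow = TRUE)
  expect_equal(cell_encode_sem(Hd, matrix(0, 4, 4), pd), mlp)
})

test_that("the autodiff forward graph agrees with the plain encoder/decoder path", {
  hg <- tiny_hypergraph(n_genes = 5, n_cells = 9, seed = 9)
  cfg <- tiny_config()
  n <- 5; m <- 9
  set.seed(9)
  params <- shrink_params(init_network_params(cfg, n, m))
  A <- init_causal_matrix(n, 0.01)$A * 0.3
  ctx <- hypergsem:::forward_context(hg)
  tape <- hypergsem:::ad_tape()
  pn <- hypergsem:::wrap_tree(tape, params, FALSE)
  pn$leaky_slope <- params$leaky_slope
  An <- hypergsem:::ad_const(tape, A)
  eps <- list(V = NULL, E = NULL, D = NULL)
  fw <- hypergsem:::forward_graph(tape, ctx, pn, An, eps, cfg, sample = FALSE)
  # independent plain-R composition of the same model
  ge <- hypergsem:::gene_encode(hg, params)
  zt <- cell_encode_sem(hg$hyperedge_features, A, params)
  latE <- cell_variational_head(zt, params)
  dec <- sem_decode(latE$mean, A, params, seed = 1)
  v <- as.numeric(ge$latent$mean %*% params$dec$wr + params$dec$br)
  Hhat <- sweep(dec$latent$mean, 2L, v, "*")
  expect_equal(fw$reconstruction,
               mean((hg$hyperedge_features - Hhat)^2), tolerance = 1e-10)
  expect_equal(fw$kl_gene, gaussian_kl(ge$latent), tolerance = 1e-10)
  expect_equal(fw$kl_cell, gaussian_kl(latE), tolerance = 1e-10)
  expect_equal(fw$sparsity, sum(abs(A)), tolerance = 1e-12)
})
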