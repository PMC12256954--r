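# Decoder (SEM inversion + reconstruction) and the training objective.

# The decoder MLP f_E' shares the genewise/dense structure of f_E.
fd_forward <- function(Z, fd) fe_forward(Z, fd)

#' SEM decoder
#'
#' Applies the decoder MLP to the sampled cell latent, inverts the SEM
#' transform along the gene axis (`%*% solve(I - A)` in the cells-in-rows
#' orientation), applies the decoder variational head and reparameterizes.
#'
#' @param ZE cells x latent_dim_cell sampled cell latent.
#' @param A An `hg_causal` or square matrix; spectral radius of t(A) must be
#'   < 1.
#' @param params An `hg_params`.
#' @param seed Optional seed for the reparameterization draw.
#' @return List with `ztilde` (cells x genes inverse-SEM features), `latent`
#'   (the decoder `hg_latent`) and `sample` (cells x latent_dim_gene, the
#'   reconstruction-ready cell representation).
#' @export
sem_decode <- function(ZE, A, params, seed = NULL) {
  if (inherits(A, "hg_causal")) A <- A$A
  n <- nrow(A)
  IA <- diag(n) - A
  rc <- rcond(IA)
  if (rc < 1e-12) {
    stop(sprintf("(I - t(A)) is numerically singular (rcond = %.3e)", rc))
  }
  zt <- fd_forward(ZE, params$dec$fd) %*% solve(IA)
  dp <- params$dec
  lat <- if (!is.null(dp$wmu)) {             # genewise diagonal head
    gaussian_latent(sweep(zt, 2L, as.numeric(dp$wmu), "*") +
                      matrix(dp$bmu, nrow(zt), ncol(zt), byrow = TRUE),
                    softplus(sweep(zt, 2L, as.numeric(dp$wsig), "*") +
                               matrix(dp$bsig, nrow(zt), ncol(zt),
                                      byrow = TRUE)))
  } else {
    gaussian_latent(zt %*% dp$Wmu + matrix(dp$bmu, nrow(zt),
                                           length(dp$bmu), byrow = TRUE),
                    softplus(zt %*% dp$Wsig + matrix(dp$bsig, nrow(zt),
                                                     length(dp$bsig),
                                                     byrow = TRUE)))
  }
  list(ztilde = zt, latent = lat, sample = reparameterize(lat, seed))
}

#' Reconstruct the expression matrix from the two latents
#'
#' The estimated matrix combines gene and cell representations through the
#' shared latent dimension: `H[c, g] = sum_k ZEprime[c, k] * ZV[g, k]`,
#' i.e. `ZEprime %*% t(ZV)`, giving a cells x genes reconstruction.
#'
#' @param ZV genes x d gene latent sample.
#' @param ZEprime cells x d decoded cell representation.
#' @return cells x genes matrix.
#' @export
reconstruct <- function(ZV, ZEprime) {
  if (ncol(ZV) != ncol(ZEprime)) {
    stop("gene and cell latents must share the latent width")
  }
  ZEprime %*% t(ZV)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form summed over entries: sum(0.5 * (mu^2 + sigma^2 - 1 -
#' log(sigma^2))); non-negative, zero iff mu = 0 and sigma = 1 everywhere.
#'
#' @param q An `hg_latent`.
#' @return A single non-negative number.
#' @export
gaussian_kl <- function(q) {
  stopifnot(inherits(q, "hg_latent"))
  sum(0.5 * (q$mean^2 + q$std^2 - 1 - 2 * log(q$std)))
}

#' Training objective breakdown
#'
#' reconstruction = mean squared error (isotropic Gaussian likelihood with
#' unit variance); KL terms via [gaussian_kl()]; sparsity = L1 norm of the
#' off-diagonal causal entries; total = reconstruction + alpha * kl_gene +
#' beta * kl_cell + gamma * sparsity. Minimizing the total maximizes the
#' weighted evidence lower bound minus the sparsity penalty.
#'
#' @param HV Observed (normalized) cells x genes matrix.
#' @param HVhat Reconstruction of the same shape.
#' @param q_gene,q_cell `hg_latent` posteriors of genes and cells.
#' @param A An `hg_causal` or square matrix.
#' @param weights Named list/vector with `alpha`, `beta`, `gamma` (>= 0).
#' @return A list of class `hg_loss` with `reconstruction`, `kl_gene`,
#'   `kl_cell`, `sparsity`, `alpha`, `beta`, `gamma`, `total`.
#' @export
elbo_loss <- function(HV, HVhat, q_gene, q_cell, A,
                      weights = list(alpha = 1, beta = 1, gamma = 1)) {
  if (!identical(dim(HV), dim(HVhat))) stop("shape mismatch in reconstruction")
  w <- lapply(weights[c("alpha", "beta", "gamma")], as.numeric)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  if (inherits(A, "hg_causal")) A <- A$A
  off <- A; diag(off) <- 0
  out <- list(reconstruction = mean((HV - HVhat)^2),
              kl_gene = gaussian_kl(q_gene),
              kl_cell = gaussian_kl(q_cell),
              sparsity = sum(abs(off)),
              alpha = w$alpha, beta = w$beta, gamma = w$gamma)
  out$total <- out$reconstruction + w$alpha * out$kl_gene +
    w$beta * out$kl_cell + w$gamma * out$sparsity
  class(out) <- "hg_loss"
  out
}

#' @export
print.hg_loss <- function(x, ...) {
  cat(sprintf(paste0("<hg_loss> total %.4f = recon %.4f + %.3g*kl_gene %.4f",
                     " + %.3g*kl_cell %.4f + %.3g*L1 %.4f\n"),
              x$total, x$reconstruction, x$alpha, x$kl_gene,
              x$beta, x$kl_cell, x$gamma, x$sparsity))
  invisible(x)
}
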