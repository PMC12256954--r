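# Gene (node) and cell (hyperedge) encoders: plain forward-pass operations.
# These functions define the mathematical surface of the two encoders and
# are used for encoding data with a fitted model and for verifying the
# autodiff training path against an independent forward implementation.

#' Model configuration
#'
#' Architecture, loss weights and optimization settings in one flat list.
#' Attention hidden layers concatenate their head outputs; the final
#' attention layer averages heads. All gene-gene mixing in the cell encoder
#' is mediated by the causal matrix when `fe_style = "genewise"` (the
#' default), which is what makes the causal matrix identifiable from
#' reconstruction; `fe_style = "dense"` gives the MLP a free gene-mixing
#' first layer instead.
#'
#' @param layers Number of attention layers (>= 1).
#' @param heads Attention heads per layer.
#' @param att_dim Per-head width of hidden attention layers.
#' @param att_out Per-head width of the final attention layer (head outputs
#'   are averaged there).
#' @param latent_dim_gene,latent_dim_cell Gaussian latent widths d and d'
#'   (`latent_dim_cell` applies only with `head_style = "dense"`; the
#'   genewise head ties the cell latent to the gene axis, d' = n_genes).
#' @param leaky_slope LeakyReLU slope in the attention score.
#' @param head_style `"genewise"` (default) gives the cell encoder a
#'   diagonal, per-gene variational head so the cell latent stays
#'   gene-indexed; `"dense"` uses a fully connected head of width
#'   `latent_dim_cell`. With the genewise head the KL term can only be
#'   lowered by whitening through (I - t(A)), which is what identifies the
#'   causal matrix; the dense head can whiten by itself and leaves A
#'   unidentified (kept for ablation).
#' @param fe_style `"genewise"` or `"dense"` cell-encoder MLP (see above).
#' @param fe_channels Hidden channels of the genewise cell-encoder MLP.
#' @param fe_hidden Hidden width of the dense cell-encoder MLP.
#' @param dec_hidden Hidden width of the decoder MLP.
#' @param alpha,beta Weights of the gene/cell KL terms.
#' @param gamma Weight of the L1 sparsity penalty on the causal matrix.
#' @param recon_sampling `"bottleneck"` (default) draws a Monte-Carlo sample
#'   only at the cell-encoder bottleneck and propagates posterior means
#'   through the gene latent and the decoder head; `"full"` reparameterizes
#'   all three Gaussian latents. The bottleneck form keeps the
#'   reconstruction gradient of the bilinear gene-by-cell product from being
#'   swamped by multiplicative sampling noise (which collapses the gene
#'   factor to zero); the KL terms are identical either way.
#' @param a_phase_sampling If `TRUE`, the causal-matrix phase keeps the
#'   stochastic reparameterization draw at the bottleneck (coupling A to the
#'   noise-propagation term of the reconstruction); by default it optimizes
#'   the deterministic posterior-mean objective.
#' @param cycles Two-phase alternation count.
#' @param epochs_net Network-phase epochs per cycle (RMSprop, lr_net).
#' @param epochs_A Causal-matrix-phase epochs per cycle (RMSprop, lr_A).
#' @param lr_net,lr_A Learning rates of the two phases.
#' @param epsilon_init Standard deviation of the causal-matrix init around
#'   1/(n_genes - 1).
#' @param init_spectral_cap The initial causal matrix is rescaled so that
#'   the spectral radius of its transpose does not exceed this value (the
#'   raw 1/(n-1) init sits at radius ~ 1, where (I - t(A)) is nearly
#'   singular).
#' @param seed Integer seed for all randomness of a run.
#' @param ... Overrides any of the above.
#' @return A list of class `hg_config`.
#' @export
hg_config <- function(layers = 2, heads = 4, att_dim = 16, att_out = 64,
                      latent_dim_gene = 64, latent_dim_cell = 64,
                      leaky_slope = 0.2,
                      head_style = c("genewise", "dense"),
                      fe_style = c("genewise", "dense"),
                      fe_channels = 4, fe_hidden = 32, dec_hidden = 32,
                      recon_sampling = c("bottleneck", "full"),
                      a_phase_sampling = FALSE,
                      alpha = 1e-5, beta = 1e-5, gamma = 1e-3,
                      cycles = 5, epochs_net = 300, epochs_A = 300,
                      lr_net = 3e-3, lr_A = 3e-3,
                      epsilon_init = 1e-4, init_spectral_cap = 0.5,
                      seed = 0, ...) {
  head_style <- match.arg(head_style)
  fe_style <- match.arg(fe_style)
  recon_sampling <- match.arg(recon_sampling)
  cfg <- c(as.list(environment()), list(...))
  cfg$... <- NULL
  stopifnot(cfg$layers >= 1, cfg$heads >= 1, cfg$cycles >= 1,
            cfg$epochs_net >= 1, cfg$epochs_A >= 1,
            cfg$lr_net >= 0, cfg$lr_A >= 0, cfg$epsilon_init >= 0)
  class(cfg) <- "hg_config"
  cfg
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

#' Attention score between two gene feature vectors
#'
#' score = LeakyReLU(a^T [W h_i || W h_j]); asymmetric in (i, j).
#'
#' @param h_i,h_j Feature vectors with the layer's input width.
#' @param params An `hg_params` object (see [init_network_params()]).
#' @param layer,head Indices selecting the attention parameters.
#' @return A single number.
#' @export
attention_score <- function(h_i, h_j, params, layer = 1, head = 1) {
  hp <- params$gene$layers[[layer]]$heads[[head]]
  if (length(h_i) != nrow(hp$W) || length(h_j) != nrow(hp$W)) {
    stop("feature width does not match the layer's input width")
  }
  pre <- sum(hp$a1 * as.numeric(h_i %*% hp$W)) +
    sum(hp$a2 * as.numeric(h_j %*% hp$W))
  leaky_relu(pre, params$leaky_slope)
}

#' Per-hyperedge attention coefficients
#'
#' For each hyperedge, the scores of its member pairs are normalized with a
#' softmax over the co-members j' of the same hyperedge; coefficients of
#' pairs not sharing the hyperedge are exactly 0.
#'
#' @param scores n x n matrix of raw attention scores.
#' @param hyperedges List of integer vectors, each the (non-empty) gene
#'   members of one hyperedge.
#' @return List of n x n coefficient matrices, one per hyperedge; rows of
#'   member genes sum to 1 over members.
#' @export
attention_coefficients <- function(scores, hyperedges) {
  n <- nrow(scores)
  lapply(hyperedges, function(mem) {
    if (length(mem) == 0) stop("empty hyperedge")
    al <- matrix(0, n, n)
    e <- exp(scores[mem, mem, drop = FALSE] -
               max(scores[mem, mem]))        # shift-invariant softmax
    al[mem, mem] <- e / rowSums(e)
    al
  })
}

#' One attention propagation step for a single head
#'
#' h_i' = sigma(sum_j alpha_ij (M Omega M^T h_j) W), where M is the
#' gene x cell incidence, Omega the hyperedge weight matrix (identity by
#' default) and alpha the summed per-hyperedge coefficients.
#'
#' @param node_features n x width matrix of gene features.
#' @param hg An `hg_hypergraph`.
#' @param coeffs n x n aggregated coefficient matrix (sum of the
#'   per-hyperedge matrices from [attention_coefficients()]).
#' @param W width x width' projection of this head.
#' @param omega Optional m x m hyperedge weight matrix (default identity).
#' @param activation `"elu"`, `"identity"`.
#' @return n x width' matrix.
#' @export
propagate <- function(node_features, hg, coeffs, W, omega = NULL,
                      activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  B <- t(hg$incidence)                       # genes x cells
  if (!identical(dim(coeffs), c(nrow(B), nrow(B)))) {
    stop("coefficient matrix does not match the incidence")
  }
  P <- incidence_product(B, omega)
  pre <- coeffs %*% (P %*% node_features) %*% W
  if (activation == "elu") elu(pre) else pre
}

# M Omega M^T with degree normalization: Dv^-1 B Omega De^-1 B^T, where De
# is the diagonal of hyperedge sizes and Dv the diagonal of node degrees.
# The row-stochastic form keeps feature magnitudes bounded independently of
# the cell count; for a single node in a single unit hyperedge it reduces
# to the literal M Omega M^T.
incidence_product <- function(B, omega = NULL) {
  s <- pmax(colSums(B), 1)
  deg <- pmax(rowSums(B), 1)
  P <- if (is.null(omega)) B %*% (t(B) / s) else B %*% omega %*% (t(B) / s)
  P / deg
}

# Full gene-encoder forward pass (plain arithmetic, no autodiff).
# Returns the pre-head embedding and the Gaussian latent.
gene_encode <- function(hg, params) {
  X <- hg$node_features                      # genes x cells
  B <- t(hg$incidence)
  P <- incidence_product(B)
  deg <- pmax(rowSums(B), 1)                 # hyperedges containing each gene
  L <- length(params$gene$layers)
  slope <- params$leaky_slope
  for (l in seq_len(L)) {
    heads <- params$gene$layers[[l]]$heads
    outs <- lapply(heads, function(hp) {
      HW <- X %*% hp$W
      S <- leaky_relu(outer(as.numeric(HW %*% hp$a1), as.numeric(HW %*% hp$a2),
                            "+"), slope)
      E <- exp(S - apply(S, 1L, max))        # row shift cancels in the ratio
      D <- E %*% B                           # per-(gene, hyperedge) denominators
      Q <- ifelse(B > 0, B / D, 0)
      Wagg <- E * (Q %*% t(B)) / deg         # per-hyperedge coefficients,
                                             # averaged over a gene's hyperedges
      Wagg %*% (P %*% X) %*% hp$W
    })
    pooled <- if (l < L) {
      do.call(cbind, outs)                   # hidden layers: concatenate heads
    } else {
      Reduce(`+`, outs) / length(outs)       # final layer: average heads
    }
    X <- elu(pooled + X %*% params$gene$layers[[l]]$Wskip)
  }
  list(embedding = X,
       latent = gene_variational_head(X, params))
}

#' Gaussian variational head for gene embeddings
#'
#' mean = Z W_mu + b_mu; std = softplus(Z W_sig + b_sig) (softplus keeps the
#' standard deviation strictly positive).
#'
#' @param z Embedding matrix (entities x width).
#' @param params An `hg_params`; the gene head weights are used.
#' @return An `hg_latent`: list with `mean` and `std` matrices.
#' @export
gene_variational_head <- function(z, params) {
  g <- params$gene
  gaussian_latent(z %*% g$Wmu + matrix(g$bmu, nrow(z), length(g$bmu),
                                       byrow = TRUE),
                  softplus(z %*% g$Wsig + matrix(g$bsig, nrow(z),
                                                 length(g$bsig), byrow = TRUE)))
}

#' Gaussian latent constructor
#' @param mean,std Matrices of equal shape; `std` strictly positive.
#' @return An `hg_latent`.
#' @export
gaussian_latent <- function(mean, std) {
  stopifnot(identical(dim(mean), dim(std)))
  if (any(!is.finite(mean)) || any(!is.finite(std))) {
    stop("non-finite latent parameters")
  }
  if (any(std <= 0)) stop("latent std must be strictly positive")
  structure(list(mean = mean, std = std), class = "hg_latent")
}

#' Reparameterized Gaussian sample
#'
#' Z = mean + std * eps with eps ~ N(0, I); deterministic given the seed.
#'
#' @param latent An `hg_latent`.
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used.
#' @return A matrix of the latent's shape.
#' @export
reparameterize <- function(latent, seed = NULL) {
  stopifnot(inherits(latent, "hg_latent"))
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(length(latent$mean)), nrow(latent$mean))
  latent$mean + latent$std * eps
}

# The cell-encoder MLP f_E (no SEM term), cells x genes -> cells x genes.
fe_forward <- function(H, fe) {
  if (fe$style == "genewise") {
    out <- matrix(fe$b2[1L], nrow(H), ncol(H))
    for (k in seq_along(fe$w1)) {
      out <- out + fe$w2[[k]][1L] * elu(H * fe$w1[[k]][1L] + fe$b1[[k]][1L])
    }
    out
  } else {
    h <- elu(H %*% fe$W1 + matrix(fe$b1, nrow(H), ncol(fe$W1), byrow = TRUE))
    h %*% fe$W2 + matrix(fe$b2, nrow(H), ncol(fe$W2), byrow = TRUE)
  }
}

#' SEM cell encoder
#'
#' Applies the cell-encoder MLP f_E to the hyperedge features and composes
#' the result with (I - t(A)) along the gene axis: in the stored cells-in-
#' rows orientation this is `f_E(H) %*% (I - A)`. With A = 0 the output is
#' the bare MLP output.
#'
#' @param hyperedge_features cells x genes matrix.
#' @param A An `hg_causal` or square matrix with dimension = genes.
#' @param params An `hg_params`.
#' @return cells x genes matrix (the pre-head cell embedding).
#' @export
cell_encode_sem <- function(hyperedge_features, A, params) {
  if (inherits(A, "hg_causal")) A <- A$A
  n <- ncol(hyperedge_features)
  if (!identical(dim(A), c(n, n))) {
    stop(sprintf("causal matrix is %d x %d but there are %d genes",
                 nrow(A), ncol(A), n))
  }
  fe_forward(hyperedge_features, params$cell$fe) %*% (diag(n) - A)
}

#' Gaussian variational head for cell embeddings
#' @param z cells x genes pre-head embedding.
#' @param params An `hg_params`; the cell head weights are used.
#' @return An `hg_latent` (cells x latent_dim_cell).
#' @export
cell_variational_head <- function(z, params) {
  cp <- params$cell
  if (!is.null(cp$wmu)) {                    # genewise diagonal head
    bmu <- matrix(cp$bmu, nrow(z), ncol(z), byrow = TRUE)
    bsig <- matrix(cp$bsig, nrow(z), ncol(z), byrow = TRUE)
    return(gaussian_latent(sweep(z, 2L, as.numeric(cp$wmu), "*") + bmu,
                           softplus(sweep(z, 2L, as.numeric(cp$wsig), "*") +
                                      bsig)))
  }
  gaussian_latent(z %*% cp$Wmu + matrix(cp$bmu, nrow(z), length(cp$bmu),
                                        byrow = TRUE),
                  softplus(z %*% cp$Wsig + matrix(cp$bsig, nrow(z),
                                                  length(cp$bsig),
                                                  byrow = TRUE)))
}
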