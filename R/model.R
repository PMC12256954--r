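# The full variational forward pass as an autodiff graph. The math here
# mirrors the plain forward functions in encoders.R / generative.R exactly;
# the test suite asserts that both routes produce identical values.

# Precomputed constants shared by every training step.
forward_context <- function(hg) {
  B <- t(hg$incidence)                        # genes x cells incidence
  n <- nrow(B)
  deg <- pmax(rowSums(B), 1)
  list(H = hg$hyperedge_features,             # cells x genes, normalized
       X = hg$node_features,                  # genes x cells
       B = B,
       P = incidence_product(B),              # normalized M Omega M^T, Omega = I
       Dinv = matrix(1 / deg, n, n))          # row-wise 1/degree mask
}

# f_E as autodiff graph (genewise channels or dense two-layer MLP).
fe_graph <- function(tape, Hc, fe) {
  if (fe$style == "genewise") {
    out <- NULL
    for (k in seq_along(fe$w1)) {
      t1 <- ad_elu(tape, ad_sadd(tape, ad_smul(tape, Hc, fe$w1[[k]]),
                                 fe$b1[[k]]))
      t2 <- ad_smul(tape, t1, fe$w2[[k]])
      out <- if (is.null(out)) t2 else ad_add(tape, out, t2)
    }
    ad_sadd(tape, out, fe$b2)
  } else {
    h <- ad_elu(tape, ad_add_bias(tape, ad_mm(tape, Hc, fe$W1), fe$b1))
    ad_add_bias(tape, ad_mm(tape, h, fe$W2), fe$b2)
  }
}

# Diagonal-Gaussian head: returns mean, std nodes.
head_graph <- function(tape, z, Wmu, bmu, Wsig, bsig) {
  list(mean = ad_add_bias(tape, ad_mm(tape, z, Wmu), bmu),
       std = ad_softplus(tape, ad_add_bias(tape, ad_mm(tape, z, Wsig), bsig)))
}

# sum(0.5 * (mu^2 + std^2 - 1 - 2 log std))
kl_graph <- function(tape, lat) {
  mu2 <- ad_mul(tape, lat$mean, lat$mean)
  s2 <- ad_mul(tape, lat$std, lat$std)
  inner <- ad_sub(tape, ad_add(tape, mu2, s2),
                  ad_scale(tape, ad_log(tape, lat$std), 2))
  ad_scale(tape, ad_sum(tape, ad_shift(tape, inner, -1)), 0.5)
}

sample_graph <- function(tape, lat, eps) {
  ad_add(tape, lat$mean, ad_mul(tape, lat$std, ad_const(tape, eps)))
}

# One multi-head attention layer over gene nodes.
attention_layer_graph <- function(tape, Xn, ctx, layer, slope, final) {
  Bc <- ad_const(tape, ctx$B)
  Bt <- ad_const(tape, t(ctx$B))
  outs <- lapply(layer$heads, function(hp) {
    HW <- ad_mm(tape, Xn, hp$W)
    f <- ad_mm(tape, HW, hp$a1)
    g <- ad_mm(tape, HW, hp$a2)
    S <- ad_leaky_relu(tape, ad_outer_sum(tape, f, g), slope)
    rmax <- apply(S$v, 1L, max)              # row shift cancels in the ratio
    E <- ad_exp(tape, ad_shift(tape, S, -rmax))
    D <- ad_mm(tape, E, Bc)
    Q <- ad_div(tape, ad_const(tape, ctx$B), D)
    Wagg <- ad_mul(tape, ad_mul(tape, E, ad_mm(tape, Q, Bt)),
                   ad_const(tape, ctx$Dinv))
    G <- ad_mm(tape, ad_const(tape, ctx$P), Xn)
    ad_mm(tape, ad_mm(tape, Wagg, G), hp$W)
  })
  pooled <- if (!final) {
    ad_cbind(tape, outs)
  } else {
    ad_scale(tape, Reduce(function(a, b) ad_add(tape, a, b), outs),
             1 / length(outs))
  }
  ad_elu(tape, ad_add(tape, pooled, ad_mm(tape, Xn, layer$Wskip)))
}

# Full model: gene encoder, SEM cell encoder, SEM decoder, reconstruction,
# weighted KL terms and the L1 sparsity penalty.
# cache: precomputed A-independent quantities for the deterministic
# causal-matrix phase (gene latent mean, f_E output, gene KL) — valid only
# while the network parameters are frozen and sampling is off.
forward_graph <- function(tape, ctx, pn, An, eps, config, sample = TRUE,
                          cache = NULL) {
  n <- ncol(ctx$H)
  mask <- matrix(1, n, n); diag(mask) <- 0
  Aeff <- ad_mul(tape, An, ad_const(tape, mask))
  IA <- ad_sub(tape, ad_const(tape, diag(n)), Aeff)
  rc <- rcond(IA$v)
  if (rc < 1e-10) {
    stop(sprintf("(I - t(A)) is numerically singular (rcond = %.3e)", rc))
  }

  full_mc <- identical(config$recon_sampling, "full") && sample

  # gene (node) encoder: multi-head hypergraph attention
  if (is.null(cache)) {
    Xn <- ad_const(tape, ctx$X)
    L <- length(pn$gene$layers)
    for (l in seq_len(L)) {
      Xn <- attention_layer_graph(tape, Xn, ctx, pn$gene$layers[[l]],
                                  config$leaky_slope, final = (l == L))
    }
    latV <- head_graph(tape, Xn, pn$gene$Wmu, pn$gene$bmu,
                       pn$gene$Wsig, pn$gene$bsig)
    ZV <- if (full_mc) sample_graph(tape, latV, eps$V) else latV$mean
    klV <- kl_graph(tape, latV)
    gene_mean <- latV$mean$v
  } else {
    ZV <- ad_const(tape, cache$ZV)
    klV <- ad_const(tape, matrix(cache$kl_gene, 1L, 1L))
    gene_mean <- cache$ZV
  }

  # cell (hyperedge) encoder: MLP then (I - t(A)) along the gene axis
  Fe <- if (is.null(cache)) {
    fe_graph(tape, ad_const(tape, ctx$H), pn$cell$fe)
  } else {
    ad_const(tape, cache$Fe)
  }
  Zt <- ad_mm(tape, Fe, IA)
  latE <- if (!is.null(pn$cell$wmu)) {       # genewise diagonal head
    list(mean = ad_add_bias(tape, ad_colmul(tape, Zt, pn$cell$wmu),
                            pn$cell$bmu),
         std = ad_softplus(tape, ad_add_bias(tape,
                                             ad_colmul(tape, Zt, pn$cell$wsig),
                                             pn$cell$bsig)))
  } else {
    head_graph(tape, Zt, pn$cell$Wmu, pn$cell$bmu, pn$cell$Wsig, pn$cell$bsig)
  }
  ZE <- if (sample) sample_graph(tape, latE, eps$E) else latE$mean

  # decoder: MLP, inverse SEM transform, head, sample
  Fd <- fe_graph(tape, ZE, pn$dec$fd)
  Ztp <- ad_mm(tape, Fd, ad_solve(tape, IA))
  latD <- if (!is.null(pn$dec$wmu)) {        # genewise diagonal head
    list(mean = ad_add_bias(tape, ad_colmul(tape, Ztp, pn$dec$wmu),
                            pn$dec$bmu),
         std = ad_softplus(tape, ad_add_bias(tape,
                                             ad_colmul(tape, Ztp, pn$dec$wsig),
                                             pn$dec$bsig)))
  } else {
    head_graph(tape, Ztp, pn$dec$Wmu, pn$dec$bmu, pn$dec$Wsig, pn$dec$bsig)
  }
  ZEp <- if (full_mc) sample_graph(tape, latD, eps$D) else latD$mean

  # reconstruction: in the genewise mode the decoder output is gene-indexed
  # and the gene latent enters as a per-gene modulation gain (equivalently,
  # a diagonal gene factor in the bilinear combiner); in the dense mode the
  # two latents combine through the shared latent width
  Hhat <- if (!is.null(pn$dec$wmu)) {
    v <- ad_add(tape, ad_mm(tape, ZV, pn$dec$wr), pn$dec$br)
    ad_colmul(tape, ZEp, ad_t(tape, v))
  } else {
    ad_mm(tape, ZEp, ad_t(tape, ZV))
  }
  diff <- ad_sub(tape, ad_const(tape, ctx$H), Hhat)
  recon <- ad_mean(tape, ad_mul(tape, diff, diff))
  klE <- kl_graph(tape, latE)
  sp <- ad_sum(tape, ad_abs(tape, Aeff))
  total <- ad_add(tape, recon, ad_scale(tape, klV, config$alpha))
  total <- ad_add(tape, total, ad_scale(tape, klE, config$beta))
  total <- ad_add(tape, total, ad_scale(tape, sp, config$gamma))
  list(total = total,
       reconstruction = recon$v[1L], kl_gene = klV$v[1L],
       kl_cell = klE$v[1L], sparsity = sp$v[1L],
       latents = list(gene_mean = gene_mean, cell_mean = latE$mean$v))
}
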