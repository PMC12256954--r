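---
title: "Methods: the hypergraph SEM variational autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hypergraph SEM variational autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypergsem)
```

This vignette is the package's own account of the model it implements: the
statistical assumptions, the role of each component, the parameters that
matter, and the design decisions taken where the architecture left real
choices open. Nothing stated here goes beyond what the test suite and the
acceptance script themselves compute.

## Data model

The input is a cells × genes expression matrix $H^V$ (raw counts or any
non-negative transform). Preprocessing follows the standard single-cell
recipe: genes kept when expressed in strictly more than 1% of cells, cells
kept when expressing strictly more than 1% of the remaining genes (gene
filter first, each applied once), optional selection of the most variable
genes ranked by the standard deviation of $\log(1+x)$ values (ties by
column order; TFs on a user list are force-included), then $\log(1+x)$
followed by a per-gene z-score with the population standard deviation.
Genes constant after the log map to all-zero columns. The "over 1%"
thresholds are read as strict inequalities.

The hypergraph view: genes are nodes, cells are hyperedges, and the binary
incidence has entry 1 exactly when the **raw** value is positive, so
normalization never changes connectivity. Node features are the normalized
gene profiles (genes × cells); hyperedge features are the transpose. The
hyperedge weight matrix $\Omega$ is the identity — no prior knowledge about
cell importance is assumed.

## Gene encoder: hypergraph multi-head attention

For genes $i, j$ sharing a hyperedge, a score
$e_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$ (slope 0.2) is
softmax-normalized over the co-members of each hyperedge; coefficients of
pairs sharing no hyperedge are exactly zero. Features propagate as a
weighted average of the transformed neighbour features through the
incidence product, heads are concatenated in hidden layers and averaged in
the final layer, and an ELU nonlinearity closes each layer. A Gaussian
variational head (linear mean; softplus standard deviation, which the
sampling and KL contracts require to be strictly positive) yields the gene
latent $Z_V$.

Three numerical/architectural choices here are the package's own:

- **Degree normalization.** The incidence product is used in the
  row-stochastic form $D_v^{-1} M \Omega D_e^{-1} M^\top$ and the summed
  per-hyperedge coefficients are averaged over each gene's hyperedge count.
  The unnormalized sum grows linearly with the number of cells containing a
  gene and overflows `exp()` within one forward pass at realistic sizes;
  the normalized form is the standard hypergraph-convolution scaling and
  reduces to the literal product for a single unit hyperedge.
- **Row-shifted softmax.** Scores are shifted by their row maximum before
  exponentiation; the per-hyperedge coefficients are invariant to any
  row-wise rescaling, so this is exact, not an approximation.
- **A per-layer linear skip term.** The concatenation-style score makes the
  attention ranking identical across query genes up to the LeakyReLU kink
  ("static" attention), and when hyperedges are large — dense matrices,
  e.g. simulated data at 20% dropout is 82% filled — the aggregation is
  close to a global average: at initialization all gene embeddings collapse
  to a single vector (observed rank 1). Each layer therefore adds
  $X W_{\text{skip}}$ before the nonlinearity, the usual over-smoothing
  guard in deep graph networks. Without it the gene factor of the
  reconstruction is unusable.

## Cell encoder and the causal matrix

The linear SEM ties the gene axis together: each cell's profile satisfies
$h = A^\top h + z$ with $z \sim N(0, \sigma^2 I)$, so
$h = (I - A^\top)^{-1} z$, and the learnable matrix $A$ (zero diagonal;
entry $A_{ij}$ = influence of gene $i$ on gene $j$) *is* the network
estimate. The encoder applies a gene-shared MLP $f_E$ and then the forward
transform: in the cells-in-rows orientation,
$\tilde Z_E = f_E(H) \, (I - A)$.

Two identifiability-critical choices:

- **$f_E$ is gene-shared (genewise).** A small per-entry MLP (default 4
  ELU channels) with weights shared across genes. If $f_E$ could mix genes
  freely, it would absorb the role of $(I - A)$ and the sparsity penalty
  would simply drive $A$ to zero. A dense variant remains available
  (`fe_style = "dense"`) for ablation.
- **The cell variational head is diagonal (`head_style = "genewise"`).**
  The cell latent stays gene-indexed ($d' = n$) with per-gene scale and
  bias. A dense head is itself a free whitening transform: with it, the KL
  term can be minimized without involving $A$ at all, and the causal matrix
  is unidentifiable — measurably so: with the dense head the trained
  $A$-gradient ranks true edges at chance level. The diagonal head weights
  are initialized at identity scale (1), not with random draws: a random
  per-gene sign and scale arbitrarily re-weights each gene's contribution
  to the KL and, empirically, destroys the informativeness of the
  bottleneck.

## Decoder and reconstruction

The decoder mirrors the encoder: an MLP on the sampled cell latent, the
inverse transform $(I - A)^{-1}$ along the gene axis (rejected with a
condition-number report when numerically singular), a Gaussian head, and a
reparameterized sample $Z'_E$. The gene and cell representations are then
combined into the cells × genes reconstruction.

The combination is the one place where the architecture leaves a genuinely
open choice, and the choice decides whether $A$ is learnable:

- In the **bilinear** reading, $\tilde H[c, g] = \langle Z'_E[c,\cdot],
  Z_V[g,\cdot]\rangle$ over a shared latent width $d$. With $d \ge n$ the
  pair (decoder head × gene factor) is a free $n \times n$ mixer that
  absorbs $(I - A^\top)^{-1}$ exactly; reconstruction then carries no
  information about $A$ (verified: trained $A$-gradients rank true edges at
  chance while the learned features' correlations rank them far above
  chance).
- In the default **genewise** reading, the decoder head is diagonal, $Z'_E$
  is cells × genes, and the gene latent enters as a per-gene modulation
  gain $v = 1 + Z_V w_r$: $\tilde H = Z'_E \,\mathrm{diag}(v)$ —
  equivalently the bilinear combiner applied to a diagonal gene factor.
  Nothing dense sits after the inverse transform, so reconstruction
  identifies $A$.

`reconstruct()` exposes the general bilinear combiner; the training graph
uses the diagonal gene factor by default.

## Objective and training

The loss is
$\mathrm{MSE}(H, \tilde H) + \alpha\,\mathrm{KL}_V + \beta\,\mathrm{KL}_E +
\gamma \|A\|_1$ (KL terms in closed form against the standard-normal
prior, summed over entries; reconstruction as the mean squared error of the
z-scored matrix, i.e. an isotropic unit-variance Gaussian likelihood; L1 on
the off-diagonal entries as the sparsity penalty). Training alternates two
RMSprop phases per cycle: all network weights with $A$ frozen
(`epochs_net` full-batch steps at `lr_net`), then $A$ alone
(`epochs_A` steps at `lr_A`), with the diagonal re-zeroed after every step.

Monte-Carlo and optimization details, each with its reason:

- **Bottleneck-only sampling** (`recon_sampling = "bottleneck"`): one
  reparameterization draw at the cell bottleneck; posterior means elsewhere.
  Sampling all three Gaussian latents puts multiplicative noise on both
  factors of the reconstruction and collapses the gene factor to zero; the
  KL terms are identical either way.
- **Deterministic causal-matrix phase**: the $A$-phase optimizes the
  posterior-mean objective, making it a clean penalized-regression
  subproblem; with the network frozen, the attention path, $f_E(H)$ and
  the gene KL are constants and are cached for the whole phase. The
  stochastic variant is available (`a_phase_sampling = TRUE`).
- **Tail averaging**: the final $A$ is the average of the iterates over the
  second half of the last $A$-phase. The L1 subgradient makes
  uninformative entries oscillate around zero at the step-size scale;
  averaging removes that floor from the rankings.
- **Initial spectral rescale**: the prescribed initialization — zero
  diagonal, off-diagonals $N(1/(n-1), \epsilon^2)$ — has spectral radius
  essentially 1 (row sums are 1 in expectation), so $(I - A^\top)$ starts
  nearly singular and the first phase diverges. `train()` rescales the
  initial matrix to spectral radius `init_spectral_cap` (default 0.5);
  `init_causal_matrix()` itself keeps the exact prescribed form.

### Defaults and how they were chosen

`hg_config()` defaults: 2 attention layers, 4 heads, per-head hidden width
16, final width 64, gene latent 64; $f_E$ with 4 genewise channels;
$\alpha = \beta = 10^{-5}$, $\gamma = 10^{-3}$;
`cycles = 5`, `epochs_net = epochs_A = 300`,
`lr_net = lr_A = 3 \times 10^{-3}`, $\epsilon = 10^{-4}$. The KL weights
merit comment: with the reconstruction as a *mean* and the KL terms as
*sums*, the exact-ELBO correspondence is $\beta = 2/(mn) \approx 10^{-4}$
at the calibration scale. Weights at or above that level sit on the
posterior-collapse boundary — and because constant weights are a stated
modelling commitment (no annealing schedules), collapse is unrecoverable
once entered, with seed-dependent outcomes. The defaults deliberately sit
below the boundary, where training is stable across seeds; the residual
coupling between reconstruction and $A$ (the genewise maps cannot exactly
cancel the $(I-A)/(I-A)^{-1}$ pair) then identifies the network. Shrinking
the encoder to 4 channels strengthens precisely that coupling, which is why
the smaller encoder recovers the network *better* than a larger one.

All weights were calibrated once on the linear-SEM simulation below and
then frozen.

## What the synthetic generator emulates — and what it does not

`simulate_grn()` draws a sparse signed network (edge probability
`density`, magnitudes uniform in `weight_range`, spectral radius of
$A^\top$ capped at 0.8 so the SEM is stable and variance inflation
bounded). `simulate_expression()` propagates i.i.d. Gaussian noise through
$(I - A^\top)^{-1}$ cell by cell, maps to the non-negative scale with
softplus (preserving the rank information the incidence construction uses,
unlike clipping), and zeroes entries independently with the dropout
probability. `simulate_clustered()` plants block mean-shifts for
cluster/module structure.

This emulates: SEM-consistent gene-gene dependence with known ground truth,
non-negative skewed marginals, dropout zeros, and separable cell
populations. It does **not** emulate UMI count distributions (no NB/ZINB
over-dispersion), library-size variation, batch effects, or
expression-dependent dropout. Passing the recovery tests therefore shows
that the estimator works when the data-generating process matches the
model's own causal assumptions; it does not certify performance on real
tissues, where preprocessing and benchmark ground truths dominate.

At the calibration conditions (50 genes, density 0.05, 300 cells, unit
noise, 20% dropout, seeds 0–2) the default configuration attains median
EPR ≈ 5 and median AUPRC ratio ≈ 3.6 against the simulated truth — these
are recomputed by the test suite, not quoted from elsewhere. Problem sizes
throughout the tests (tens of genes, hundreds of cells, a few thousand
optimizer steps) were chosen so a full run takes minutes on one CPU.

## Evaluation statistics

- **EPR**: with $K$ the number of ground-truth edges and $P$ the number of
  evaluable ordered (TF, gene) pairs excluding self-pairs,
  $\mathrm{EPR} = (TP_K / K) / (K / P)$; ties at the $K$-th rank break by
  the stored deterministic order (reproducibility over optimism). The TF
  universe is the truth's TF set when one exists, else all genes.
- **AUPRC ratio**: trapezoidal area under the per-rank precision–recall
  points, divided by the *exact expected AUPRC of a uniformly random
  ranking* (hypergeometric closed form, cross-checked against exhaustive
  enumeration in the tests). The naive $K/P$ baseline overstates random
  performance by ~20% on small instances; with the exact baseline a random
  ranking averages exactly 1, and the perfect-ranking ratio approaches
  $P/K$ for large instances.
- **Overlap coefficient** $|A \cap B| / \min(|A|, |B|)$; **NES** as the
  z-score of a motif AUC against all motif AUCs with the sample (N−1)
  standard deviation; **NMI** normalized by the arithmetic mean of the two
  entropies, **ARI**, **homogeneity**, **completeness** from the
  contingency table.
- **Latent clustering**: top 10 principal components when the latent
  exceeds 10 dimensions, a Euclidean 30-nearest-neighbour graph, and
  Louvain with its resolution binary-searched on $[10^{-3}, 10]$ (at most
  30 iterations) to hit the requested cluster count; if the interval
  collapses first, the closest count is returned with a warning.

## Degenerate inputs and edge handling

Orientation-ambiguous files (numeric header corner) are rejected rather
than silently transposed; duplicate identifiers, NA values and negative raw
values are errors. Empty filter results name the failing axis. Edges with
score exactly zero stay in the full ranking (lexical order) but never
survive a top-fraction cut when positive scores exist;
`select_top_fraction()` keeps the ceiling of fraction × n edges, matching
the top-0.5% convention used to hand edge lists to downstream regulon
analysis.

## Known limitations

- No acyclicity constraint is imposed on $A$; invertibility of
  $(I - A^\top)$ is monitored instead. Scores are undirected-skeleton-like
  in hard cases: reversed edges of true links rank high.
- Full-batch training only; attention cost grows with genes² × cells, so
  the practical ceiling is a few thousand genes after variable-gene
  selection.
- The dense (`head_style = "dense"`) configuration realizes the fully
  bilinear architecture but is *expected* to fail at network recovery; it
  exists as a documented ablation.
- Count likelihoods (NB/ZINB), KL schedules, and sparse-attention variants
  are out of scope.
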