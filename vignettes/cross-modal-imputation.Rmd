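---
title: "Cross-modal imputation of unmeasured spatial genes: model and methods"
author: "cycleImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal imputation of unmeasured spatial genes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleImpute)
```

## The problem

Imaging-based spatial transcriptomics (ST) measures expression in situ with
2-D coordinates but over a limited gene panel; dissociated single-cell
RNA-seq (SC) covers far more genes but loses position. When the two assays
profile the same tissue type, the genes they share are the only direct
molecular correspondence between them. `cycleImpute` predicts the
expression of genes *absent* from the ST panel, per ST cell, from an SC
reference.

The design premise is that the two modalities should **not** be forced
into one latent space: SC suffers dissociation dropout, amplification
noise and library-size variation, while ST carries optical background and
platform-specific biases. Each modality therefore gets its own
autoencoder, and a pair of *translators* maps between the two latent
spaces, trained so that translation respects biology (shared genes),
geometry (cycle consistency) and the target latent distribution
(adversarial alignment).

## Model

Eight multilayer perceptrons:

| network | map | hidden widths | output |
|---|---|---|---|
| ST encoder | genes → 256-d latent | 2048, 1024, 512 | linear |
| ST decoder | 256-d latent → genes | 512, 1024, 2048 | linear |
| SC encoder | genes → 512-d latent | 2048, 1024, 512 | linear |
| SC decoder | 512-d latent → genes | 512, 1024, 2048 | linear |
| translator ST→SC | 256 → 512 | 512, 512, 512, 1024, 1024 | linear |
| translator SC→ST | 512 → 256 | 512, 256, 256, 128, 128 | linear |
| discriminators (×2) | latent → score | 256, 128, 128, 64 | linear |

Every hidden layer is linear → batch normalization → LeakyReLU (negative
slope 0.01) → dropout (p = 0.2). Output layers are purely linear; decoder
outputs are clamped at zero only at inference, never inside a loss, so
clamping cannot zero gradients. The negative slope and the fan-in-scaled
uniform weight initialization are not dictated by the architecture
description; we pin the common defaults and a seeded init so that every
build is bit-reproducible.

Losses (with \(z_{ST} = E_{ST}(x_{ST})\), \(z_{SC} = E_{SC}(x_{SC})\)):

* **Reconstruction** (stage 1): \(\mathrm{MSE}(D(E(x)), x)\) per domain,
  trained independently — the ST autoencoder never sees SC data.
* **Cycle**: translate to the other latent space and back, decode in the
  source domain;
  \(L_{cyc} = \mathrm{MSE}(x^{cyc}_{ST}, x_{ST}) + \mathrm{MSE}(x^{cyc}_{SC}, x_{SC})\).
* **Identity**: decode the translated latent in the *target* domain and
  compare with the source cell at the shared gene columns via Pearson
  correlation; \(L_{ID} = (1-\rho_{ST\to SC}) + (1-\rho_{SC\to ST})\).
  Only shared output columns carry gradient, so unshared genes remain
  free to be inferred.
* **Adversarial**: hinge-loss discriminators score real versus translated
  embeddings (\(L_{disc}\), fakes detached); translators receive
  \(L_{GAN} = -E[C(T(z))]\).
* **Total translator objective**:
  \(L_{trans} = \lambda_{ID} L_{ID} + \lambda_{cyc} L_{cyc} + \lambda_{GAN} L_{GAN}\)
  with \(\lambda_{ID} = \lambda_{cyc} = 1\), \(\lambda_{GAN} = 0.1\).

The Pearson term in the identity loss is written ambiguously in scalar
notation; we compute it **per cell across the shared genes** and average
over the batch, because translation is a cell-wise operation and the loss
must be defined for any batch. The per-gene-across-cells alternative is
available via `identityLoss(..., perGene = TRUE)` for sensitivity checks.
A cell whose shared vector has zero variance contributes \(\rho = 0\)
(loss 1) with zero gradient rather than NaN.

Training is two-stage: 100 epochs of autoencoder pretraining (Adam,
lr 1e-3, batch 512), then the autoencoders are **frozen** and translators
(lr 1e-3) and discriminators (lr 5e-4, deliberately smaller to avoid
discriminator overpowering) train for 50 epochs, one discriminator step
then one translator step per batch. Freezing stabilizes the
modality-specific representations before adversarial alignment; frozen
networks run in evaluation mode (running batch-norm statistics), so their
parameters and statistics stay bit-identical through stage 2. Because the
two domains have unequal cell counts, an epoch is
\(\lceil \max(n_{ST}, n_{SC})/B \rceil\) steps over independently
shuffled samplers, recycling the smaller domain; trailing batches of size
1 are dropped because batch statistics are undefined on one row.

**Inference**: \(\hat x = D_{SC}(T_{ST\to SC}(E_{ST}(x_{ST})))\), floored
at zero — predictions live in the SC gene space, including genes never
measured in ST.

## Preprocessing

In order: genes with detection rate < 0.05 are dropped (detection rate =
fraction of cells with nonzero expression), cells with detection rate
< 0.1 are dropped (ST coordinates subset in lockstep), 2000 highly
variable genes are selected for the SC reference, per-feature values
above mean + 2 SD are clipped to that cap, and everything is square-root
transformed (a mild variance stabilizer that preserves dynamic range more
gently than log). Choices the pipeline description leaves open, pinned
here:

* **SD convention**: population (divide by N) for clipping — well defined
  at any n and deterministic.
* **Clipping scale**: statistics are computed on pre-sqrt values,
  following the narrative order of the pipeline; a second application of
  the pipeline is therefore *not* idempotent (documented, tested as
  well-defined).
* **HVG ranking**: dispersion (variance/mean) of log1p values, ties
  broken by gene name — a deterministic pin of the standard
  dispersion-based selection.
* **Shared genes are force-retained** through HVG selection: the identity
  loss needs them in the SC feature space.
* **Gene matching** across panels is case-insensitive exact symbol match;
  no ortholog/alias resolution. Duplicate names keep the column with the
  highest detection rate.

## Gene-holdout benchmarking

Shared genes are shuffled (seeded) into 5 disjoint, near-equal folds. Per
fold, the held-out genes are removed from the ST matrix *before* any
training; a fresh model is built and trained entirely within the fold;
imputation is evaluated only on the fold's genes against the measured ST
values on the sqrt scale (the model's supervision scale). A leakage audit
is armed for the whole fold: any ST tensor containing a held-out gene
name aborts the run. Preprocessing runs once on the full pair and columns
are dropped per fold, keeping fold inputs comparable.

Two ablations mirror the robustness protocols:

* **Overlap**: only a fraction {10, 25, 50, 75, 100}% of the shared genes
  is retained; subsets are nested (one seeded priority order, truncated),
  and retained genes keep their original order so that fraction 1.0 is
  exactly the plain CV. Non-retained shared genes are **removed from the
  ST panel entirely**. We initially implemented the milder intervention —
  dropping genes only from the shared map while leaving their columns in
  the ST input — and found it *inverts* the expected trend: the encoder
  still sees the genes' expression, so removing anchors while keeping
  information helps rather than hurts. Treating non-retained genes as
  unmeasured is the intervention that matches a genuinely smaller panel.
* **Sparsity**: {0, 25, 50, 75, 90}% of the raw ST nonzero entries are
  masked (seeded) before preprocessing statistics are recomputed, then
  the same CV is repeated.

The per-gene-mean baseline predicts each held-out gene by a constant;
under the zero-variance convention its PCC is exactly 0, making it the
natural floor that trained imputation must beat.

## Evaluation metrics

Per held-out gene, on the sqrt scale: Pearson correlation (population
moments; constant vector → 0), SSIM on independently min-max-normalized
vectors with C1 = 0.01, C2 = 0.03 (constant vector → all zeros), RMSE on
independently z-scored vectors (affine-invariant), 1-D Wasserstein
distance between the z-scored empirical distributions (mean absolute
difference of sorted samples), and Jensen–Shannon divergence of the
cell-wise probability profiles under **base-2 logarithms** so JS ∈ [0, 1]
(the defining equations leave the base open; the bounded variant is the
interpretable one). Genes with an all-zero measured vector are excluded
and listed. Report averages are arithmetic means over finite per-gene
entries.

Diagnostics:

* **ΔMoran's I** — per-gene difference in spatial autocorrelation between
  imputed and measured expression, with a row-standardized 6-nearest-
  neighbor weight graph (no weight scheme is dictated; kNN row-
  standardized is the common default for segmented cells). Reported:
  median, mean, and the fraction of genes within |ΔI| ≤ 0.10.
* **Neighborhood recall** — fraction of a cell's k = 15 cosine nearest
  neighbors in the source latent space found among the m = 45 neighbors
  of its translated (one-way) or cycle-translated embedding.
* **ARI / NMI / silhouette** for downstream clustering structure; the
  silhouette follows the cluster-balanced definition (mean over clusters
  of per-cluster mean widths), which differs from the per-sample mean
  when clusters are unbalanced.
* **AUPRC utility** (`prAuc`) for recovery of an externally supplied
  spatially-variable-gene reference set; calling SVGs is out of scope, the
  hook takes any reference set.

## The synthetic generator

`simulatePair()` draws a rank-R factor model shared by both modalities:
per-gene loadings (clipped Gaussian), per-gene intercepts, an exponential
link keeping expression positive and right-skewed (what the sqrt step
presumes). SC cells draw factors i.i.d.; ST cells draw them from a
spatially smooth field over random 2-D coordinates, built from 64 random
Fourier features of a Gaussian kernel (a low-rank GP approximation chosen
to stay O(n) in memory), standardized to unit variance. Counts are
Poisson draws of the (optionally log-normal-jittered) means with per-cell
library-size variation, then modality-specific dropout zeroes entries.
The ST panel is half the genes; `overlapFraction` of it is shared with
the SC panel; the SC panel holds everything except ST-only genes, so
SC-only imputation targets always exist.

`easyRegime()` (2000 ST / 3000 SC cells, 300 genes, 60% overlap, rank 8,
dropout 0.1/0.3, log-noise 0.1, library CV 0.2) is the benign study
condition; `hardRegime()` degrades it to 10% overlap and 0.7 dropout.
Noise levels not fixed by the protocol were chosen once as desk-scale
plausible values for imaging-based ST and droplet SC and are not tuned.

What the generator deliberately does **not** emulate: discrete cell
types (continuous factors suffice to test information transfer), real
platform noise spectra, segmentation errors, multi-sample batch
structure. Passing tests on this generator demonstrate that the
machinery recovers a shared low-rank program under modality-specific
noise — not that any particular real dataset pair will reach a given
accuracy.

## Problem sizes used by the test-suite and acceptance script

The published configuration (full network widths, 100 + 50 epochs,
thousands of cells) is a GPU-scale workload. All empirical checks in this
package run the same code paths at desk scale, chosen once:

* metric/loss oracles: hundreds of random instances, ≤ 200 cells;
* recovery benchmark: 500 ST / 750 SC cells, 150 genes, 60% overlap,
  rank 8, `widthScale = 0.25` (every hidden and latent width at a
  quarter), 30 + 15 epochs, batch 128, 5 folds;
* ablation trends: 350 ST / 500 SC cells, 150 genes, `widthScale = 0.2`,
  20 + 10 epochs, 2 folds per CV;
* determinism: two bit-compared CV runs at toy scale.

`widthScale` multiplies every hidden and latent width while preserving
the architecture's shape and all loss semantics; `widthScale = 1` is the
published model. Batch 128 keeps several optimizer steps per epoch at
these cell counts (with 512, an epoch would be a single step).

## Numerical choices and degenerate inputs

* Batch norm: population variance, momentum 0.1, eps 1e-5; normalization
  before activation, dropout after (the stated layer order).
* Adam moments (0.9, 0.999), eps 1e-8.
* Discriminator scores are raw linear outputs, as hinge loss expects.
* Zero-variance guards: PCC/SSIM → 0; z-scores of a constant vector →
  zeros; JS of a zero-sum vector → 1 with a warning; Moran's I of a
  constant field → 0.
* kNN ties (Moran weights, recall) break by index order — deterministic.
* All randomness flows from one master seed through fixed sub-seed
  derivations (init, samplers, dropout, fold shuffles); two runs with the
  same seed are bit-identical on CPU.

## Known limitations

* Pure-R training: practical up to a few thousand cells and a few hundred
  genes; the full-width architecture at atlas scale wants a GPU
  implementation.
* The identity loss orientation (per-cell) is a documented choice, not
  the only reading; the alternative is exposed but not the default.
* No uncertainty quantification on imputed values.
* h5ad support covers dense and CSR/CSC `X` with standard `obs`/`var`
  index layout; exotic AnnData encodings are out of scope.
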