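---
title: "Characterizing 5D spatiotemporal brain-network dynamics with spatiodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing 5D spatiotemporal brain-network dynamics with spatiodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatiodyn)
```

## The problem

Resting-state fMRI is usually summarized either by static spatial maps
(each network reduced to one fixed image) or by temporal coupling between
fixed nodes. Both views discard *spatial dynamics*: the shape, size and
position of a functional network change over the course of a scan, and
those changes can differ between clinical groups. spatiodyn implements a
framework that keeps all five dimensions — space (3), time, and network —
by regressing, at every timepoint, a voxel-wise score map for each of K
brain networks from the raw volume, and then summarizing the resulting 5D
data with interpretable statistics.

The framework has four computational layers:

1. **Per-network regressors.** One residual encoder/decoder 3D
   convolutional network per brain network maps a single fMRI volume
   (one timepoint, min-max normalized) to that network's score volume in
   [0, 1]. Stacking outputs over timepoints yields the 4D score map
   `ω_k(v, t)`; doing this for all K networks yields the subject's 5D
   representation.
2. **Voxel-wise summaries.** The time mean `ω̄(v) = Σ_t ω(v, t) / T`
   captures static amplitude; the temporal deviation
   `ω̃(v) = Σ_t |ω(v, t+1) − ω(v, t)|` captures spatial dynamics —
   it is zero exactly where the score series is constant in time.
   Group averages of either map, their difference maps, and voxel-wise
   Welch two-sample t-maps quantify group effects.
3. **Connectivity.** Static functional network connectivity (sFNC) is the
   Pearson correlation between two networks' 4D maps flattened over
   (masked voxels × all timepoints); computing all pairs gives a K × K
   matrix per subject. Sliding rectangular windows (default length 30,
   overlap 10, i.e. stride 20) give dynamic FNC; k-means over the
   vectorized window matrices yields recurring connectivity states, and
   each subject's occupancy ratio (OR) is the fraction of windows assigned
   to each state.
4. **Group inference.** Voxel-wise Welch t-maps with
   Welch–Satterthwaite p-values; FNC cell-wise Welch tests corrected by
   Benjamini–Hochberg FDR over the K(K−1)/2 upper-triangle cells.

## The regressor architecture

Each model is a U-Net-style residual regressor operating on full 3D
volumes. For the default 3 mm grid (53 × 63 × 52):

* stem: unpadded 3³ convolution 1→64 followed by a sigmoid (as in the
  published layer table, the stem activation is a sigmoid);
* three encoder blocks 64→32→16→8, each block three 3³ convolutions with
  batch normalization after each, closed by max pooling with kernel 3 and
  stride 1; dropout (rate 0.5) after the encoder;
* three decoder blocks 8→16→32→64, each two unpadded 3³ transposed
  convolutions with batch normalization after each, dropout after the
  second block;
* a final transposed convolution 64→1 and a terminal sigmoid, so outputs
  live in [0, 1];
* additive, parameter-free skip connections join the stem output and the
  first two encoder-block outputs to the decoder features with the
  identical channel-and-spatial shape (64@51·61·50, 32@47·57·46,
  16@43·53·42 for the default grid).

```{r}
model <- build_model(model_spec(), c(53, 63, 52))
summarize_parameters(model)
glance(summarize_parameters(model))
```

The table reproduces the reference architecture exactly: 367,577 trainable
parameters, with the spatial chain
51·61·50 → 47·57·46 → 43·53·42 → 39·49·38 and back to 53·63·52.

### Design choices in the architecture

Three aspects of the layer table are under-determined and were fixed as
follows.

* **Padding split.** Each encoder block must shrink every spatial
  dimension by 4; the pool contributes 2, so exactly one of the three
  convolutions is unpadded (we chose the first) and the others preserve
  shape. Parameter counts are padding-independent, so the accounting is
  unaffected.
* **Skip semantics.** The parameter totals leave no room for projection
  layers, and concatenation would change downstream counts; the skips are
  therefore additive at the three shape-matching pairs. Identity shortcuts
  *within* a block have no parameter-free form (channel counts and spatial
  sizes change inside a block) and are omitted.
* **Mirror rule for ablations.** The ablation variants add or remove one
  convolution together with one transposed convolution. To keep encoder
  and decoder shapes mirror-symmetric, encoder block *b* carries
  `tconvs_per_decoder_block[mirror(b)] − 1` unpadded convolutions; S2
  removes the unpadded convolution of encoder block 1 and one transposed
  convolution of decoder block 3, S3 adds one of each at the same sites.
  Both keep the final output shape identical, and their parameter totals
  are strictly smaller / larger than the original.

### Training

Training minimizes voxel-wise mean squared error with Adam under a
volume-based feeding policy: every (subject, timepoint) pair is one
sample, inputs are min-max normalized per volume, and the train/validation
split is by subject to avoid leakage. The learning-rate schedule is a step
decay: the published recipe gives the base rate (1e-5) and the step
(5 epochs); the decay factor is not stated and defaults to 0.9,
configurable. Early stopping watches the validation loss with a default
patience of 10 epochs, and the returned model is the best-validation
checkpoint, not the last epoch.

Two practical notes for small synthetic fixtures. First, the published
learning rate is tuned for a training set of ~1,470 volumes and hundreds
of epochs; on a desk-scale fixture (a few dozen volumes, tens of epochs) a
rate around 1e-3 is appropriate. Second, with sparse targets (most voxels
near 0) the terminal sigmoid invites a saturation trap: a large rate first
drives the output toward zero everywhere, after which the sigmoid
derivative — and with it every gradient — collapses. The package
therefore initializes the final bias to the logit of the expected target
mean (`out_bias_init`, default −3), the standard initialization for
regressors with sparse targets; this removes the mean-fitting transient
and keeps gradients alive. With these settings a single small-grid model
trains to a held-out voxel-wise correlation above 0.5 within 20 epochs
(checked in the test suite).

## The synthetic-study generator

Nothing in the statistics layer can be validated on real data inside a
test suite, so the generator produces studies with known ground truth:

* **Templates.** K two-lobed, axis-aligned Gaussian networks (value 1 at
  the primary center voxel) grouped into up to 7 named domains (SM, DMN,
  AU, CC, VI, SC, CB; the 53-network default splits 9/7/2/17/9/5/4 across
  SM/DMN/AU/CC/VI/SC/CB). Domain anchors are placed by greedy max–min
  selection over a seeded candidate pool; each network's primary lobe
  perturbs its domain anchor by ~1.5 voxels, so within-domain centers are
  closer than cross-domain ones and a domain-block structure emerges in
  connectivity. A weaker secondary lobe (relative amplitude 0.6) sits near
  the *next* domain's anchor, making networks of neighbouring domains
  spatially overlapping the way real multi-lobed network templates are.
  This overlap is not cosmetic: map-based connectivity correlates
  flattened (voxel × time) maps, and for two maps with disjoint support
  the timecourse-coupling contribution to their correlation is scaled by
  the spatial inner product of the maps — essentially zero. Without
  overlap, no amount of temporal coupling between domains would be visible
  to sFNC.
* **Timecourses.** Unit-variance AR(1) signals (low-pass, φ = 0.9) that
  mix a domain-shared latent with a private component:
  within-domain correlation equals `coupling_within` (default 0.45),
  cross-domain correlation is 0 for controls. A patient coupling effect of
  δ on a domain pair correlates the two domain latents at δ /
  `coupling_within`, shifting the network-level correlation to δ;
  requested targets outside (−1, 1) are rejected.
* **Spatial dynamics.** Each network's center and log-width follow an
  Ornstein–Uhlenbeck-style random walk (AR(1), ρ = 0.9) with stationary
  standard deviation `jitter_sd` voxels (default 0.5). Smoothness matters:
  white jitter would make the temporal-deviation maps structureless.
* **Rendering.** The network's score map at time t is its jittered
  template scaled by an amplitude in [0, 1]
  (`amp_base + amp_gain × timecourse`, defaults 0.45 and 0.12); the fMRI
  volume is the sum over networks plus i.i.d. Gaussian noise
  (`noise_sd`, default 0.05). Patients multiply amplitudes by
  `amplitude_effect` and scale jitter by `deviation_effect`, per network.

The same seed reproduces a study bit-identically, including the NIfTI
payloads. What the generator deliberately omits: hemodynamics, motion,
physiological confounds, scanner/site effects. Passing tests therefore
demonstrate that the *estimators* behave correctly on data that match
their assumptions, not that the pipeline is robust to real-world artifact
structure.

Default study sizes are desk-scale (20 + 20 subjects, reduced grids such
as 24 × 28 × 24 with 8 networks for routine work); the full 53-network,
53 × 63 × 52 configuration is reserved for integration runs.

## Statistical notes

* **Welch everywhere.** The group comparison statistic is the Welch t
  (unpooled variances, sample variances with denominator n − 1), exactly
  as the formula is written; p-values use Welch–Satterthwaite degrees of
  freedom, on which the source is silent. Voxels with zero variance in
  both groups are reported as t = 0 and excluded from the validity mask
  rather than infinite.
* **Where type-I calibration is checked.** On a null study the voxel-wise
  test is checked on the temporal-deviation maps of the noisy volumes. On
  time-mean maps the across-subject variation at network voxels is
  dominated by per-subject amplitude and jitter shared across each blob,
  so rejections are spatially correlated and a binomial band around the
  empirical rate is not a valid yardstick; on temporal-deviation maps the
  across-subject variation is dominated by independent voxel noise, so
  the observed rejection rate is comparable to its binomial error.
* **FNC features.** Correlations are computed inside a brain mask (the
  union of template supports, threshold 0.05) — full-grid background
  would dilute ρ. Windows are rectangular and untapered. k-means uses
  vectorized upper triangles (not full matrices) and unstandardized
  features by default, k-means++ initialization, Euclidean distance, 10
  seeded restarts, ties to the lowest state index. The elbow choice is
  made algorithmic as the maximum second difference of the inertia curve
  over the candidate k range (the visual criterion is not reproducible);
  with fewer than three candidates the minimum-inertia k is returned.
* **FDR.** The FNC group test corrects the K(K−1)/2 upper-triangle
  p-values with Benjamini–Hochberg at q = 0.05 and mirrors the
  significance mask to the full matrix. Note that "any BH rejection at the
  global null" is exactly a level-0.05 Simes test, so across repeated null
  studies roughly one in twenty is expected to produce a non-empty mask
  even for a perfectly calibrated implementation; a repeated-null check
  that demands at most one non-empty mask in 20 runs therefore sits on the
  boundary of what a correct implementation can guarantee.
* **Degenerate inputs.** Constant volumes min-max normalize to zero;
  zero-variance FNC features give missing correlations; all-positive
  difference maps report the negative peak as absent; duplicated k-means++
  seeds (possible on degenerate synthetic data) fall back to
  nearest-centroid assignment with ties to the lowest index.

## Problem sizes used in the test suite

The packaged tests run the full statistical pipeline at reduced scale,
chosen so the whole suite completes on a single CPU: calibration studies
use 20 + 20 subjects on grids around 20³ with 8 networks and 40
timepoints; effect-recovery studies inject `amplitude_effect = 1.3`,
`deviation_effect = 0.5` and a domain-pair coupling shift of 0.3; the
learning-sanity check trains one default-architecture model on a
16 × 18 × 16 grid with 4 networks and ≤ 30 epochs. These sizes are the
package's standing test conditions; they are deliberately far smaller
than a real cohort, which is also why the suite checks statistical
*properties* (calibration, power ordering, recovery) rather than any
particular clinical effect.

## Known limitations

* The regressors are trained per network; nothing enforces that the K
  score maps partition the signal, exactly as in the original design.
* The generator's blobs are axis-aligned Gaussians; real networks are
  neither Gaussian nor connected blobs, so spatial-overlap statistics on
  real data will differ quantitatively.
* Mean dwell time and state-transition statistics are out of scope (only
  the occupancy ratio is computed).
* The CLI trains models sequentially; for K = 53 networks at full grid
  this is an overnight run on CPU.
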