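---
title: "Structural-functional gradient coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-functional gradient coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfgc)
```

## The scientific problem

Structural connectivity (SC, white-matter pathways) and functional
connectivity (FC, temporal synchronization of activity) each admit a
low-dimensional description through *gradients*: continuous spatial axes
obtained by spectral embedding of a connectome. Structural-functional
gradient coupling (SFGC) asks how well the two hierarchies align — as a
whole cortex (macroscale) and within each canonical subnetwork — and how
that alignment relates to development, behavior, heritability and gene
expression. `sfgc` implements the full analysis chain and, because the
cohort data such analyses are usually run on are access-restricted, ships a
synthetic-data module that generates every required input with known ground
truth, so each stage can be validated by parameter recovery rather than by
eyeballing.

## Gradients

For a subject's dense symmetric connectome the pipeline is:

1. **Motion QC** — subjects with mean framewise displacement above 0.3 mm
   are excluded (`qc_filter_fd()`; the cutoff is strict `>`).
2. **Fisher z** (FC only) — `atanh` off-diagonal, diagonal set to zero so
   self-edges never enter the ranking.
3. **Proportional thresholding** — all non-diagonal weights are ranked
   globally (single ranking on the upper triangle, stable tie-break by
   index) and the strongest 10% of undirected edges are kept
   (`threshold_top_fraction()`).
4. **Cosine affinity** — pairwise cosine of the sparsified rows; negative
   cosines are clamped to zero because the Markov operator requires
   non-negative weights.
5. **Diffusion-map embedding** (`diffusion_embedding()`) — the affinity is
   reweighted anisotropically, row-normalized into a Markov operator, and
   its non-trivial right eigenvectors (by descending eigenvalue, trivial
   unit eigenvector dropped) scaled by `lambda^t` form the embedding.
   Defaults: `alpha = 0.5` (balances sampling density), `t = 0` (preserve
   the full spectrum), `D = 20` retained components.

Two numerical conventions deserve comment. First, the anisotropic
reweighting exponent: the standard normalization divides by the degree to
the power `alpha`, and that is the default; a `normalization_exponent =
"inv_alpha"` switch implements the reciprocal-exponent variant so both are
testable. Second, *variance explained* of a component is defined as
`lambda^2 / sum(lambda^2)` over the computed non-trivial spectrum, the
convention common in gradient toolboxes; `select_components()` returns the
smallest count reaching the cumulative threshold (default 0.70), capped at
`D`.

Eigenvector signs are arbitrary, so the cohort template pins each gradient
to correlate non-negatively with a fixed reference axis (the `x`
coordinate of the synthetic sphere, falling back to `y` and then `z` when
a gradient is numerically orthogonal to the reference — the mirror-
symmetric planted axes make this fallback necessary). Subjects inherit the
orientation through single-pass orthogonal Procrustes alignment to the
template (`procrustes_align()`: rotation/reflection only, no scaling or
translation; iterative generalized Procrustes would be a possible
extension). The template itself is the embedding of the element-wise mean
of the per-subject preprocessed connectomes — the simplest construction
consistent with a cohort-level template.

## Coupling

`macroscale_sfgc()` computes the cosine similarity between every pair of
functional and structural gradient columns over all vertices (length `D^2 =
400` at the default `D = 20`); `subnetwork_sfgc()` restricts the same
cosine to each parcel's vertices (length `J * D^2 = 5600` for a 7-network
by 2-hemisphere parcellation). Values are stored *signed*; absolute values
are taken only in strength summaries and cohort contrasts
(`coupling_strength()`, `cohort_coupling_difference()`). The feature order
is frozen — parcel-major, then functional gradient, then structural
gradient (`P{j}_F{d}_S{d'}`) — so feature-importance indices are stable
across runs. A zero-norm parcel sub-column yields 0 with a warning rather
than an error, so tiny parcels cannot kill a batch run.

## Harmonization

`combat_fit_transform()` implements the standard parametric empirical-Bayes
location/scale batch model: per-feature standardization from a pooled
batch + covariate fit, per-batch location/scale estimates shrunk with
normal / inverse-gamma priors, adjustment, and restoration of covariate
effects (age and sex are preserved by construction). The implementation is
authored in-package because the bridging step needs the covariate-adjusted
batch locations, which the usual interfaces do not expose; the test-suite
cross-checks the output against `sva::ComBat` to ~1e-3. `eb = FALSE`
switches to exact per-batch estimates, which are more stable for the very
small synthetic batches used in tests.

Cross-study alignment uses a bridging cohort that shares a processing
pipeline with one study and an age range with the other: a second
harmonization fit treating *study* as the batch yields the per-feature
covariate-adjusted study offset (child minus bridge), which is then added
to every subject of the non-bridged cohort (`estimate_bridge_delta()`,
`apply_bridge()`). The shift is purely additive location (the scale-
adjusted alternative is not implemented), identical for every subject, so
within-cohort covariance is untouched to machine precision. Harmonization
is applied separately to gradients, macroscale SFGC, and subnetwork SFGC
feature tables.

## Prediction

Out-of-sample association between coupling features and outcomes uses
100 replicates of family-grouped 10-fold cross-validation
(`make_family_folds()`): all members of a family share a fold, in the outer
loop and in the inner model-selection loop, so familial correlation never
leaks into test folds. Features are standardized with training statistics
only.

**Kernel ridge regression** (`fit_krr()`) uses the linear kernel and, by
default, the dual objective `(1/n)||y - psi w||^2 + lambda ||w||^2`, solved
exactly through its normal equations by one eigendecomposition of the
kernel; note this penalty is on the dual coefficients themselves, which is
*not* equivalent to the standard reproducing-kernel penalty `lambda w' psi
w` — the latter is available via `penalty = "rkhs"`. The regularization is
selected by grouped inner cross-validation from the fixed 11-value grid
`{0.01, 0.1, 0.5, 1, 5, 10, 50, 1e2, 1e3, 1e4, 1e5}`. Raw feature
importance is the primal coefficient vector `X'w`.

**Feed-forward network** (`fit_mlp()`): three fully connected layers,
hidden width 128, dropout 0.5, leaky-ReLU slope 0.2 on the first two
layers, sigmoid output for binary targets, trained with Adam (learning
rate 1e-3, batch size 32 — conventional defaults, exposed in
`mlp_spec()`) for an epoch count chosen by inner cross-validation up to
50. Back-propagation is implemented exactly (verified against central
finite differences to 1e-4), and saliency importance is the mean gradient
of the output with respect to the inputs with dropout off.

Metrics: Pearson *r* for continuous outcomes, Mann-Whitney AUC with ties
counted half for binary ones, computed per test fold and averaged within
each replicate. Pooling out-of-fold predictions across fold-specific
models was considered and rejected: under inner-CV regularization
selection the pooled correlation acquires a systematic negative bias at
null (about −0.05 to −0.08 at a few hundred subjects, because the fold
models' training fit leaks into the pooled mean), whereas the per-fold
average is unbiased; the two agree closely when real signal is present.
Importance vectors are min-max normalized on their absolute values (Eq.
`FI = (|FI0| - min) / (max - min)`), averaged across splits and methods,
then summarized as the maximum within each parcel's feature block.

## Heritability

`build_kinship()` turns zygosity and family labels into the genetic
relatedness matrix K (MZ 1, DZ/full-sib 0.5, half-sib 0.25) and the
shared-environment indicator. `fit_ace()` follows the two-stage scheme:
ordinary least squares for age/sex fixed effects, then maximum likelihood
for the non-negative variance components of the residuals under `sigma_a2
K + sigma_c2 Lambda + sigma_e2 I` (a joint fit is deliberately not the
default). The likelihood is evaluated family-block-wise — closed form for
singletons and pairs, small dense solves for larger families — which is
algebraically identical to the dense multivariate-normal density (tested
to 1e-8) but orders of magnitude faster, making the 5000-replicate
calibration runs tractable. Optimization runs on softplus-transformed
variances (boundary optima at zero variance are common) from a simplex-
grid warm start with up to five deterministic restarts; `power_simulation()`
uses the warm start plus two restarts as a speed/robustness compromise.
Pedigrees with no variation in relatedness among household members (e.g.
MZ pairs only) cannot separate A from C; such fits are flagged
non-identifiable.

Significance of the additive genetic variance uses the likelihood-ratio
statistic against the `sigma_a2 = 0` reduced model, referred to the 50:50
mixture of a point mass at zero and a chi-square with one degree of
freedom — the correct reference for a variance component on its boundary.
Power simulation draws phenotypes with total variance one over a grid of
true heritabilities and shared-environment proportions
`{0, 0.3, 0.5, 0.8}` and reports the rejection fraction at the 0.05 level.
Unimodal gradients are aggregated to parcel means
(`aggregate_gradient_phenotypes()`) so coupling and gradient heritability
can be compared by paired t-tests with Bonferroni correction.

## Spin tests

`generate_spins()` draws rotations uniform on SO(3) (orthonormalized
Gaussian frames, determinant forced to +1); the right hemisphere uses the
left rotation mirrored through the sagittal plane. Because the synthetic
cortex places each hemisphere on a longitudinal half-sphere, each
hemisphere is first unfolded onto its own full sphere (the analogue of
per-hemisphere spherical registration) so rotations act bijectively on the
domain; without this the nearest-neighbor reassignment collapses many
locations onto the hemisphere border and the null is under-dispersed.
Values are carried by nearest-original-location assignment within
hemisphere; at parcel level two targets may map to one source, which is
accepted and standard for centroid spins. Spin p-values are two-sided on
magnitude with the +1 correction (one-sided available); these are
conventions, not settled prescriptions.

## Transcriptomics

Expression is normalized within each region to a fixed total count
(10,000). Cell-type markers are the top-200 genes by Welch t-statistic of
log1p expression, type versus rest (the t-test variant is a package
choice). Genes are ranked by Spearman correlation with the regional
heritability map; enrichment of a gene set is the weighted
Kolmogorov-Smirnov running-sum extremum with exponent 1 (the common
default; exponent 0 recovers the classical KS statistic). Spatial
significance re-runs the entire correlate-rank-score pipeline on every
spun map (a map-permutation null, not a gene-label permutation), and both
the raw spin p and a BH-adjusted column are reported.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Geometry** — a Fibonacci lattice on each longitudinal half of the unit
  sphere (mirror-symmetric hemispheres); parcels are equal-count longitude
  wedges so every parcel spans the full range of the leading axis.
* **Axes** — real spherical harmonics that are even in `x`, hence
  mirror-symmetric and mutually orthogonal (an orthogonal basis is what
  prevents distinct axes from aliasing each other in the embeddings). The
  first structural axis mixes the first functional axis with a globally
  smooth companion field, with per-parcel coefficients solved in closed
  form so the within-parcel cosine equals the planted coupling strength
  exactly at the axis level.
* **Connectomes** — FC is the correlation matrix of synthetic vertex time
  series driven by the weighted axes plus a global component; SC decays
  exponentially with the correlation distance between latent
  streamline-density profiles and is floored to zero. Both blend in a
  short-range spatial kernel (weight 0.15) emulating acquisition
  smoothness; this also keeps every vertex connected under 10%
  proportional thresholding. Inter-subject variability is a single
  noise-scale knob perturbing the axes (default 0.1), since the
  literature does not constrain its covariance structure.
* **Phenotypes** — twin phenotypes are drawn exactly from the ACE
  covariance; behavioral outcomes are a sparse linear signal in chosen
  coupling features with noise scaled to a target population R^2 (default
  0.25); binary outcomes threshold an independent noisy latent at its
  median.
* **Expression** — a designated gene block has expected *Spearman*
  correlation with the target map equal to the planted value (the Gaussian
  mixing coefficient is de-attenuated via `rho_p = 2 sin(pi rho_s / 6)`);
  each cell type overexpresses a disjoint marker block at a configurable
  log-scale effect.

Default coupling strength is 0.7 in every parcel — in the middle of the
range reported for unimodal systems — with 14 parcels, 300 vertices and
site batch effects matching the harmonization model (additive location
plus multiplicative scale per feature per site).

What passing tests do *not* show about real data: the generator has no
head-motion structure beyond the mean-FD summary, no distance-dependent
tractography bias, no antagonistic (negative) FC networks, and its
gradients are exactly low-order harmonics, so real-data gradients with
mixed spectra will be recovered less cleanly than the planted ones.

### Known estimator bias at small parcels

Planting an exact within-parcel cosine for many small parcels conflicts
with global smoothness of the axis: the mixing coefficients jump at parcel
boundaries, the embedding suppresses the resulting rough component, and
per-parcel recovered coupling acquires a bias up to ~0.1 with strongly
heterogeneous planted values. Recovery experiments therefore use four
wedges at 160 vertices, where the estimator is accurate to better than
0.1; with uniform planted strength the bias at 14 parcels is below 0.08.

## Problem sizes

The `desk` preset runs 300 child subjects, 120 adults (with MZ/DZ/sibling
pairs) and a 40-subject bridging cohort at 300 vertices, 14 parcels,
`D = 20`, 200 spins, 200 power replicates per grid cell, and 10 prediction
replicates; it completes in minutes on one CPU and is bit-reproducible
under a fixed seed. The `study` preset restores the full-scale settings
(10,000 spins, 5000 power replicates, 100 prediction replicates).
Calibration tests use 5000 LRT replicates at 150+150 twin pairs, 200
replicates for spin uniformity, and 200 subjects for coupling recovery.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_subjects = 50, n_vertices = 160, n_parcels = 4,
                    coupling_strength = 0.7, seed = 1)
ax <- planted_axes(cfg)
pair <- gen_connectome_pair("sub00001", cfg, ax)
dcfg <- diffusion_config(n_components_retained = 5)
gf <- compute_gradients(pair$fc, dcfg)
gs <- compute_gradients(pair$sc, dcfg)
subnetwork_sfgc(gf, gs, ax$parcellation, D = 2)
```

## Limitations

* The coupling metric is a linear cosine; nonlinear manifold alignment and
  time-resolved coupling are out of scope.
* Single-pass Procrustes alignment; no iterative template refinement.
* No SNP-based heritability, no bivariate genetic correlations, no AE/CE
  model selection beyond the single boundary LRT.
* Spin tests only; no variogram-matched or autoregressive surrogates.
* Expression enters as a ready-made region-by-gene table; probe-to-gene
  aggregation and atlas mapping are upstream concerns.
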