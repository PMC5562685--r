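---
title: "Source-based morphometry with sbmica: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-based morphometry with sbmica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmica)
```

## The model

Source-based morphometry treats each subject's preprocessed gray-matter
volume map as a linear mixture of a small number of spatial sources:

$$X = A\,S + E,$$

with $X$ the $n \times V$ subjects-by-voxels matrix over the brain mask,
$A$ the $n \times K$ mixing matrix (ICA weights), $S$ the $K \times V$
source matrix (one spatial network per row) and $E$ noise. The working
assumptions are:

* **Linearity** — a subject's map is an additive combination of networks,
  each scaled by that subject's weight. Gray-matter volume is approximately
  additive across overlapping anatomical systems, which is what makes the
  blind-source view sensible for structural data.
* **Spatial independence and super-Gaussianity** — the sources are treated
  as independent random fields over voxels with sparse (positively-peaked)
  amplitude distributions. `sbmica` implements *non-extended* infomax with
  a logistic nonlinearity, whose separating solution is a stable fixed
  point only for super-Gaussian sources. Structural covariance networks —
  localized clusters on a near-zero background — are of exactly this type;
  a diffuse pattern covering most of the mask is not, and the generator
  refuses to produce one (see below).
* **Confounds are additive and voxelwise linear** — scanner site and sex
  enter as per-voxel additive offsets, so OLS residualization on an
  intercept + site + sex design removes them exactly.

The pipeline (`run_pipeline()`) is: smooth → residualize → whiten →
infomax → z-map + cluster tables → trajectory fits → age-range
sensitivity. Every stage is exposed as a standalone function.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `K` (components) | 20 | — | conventional component count for structural/resting-state ICA; the component count also sets the Bonferroni family size `m` |
| `fwhm_mm` | 8 | mm | standard single-subject VBM smoothing kernel; `fwhm_to_sigma()` converts to the Gaussian sigma 3.397 mm |
| `z_threshold` | 3 | z units | conventional network-extent threshold for ICA z-maps |
| `orders` | 1–3 | — | linear, quadratic and cubic age models are fitted and compared by BIC |
| `alpha`, `m` | 0.05, `K` | — | Bonferroni-corrected per-test level `alpha/m`; with `m = 20` the threshold is 2.5e-3 |
| `age_subsets` | 80, 70, 60 | years | upper bounds for the range-restriction sensitivity analysis |
| `connectivity` | 26 | — | the common neuroimaging 3-D neighbourhood; 6 and 18 are available and tested to refine it |
| infomax `lr0`, `max_iter`, `tol` | 0.1, 2048, 1e-6 | — | full-batch natural-gradient steps; the logistic contrast reaches its equilibrium output scale slowly, so small rates stall short of `tol` (the rate is halved whenever successive updates turn by more than 60°, so a large initial rate is safe) |

## What the synthetic generator emulates — and what it does not

`ground_truth()` + `synthesize()` produce cohorts with the statistical
structure the analysis targets:

* **Sources** (`make_sources()`): sums of 1–4 Gaussian blobs, optionally
  mirrored across the midline (bilateral networks), standardized over the
  mask. Draws are rejected until (a) every pair of sources has absolute
  spatial correlation below 0.15 and (b) every source has excess kurtosis
  ≥ 2. Both bounds are identifiability conditions, not cosmetics: ICA
  outputs are decorrelated by construction, so the unavoidable crosstalk
  between two estimated components is of the order of the spatial
  correlation of the corresponding true (smoothed) sources; and a
  sub-Gaussian source is an unstable fixed point of the logistic contrast
  and would be returned as a mixture.
* **Cohort** (`sample_cohort()`): ages uniform within decade bins with
  counts 93/106/86/88/116/41/6 (n = 536, range 20–86, sparse over 80),
  female fraction 273/536, three scanner sites with frequencies
  289/179/68 — the marginal structure of a large public three-site
  adult-lifespan sample.
* **Loadings**: three components decline linearly (slopes −0.040, −0.045,
  −0.050 weight/year, loading noise sd 0.2) and one follows an inverted U,
  $1 - 4\times10^{-4}(\mathrm{age}-50)^2$ with noise sd 0.033. Every
  component's deterministic-trend-to-noise ratio is between 3 and 4.5.
  Two facts drove this balance, chosen once: (i) after per-voxel
  centering, all linear trends are mutually proportional, so the
  *loading noise is the only signal that makes the mixing columns linearly
  independent* — it must dominate the voxelwise noise (default sd 0.008)
  for the whitening to resolve the individual components; (ii) the
  quadratic trend's amplitude is kept small enough that the residual ICA
  crosstalk of that component into the linear ones stays statistically
  invisible to BIC at n = 200–536, while its own quadratic t statistic
  remains ≈ 20–40.
* **Confounds**: smooth random per-site and sex offset maps (sd 0.05), plus
  a positive baseline (5) so voxel values are gray-matter-like.

Not emulated: anatomy (no tissue priors, no template registration, no
Jacobian modulation — the pipeline consumes already-normalized maps),
spatially correlated noise, site-by-age interactions, and longitudinal
structure. Passing recovery tests therefore demonstrates the correctness
of the estimation machinery under the stated generative model, not
robustness to the full messiness of real multi-site MRI.

## Numerical choices

* **Whitening**: the data are centred per voxel (across subjects) and per
  subject (across voxels), then SVD-projected to exactly `K` axes scaled to
  unit sample variance; the de-whitening operator is stored so
  `mixing %*% sources` reproduces the rank-K truncation of the centred data
  to machine precision on every run — an identity asserted by the pipeline,
  independent of ICA convergence.
* **Canonical form**: ICA leaves per-component sign and order arbitrary.
  Sources are flipped to non-negative skewness and ordered by descending
  explained variance, making runs comparable and bitwise reproducible
  under a fixed seed.
* **Polynomial fits** use powers of mean-centred age for conditioning;
  coefficients are reported in the raw-age basis via binomial
  back-transformation. The highest-order coefficient and its SE are
  identical in both bases (tested), so the t-test is basis-invariant.
* **BIC** counts the regression coefficients (`order + 1`) as parameters;
  including the error variance would add the same `ln n` to every model
  and cannot change a comparison. `RSS = 0` maps to −∞ with ties broken
  toward the lower order (parsimony), which also resolves saturated fits.
* **p-values** come from `pt()` on the magnitude of t, which is accurate in
  double precision down to ~1e-300 — printed magnitudes like 1e-77 are
  represented exactly rather than flushed to zero.
* **Smoothing** is separable Gaussian convolution with per-axis sigma in
  voxel units (anisotropy-aware), kernels truncated at 4σ, and normalized
  convolution at the array boundary (division by the smoothed all-ones
  field), so constants are exactly invariant and interior mass is
  preserved to well within 0.1%.
* **Cluster extraction** labels `{z ≥ threshold}` by union-find over the
  chosen neighbourhood; peaks tie-break toward the smallest linear index
  for determinism. The positive tail is reported by default (network
  extent is a positive-covariance statement); `negative_tail = TRUE` labels
  the negative tail separately.
* **Seeds**: a single master seed is split into per-stage seeds by
  `derive_seed(seed, stage_label)` (a fixed affine hash of the label into
  the 31-bit range), so any stage can be rerun in isolation and reproduce
  its in-pipeline behaviour.

## Design choices where the design was open

* **Site coding**: one dummy column per scanner plus an intercept is rank
  deficient, so the design uses an intercept + (L−1) reference-coded site
  indicators + a sex indicator. The residuals — the only quantity consumed
  downstream — are invariant to any full-rank coding, which the suite
  verifies by comparing reference and sum coding.
* **Grand mean re-added after residualization**, keeping the matrix on a
  positive gray-matter-like scale. The decomposition centres internally,
  so this is provably inconsequential to the ICA; it is cosmetic for
  serialized intermediates.
* **PCA reduction to exactly `K`** before ICA makes the unmixing matrix
  square and the whitened problem a pure rotation.
* **Age-range sensitivity** re-fits trajectories on subsets of subjects
  while keeping the weights from the full-cohort decomposition, isolating
  range restriction from re-estimation variability.
* **Select-then-test multiplicity**: testing the BIC-selected model's
  highest-order coefficient at `alpha/m` does *not* bound the family-wise
  error at `alpha`. Under the null, each candidate order's t statistic
  clears the corrected cut with probability ≈ `alpha/m`, and clearing the
  cut virtually guarantees that order wins the BIC comparison, so the
  per-component error rate is ~2–3× `alpha/m` (measured ≈ 0.10 family-wise
  at m = 20 over 1,000 simulated null families, versus 0.05 for the
  selection-free Bonferroni test, which the suite verifies is controlled).
  This is a property of the published procedure itself, worth keeping in
  mind when interpreting borderline components; it is negligible for
  p-values many orders of magnitude below the threshold.

## Problem sizes

The test and acceptance suites run on a 24 × 28 × 24 grid at 3 mm (≈ 6,400
in-mask voxels) with cohorts of 120–536 subjects and K = 4 latent
networks; a full synthetic pipeline run takes a couple of seconds, and the
complete suite a few minutes, on a single CPU. These sizes were chosen so
the decomposition is comfortably identified (n ≫ K, V ≫ n) while keeping
iteration fast; nothing in the implementation is specific to them, and
real-mode inputs of standard VBM dimensions are handled by the same code
paths.

## Known limitations

* Non-extended infomax only: components must be super-Gaussian. Extended
  infomax (sign-adaptive) is out of scope.
* No ICASSO-style stability resampling and no automatic choice of `K`.
* No cluster-level inference (no random-field theory): cluster tables are
  descriptive.
* Anatomical labels are out of scope; tables carry coordinates only.
* Trajectories are polynomial only — no splines or GAMs — and adjust for
  no covariates beyond age (site and sex are removed upstream).
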