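# sbmica — source-based morphometry of gray-matter networks

`sbmica` is an R implementation of source-based morphometry (SBM): the
decomposition of a subjects × voxels gray-matter volume matrix into
covariant spatial networks and per-subject network weights, followed by an
analysis of how those weights change across the adult lifespan. It is aimed
at researchers studying structural covariance networks in large structural
MRI cohorts, and at methodologists who want a fully testable, synthetic-
data-driven reimplementation of that workflow.

## The method

Given preprocessed, spatially normalized gray-matter maps for *n* subjects,
the in-mask voxels of each subject are concatenated into a row of a data
matrix **X** (*n* × *V*). After Gaussian smoothing (8 mm FWHM by default)
and voxelwise removal of scanner-site and sex confounds by OLS
residualization, **X** is factored as

**X** ≈ **A** **S**

where **A** (*n* × *K*) is the mixing matrix (ICA weights: how strongly each
subject expresses each network) and **S** (*K* × *V*) holds statistically
independent spatial sources (the networks). The factorization uses PCA
whitening to *K* dimensions followed by non-extended infomax ICA — natural-
gradient ascent of the output entropy through a logistic nonlinearity, the
classic contrast for super-Gaussian (sparse) spatial sources. *K* = 20 is
the default. Each source row is converted to a z-score map over the mask
and thresholded at *Z* ≥ 3; connected components (26-connectivity) are
tabulated with peak world coordinates (mm) and cluster sizes (mm³).

Each component's age trajectory is characterised by fitting linear,
quadratic and cubic polynomials of age to its column of **A**, selecting the
order with the smallest BIC (`n·ln(RSS/n) + (order+1)·ln(n)`), and testing
the selected model's highest-order coefficient with a two-sided t-test at
the Bonferroni-corrected level α/m (0.05/20 = 2.5 × 10⁻³). The same
analysis is repeated for age-restricted subsets (20–80, 20–70, 20–60 years)
to quantify the effect of range restriction.

A synthetic-cohort generator produces 3-D volumes with known blob-shaped
super-Gaussian sources, age-dependent loadings (linear declines and an
inverted-U quadratic), scanner/sex confounds and noise, so every stage —
smoothing, residualization, unmixing, cluster mapping, trajectory fitting —
is tested against ground truth. Recovery is quantified by optimally
matching estimated to true components (Hungarian assignment on absolute
spatial correlations) and by the Amari index.

## Worked example

A full synthetic run — 200 subjects on a 24 × 28 × 24 grid at 3 mm, four
latent networks (three linear declines, one inverted-U quadratic):

```r
library(sbmica)
cfg <- run_config(mode = "synthetic", K = 4, K_truth = 4,
                  n_subjects = 200, seed = 7, output_dir = "run7")
res <- run_pipeline(cfg)
print(res$traj)
#> trajectory_analysis: 4 components, 4 significant at p < 0.0125
#>   component selected_order     r2  beta_high      t          p significant
#> 1         1              1 0.9022 -0.0359176 -42.74 6.514e-102        TRUE
#> 2         2              1 0.8930 -0.0330513 -40.64  5.070e-98        TRUE
#> 3         3              1 0.8896 -0.0304810 -39.95  1.032e-96        TRUE
#> 4         4              2 0.9130 -0.0003246 -37.79  3.326e-92        TRUE
print(res$recovery)
#> sbm_recovery: 4 matched pairs, mean |cor| = 0.989
```

Reading the output: components 1–3 are best described by linear age models
with negative slopes (`beta_high` is the highest-order age coefficient, in
weight units per year), component 4 by a quadratic with a negative age²
coefficient — an inverted-U trajectory — and all four clear the
Bonferroni-corrected threshold (here 0.05/4). The recovery report confirms
the estimated spatial maps correlate ≥ 0.98 with the generating sources.
The run directory contains `trajectories.tsv`, `sensitivity.tsv` (age-range
subsets), `clusters.tsv` (peak coordinates in mm and sizes in mm³),
`mixing.tsv` and a `manifest.json` with checksums; rerunning the same
config and seed reproduces all of them bitwise.

Published regression tables that report R², beta with its 95% CI, t and p
side by side can be consistency-checked with `validate_report()`, which
enforces the linear-fit identities `t² = R²(n−2)/(1−R²)` and
`t = beta · 2·q₀.₉₇₅(df) / (CI_high − CI_low)`.

A thin CLI wraps the same functions: `sbm run -c config.yaml`,
`sbm simulate -c config.yaml -o dir`, `sbm validate-table table.tsv`.

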