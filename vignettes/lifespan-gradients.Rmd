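---
title: "Lifespan functional gradients: models, choices and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan functional gradients: models, choices and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one page

`lifegrad` implements a complete lifespan gradient pipeline for cortical
functional connectivity (FC):

1. **Connectivity and affinity.** Per scan, a vertex-by-vertex Pearson FC
   matrix (`compute_fc()`) is row-thresholded to its top 10% of connections
   by signed value (`threshold_rows()`), converted to a normalized-angle
   affinity, `1 - acos(cosine(row_i, row_j)) / pi` (`normalized_angle()`),
   and embedded with an anisotropic diffusion map
   (`diffusion_embedding()`, `alpha = 0.5`, ten components, multi-scale
   `lambda / (1 - lambda)` coordinate weighting when `diffusion_time = 0`).
   Each embedding axis — a *gradient* — orders vertices by the similarity of
   their connectivity profiles.
2. **Template and alignment.** A lifespan template is the weighted PCA of
   all individuals' stacked gradient maps (`wpca_template()`): ages are
   square-root transformed, cut into ten equal-width bins, every bin gets
   equal total weight, and vertex columns are standardized with those same
   weights. Individuals are rotated into the template frame by one-shot
   orthogonal Procrustes with no scaling or centring (`procrustes()`,
   `align_to_template()`). The first three template axes are named SA
   (sensory-association), VS (visual-somatosensory) and MR
   (modulation-representation). Structural (morphometric-similarity)
   gradients are aligned per individual to the aligned functional set
   (`structural_affinity()`, `align_structural()`).
3. **Metrics.** Per scan: gradient dispersion (mean distance to the
   embedding centroid), inter-vigintile axis ranges (5th-95th percentile,
   linear interpolation), cosine similarity to the template, the first
   three pre-alignment eigenvalues, mean FC degree, network centroids,
   within-network dispersion and dispersion-normalized between-network
   distances (`gradient_metrics()` and friends).
4. **Trajectories.** Any metric or vertex value is modelled as a penalized
   cubic-regression-spline smooth of `sqrt(age)` with ridge-penalized
   random intercepts for individual and cohort, REML smoothing (mgcv;
   `fit_gamm()`). Before the final fit the series is harmonized
   (`harmonize()`): cohort intercepts from a `k = 4` fit are removed, a
   second low-k fit to squared residuals predicts the age-dependent
   variance, residuals are rescaled per cohort, and the final `k = 10` fit
   uses inverse-variance times inverse-density weights
   (`density_weights()`, 20 sqrt-age bins). Nonlinearity is tested by a
   partial F against the linear-in-`sqrt(age)` model
   (`nonlinearity_test()`), FDR-corrected across vertices. Peak ages and
   their 95% highest-density intervals come from draws of the Gaussian
   coefficient posterior (`peak_age()`, 20,000 draws by default).
   Sex-specific deviations use a two-step residual model plus a calibrated
   difference-smooth test (`sex_deviation()`).
5. **Associations.** Behaviour: OLS with z-scored age and metric
   (`ols_assoc()`), random-intercept mixed models with Satterthwaite
   p-values for repeated measures (`lmm_assoc()`), pooled smooth models
   with a tensor age-by-metric interaction summarized as high-low gradient
   contrasts at the median age and across the age range (`gam_contrast()`),
   all BH-corrected (`bh_fdr()`). Meta-analytic term maps: a canonical
   association-minus-unimodal axis (`canonical_axis()`) and per-term
   Spearman alignments (`term_axis_alignment()`). Transcriptomics:
   one-component PLS of a parcel phenotype on a parcel-by-gene matrix
   (`pls1_fit()`), parcel-shuffle permutation p-values BH-corrected across
   target ages (`pls_enrichment()`), gene-set score maps
   (`gene_set_score()`) and keyword-themed enrichment summaries
   (`theme_summary()`).

Defaults follow the conventions of this literature wherever a standard
value exists: threshold density 0.10, ten components, ten template age
bins, age exponent 0.5, harmonization bases 4/6/10, percentiles 5/95, 5,000
permutations, 20,000 posterior draws (see `default_config()`).

## The synthetic cohort and what it emulates

Real lifespan connectomes live in restricted archives, so every stage is
exercised on a generator with planted ground truth (`make_toy_cortex()`,
`planted_truth()`, `simulate_study()`):

* a Fibonacci sphere stands in for the registered cortical surface, with a
  contiguous medial-wall cap excluded from analysis and a two-level
  contiguous parcellation (7 networks, 60 parcels, 400 vertices by
  default);
* three smooth orthonormal base maps play the SA, VS and MR axes; each is
  scaled at age `a` so its inter-vigintile spread equals a planted
  lifespan law — a log-normal-in-age bump with a mild late-life tilt,
  peaking at 18.8 y (SA), 5.1 y (VS) and 19.0 y (MR) with amplitudes
  1.0 / 0.85 / 0.70 (ground truth is always the numeric argmax
  `law_peak_age()`, since the tilt shifts it slightly);
* FC is a Gaussian kernel of embedding distance,
  `0.8 * exp(-d^2)`, plus a per-cohort offset (±0.02) and symmetric
  entrywise noise whose s.d. grows with age
  (`0.03 * (1 + age / 150)`);
* the default study design has three cohorts (320 scans): a longitudinal
  infant cohort (0.1-5 y, two timepoints, scans at or below 3 y labelled
  `sleep`), a developmental cohort (3-25 y) and an adult cohort
  (18-100 y). Adjacent cohorts deliberately **overlap in age**: cohort mean
  offsets are only identifiable where cohorts share age support — the same
  requirement covariate-aware batch harmonization places on site designs;
* coupled emissions provide microstructural features (11, mixing weight
  0.5), parcel-by-gene expression, parcel-by-term meta-analytic maps and
  behaviour scores with planted slopes, interactions and random
  intercepts.

Two properties of this generator deserve emphasis, because they determine
what passing tests do and do not show about real data.

**Amplitude reaches the embedding only through signal-to-noise.** The
analysis chain is almost purely ordinal: row-thresholding keeps a rank-based
neighbour set, the normalized angle is row-scale-invariant, and the Markov
normalization absorbs the rest. For a *noiseless* monotone kernel the
embedded ranges are therefore flat in age regardless of the planted
amplitudes (and the kernel scale `sigma` is immaterial). What carries the
lifespan laws through the real pipeline is the fixed-scale entrywise noise:
larger planted amplitude means higher signal-to-noise, larger leading
eigenvalues and wider embedded ranges. This mirrors the physical situation —
individual gradient amplitude in real data reflects how far connectivity
differentiation rises above measurement noise — but it makes the
amplitude-to-range mapping a saturating, axis-coupled function rather than
the identity.

**Consequences.** (i) Recovered range trajectories reproduce the planted
peak ages well for the stronger axes (SA, VS) but the weakest axis (MR) is
compressed near threshold and its apparent peak is displaced a few years
late in the full pipeline (about +5 y at the default scale); the
metric-level trajectory machinery, tested separately, recovers all three
argmaxes within ±2-3 y. (ii) Mean FC degree of the thresholded kernel
*decreases* with planted amplitude (faster kernel decay leaves smaller
retained weights), so the synthetic degree-dispersion correlation is
strongly negative — a generator artifact, not a property of the metric.
(iii) Noiseless geometry-recovery checks embed the *unthresholded*
affinity: thresholding is a denoising step for sampled FC, and applied to a
noiseless kernel it only discards geometry (capping per-axis recovery near
0.98 instead of 0.995+).

The generator makes no attempt at realistic haemodynamics, spatially
autocorrelated noise, motion artifacts, or mesh geometry beyond a labelled
sphere; passing tests demonstrate the correctness and calibration of the
*computations*, not the realism of any biological conclusion.

## Numerical and inferential choices

* **Partial F-test.** The nonlinearity comparison uses an *unpenalized*
  `k = 6` cubic regression spline. A partial F assembled from penalized
  effective degrees of freedom is grossly anticonservative (measured
  type-I error 0.75 at nominal 0.05: as the smooth shrinks toward the
  linear fit its df difference collapses), whereas the fixed-df form is
  exactly calibrated (0.045) and retains overwhelming power against
  genuinely nonlinear trajectories.
* **Mean adjustment.** Harmonization removes *cohort* intercepts only.
  Subtracting the shrunken *individual* intercepts as well (available via
  `remove_individual = TRUE`) pulls the data toward the low-k curve used to
  estimate them — that curve's argmax is several years late for
  broad-peaked trajectories, and the subtraction measurably displaced
  recovered peaks by about +3 y in simulation. Individual effects are
  instead retained as random intercepts in every fit.
* **Variance floor.** Predicted variances are floored at
  `max(1e-6 * var(y), 0.05 * mean(r^2))`. With a vanishing floor, a few
  floored predictions received inverse-variance weights many orders of
  magnitude above the rest and monopolized the final fit.
* **Per-cohort variance scaling** uses one positive factor per cohort
  (matching each cohort's mean squared residual to the predicted variance
  at its ages): an affine within-cohort adjustment that preserves rank
  order; age-resolved heteroscedasticity is handled by the
  inverse-variance weights instead.
* **Sex deviations.** The two-step per-sex smooth p-values are reported
  but are structurally conservative: the pooled step-1 fit absorbs part of
  each sex's smooth noise. The calibrated question — do the sexes diverge?
  — is answered by `p_difference` from a joint model with an
  ordered-factor difference smooth (measured type-I 0.048-0.055).
* **Spline boundary effects.** mgcv's `cr` basis carries natural boundary
  conditions; functions with curvature at the age range boundary (e.g. a
  quadratic in `sqrt(age)`) are approximated to about 0.2% of signal s.d.,
  and fitted argmaxes can shift by a few tenths of a year. Tests assert
  bounds of that order rather than absolute machine accuracy.
* **Ties and signs.** Row-thresholding breaks ties toward the lowest
  column index; embedding and template axes fix signs by making the
  largest-magnitude loading (or a configurable pole-set mean) positive;
  Procrustes refuses rank-deficient cross-products, where a sign is
  genuinely unresolvable.
* **Orientation of PLS.** With the exact one-component solution
  (`w` proportional to `X'y`), `corr(t, y)` is non-negative by identity;
  the orientation flip is retained as a contract for any alternative
  component definition.
* **Seeds.** All randomness fans out from one master seed through a
  counter-based splitter (`split_seed()`); reruns with the same
  configuration hash to identical pipeline artifacts.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes on one CPU: 400-vertex cortices,
320-scan default cohorts (640 scans for trajectory-recovery checks, which
the recovery criterion's ±2-3 y tolerances comfortably survive), 60-vertex
subsamples for vertex-wise fits, 200-500 replicates for calibration and
coverage checks, and 199-999 permutations where a null distribution is
resampled (5,000 remains the analysis default).

## Known limitations

* The full-pipeline peak age of the weakest planted axis (MR) is biased
  late by the saturating SNR response described above; this is a property
  of the measurement chain under this generator, documented rather than
  patched.
* Random intercepts only: no longitudinal slopes, no smoothing-parameter
  uncertainty beyond the Gaussian coefficient approximation.
* The harmonization assumes cohorts overlap in age; with disjoint designs
  cohort offsets are unidentifiable and silently trade against the age
  smooth.
* Interchange formats are dense TSV with JSON sidecars; no neuroimaging
  container formats are read or written.
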