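---
title: "Chemometric optimization of a cold-water botanical extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric optimization of a cold-water botanical extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoextract)
```

## The problem

Extracting plant bioactives (here: chamomile polyphenols) with cold water is
attractive because it avoids thermal degradation, but the yield and the
composition of the extract depend jointly on temperature (T), extraction time
(t) and plant quantity (Q). `chemoextract` implements the full chemometric
workflow for optimizing such a process from designed experiments:

1. **Design**: three-level full factorial (27 conditions) or face-centered
   central composite design (15 conditions), with replicate runs at the cube
   vertices and center supplying a pure-error estimate.
2. **Multiresponse condensation**: a table of many chromatographic peak
   areas is autoscaled and reduced by PCA to a single composite "extract
   quality" response (the PC1 scores).
3. **Response-surface model**: a second-order polynomial in coded factors,
   with pooled-variance *t* tests of the coefficients, hierarchical backward
   reduction, lack-of-fit ANOVA, and grid optimization over the domain.
4. **Untargeted spectral analysis**: UV-Vis spectra are SNV-pretreated and
   decomposed by ASCA into per-factor effect matrices; effect significance is
   assessed by permutation, loading significance by bootstrap.
5. **Antioxidant activity**: DPPH inhibition percentages, the
   inhibition-concentration calibration line, and the IC50.

## The model

All modelling happens on coded levels $x_i = (z_i - \bar z_i)/(\Delta z_i/2)
\in [-1, +1]$, where $z_i$ is the natural level. The response surface is the
full second-order polynomial

$$Y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \sum_i b_{ii} x_i^2,$$

fitted by least squares via QR decomposition. The standard deviation of each
coefficient is $S_c = \sqrt{S^2_{\mathrm{pooled}}\, C_{ii}}$, where
$S^2_{\mathrm{pooled}}$ pools the within-group sums of squares of replicated
conditions, $C_{ii}$ is the corresponding diagonal element of
$(\mathbf{M}'\mathbf{M})^{-1}$, and the *t* test uses the pooled degrees of
freedom $\sum_g (n_g - 1)$ rather than the residual degrees of freedom. This
keeps coefficient inference valid when the polynomial underfits: the pure
error is estimated from replication alone. Residual-based testing remains
available (`variance = "residual"`).

**Hierarchical reduction** removes, iteratively until stable, every
non-significant pure quadratic term, and removes a non-significant
interaction only once both of its parent quadratics are gone; the intercept
and all linear terms are always retained, so the reduced polynomial stays
well-defined under shifts and rotations of the factor axes. Removing terms in
passes (with a refit and retest between passes) rather than all at once lets
a term's significance change as collinear partners leave.

The **ANOVA** splits the total sum of squares about the mean into regression
(DF = number of non-intercept terms) and residual; replicate groups further
split the residual into lack of fit and pure error, each tested with an
upper-tail F. Adjusted $R^2$ is
$1 - (SS_{res}/df_{res})/(SS_{tot}/df_{tot})$.

For **ASCA**, the (SNV-pretreated) spectral matrix is decomposed as
$X = X_{mean} + X_\alpha + X_\beta + X_\gamma (+ X_{\alpha\beta} + \dots) + X_E$:
each main-effect row holds the deviation of its level-mean spectrum from the
grand mean; a PCA of each effect matrix gives per-effect scores and loadings,
and per-sample scatter is shown by projecting effect-plus-residual rows onto
the effect loadings. Effect significance uses label permutation of the tested
factor only (p = (1 + #\{SS* ≥ SS\})/(n~perm~ + 1)); loading significance
uses a percentile bootstrap interval with sign alignment to the point
estimate.

For the **DPPH assay**, inhibition is $100\,(t_0 - t_1)/t_0$ at 516 nm, the
calibration is an ordinary straight line of mean inhibition on concentration
(the assay is operated in its linear range; a saturating 4PL model is out of
scope), and $IC_{50} = (50 - b_0)/b_1$ with a delta-method standard error.

## A worked run

```{r ccd}
tab <- load_ccd_table()     # packaged 22-run composite-design table
fit <- fit_quadratic(tab$design, tab$response)
red <- reduce_hierarchical(fit, alpha = 0.05)
red$eliminated
anova_lack_of_fit(red)
optimize_response(red)$optimum_natural
```

The published antioxidant table reproduces an adjusted $R^2$ of about 98.6%,
drops only the time quadratic, keeps negative quadratic terms for
temperature and quantity and a negative temperature-time interaction, and
places the optimum at maximum quantity (2.5 g), the shortest time (32 min)
and a mild temperature (about 21-22 °C).

```{r dpph}
pts <- read.csv(chemoextract_example("dpph_inhibition.csv"), comment.char = "#")
fit_inhibition_line(pts$concentration_mg_per_ml, pts$inhibition_pct)
```

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `alpha` (elimination / stars) | 0.05 | conventional screening level; stars at 0.05/0.01/0.001 |
| `grid_step` (coded) | 0.05 | 2.5% of the domain per step: sub-degree resolution, instantaneous evaluation |
| wavelength window | 220-400 nm | the polyphenol absorption region; acquisition may span more |
| `n_perm` | 999 | p-value resolution of 0.001 at negligible cost |
| `n_boot` | 1000 | stable 95% percentile intervals |
| bootstrap `level` | 0.95 | nominal per-wavelength error rate of 5% |

Seeds are mandatory arguments for both resampling operations; there is no
hidden RNG state.

## The synthetic-data generators

No raw chromatographic or spectral data accompany the study conditions, so
every pipeline stage is exercised against generated data with known ground
truth (recorded in a `ground_truth` attribute of each dataset, seed
included):

* `simulate_areas()` draws each peak area from a latent "quality" quadratic
  surface through positive per-response loadings — reproducing the
  empirically observed structure in which all peaks load with one sign on
  PC1 — plus independent Gaussian noise. The default noise level
  (`example_truth("quality")`, sd 0.66) was chosen so that the regression F
  ratio of the fitted factorial model is near 27, the signal-to-noise regime
  of the published chromatographic model.
* `simulate_spectra()` sums Gaussian absorption bands at the class-typical
  positions (hydroxybenzoic ~250/290 nm, hydroxycinnamic ~320 nm,
  flavone/flavonol 330-370 nm) with factor-dependent amplitudes, then applies
  multiplicative gain, baseline offset and white noise — exactly the
  distortions SNV removes. Gaussian bands are adequate for testing band
  localization; they make no claim of spectro-physical realism, and passing
  tests therefore say nothing about overlapping real band shapes,
  instrument drift, or detector nonlinearity.
* `simulate_dpph()` draws the absorbance-drop response from a concave
  quadratic surface (negative temperature and quantity curvature, as
  observed) and clips to the physical range $[0, t_0]$.

## Numerical choices and degenerate inputs

* OLS is solved by QR; $C_{ii}$ is still reported from the inverse
  cross-product because the pooled-variance test needs it explicitly. A
  rank-deficient model matrix raises an error naming the collinear terms.
* PCA signs are fixed by a majority-positive-loadings rule per component
  (ties broken by the largest-magnitude loading), making scores
  deterministic across SVD implementations; the composite DOE response is
  always the raw (unscaled) PC1 score, never biplot-scaled scores.
* Level and grand means in ASCA are unweighted means of cell means, so
  mildly unbalanced layouts (dropped runs) keep the effect-matrix
  interpretation; sums of squares are additive only for balanced layouts and
  are reported as shares of the centered total.
* Bootstrap resampling is within design cells; when any cell holds a single
  run (e.g. a factorial replicated only at vertices and center) the
  generator falls back to a residual bootstrap with a warning.
* `pooled_variance()` errors when no condition is replicated (no pure
  error); coefficient tests error on an exactly zero pooled variance.
* Predictions outside the studied domain are allowed but flagged with a
  warning at the coded-natural transform.

## Design choices that were genuinely open

* **Pooled vs residual DF for coefficient tests**: pooled (replicate-based)
  is the default because pure error is the only variance estimate that does
  not depend on the model being correct; the composite-design fixture is
  tested with its replicate-based degrees of freedom as printed in the
  packaged table (seven duplicated conditions).
* **Permutation scheme**: labels of the tested factor only are permuted,
  other factors untouched. Permuting residuals under a reduced model is a
  reasonable alternative; with near-balanced layouts the two agree closely,
  and label permutation requires no model assumption.
* **Interactions in the spectral decomposition** are estimable and available
  but off by default: with single-run cells the interaction matrix absorbs
  cell-level noise, and the analyses this package mirrors interpret main
  effects.
* **Factor-to-axis mapping** is by name (T, t, Q), not by position, so
  design files may order columns freely.
* The acceptance/property simulations use problem sizes chosen for stable
  Monte-Carlo estimates at desk scale: 200 simulations for CI coverage, 200
  null datasets for permutation size, five to ten spectra sets of 36 runs
  for bootstrap localization.

## Known limitations

* The dose-response model is a straight line; IC50 from strongly saturating
  data would need a log-logistic model.
* ASCA here has no covariate adjustment (no ASCA+/LiMM-PCA) and no
  smoothing or derivative pretreatments.
* The ASCA effect-variance percentage is the raw share of the centered total
  and inflates under noise (an effect matrix absorbs $(k-1)\,p\,\sigma^2$ of
  noise in expectation); compare like with like or rely on the permutation
  p-value.
* Run-order randomization is supported but no time-drift covariate is
  modelled.
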