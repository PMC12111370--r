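---
title: "Methods: Amide III band deconvolution and cohort screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Amide III band deconvolution and cohort screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amide3)
```

This vignette is the package's account of its own science: the models it
fits, the defaults it ships, the numerical decisions behind them, and what
its validation does and does not demonstrate.

## 1. The two-stage analysis

Stage one treats the cohort as a spectral matrix (rows = samples, columns
= absorbance at each retained wavenumber in the Amide III band) and asks
which clinical factors structure it. Stage two takes a small set of
samples selected in stage one and quantifies their protein secondary
structure by decomposing the Amide III band into twelve Gaussian
components with fixed class assignments (I–V β-sheet, VI–VII random coil,
VIII–IX β-turn, X–XII α-helix), then compares samples component by
component.

## 2. Band model and constraints

Each component is an area-parameterized Gaussian,
$g(\nu) = a\,\varphi(\nu; c, \sigma)$ with
$\sigma = w / (2\sqrt{2\ln 2})$, so `area` is the integral intensity and
`fwhm` is the literal full width at half maximum. The twelve-component sum
has 36 free parameters on a 291-point band (1185–1330 cm⁻¹ at
0.5 cm⁻¹) — formally well-posed, but the bands overlap so strongly that
the unconstrained inverse problem is severely ill-conditioned (see §7).
The fit is therefore boxed:

* **centers** move at most ±2 cm⁻¹ around their initialized positions —
  the conventional lock-in for Amide III sub-bands;
* **FWHM** is confined to [7, 19] cm⁻¹. Protocols sometimes quote a
  strict 7–10 cm⁻¹ range, but measured Amide III sub-bands of GCF reach
  18 cm⁻¹; the strict box is available as
  `fit_constraints(strict_fwhm = TRUE)` and will truncate genuinely broad
  components. This discrepancy is deliberate and documented here rather
  than hidden;
* **areas** are non-negative (physical absorbance), although exact zero is
  allowed — components are never dropped, keeping all fits
  component-by-component comparable.

Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) with an
analytic Jacobian, relative-χ² tolerance 1e-10 and at most 500 iterations
per run. χ² is the reduced residual sum of squares, RSS/(N − 36), with
unit weights (no per-point variance model is assumed).

### Initialization

Candidate centers are local minima of the Savitzky–Golay-smoothed second
derivative, refined to the nearest local maximum of the fourth derivative
(sharper under overlap); the derivative traces use polynomial order 4 (the
fourth derivative requires at least order 4) over the same 25-point
window. Each library component takes the candidate inside its window
closest to the window midpoint — ties thereby break toward the midpoint —
and falls back to the midpoint when overlap has merged the candidates
away. Windows are padded by 0.5 cm⁻¹ during matching because measured
band centers occasionally sit a fraction of a wavenumber outside the
literature windows. Starting FWHM is the box midpoint; starting areas
follow from the local band height via the Gaussian height–area relation.

### Restarts and multistart

Two mechanisms address local minima, both deterministic:

* **Box re-centering**: when a center converges exactly onto a box
  boundary, the fit is restarted with that box re-centered on the
  converged value (up to 6 times). This mirrors the operator practice of
  releasing a peak that presses against its constraint; each individual
  run still respects the ±2 cm⁻¹ excursion around its starting point.
* **Multistart** (`deconvolve()`): the fit is run from (i) the derivative
  initialization with areas replaced by a linear least-squares warm start,
  (ii) the raw derivative initialization, and (iii) an all-midpoint
  initialization, keeping the lowest-χ² solution. A fit that reproduces
  the data to numerical noise ends the search early.

On noiseless reference bands this combination recovers every generating
center within 0.05 cm⁻¹ and every intensity share within 0.05 points —
the acceptance tests assert the (much looser) tabulated precisions.

### Portioned samples

A measured sample arrives as ~10 replicate portion spectra.
`deconvolve_portions()` first deconvolves the portion-averaged spectrum
(the preliminary determination of the sample's component parameters), then
fits each portion starting from those parameters under strict boxes with
no restarts. Anchoring all portions in one solution makes the
across-portion spread of each parameter reflect portion variability rather
than refitting ambiguity, which is how tabulated spreads of a few tenths
of a percentage point arise at all. Independent per-portion fits are
available (`anchor = "independent"`) for studying that ambiguity.

## 3. Preprocessing

* **Savitzky–Golay** smoothing with window 25 points and order 2. Edge
  points are fitted on truncated windows (no reflection or padding), so a
  cropped band is smoothed independently of out-of-band content, and
  smoothing commutes with cropping away from the crop edges.
* **ALS baseline**: the baseline $z$ minimizes
  $\sum_i w_i (y_i - z_i)^2 + \lambda \sum (\Delta^2 z)^2$ with
  $w_i = p$ above the baseline and $1-p$ below, iterated to a fixpoint.
  Defaults: asymmetry $p = 0.001$, convergence threshold 0.01 interpreted
  as the relative change of the baseline between iterations (the commonly
  quoted "threshold" of interactive tools is not documented; this is the
  natural reading), at most 50 iterations, and $\lambda = 10^6$ — a
  typical value for cm⁻¹-gridded FTIR that is not critical: recovered peak
  areas on baseline+peak phantoms stay within 5% of truth for
  $\lambda \in [10^5, 10^7]$, which the tests assert. Baseline correction
  is applied to the full recorded range before cropping.
* **Cropping** to 1330–1185 cm⁻¹, the Amide III analysis band.

## 4. The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes:

* a cohort of 17 participants (the study roster, five-letter codes
  encoding gender, age group, caries, periodontal and comorbidity status),
  each divided into **10 portions** with an individual spectrum per
  portion;
* per-participant component parameters drawn by perturbing a base
  parameter set: centers jittered by 0.5 cm⁻¹ (clipped to the library
  windows), FWHMs and areas by 5% relative noise;
* per-portion **multiplicative intensity scatter** of SD 0.05 — the
  "slight variation in intensity" between portions of one sample — plus
  additive Gaussian noise with SD 0.5% of the band maximum;
* a gently sloping linear baseline (intercept 0.02, slope 2e-4 per cm⁻¹)
  whose only role is to exercise the ALS stage;
* a wavenumber grid of 1185–1330 cm⁻¹ at 0.5 cm⁻¹. The nominal
  instrument resolution behind such data is 4 cm⁻¹ with zero-filling;
  the finer default grid is needed for stable derivative initialization
  and is configurable.

Published integral intensities are printed as percentages; the generator
uses them directly as areas in arbitrary units (summing to ~100), since
only relative content is analyzed downstream. All randomness is keyed on
`(seed, portion)` pairs, so any portion is bit-reproducible independently
of generation order.

The generator does **not** emulate Amide I/II bands, water-vapor lines,
ATR penetration-depth effects, instrument line-shape convolution, or
wavenumber-correlated noise. Consequences: validation against synthetic
cohorts demonstrates the correctness and calibration of the *analysis*
under the model's assumptions, not robustness to instrumental artifacts
of real spectra.

## 5. Screening statistics

* **PCA** via SVD of the centered matrix; columns are scaled to unit
  variance by default so the eigenvalues are correlation-matrix
  eigenvalues — the scale on which the Kaiser criterion (retain
  eigenvalues > 1) is defined. Zero-variance columns are dropped with a
  warning when scaling. Retention combines Kaiser with the scree elbow
  (sharpest proportional drop) when they disagree.
* **Dimension description**: per (PC, factor), a one-way ANOVA of scores
  on the factor (F, R² = SS\_between/SS\_total, p); per factor level, the
  estimate is the level-mean score minus the grand mean, tested with a
  contrast t-test against the ANOVA residual variance. That construction
  is chosen deliberately because it remains defined for single-observation
  levels, which small clinical cohorts routinely contain (a
  one-participant disease stage still receives an estimate and p-value).
  Raw p-values are reported; the flagging threshold (default 0.05) is a
  display choice, not a correction.
* **v-test**: for level $\ell$ of size $n_\ell$ among $N$ samples,
  $v = (\bar{x}_\ell - \bar{x}) / \sqrt{ (s^2/n_\ell)\,(N-n_\ell)/(N-1)}$
  with $s^2$ the overall population (1/N) variance; two-sided normal
  p-value. The sign gives the direction of the deviation.
* **Level distances**: barycenter of scores per factor level; the per-level
  statistic tabulated is the Euclidean distance of the barycenter from the
  overall center in the first 2 PCs (the full level×level matrix is also
  returned). Distance-to-center is a reading choice — the source
  convention is not fully specified — and is flagged as such here.

Rows of the spectral matrix default to portion-averaged spectra (samples
are characterized by their average profiles); per-portion rows are
available for power studies.

## 6. Pairwise comparison

`tsum_test()` computes the two-sample t-test from summary statistics
(mean, SD, n per group), Welch by default (pooled available), with a 95%
confidence interval — numerically identical to `t.test()` on raw data
with those summaries, which the tests assert to 1e-10.
`compare_samples()` applies it per component and measure (integral
intensity and relative %), then Bonferroni-adjusts with family size
$m = \text{(pairs in the run)} \times 12 \times \text{(measures)}$ —
the conservative reading appropriate when samples are reused across
pairs; a per-comparison family is selectable. Tabulated "(±)" spreads are
accepted directly as the SD input when raw portions are unavailable;
when portions are available the SDs are recomputed from them.

Calibration and power are validated by simulation at the portion level
(500 replicates): under identical generating parameters the family-wise
false-positive rate stays at the nominal level, and a +5-point shift of
component V's share is detected with power above 0.9. These simulations
draw per-portion component intensities from the portion-variability model
directly — they test the statistical decision machinery, which consumes
per-portion intensities, while the full synthesize→preprocess→deconvolve→
compare path is exercised separately by the cohort-pattern validation
(20 replicates of a four-sample cohort with a caries-linked +5-point shift
on component V and no other structured effects, in which component V must
flag exactly the mixed-caries pairs).

## 7. Known limitations: identifiability under noise

The central numerical caveat of twelve-Gaussian Amide III deconvolution is
that distinct decompositions of the same band can agree to a residual of
order 1e-4 of the band maximum. With measurement noise at 1% of the band
maximum (even averaged over 10 portions and smoothed), such decompositions
are statistically indistinguishable: the likelihood cannot say which basin
is "true", and the unconstrained Fisher information on individual
component intensities is essentially nil for the most overlapped
components (VI–VIII). What makes the procedure reproducible in practice is
the *anchoring*: boxed centers and widths around the preliminary
parameters. When those anchors are placed near the generating parameters
(as an operator does interactively, or as the average-spectrum fit does
when derivative candidates resolve), portion-level intensity shares are
recovered within a few tenths of a point; when overlap forces a window
midpoint fallback ~2 cm⁻¹ from the generating center, the fit can settle
in a neighboring basin whose shares differ by several points while fitting
the curve equally well. Validation quantifies this honestly: noiseless
recovery is essentially exact, while noisy portion-mean recovery within
the tabulated spreads is limited by this degeneracy, not by the optimizer.
Interpretation of small between-sample differences in the most overlapped
components should always be accompanied by the fitted χ² and the anchor
provenance (`source` column of the initialization).

## 8. Validation problem sizes

The shipped validation uses: the four reference parameter sets fitted
noiselessly; 20 seeds × 10 portions of 1%-noise synthesis for noisy
recovery; 500-replicate summary-level null/power simulations; a
20-replicate four-sample cohort for the comparison pattern; and
291-point spectra throughout — sizes chosen so the whole suite runs in a
few minutes on one CPU while keeping Monte-Carlo error well below the
asserted margins.
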