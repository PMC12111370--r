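# amide3

Deconvolution and multivariate analysis of FTIR Amide III spectra of
protein-containing biofluids.

## The problem

Gingival crevicular fluid (GCF) and similar biofluids carry a protein
fraction whose secondary structure shifts with disease. The Amide III
absorption band of an FTIR spectrum (1330–1185 cm⁻¹, coupled N–H bending /
C–N stretching) is sensitive to those shifts and, unlike Amide I/II, free
of water interference — but it is a superposition of many overlapping
sub-bands. `amide3` implements a two-stage analysis for such data:

1. **Screening** — principal component analysis of the spectral matrix
   (samples × wavenumbers), description of each component by categorical
   clinical factors (one-way ANOVA F, R², p; per-level barycenter
   contrasts), v-tests of factor levels against quantitative variables,
   and Euclidean distances between factor-level barycenters in PC space.
2. **Deconvolution and comparison** — decomposition of the Amide III band
   into a fixed library of **twelve Gaussian components**, each confined to
   a literature wavenumber window and assigned to a secondary-structure
   class (I–V β-sheet, VI–VII random coil, VIII–IX β-turn, X–XII α-helix),
   followed by component-wise two-sample t-tests between samples from
   portion summary statistics, Bonferroni-corrected.

The band model is

```
A(ν) = Σₖ₌₁¹² aₖ · exp( −(ν − cₖ)² / 2σₖ² ) / (σₖ√2π),   σₖ = wₖ / (2√(2 ln 2)),
```

with area `aₖ` (integral intensity), center `cₖ` and FWHM `wₖ` per
component. Fitting is box-constrained Levenberg–Marquardt: centers move at
most ±2 cm⁻¹ from their initialization (derivative-based peak search on
Savitzky–Golay-smoothed second and fourth derivatives), FWHMs stay in
[7, 19] cm⁻¹ and areas are non-negative. Relative secondary-structure
content is `100·aₖ/Σaⱼ`.

Preprocessing follows standard FTIR practice: Savitzky–Golay smoothing
(window 25 points, order 2), asymmetric least squares baseline estimation
(Whittaker smoother with asymmetric weights), band cropping.

A synthetic-data module generates portioned cohorts from the generative
model the analysis assumes (12-Gaussian band + polynomial baseline +
per-portion intensity scatter + noise), so the whole pipeline can be
validated end to end without measured spectra; the published deconvolution
parameters of four reference samples (`reference_parameters()`) serve as
ground truth.

## Worked example

```r
library(amide3)

s   <- spectrum_from_table("FOMLG")   # noiseless reference Amide III band
fit <- deconvolve(s)                  # initialize_peaks() + fit_gaussians()
summary(fit)
#>  index  assignment center area relative_pct fwhm
#>    XII alpha-helix 1317.5  3.6          3.6  8.1
#>     XI alpha-helix 1309.8  3.5          3.5 13.0
#>      X alpha-helix 1298.6  2.1          2.1 13.9
#>     IX   beta-turn 1283.0  1.6          1.6 16.5
#>   VIII   beta-turn 1269.9  4.5          4.5 18.0
#>    VII random coil 1261.8  6.0          6.0 16.4
#>     VI random coil 1251.0 17.8         17.8 13.0
#>      V  beta-sheet 1238.5 30.2         30.2 13.4
#>     IV  beta-sheet 1224.7 19.9         19.9 14.3
#>    III  beta-sheet 1213.8  7.2          7.2 14.2
#>     II  beta-sheet 1203.5  3.1          3.1 10.4
#>      I  beta-sheet 1196.4  0.5          0.5  9.6
#> reduced chi-square 3.38e-23 (converged after 1023 iterations)
```

Every fitted center, width and intensity share reproduces the generating
parameter set: component V (β-sheet) sits at 1238.5 cm⁻¹ and carries 30.2%
of the band. Class totals and a summary-statistic comparison:

```r
class_totals(fit)
#>    assignment area_total pct_total
#> 1  beta-sheet   60.90000  60.90000
#> 2 random coil   23.79993  23.79993
#> 3   beta-turn    6.10007   6.10007
#> 4 alpha-helix    9.20000   9.20000

# component V intensity share, FOMLG vs FYHHH (means/SDs over 10 portions)
tsum_test(30.2, 1.70, 10, 21.0, 2.12, 10)
#> Welch two-sample t-test from summaries
#> t = 10.71, df = 17.19, p = 5.03e-09
#> mean difference 9.2, CI [7.388, 11.01]
```

`run_pipeline(pipeline_config(seed = 1))` drives the full chain
(synthesize or load → preprocess → PCA screening → deconvolution of
selected samples → class totals → pairwise comparisons) and can export all
tables as CSV.

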