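---
title: "Spectroscopic profiling of replicative senescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic profiling of replicative senescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senespec)
```

## What the package models

Primary human fibroblasts kept in long-term culture stop dividing after a
limited number of passages — replicative senescence. Along the way the cells'
bulk biochemistry drifts: lipid acyl chains shorten, unsaturation rises,
protein secondary structure shifts toward aggregation-prone β-structures,
nuclear lamin B1 declines, and the spent medium accumulates lactate.
`senespec` implements a complete analysis chain for three readouts of that
drift:

1. **ATR-FTIR spectra of whole cells**, one spectrum per (passage,
   biological replicate, technical replicate), regressed against passage
   number by PLS1 and summarized by eight band-ratio indices;
2. **¹H-NMR spectra** of the aqueous and lipid endometabolome fractions and
   the exometabolome (spent medium), analyzed by Pareto-scaled PLS with VIP
   scores and chemical-shift assignment;
3. **lamin-B1 immunofluorescence z-stacks**, quantified as corrected total
   cell fluorescence (CTCF) per nucleus.

No public instrument data exist for this design, so the package ships a
synthetic-cohort generator that emulates the study conditions; every
downstream stage is exercised, end to end, against cohorts whose ground
truth is known exactly.

## The synthetic cohort

A cohort is a set of spectra

$$ y_i(\nu) \;=\; s_i \sum_b A_b\, m_b(p_i)\, e_{ib}\, f_b(\nu)\;+\;
   \mathrm{poly}_i(\nu) \;+\; \varepsilon_i(\nu), $$

where $f_b$ is a unit-height Gaussian, Lorentzian or pseudo-Voigt line of
fixed center and half-width at half-maximum, $A_b$ the base amplitude,
$m_b(p)$ a piecewise-linear **trend multiplier** of passage $p$ anchored at
knots (clamped outside the knot hull), $e_{ib}$ a lognormal per-(biological
replicate, band) perturbation shared by technical replicates, $s_i$ a
multiplicative scatter factor, $\mathrm{poly}_i$ a random low-order
baseline, and $\varepsilon_i$ i.i.d. Gaussian noise. Generation is a pure
function of (design, seed).

Default FTIR conditions mirror the emulated experiment: passages 4–17, five
biological × three technical replicates (210 spectra), bands at the standard
whole-cell assignments (CH₂/CH₃/olefinic stretches, ester C=O 1741, amide I
sub-bands 1693/1682/1648/1628, amide II, cholesterol esters 1169,
fingerprint bands). Trend knots are placed at passages 5, 11 and 17 —
the passages at which the profiled directions are anchored — and intermediate
passages interpolate linearly, the simplest reading of endpoint/turning-point
behavior. Lipid bands carry v-shaped trends (trough at P11) with asymmetric
endpoints so that CH₂ bands associate with early and CH₃/olefinic bands with
late passages; the antiparallel β-sheet band doubles monotonically; the
intermolecular β-sheet band rises to P11 and collapses by P17; cholesterol
esters recover at P17 but stay below their P5 level.

Two deliberate numerical choices deserve a note:

* **Axis spacing is 2 cm⁻¹** (the zero-filled storage spacing FTIR software
  typically produces at 8 cm⁻¹ optical resolution; resolution itself is
  modeled by band widths, not convolution). At 4 cm⁻¹ spacing the default
  7-point Savitzky–Golay window spans 25 cm⁻¹ and provably cannot separate
  the 1693/1682 cm⁻¹ amide I sub-bands into distinct second-derivative
  minima — the indices that read those lobes would be undefined.
* **Noise is calibrated so per-channel SNR at the tallest band is ≈ 50**
  (`noise_sd = 0.012` against a 0.6-absorbance tallest band); this is the
  anchor point for all recovery checks. Biological variability defaults to
  an 8 % lognormal spread, technical variability to additive noise plus 2 %
  scatter and a random quadratic baseline.

The NMR arm generates 4 passages × 2 replicates per fraction on a 0.2–9.8
ppm grid at 0.005 ppm. The medium fraction injects rising lactate (1.30 and
4.10 ppm, ×2.2 by P17) against falling glucose; the lipid fraction opposes
the acyl CH₂ resonances at 1.25 ppm (high at P5/P17) and 1.54 ppm (high at
P7/P11). For the aqueous phosphocholine (3.19) and glycine (3.54) trend the
source material supports two readings — elevated at P5/P7/P17 relative to
P11, or monotonically higher in old cells — so the generator exposes both
(`aqueous_trend = "results"` (default) or `"old_up"`) rather than silently
picking one.

The imaging arm draws elliptical nuclei (30 per experiment, 3 experiments,
passages 5/7/11/17) of known area over a uniform background, with per-slice
signal following the declining lamin-B1 trend (P5 ≈ P7 > P11 > P17) and
per-nucleus ground-truth CTCF equal to `z_slices × area × signal`.

What the generator does **not** emulate: ATR penetration-depth effects,
water-vapor lines, Mie scatter, NMR phasing artifacts, cell-to-cell
segmentation ambiguity. Passing recovery tests therefore demonstrate that
the *analysis chain* is correct and sensitive at realistic SNR — not that it
would survive every artifact of real instruments.

## FTIR preprocessing

The stage order is fixed: region extraction → outlier screening → baseline
correction → area normalization → (optionally) second derivative; each stage
appends itself to the set's provenance record.

* Regions use inclusive bounds; the three analysis regions are 3050–2800,
  1800–1500 and 1200–900 cm⁻¹ (plus the 1700–1600 amide I window, supported
  in configuration with a 4-factor default though no headline result depends
  on it).
* **Rubberband baseline**: subtraction of the lower convex hull of the
  spectrum, computed by a monotone-chain hull; it is exactly invariant under
  addition of affine functions of wavenumber, and a linear (two-endpoint
  chord) option exists. Constant spectra correct to zero rather than
  erroring.
* **Area normalization** scales each spectrum to unit trapezoidal integral
  of |intensity| over the current axis; it is idempotent and removes the
  pellet-amount scale.
* **Second derivative**: Savitzky–Golay with half-window 3 (7 points) and
  polynomial order 2, both configurable. The instrument software's
  "3 smoothing points" is read as points per side, because a 3-point total
  window with an order-2 fit has no smoothing freedom. The filter is exact
  on polynomials up to the fit order, edges included (one-sided fits).
* **Outlier screening**: PCA Q-residuals — squared reconstruction error
  outside the first 3 mean-centered principal components — with an
  empirical 95th-percentile cutoff and an absolute floor of 1e-10 so a
  full-rank model flags nothing. Screening runs per region, where the model
  is consumed. Both the component count and the quantile are configurable;
  the cutoff is deliberately empirical ("high values"), not a parametric
  Jackson–Mudholkar limit.

## PLS1, cross-validation, VIP

The regression engine is written in the package, not delegated: NIPALS PLS1
with X-deflation, mean-centering (FTIR default) or Pareto scaling
(mean-center then divide by √sd; the NMR metabolomics default). The
regression vector is reconstructed so predictions are an affine map of raw
spectra. Fitting stops early, with the factors found, if the residual
covariance ‖X'y‖ vanishes.

Cross-validation partitions samples into 10 random seeded segments; pooled
out-of-segment predictions are correlated with the reference passage numbers
globally (never per segment, which would be undefined for constant-response
segments). VIP scores use the standard formula
$\mathrm{VIP}_j^2 = p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a$
with unit-norm weights, so $\sum_j \mathrm{VIP}_j^2 = p$ on every fit.

Two independent routes guard the implementation: at full rank PLS1 must
reproduce the ordinary least-squares solution, and an improved
kernel-algorithm PLS1 (working entirely from X'X and X'y, no deflation)
must reproduce the NIPALS regression vector to 1e-8 — the two algorithms
are algebraically equivalent for a univariate response, which is also why
the choice between them cannot matter for the results.

A small-sample caveat the tests encode explicitly: with only 8 spectra per
NMR fraction, segment cross-validation under the *null* (no
passage-dependent signal) produces strongly **negative** R_cv, because each
held-out prediction collapses toward the training mean, which anticorrelates
with the held-out response. The meaningful null guarantee at that sample
size is the absence of optimistic (positive) R_cv, and that is what the
suite asserts; at the FTIR cohort size (n = 210, permutation null) R_cv is
centered on zero as expected.

## Band indices

Eight indices are computed per sample. From second-derivative spectra, band
intensity is the absolute depth of the negative lobe at the local minimum
nearest the nominal center within ±8 cm⁻¹ (the tolerance absorbs the small
assignment variants 3010/3013, 1733/1741, 2956/2959 used interchangeably in
the literature); from non-derivative normalized spectra, the amide I and II
peak heights are the maxima of the 1700–1600 and 1580–1500 cm⁻¹ windows.

| index | formula |
|---|---|
| acyl chain length | (I₂₈₅₁+I₂₉₂₂)/(I₂₉₅₉+I₂₈₇₁) |
| unsaturation | I₃₀₁₃/(I₂₈₅₁+I₂₉₂₂) |
| triglycerides | I₁₇₄₁ |
| total protein | I(amide I) + I(amide II) |
| antiparallel β share | I₁₆₉₃/(I₁₆₉₃+I₁₆₈₂+I₁₆₂₈) |
| intermolecular β share | I₁₆₂₈/(I₁₆₉₃+I₁₆₈₂+I₁₆₂₈) |
| fibril ratio | I(amide II)/I(amide I) |
| cholesterol esters | I₁₁₆₉ |

Total protein is the *sum* of the amide peaks (the ratio is already the
fibril index). A band whose lobe cannot be located yields a flagged `NA`
for the indices that use it, never a crash. Whether the original analyses
read fixed channels or located minima is not documented; located minima
within a tolerance window is the interpretation implemented, and it makes
the indices robust to ±1-channel grid offsets.

## NMR pipeline

Per fraction: area normalization → exclusion of the water (4.85–4.65 ppm)
and chloroform (7.50–7.00 ppm) windows → alignment → Pareto-PLS1 against
passage → assignment of the top-VIP channels. Alignment is a deliberately
simplified stand-in for hierarchical peak alignment: each spectrum is
shifted by the integer-channel lag maximizing cross-correlation with the
mean (or a chosen reference), capped at 0.03 ppm, with capped shifts
flagged. Assignment matches picked peaks to a per-fraction table of
diagnostic shifts at 0.02 ppm tolerance (~2 channels at the default grid),
ties broken by distance then name.

## CTCF

Stacks are sum-projected over z; for each nucleus,
`CTCF = Σ(nucleus) − area × mean(background)`. The background is a
caller-supplied mask; `background_annulus()` builds the standard automated
analogue of a manually drawn adjacent region — a 2-pixel dilation ring
excluding all nuclei. CTCF is exactly zero on uniform images, invariant to
constant offsets, and linear in intensity scaling; on generated stacks the
recovered value matches ground truth within a noise-scaled tolerance.
Nucleus segmentation is intentionally out of scope (masks are inputs),
matching the manual-ROI workflow the measurement comes from.

## Group statistics

`select_and_compare()` routes by distribution: per-group Shapiro–Wilk at
0.05; all groups normal → one-way ANOVA with Tukey's HSD; otherwise
Kruskal–Wallis with Dunn's z-tests, Bonferroni-adjusted (the conventional
default of biology stats software; the adjustment is configurable). A
zero-variance group forces the non-parametric route with a warning. The
route taken is recorded in the result. Stars follow the strict thresholds
p < 0.05/0.01/0.001/0.0001. Under the null the family-wise rejection rate
sits in [0.03, 0.07] at α = 0.05 (Monte Carlo, 1000 seeded replicates, in
the test suite). `population_doubling_time()` implements
`elapsed × ln 2 / ln(n_end/n_start)`.

## Problem sizes and determinism

The acceptance-level checks run the full study geometry: 210 FTIR spectra ×
1551 channels, 8 NMR spectra × ~1900 channels per fraction, 360 nuclei.
Unit tests use reduced cohorts (2–5 passages, 1–2 replicates) chosen to
exercise every code path quickly; Monte-Carlo suites use 200 permutations
(PLS null), 1000 replicates (type-I control) and 3000 renders (noise
calibration). All randomness flows through explicit seeds; generators save
and restore the caller's RNG state, and a pipeline rerun with the same
configuration is bit-identical.

## Known limitations

* The aligner recovers rigid shifts only; it will not correct
  peak-specific (local) misalignment the way hierarchical alignment does.
* Indices depend on resolvable second-derivative lobes; heavily overlapped
  sub-bands (closer than ~10 cm⁻¹ at these widths) merge and are reported
  as flagged missing values rather than guessed.
* The NMR fractions use n = 8; their PLS models are exploratory
  (scores/VIP), and cross-validated correlations at that size are
  pessimistically biased (see above).
* PDT helper aside, no growth-curve modeling is attempted; the anchor
  doubling times cannot be reproduced without the underlying cell counts,
  which were never published.
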