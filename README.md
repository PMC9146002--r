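# senespec

Spectroscopic profiling of replicative senescence in long-term cultures of
primary human fibroblasts.

Primary fibroblasts passaged for months drift toward senescence, and that
drift leaves measurable traces in three cheap, label-light readouts:
whole-cell ATR-FTIR spectra, ¹H-NMR spectra of the endo- and exometabolome,
and lamin-B1 immunofluorescence of nuclei. `senespec` implements the full
analysis chain for all three — for spectroscopists and cell biologists who
want a reproducible, scriptable alternative to point-and-click chemometrics
software — together with a synthetic-cohort generator that emulates the
study design (passages 4–17, five biological × three technical FTIR
replicates, four NMR timepoints × two replicates, 30 nuclei × three
experiments × four passages), so every stage is testable end to end without
instrument data.

## The methods at the core

* **FTIR preprocessing** — region extraction (3050–2800, 1800–1500,
  1200–900 cm⁻¹), PCA Q-residual outlier screening, rubberband (lower
  convex hull) baseline correction, area normalization, Savitzky–Golay
  second derivatives (7-point window, order 2).
* **PLS1 regression against passage number** (NIPALS, written here, with a
  kernel-algorithm cross-check): for mean-centered X and response y,
  factors are extracted as w ∝ Xᵀy, t = Xw with X-deflation; predictions
  are ŷ = Xβ + b₀; calibration and 10-segment cross-validated Pearson
  correlations (R_cal, R_cv), β-coefficient and VIP spectra, with
  Σⱼ VIPⱼ² = p.
* **Eight band-ratio senescence indices** from second-derivative lobe
  depths and amide peak heights, e.g. acyl chain length
  (I₂₈₅₁+I₂₉₂₂)/(I₂₉₅₉+I₂₈₇₁) and the antiparallel β-sheet share
  I₁₆₉₃/(I₁₆₉₃+I₁₆₈₂+I₁₆₂₈).
* **NMR pipeline** — normalization, water/chloroform exclusion,
  cross-correlation alignment, Pareto-scaled PLS with VIP, chemical-shift
  assignment (lactate 1.30/4.10, phosphocholine 3.19, glycine 3.54 ppm, …).
* **CTCF** — sum z-projection, then per nucleus
  CTCF = Σ(nucleus) − area × mean(adjacent background).
* **Group statistics** — Shapiro–Wilk-routed ANOVA/Tukey or
  Kruskal–Wallis/Dunn with significance stars, and the population doubling
  time helper PDT = Δt·ln2/ln(N_end/N_start).

See `vignette("senescence-profiling")` for models, assumptions, parameter
defaults and design rationale.

## Worked example

```r
library(senespec)
library(dplyr)

cohort <- generate_ftir_cohort(cohort_design(seed = 1))
cohort
#> <spectra_set> 210 spectra x 1551 channels [ftir], axis 4000..900

model <- cohort |>
  ftir_preprocess(1500, 1800) |>       # amide region, SG 2nd derivative
  pls_passage_model(n_factors = 3, n_segments = 10, seed = 2)
model
#> <senes_pls> 3 factor(s), 151 variables; R_cal = 0.942, R_cv = 0.914
```

R_cal is the Pearson correlation between PLS-predicted and true passage
numbers on the training cohort; R_cv the same for pooled out-of-segment
predictions — 0.94/0.91 says the amide-region spectral profile tracks
passage closely at the default signal-to-noise. `autoplot(model)` draws the
predicted-vs-reference plot, `plot_coefficients(model, "beta")` the
β-spectrum.

```r
compute_band_indices_regions(cohort) |>
  filter(passage %in% c(5, 11, 17)) |>
  group_by(passage) |>
  summarise(acyl = mean(acyl_chain), antiparallel = mean(antiparallel_ratio))
#>   passage  acyl antiparallel
#> 1       5  1.83        0.193
#> 2      11  1.12        0.304
#> 3      17  1.18        0.460
```

Acyl chain length dips at passage 11 and partially recovers (the v-profile
of the lipid bands); the antiparallel β-sheet share rises monotonically —
the oligomer-accumulation signature.

```r
run_fraction_analysis(generate_nmr_cohort("medium", seed = 1), seed = 2)$top_assignments
#>   peak_ppm metabolite matched_shift distance   vip
#> 1     1.3  lactate              1.3 6.66e-16  8.21   ...

img <- generate_nucleus_stacks(imaging_design(seed = 1))
ct  <- quantify_ctcf(img$stacks, img$truth)
summarize_ctcf(ct)$by_passage
#>   passage  n    mean     sd
#> 1       5 90 102165. 10226.
#> 2       7 90  97498. 10106.
#> 3      11 90  60463.  6419.
#> 4      17 90  30035.  2823.
select_and_compare(ct, "ctcf", "passage")
#> <comparison_result> anova_tukey on 'ctcf': omnibus p = 4.6e-207 (****)
```

The exometabolome's top-VIP channels assign to lactate, and nuclear CTCF
falls by two thirds from passage 5 to 17 with every pairwise contrast
significant — the expected senescence picture.

`run_senescence_pipeline(senescence_config(seed = 1))` chains all of the
above into one seeded, bit-reproducible report.

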