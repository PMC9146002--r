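#' Define a passage-dependent amplitude trend
#'
#' A trend is a piecewise-linear multiplier of a band's base amplitude as a
#' function of cell passage, anchored at knots. Passages outside the knot hull
#' are clamped to the nearest knot. Trends encode the direction of change of a
#' spectral feature over a long-term culture: constant, monotone, v-shaped
#' (decrease then recovery), or inverted-v (rise then collapse).
#'
#' @param kind one of `"constant"`, `"linear"`, `"monotone_increasing"`,
#'   `"v_shape"`, `"inverted_v"`.
#' @param knots two-column matrix-like (passage, multiplier) or a data frame
#'   with columns `passage` and `mult`; passages strictly increasing,
#'   multipliers strictly positive.
#' @return an object of class `trend_spec`.
#' @examples
#' tr <- trend_spec("v_shape", data.frame(passage = c(5, 11, 17),
#'                                        mult = c(1, 0.5, 1)))
#' trend_multiplier(tr, 8)  # 0.75
#' @export
trend_spec <- function(kind = c("constant", "linear", "monotone_increasing",
                                "v_shape", "inverted_v"),
                       knots = data.frame(passage = 5, mult = 1)) {
  kind <- match.arg(kind)
  knots <- as.data.frame(knots)
  if (!all(c("passage", "mult") %in% names(knots))) {
    names(knots)[1:2] <- c("passage", "mult")
  }
  if (any(knots$mult <= 0)) abort("trend multipliers must be > 0")
  if (is.unsorted(knots$passage, strictly = TRUE)) {
    abort("knot passages must be strictly increasing")
  }
  if (kind == "v_shape" && nrow(knots) >= 3) {
    i <- which.min(knots$mult)
    if (i == 1L || i == nrow(knots)) {
      abort("v_shape trend must have its minimum at an interior knot")
    }
  }
  if (kind == "inverted_v" && nrow(knots) >= 3) {
    i <- which.max(knots$mult)
    if (i == 1L || i == nrow(knots)) {
      abort("inverted_v trend must have its maximum at an interior knot")
    }
  }
  structure(list(kind = kind, knots = knots), class = "trend_spec")
}

#' Evaluate a trend multiplier at a passage
#'
#' Piecewise-linear interpolation through the knots; exact at knots; passages
#' outside the knot hull are clamped to the nearest knot (rule = 2).
#'
#' @param trend a [trend_spec()].
#' @param passage integer passage number(s).
#' @return numeric multiplier(s), same length as `passage`.
#' @export
trend_multiplier <- function(trend, passage) {
  stopifnot(inherits(trend, "trend_spec"))
  k <- trend$knots
  if (nrow(k) == 1L) return(rep(k$mult, length(passage)))
  approx(k$passage, k$mult, xout = passage, rule = 2)$y
}

#' Define a spectral band
#'
#' A band is a single absorption (FTIR) or resonance (NMR) line with a fixed
#' center and width, a base amplitude, and a passage trend. Widths are
#' half-width at half-maximum in the axis units (cm-1 or ppm).
#'
#' @param name band label.
#' @param center band center (cm-1 or ppm).
#' @param width half-width at half-maximum, same units as `center`; > 0.
#' @param base_amplitude peak height in absorbance units at trend multiplier 1.
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param mix Lorentzian fraction in \[0, 1\] for `pseudo_voigt`.
#' @param trend a [trend_spec()].
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(name, center, width, base_amplitude,
                      shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                      mix = 0.5, trend = trend_spec("constant")) {
  shape <- match.arg(shape)
  if (width <= 0) abort("band width must be > 0")
  if (base_amplitude < 0) abort("base_amplitude must be >= 0")
  if (mix < 0 || mix > 1) abort("pseudo_voigt mix fraction must be in [0, 1]")
  structure(list(name = name, center = center, width = width,
                 base_amplitude = base_amplitude, shape = shape, mix = mix,
                 trend = trend),
            class = "band_spec")
}

#' Trend-adjusted amplitude of a band at a passage
#'
#' @param band a [band_spec()].
#' @param passage integer passage number(s).
#' @return `base_amplitude * trend_multiplier(trend, passage)`.
#' @export
trend_amplitude <- function(band, passage) {
  stopifnot(inherits(band, "band_spec"))
  band$base_amplitude * trend_multiplier(band$trend, passage)
}

# Unit-height line shapes parameterized by HWHM.
lineshape <- function(x, center, hwhm, shape, mix = 0.5) {
  g <- exp(-log(2) * ((x - center) / hwhm)^2)
  if (shape == "gaussian") return(g)
  l <- 1 / (1 + ((x - center) / hwhm)^2)
  if (shape == "lorentzian") return(l)
  mix * l + (1 - mix) * g
}

#' Evaluate the noise-free band sum on an axis
#'
#' Analytic sum of all band line shapes at the given passage; the oracle for
#' what a rendered spectrum looks like before baseline, scatter and noise.
#'
#' @param bands list of [band_spec()].
#' @param axis numeric axis (cm-1 or ppm), strictly monotone.
#' @param passage passage at which trends are evaluated.
#' @param mult extra amplitude multipliers, one per band (biological
#'   perturbation); default all 1.
#' @return numeric vector of intensities.
#' @export
band_sum <- function(bands, axis, passage, mult = rep(1, length(bands))) {
  if (length(bands) == 0L) abort("band list must not be empty")
  out <- numeric(length(axis))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    a <- trend_amplitude(b, passage) * mult[[i]]
    out <- out + a * lineshape(axis, b$center, b$width, b$shape, b$mix)
  }
  out
}

v3 <- function(p5, p11, p17) {
  trend_spec("v_shape", data.frame(passage = c(5, 11, 17),
                                   mult = c(p5, p11, p17)))
}
mono2 <- function(p5, p17) {
  kind <- if (p17 >= p5) "monotone_increasing" else "linear"
  trend_spec(kind, data.frame(passage = c(5, 17), mult = c(p5, p17)))
}

#' Default FTIR band library
#'
#' The bands and passage trends used by the default synthetic fibroblast
#' cohort. Centers follow the standard mid-IR assignments for whole cells:
#' olefinic =CH (3013), CH3/CH2 stretches (2959/2922/2871/2851), ester C=O of
#' triglycerides (1741), amide I secondary-structure sub-bands (antiparallel
#' beta 1693, beta-sheet 1682, alpha-helix 1648, intermolecular beta 1628),
#' amide II sub-bands (1554/1543/1509), cholesterol esters (1169) and
#' fingerprint carbohydrate/phosphate bands. Lipid bands carry v-shaped
#' trends (decline to passage 11, recovery by 17); the antiparallel
#' beta-sheet band rises monotonically; intermolecular beta-sheet rises then
#' collapses at senescence.
#'
#' @return list of [band_spec()] objects.
#' @export
ftir_band_library <- function() {
  list(
    band_spec("amide_A", 3290, 70, 0.60, trend = trend_spec("constant")),
    band_spec("olefinic_CH", 3013, 8, 0.15, trend = v3(0.95, 0.25, 1.25)),
    band_spec("CH3_asym", 2959, 9, 0.35, trend = v3(0.95, 0.75, 1.15)),
    band_spec("CH2_asym", 2922, 9, 0.55, trend = v3(1.0, 0.50, 0.85)),
    band_spec("CH3_sym", 2871, 9, 0.25, trend = v3(0.95, 0.75, 1.15)),
    band_spec("CH2_sym", 2851, 9, 0.45, trend = v3(1.0, 0.50, 0.85)),
    band_spec("ester_CO", 1741, 10, 0.30, trend = v3(1.0, 0.45, 1.10)),
    band_spec("beta_antiparallel", 1693, 5, 0.25, trend = mono2(1.0, 2.0)),
    band_spec("beta_sheet", 1682, 5, 0.35, trend = trend_spec("constant")),
    band_spec("alpha_helix", 1648, 9, 0.60, trend = mono2(1.0, 1.3)),
    band_spec("beta_intermolecular", 1628, 5, 0.45,
              trend = trend_spec("inverted_v",
                                 data.frame(passage = c(5, 11, 17),
                                            mult = c(0.8, 1.2, 0.6)))),
    band_spec("amide_II_a", 1554, 8, 0.45, trend = mono2(1.0, 1.25)),
    band_spec("amide_II_b", 1543, 8, 0.40, trend = mono2(1.1, 0.90)),
    band_spec("amide_II_c", 1509, 8, 0.20, trend = mono2(1.1, 0.85)),
    band_spec("chol_ester", 1169, 10, 0.25,
              trend = trend_spec("v_shape",
                                 data.frame(passage = c(5, 11, 17),
                                            mult = c(1.0, 0.45, 0.70)))),
    band_spec("phosphate_sym", 1085, 12, 0.50, trend = mono2(1.0, 1.25)),
    band_spec("glycogen", 1030, 12, 0.45, trend = mono2(1.15, 0.85)),
    band_spec("carbohydrate_CO", 970, 10, 0.20, trend = mono2(0.90, 1.20))
  )
}

#' Default NMR band library per metabolome fraction
#'
#' Resonances (ppm) with passage trends emulating the reported senescence
#' metabolome: the spent-medium (exometabolome) fraction injects rising
#' lactate (1.30 and 4.10 ppm); the aqueous endometabolome carries the
#' phosphocholine (3.19) and glycine (3.54) trend; the lipid fraction opposes
#' acyl-chain CH2 resonances at 1.25 and 1.54 ppm.
#'
#' The aqueous phosphocholine/glycine direction is ambiguous in the source
#' material, so both readings are exposed: `aqueous_trend = "results"`
#' (elevated at passages 5, 7 and 17 relative to 11) or `"old_up"` (monotone
#' increase toward senescence).
#'
#' @param fraction `"aqueous"`, `"lipid"` or `"medium"`.
#' @param aqueous_trend which reading of the phosphocholine/glycine direction
#'   to encode; see Details.
#' @return list of [band_spec()] objects.
#' @export
nmr_band_library <- function(fraction = c("aqueous", "lipid", "medium"),
                             aqueous_trend = c("results", "old_up")) {
  fraction <- match.arg(fraction)
  aqueous_trend <- match.arg(aqueous_trend)
  w <- 0.012  # HWHM in ppm, ~2.4 grid steps at the default 0.005 ppm axis
  pc_trend <- if (aqueous_trend == "results") {
    trend_spec("v_shape", data.frame(passage = c(5, 7, 11, 17),
                                     mult = c(1.3, 1.3, 1.0, 1.3)))
  } else {
    mono2(1.0, 1.6)
  }
  switch(fraction,
    aqueous = list(
      band_spec("phosphocholine_NCH3", 3.19, w, 0.80, trend = pc_trend),
      band_spec("glycine_CH2", 3.54, w, 0.60, trend = pc_trend),
      band_spec("lactate_CH3", 1.30, w, 0.40),
      band_spec("lactate_CH", 4.10, w, 0.12),
      band_spec("alanine_CH3", 1.47, w, 0.30),
      band_spec("creatine_CH3", 3.03, w, 0.30)
    ),
    lipid = list(
      band_spec("acyl_CH2_bulk", 1.25, 0.02, 1.00,
                trend = trend_spec("v_shape",
                                   data.frame(passage = c(5, 11, 17),
                                              mult = c(1.2, 0.85, 1.2)))),
      band_spec("acyl_CH2_beta", 1.54, 0.015, 0.50,
                trend = trend_spec("inverted_v",
                                   data.frame(passage = c(5, 11, 17),
                                              mult = c(0.85, 1.2, 0.85)))),
      band_spec("acyl_CH3", 0.88, 0.015, 0.60),
      band_spec("olefinic_HC", 5.33, 0.015, 0.30)
    ),
    medium = list(
      band_spec("lactate_CH3", 1.30, w, 0.80, trend = mono2(1.0, 2.2)),
      band_spec("lactate_CH", 4.10, w, 0.25, trend = mono2(1.0, 2.2)),
      band_spec("glucose_ring", 3.40, w, 0.90, trend = mono2(1.2, 0.70)),
      band_spec("glucose_anomeric", 5.22, w, 0.30, trend = mono2(1.2, 0.70)),
      band_spec("glutamine_CH2", 2.45, w, 0.30),
      band_spec("alanine_CH3", 1.47, w, 0.20)
    )
  )
}
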