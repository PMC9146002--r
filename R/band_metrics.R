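#' Default band registry for the senescence indices
#'
#' Nominal centers of the bands entering the eight indices, the source
#' spectrum each is read from, and the search tolerance. Second-derivative
#' bands are read as the absolute depth of the negative lobe nearest the
#' nominal center; the amide I/II intensities come from non-derivative
#' normalized spectra. Centers follow the index formulas (3013, 1741, 2959);
#' the +-8 cm-1 search window absorbs the small assignment variants (3010,
#' 1733, 2956) quoted elsewhere for the same vibrations.
#'
#' @return tibble with `name`, `center`, `tolerance`, `source`.
#' @export
band_registry <- function() {
  tibble(
    name = c("I3013", "I2959", "I2922", "I2871", "I2851",
             "I1741", "I1693", "I1682", "I1628", "I1169"),
    center = c(3013, 2959, 2922, 2871, 2851, 1741, 1693, 1682, 1628, 1169),
    tolerance = 8,
    source = "second_derivative"
  )
}

# Local minima indices of v (interior channels).
local_minima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1)] <= v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1L
}

#' Peak intensity of a second-derivative band
#'
#' Absorbance bands appear as negative lobes in the second derivative; the
#' intensity is the absolute value of the spectrum at the local minimum
#' nearest `center` within `center +- tolerance`.
#'
#' @param axis,y axis and second-derivative intensities of one spectrum.
#' @param center nominal band center.
#' @param tolerance half-width of the search window (default 8).
#' @param band_name used in error messages.
#' @return list with `intensity` (absolute lobe depth) and `located_center`.
#' @export
peak_intensity <- function(axis, y, center, tolerance = 8,
                           band_name = as.character(center)) {
  win <- which(axis >= center - tolerance & axis <= center + tolerance)
  if (!length(win)) abort(sprintf("band %s: window outside axis", band_name))
  mins <- local_minima(y)
  mins <- mins[mins %in% win & y[mins] < 0]
  if (!length(mins)) {
    abort(sprintf("band %s: no second-derivative minimum within %g of %g",
                  band_name, tolerance, center))
  }
  i <- mins[which.min(abs(axis[mins] - center))]
  list(intensity = abs(y[i]), located_center = axis[i])
}

#' Amide I / amide II peak intensity from non-derivative spectra
#'
#' Maximum normalized intensity within 1700-1600 cm-1 (amide I) or
#' 1580-1500 cm-1 (amide II).
#'
#' @param axis,y axis and intensities of one baseline-corrected,
#'   area-normalized (non-derivative) spectrum.
#' @param which `"amideI"` or `"amideII"`.
#' @return maximum intensity in the window.
#' @export
amide_intensity <- function(axis, y, which = c("amideI", "amideII")) {
  which <- match.arg(which)
  w <- if (which == "amideI") c(1600, 1700) else c(1500, 1580)
  win <- axis >= w[1] & axis <= w[2]
  if (!any(win)) abort(sprintf("%s window [%g, %g] absent", which, w[1], w[2]))
  max(y[win])
}

#' Compute the eight band-ratio senescence indices
#'
#' Per sample, from second-derivative band depths `I_v` and non-derivative
#' amide peak heights:
#' \itemize{
#'   \item acyl_chain = (I2851 + I2922) / (I2959 + I2871) — acyl chain length
#'   \item unsaturation = I3013 / (I2851 + I2922) — olefinic / CH2
#'   \item triglycerides = I1741 — ester C=O depth
#'   \item total_protein = I_amideI + I_amideII (non-derivative)
#'   \item antiparallel_ratio = I1693 / (I1693 + I1682 + I1628)
#'   \item intermolecular_ratio = I1628 / (I1693 + I1682 + I1628)
#'   \item fibril_ratio = I_amideII / I_amideI (non-derivative)
#'   \item cholesterol_esters = I1169
#' }
#' A band whose lobe cannot be located yields NA for the indices that use it
#' (with a warning naming sample and band), never an error.
#'
#' @param deriv processed second-derivative [spectra_set()] covering
#'   3050-2800, 1800-1500 and 1200-900 cm-1 (one set spanning them, or the
#'   concatenation produced by [ftir_preprocess()] per region via
#'   [compute_band_indices_regions()]).
#' @param nonderiv baseline-corrected, area-normalized non-derivative
#'   [spectra_set()] covering 1800-1500 cm-1; same samples as `deriv`.
#' @param registry band registry tibble, see [band_registry()].
#' @return `IndexTable`: tibble with sample metadata and the eight indices.
#' @export
compute_band_indices <- function(deriv, nonderiv,
                                 registry = band_registry()) {
  stopifnot(inherits(deriv, "spectra_set"), inherits(nonderiv, "spectra_set"))
  if (!identical(deriv$samples$sample_id, nonderiv$samples$sample_id)) {
    abort("deriv and nonderiv sets must hold the same samples in order")
  }
  n <- nrow(deriv$intensities)
  get_band <- function(y, nm) {
    row <- registry[registry$name == nm, ]
    tryCatch(peak_intensity(deriv$axis, y, row$center, row$tolerance,
                            nm)$intensity,
             error = function(e) { warn(conditionMessage(e)); NA_real_ })
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    y2 <- deriv$intensities[i, ]
    yr <- nonderiv$intensities[i, ]
    I <- setNames(
      vapply(registry$name, function(nm) get_band(y2, nm), numeric(1)),
      registry$name)
    aI <- amide_intensity(nonderiv$axis, yr, "amideI")
    aII <- amide_intensity(nonderiv$axis, yr, "amideII")
    beta_sum <- I["I1693"] + I["I1682"] + I["I1628"]
    out[[i]] <- tibble(
      acyl_chain = unname((I["I2851"] + I["I2922"]) / (I["I2959"] + I["I2871"])),
      unsaturation = unname(I["I3013"] / (I["I2851"] + I["I2922"])),
      triglycerides = unname(I["I1741"]),
      total_protein = aI + aII,
      antiparallel_ratio = unname(I["I1693"] / beta_sum),
      intermolecular_ratio = unname(I["I1628"] / beta_sum),
      fibril_ratio = aII / aI,
      cholesterol_esters = unname(I["I1169"])
    )
  }
  dplyr::bind_cols(deriv$samples, dplyr::bind_rows(out))
}

#' Band indices straight from a raw cohort
#'
#' Runs the per-region preprocessing ([ftir_preprocess()]) that the indices
#' require — second derivatives of the 3050-2800, 1800-1500 and 1200-900
#' cm-1 regions, and the non-derivative normalized 1800-1500 cm-1 region —
#' and evaluates [compute_band_indices()].
#'
#' @param cohort raw [spectra_set()] spanning 3050-900 cm-1.
#' @param registry band registry, see [band_registry()].
#' @param ... passed to [ftir_preprocess()] (outlier screening is disabled
#'   here: the index table carries every sample and the caller screens
#'   beforehand if wanted).
#' @return tibble, one row per sample, metadata plus the eight indices.
#' @export
compute_band_indices_regions <- function(cohort, registry = band_registry(),
                                         ...) {
  regs <- list(c(2800, 3050), c(1500, 1800), c(900, 1200))
  deriv_sets <- lapply(regs, function(r) {
    ftir_preprocess(cohort, r[1], r[2], derivative = TRUE,
                    remove_outliers = FALSE, ...)
  })
  axis <- do.call(c, lapply(deriv_sets, function(s) s$axis))
  mat <- do.call(cbind, lapply(deriv_sets, function(s) s$intensities))
  o <- order(axis, decreasing = TRUE)
  deriv <- spectra_set(axis[o], mat[, o, drop = FALSE],
                       deriv_sets[[1]]$samples, cohort$modality,
                       stages = c(cohort$stages, "regions+sg_d2"))
  nonderiv <- ftir_preprocess(cohort, 1500, 1800, derivative = FALSE,
                              remove_outliers = FALSE)
  compute_band_indices(deriv, nonderiv, registry)
}
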