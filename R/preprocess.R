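#' Standard FTIR analysis regions
#'
#' The three main mid-IR regions used for multivariate analysis, plus the
#' amide I window.
#'
#' @return tibble with columns `name`, `lo`, `hi` (cm-1, inclusive bounds).
#' @export
ftir_regions <- function() {
  tibble(name = c("lipid_3050_2800", "amide_1800_1500", "fingerprint_1200_900",
                  "amide_I_1700_1600"),
         lo = c(2800, 1500, 900, 1600),
         hi = c(3050, 1800, 1200, 1700))
}

#' Extract an axis region
#'
#' Keeps channels with `lo <= axis <= hi` (inclusive both ends), preserving
#' channel order.
#'
#' @param s a [spectra_set()].
#' @param lo,hi region bounds in axis units; `lo < hi`.
#' @return a [spectra_set()] restricted to the region.
#' @export
extract_region <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectra_set"))
  if (lo >= hi) abort("region requires lo < hi")
  keep <- s$axis >= lo & s$axis <= hi
  if (!any(keep)) abort(sprintf("region [%g, %g] contains no channels", lo, hi))
  out <- spectra_set(s$axis[keep], s$intensities[, keep, drop = FALSE],
                     s$samples, s$modality, s$stages)
  record_stage(out, sprintf("region[%g,%g]", lo, hi))
}

# Lower convex hull (Andrew monotone chain) of (x, y), x ascending.
lower_hull_baseline <- function(x, y) {
  n <- length(x)
  hull <- integer(n); h <- 0L
  for (i in seq_len(n)) {
    while (h >= 2L) {
      i1 <- hull[h - 1L]; i2 <- hull[h]
      # pop i2 if it lies on or above the chord i1 -> i
      if ((x[i2] - x[i1]) * (y[i] - y[i1]) -
          (y[i2] - y[i1]) * (x[i] - x[i1]) <= 0) h <- h - 1L else break
    }
    h <- h + 1L; hull[h] <- i
  }
  idx <- hull[seq_len(h)]
  approx(x[idx], y[idx], xout = x)$y
}

#' Baseline-correct spectra
#'
#' `"rubberband"` subtracts the lower convex hull of each spectrum (corrected
#' values are zero at hull support points and >= 0 elsewhere, up to floating
#' point); `"linear"` subtracts the chord through the two endpoint channels.
#' Rubberband correction is invariant under addition of any affine function
#' of the axis. A constant spectrum corrects to all zeros.
#'
#' @param s a [spectra_set()].
#' @param method `"rubberband"` or `"linear"`.
#' @return corrected [spectra_set()].
#' @export
baseline_correct <- function(s, method = c("rubberband", "linear")) {
  stopifnot(inherits(s, "spectra_set"))
  method <- match.arg(method)
  asc <- order(s$axis)          # operate ascending, restore original order
  x <- s$axis[asc]
  m <- s$intensities
  for (i in seq_len(nrow(m))) {
    y <- m[i, asc]
    base <- if (method == "rubberband") {
      lower_hull_baseline(x, y)
    } else {
      y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
    }
    yc <- y - base
    m[i, asc] <- yc
  }
  out <- spectra_set(s$axis, m, s$samples, s$modality, s$stages)
  record_stage(out, paste0("baseline:", method))
}

trapz_abs <- function(x, y) {
  # trapezoid integral of |y| over x, orientation-agnostic
  o <- order(x)
  sum(diff(x[o]) * (abs(y[o])[-1] + abs(y[o])[-length(y)]) / 2)
}

#' Area-normalize spectra
#'
#' Scales each spectrum so the trapezoidal integral of its absolute value
#' over the current axis equals 1. Idempotent; invariant to positive scaling
#' of the input.
#'
#' @param s a [spectra_set()].
#' @return normalized [spectra_set()].
#' @export
area_normalize <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  m <- s$intensities
  for (i in seq_len(nrow(m))) {
    a <- trapz_abs(s$axis, m[i, ])
    if (a <= 0) {
      abort(sprintf("cannot area-normalize zero spectrum '%s'",
                    s$samples$sample_id[i]))
    }
    m[i, ] <- m[i, ] / a
  }
  out <- spectra_set(s$axis, m, s$samples, s$modality, s$stages)
  record_stage(out, "area_normalize")
}

#' Savitzky-Golay second derivative
#'
#' Per-channel second derivative in intensity/(axis unit)^2, computed with a
#' Savitzky-Golay filter of window `2 * half_window + 1` points and the given
#' polynomial order. Exact on polynomials up to `polyorder`; edges are
#' handled by the filter's one-sided fits. The default half-window of 3
#' (7-point window) reads the instrument software's "3 smoothing points" as
#' points per side.
#'
#' @param s a [spectra_set()] on a uniformly spaced axis.
#' @param half_window points per side; window must not exceed the channel
#'   count.
#' @param polyorder polynomial order, >= 2.
#' @return differentiated [spectra_set()].
#' @export
second_derivative <- function(s, half_window = 3, polyorder = 2) {
  stopifnot(inherits(s, "spectra_set"))
  if (polyorder < 2) abort("polyorder must be >= 2 for a second derivative")
  n <- 2L * as.integer(half_window) + 1L
  if (n > length(s$axis)) abort("SG window exceeds channel count")
  h <- abs(diff(s$axis))
  if (diff(range(h)) > 1e-8 * mean(h)) {
    abort("second_derivative requires a uniformly spaced axis")
  }
  m <- t(apply(s$intensities, 1, signal::sgolayfilt,
               p = polyorder, n = n, m = 2, ts = mean(h)))
  out <- spectra_set(s$axis, m, s$samples, s$modality, s$stages)
  record_stage(out, sprintf("sg_d2[hw=%d,p=%d]", half_window, polyorder))
}

#' Flag outlier spectra by PCA Q-residuals
#'
#' Mean-centers the matrix, retains `n_components` principal components, and
#' computes each sample's Q-residual: the squared reconstruction error
#' outside the retained subspace. Samples with Q above the empirical
#' `quantile` cutoff (and above a 1e-10 absolute floor, so a full-rank model
#' flags nothing) are marked as outliers.
#'
#' @param s a [spectra_set()].
#' @param n_components retained components; default 3.
#' @param quantile empirical cutoff quantile, default 0.95.
#' @return tibble with `sample_id`, `q_residual`, `outlier`.
#' @export
detect_outliers <- function(s, n_components = 3, quantile = 0.95) {
  stopifnot(inherits(s, "spectra_set"))
  X <- s$intensities
  if (nrow(X) <= n_components) abort("need more samples than components")
  pca <- pca_fit(X, n_components)
  q <- q_residuals(pca, X)
  cut <- stats::quantile(q, quantile, names = FALSE)
  tibble(sample_id = s$samples$sample_id, q_residual = q,
         outlier = q > cut & q > 1e-10)
}

#' Drop flagged outliers from a spectra set
#'
#' @param s a [spectra_set()].
#' @param flags output of [detect_outliers()].
#' @return a [spectra_set()] without the flagged samples.
#' @export
remove_outliers <- function(s, flags) {
  keep <- !flags$outlier[match(s$samples$sample_id, flags$sample_id)]
  out <- spectra_set(s$axis, s$intensities[keep, , drop = FALSE],
                     s$samples[keep, , drop = FALSE], s$modality, s$stages)
  record_stage(out, sprintf("outliers_removed[%d]", sum(!keep)))
}

#' Run the full FTIR preprocessing chain for one region
#'
#' Fixed stage order: region extraction, PCA Q-residual outlier removal
#' (within the region, where the model is consumed), rubberband baseline
#' correction, area normalization, then optionally the Savitzky-Golay second
#' derivative. Each stage records itself in the set's `stages` provenance.
#'
#' @param s a raw [spectra_set()] covering the region.
#' @param lo,hi region bounds (cm-1).
#' @param derivative apply the second derivative (default TRUE).
#' @param half_window,polyorder SG parameters, see [second_derivative()].
#' @param remove_outliers screen Q-residual outliers first (default TRUE).
#' @param n_components PCA components for the outlier screen.
#' @return processed [spectra_set()].
#' @export
ftir_preprocess <- function(s, lo, hi, derivative = TRUE,
                            half_window = 3, polyorder = 2,
                            remove_outliers = TRUE, n_components = 3) {
  out <- extract_region(s, lo, hi)
  if (remove_outliers && nrow(out$intensities) > n_components + 2) {
    out <- remove_outliers(out, detect_outliers(out, n_components))
  }
  out <- area_normalize(baseline_correct(out, "rubberband"))
  if (derivative) out <- second_derivative(out, half_window, polyorder)
  out
}
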