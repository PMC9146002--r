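#' Plot a spectra set
#'
#' Overlaid spectra colored by passage; the x axis is reversed to follow the
#' instrument convention (high wavenumber / ppm on the left).
#'
#' @param object a [spectra_set()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectra_set <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$intensity,
                                   group = .data$sample_id,
                                   colour = .data$passage)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = object$modality, y = "intensity") +
    ggplot2::theme_minimal()
}

#' Predicted-vs-reference plot for a PLS model
#'
#' Calibration fit (and cross-validated predictions when present) against
#' the reference passage numbers, with the identity line.
#'
#' @param object a `senes_pls` from [pls_passage_model()] or [pls1_fit()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.senes_pls <- function(object, ...) {
  df <- tibble(reference = object$y, predicted = object$fitted,
               set = "calibration")
  if (!is.null(object$cv_predicted)) {
    df <- dplyr::bind_rows(df, tibble(reference = object$y,
                                      predicted = object$cv_predicted,
                                      set = "cross-validation"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$predicted,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "reference passage", y = "predicted passage",
                  subtitle = sprintf("R_cal = %.2f, R_cv = %.2f",
                                     object$r_cal, object$r_cv)) +
    ggplot2::theme_minimal()
}

#' Regression-vector and VIP plot by wavenumber / ppm
#'
#' @param model a `senes_pls` with a stored axis.
#' @param what `"beta"` or `"vip"`.
#' @return a ggplot.
#' @export
plot_coefficients <- function(model, what = c("beta", "vip")) {
  what <- match.arg(what)
  df <- tidy(model)
  if (!"axis" %in% names(df)) abort("model carries no axis; fit via pls_passage_model()")
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data[[what]])) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "axis", y = what) +
    ggplot2::theme_minimal()
}

#' Passage profiles of the band indices
#'
#' Mean +- sd of each index by passage — the per-panel view of the
#' senescence indices.
#'
#' @param indices IndexTable tibble from [compute_band_indices_regions()].
#' @return a ggplot, faceted by index.
#' @export
plot_band_indices <- function(indices) {
  idx_cols <- c("acyl_chain", "unsaturation", "triglycerides",
                "total_protein", "antiparallel_ratio",
                "intermolecular_ratio", "fibril_ratio", "cholesterol_esters")
  long <- indices |>
    tidyr::pivot_longer(dplyr::all_of(idx_cols),
                        names_to = "index", values_to = "value") |>
    dplyr::group_by(.data$passage, .data$index) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$passage, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "passage", y = "index value") +
    ggplot2::theme_minimal()
}

#' CTCF by passage
#'
#' @param ctcf per-nucleus tibble from [quantify_ctcf()].
#' @return a ggplot.
#' @export
plot_ctcf <- function(ctcf) {
  ggplot2::ggplot(ctcf, ggplot2::aes(factor(.data$passage), .data$ctcf)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "passage", y = "CTCF (a.u.)") +
    ggplot2::theme_minimal()
}
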