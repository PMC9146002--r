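#' Exclude solvent regions from NMR spectra
#'
#' Removes channels whose chemical shift falls inside any closed interval of
#' `regions` — by default the water (4.85-4.65 ppm) and chloroform
#' (7.50-7.00 ppm) windows. The axis stays monotone (a gap is left where the
#' region was).
#'
#' @param s a [spectra_set()] on a ppm axis.
#' @param regions list of `c(hi, lo)` or `c(lo, hi)` ppm pairs.
#' @return a [spectra_set()] without the excluded channels.
#' @export
exclude_regions <- function(s, regions = list(c(4.85, 4.65),
                                              c(7.50, 7.00))) {
  stopifnot(inherits(s, "spectra_set"))
  if (!length(regions)) return(s)
  drop <- rep(FALSE, length(s$axis))
  eps <- 1e-8 * max(abs(s$axis))   # grid values are rarely exact binary floats
  for (r in regions) {
    drop <- drop | (s$axis >= min(r) - eps & s$axis <= max(r) + eps)
  }
  if (all(drop)) abort("exclusion regions cover the whole axis")
  out <- spectra_set(s$axis[!drop], s$intensities[, !drop, drop = FALSE],
                     s$samples, s$modality, s$stages)
  record_stage(out, sprintf("exclude[%d regions]", length(regions)))
}

#' Align spectra by capped cross-correlation
#'
#' Simplified peak alignment: each spectrum is shifted by the integer-channel
#' lag that maximizes its cross-correlation with a reference (the mean
#' spectrum, or a chosen row), capped at `max_shift_ppm`. Shifts that hit the
#' cap are flagged. Vacated channels are filled with the edge value.
#'
#' @param s a [spectra_set()].
#' @param reference `"mean"` or a sample index.
#' @param max_shift_ppm maximum allowed |shift| in ppm (default 0.03).
#' @return list with `aligned` (a [spectra_set()]), and `shifts` tibble
#'   (`sample_id`, `lag_channels`, `shift_ppm`, `capped`).
#' @export
align_spectra <- function(s, reference = "mean", max_shift_ppm = 0.03) {
  stopifnot(inherits(s, "spectra_set"))
  step <- abs(mean(diff(s$axis)))
  max_lag <- max(1L, floor(max_shift_ppm / step))
  ref <- if (identical(reference, "mean")) {
    colMeans(s$intensities)
  } else {
    s$intensities[reference, ]
  }
  n <- ncol(s$intensities)
  m <- s$intensities
  lags <- integer(nrow(m)); capped <- logical(nrow(m))
  refc <- ref - mean(ref)
  for (i in seq_len(nrow(m))) {
    y <- m[i, ] - mean(m[i, ])
    cc <- vapply(-max_lag:max_lag, function(L) {
      if (L >= 0) sum(y[(1 + L):n] * refc[1:(n - L)])
      else sum(y[1:(n + L)] * refc[(1 - L):n])
    }, numeric(1))
    L <- (-max_lag:max_lag)[which.max(cc)]
    lags[i] <- L
    capped[i] <- abs(L) == max_lag && max_lag > 0L
    if (L > 0) m[i, ] <- c(m[i, (1 + L):n], rep(m[i, n], L))
    else if (L < 0) m[i, ] <- c(rep(m[i, 1], -L), m[i, 1:(n + L)])
  }
  aligned <- record_stage(
    spectra_set(s$axis, m, s$samples, s$modality, s$stages), "align")
  list(aligned = aligned,
       shifts = tibble(sample_id = s$samples$sample_id,
                       lag_channels = lags, shift_ppm = lags * step,
                       capped = capped))
}

#' Convert a sweep width in Hz to ppm
#'
#' `ppm = width_hz / larmor_mhz`; e.g. 7002 Hz on a 500.13 MHz instrument is
#' a 14.00 ppm sweep.
#'
#' @param width_hz width in Hz.
#' @param larmor_mhz spectrometer proton frequency in MHz; > 0.
#' @return width in ppm.
#' @export
hz_to_ppm <- function(width_hz, larmor_mhz = 500.13) {
  if (larmor_mhz <= 0) abort("larmor frequency must be > 0")
  width_hz / larmor_mhz
}

#' Default chemical-shift assignment table
#'
#' Diagnostic shifts per fraction, matched with a 0.02 ppm tolerance
#' (about two channels at the default 0.005 ppm grid).
#'
#' @return tibble with `metabolite`, `fraction`, `shift`, `tolerance`.
#' @export
assignment_table <- function() {
  entry <- function(met, frac, shifts) {
    tibble(metabolite = met, fraction = frac, shift = shifts, tolerance = 0.02)
  }
  dplyr::bind_rows(
    entry("phosphocholine", "aqueous", 3.19),
    entry("glycine", "aqueous", 3.54),
    entry("lactate", "aqueous", c(1.30, 4.10)),
    entry("alanine", "aqueous", 1.47),
    entry("creatine", "aqueous", 3.03),
    entry("fatty acid acyl CH2", "lipid", c(1.25, 1.54)),
    entry("fatty acid CH3", "lipid", 0.88),
    entry("olefinic HC=CH", "lipid", 5.33),
    entry("lactate", "medium", c(1.30, 4.10)),
    entry("glucose", "medium", c(3.40, 5.22)),
    entry("alanine", "medium", 1.47),
    entry("glutamine", "medium", 2.45)
  )
}

#' Assign picked peaks to metabolites
#'
#' Each peak is matched to the table entry whose nearest diagnostic shift for
#' the fraction lies within that entry's tolerance; unmatched peaks are
#' labeled `"unassigned"`. Ties are broken by smallest distance, then
#' alphabetically by metabolite name.
#'
#' @param peak_ppms numeric vector of peak positions (ppm).
#' @param fraction `"aqueous"`, `"lipid"` or `"medium"`.
#' @param table assignment table, see [assignment_table()].
#' @return tibble with `peak_ppm`, `metabolite`, `matched_shift`, `distance`.
#' @export
assign_peaks <- function(peak_ppms, fraction, table = assignment_table()) {
  tab <- table[table$fraction == fraction, ]
  if (!nrow(tab)) abort(paste("no assignment entries for fraction", fraction))
  purrr::map_dfr(peak_ppms, function(p) {
    d <- abs(tab$shift - p)
    ok <- d <= tab$tolerance
    if (!any(ok)) {
      return(tibble(peak_ppm = p, metabolite = "unassigned",
                    matched_shift = NA_real_, distance = NA_real_))
    }
    cand <- tab[ok, ]
    cand_d <- d[ok]
    o <- order(cand_d, cand$metabolite)
    tibble(peak_ppm = p, metabolite = cand$metabolite[o[1]],
           matched_shift = cand$shift[o[1]], distance = cand_d[o[1]])
  })
}

#' Run the full per-fraction NMR analysis
#'
#' Processing chain for one metabolome fraction: area normalization, solvent
#' region exclusion, cross-correlation alignment, Pareto-scaled PLS1 against
#' passage number, and chemical-shift assignment of the top-VIP channels.
#'
#' @param s a [spectra_set()] for one fraction, >= 4 spectra spanning >= 2
#'   distinct passages, sample table with `passage` and `fraction`.
#' @param n_factors PLS factors (default 2; the scores/loadings of factor 1
#'   carry the reported discrimination).
#' @param top_k number of top-VIP channels to assign (default 5).
#' @param n_segments,seed cross-validation controls; segments are capped at
#'   the sample count.
#' @param exclusions solvent regions, see [exclude_regions()].
#' @param table assignment table.
#' @return list of class `nmr_report`: `model` (`senes_pls`), `scores`
#'   tibble, `loadings` tibble (ppm, beta, vip), `top_assignments` tibble,
#'   `shifts` (alignment record).
#' @export
run_fraction_analysis <- function(s, n_factors = 2, top_k = 5,
                                  n_segments = 10, seed = 1L,
                                  exclusions = list(c(4.85, 4.65),
                                                    c(7.50, 7.00)),
                                  table = assignment_table()) {
  stopifnot(inherits(s, "spectra_set"))
  if (nrow(s$intensities) < 4) abort("need >= 4 spectra")
  if (length(unique(s$samples$passage)) < 2) {
    abort("need >= 2 distinct passages")
  }
  fraction <- s$samples$fraction[1]
  al <- align_spectra(exclude_regions(area_normalize(s), exclusions))
  proc <- al$aligned
  n <- nrow(proc$intensities)
  model <- pls_passage_model(proc, n_factors = min(n_factors, n - 2L),
                             n_segments = min(n_segments, n), seed = seed,
                             scaling = "pareto")
  scores <- dplyr::bind_cols(
    proc$samples,
    as_tibble(model$scores, .name_repair = ~ paste0("t", seq_along(.x))))
  loadings <- tidy(model) |> dplyr::rename(ppm = "axis")
  top <- loadings |> dplyr::arrange(dplyr::desc(.data$vip)) |>
    head(top_k)
  assignments <- assign_peaks(top$ppm, fraction, table) |>
    dplyr::mutate(vip = top$vip)
  structure(list(fraction = fraction, model = model, scores = scores,
                 loadings = loadings, top_assignments = assignments,
                 shifts = al$shifts),
            class = "nmr_report")
}

#' @export
print.nmr_report <- function(x, ...) {
  cat(sprintf("<nmr_report> fraction '%s': R_cal = %.3f, R_cv = %.3f\n",
              x$fraction, x$model$r_cal, x$model$r_cv))
  cat("  top-VIP assignments:\n")
  print(x$top_assignments)
  invisible(x)
}
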