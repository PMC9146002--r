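# Run code under a temporary RNG state so generators are pure functions of
# (design, seed) and never disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameterize a synthetic spectroscopy cohort
#'
#' Captures the full design of the emulated long-term-culture experiment:
#' passage range, replicate hierarchy (biological replicates carry a shared
#' lognormal per-band amplitude perturbation; technical replicates differ only
#' by noise, scatter and baseline), axis grid, noise model and band library.
#'
#' Defaults mirror the emulated FTIR study arm: passages 4-17, five
#' biological x three technical replicates, a 4000-900 cm-1 axis at 2 cm-1
#' spacing (the zero-filled point spacing instruments store at 8 cm-1
#' resolution; resolution itself is modeled by band widths), and additive noise calibrated so the
#' per-channel SNR at the tallest band is about 50.
#'
#' @param passages integer vector of passages.
#' @param n_bio,n_tech biological / technical replicate counts (>= 1).
#' @param axis_lo,axis_hi,axis_step axis limits and spacing (axis is stored
#'   descending).
#' @param bands band library, list of [band_spec()].
#' @param noise_sd additive i.i.d. Gaussian noise sd (absorbance units).
#' @param baseline_order,baseline_scale random smooth-baseline polynomial
#'   order and coefficient scale.
#' @param scatter_sd sd of the multiplicative scatter factor (dimensionless).
#' @param bio_sdlog sdlog of the per-(biological replicate, band) lognormal
#'   amplitude multiplier.
#' @param seed integer seed; all generation is a pure function of
#'   (design, seed).
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(passages = 4:17, n_bio = 5, n_tech = 3,
                          axis_lo = 900, axis_hi = 4000, axis_step = 2,
                          bands = ftir_band_library(),
                          noise_sd = 0.012,
                          baseline_order = 2, baseline_scale = 0.05,
                          scatter_sd = 0.02, bio_sdlog = 0.08,
                          seed = 1L) {
  if (n_bio < 1 || n_tech < 1) abort("replicate counts must be >= 1")
  if (axis_step <= 0) abort("axis_step must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (baseline_order < 0) abort("baseline_order must be >= 0")
  if (!length(bands)) abort("band library must not be empty")
  structure(list(passages = as.integer(passages), n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), axis_lo = axis_lo,
                 axis_hi = axis_hi, axis_step = axis_step, bands = bands,
                 noise_sd = noise_sd, baseline_order = baseline_order,
                 baseline_scale = baseline_scale, scatter_sd = scatter_sd,
                 bio_sdlog = bio_sdlog, seed = as.integer(seed)),
            class = "cohort_design")
}

design_axis <- function(design) {
  seq(design$axis_hi, design$axis_lo, by = -design$axis_step)
}

#' Render one synthetic spectrum
#'
#' intensities = scatter x (sum of band line shapes) + random polynomial
#' baseline + i.i.d. Gaussian noise. Draws from the current RNG stream; wrap
#' with a seed (as the cohort generators do) for reproducibility.
#'
#' @param bands list of [band_spec()]; must be non-empty.
#' @param axis strictly monotone numeric axis.
#' @param passage passage at which band trends are evaluated.
#' @param noise_sd,baseline_order,baseline_scale,scatter_sd noise model; zero
#'   values disable each component.
#' @param mult per-band amplitude multipliers (biological perturbation).
#' @return numeric intensity vector.
#' @export
render_spectrum <- function(bands, axis, passage, noise_sd = 0,
                            baseline_order = 0, baseline_scale = 0,
                            scatter_sd = 0, mult = rep(1, length(bands))) {
  if (!length(bands)) abort("band list must not be empty")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) abort("axis must be strictly monotone")
  y <- band_sum(bands, axis, passage, mult)
  scatter <- if (scatter_sd > 0) 1 + rnorm(1, 0, scatter_sd) else 1
  y <- scatter * y
  if (baseline_scale > 0) {
    u <- (axis - min(axis)) / (max(axis) - min(axis)) * 2 - 1
    coef <- rnorm(baseline_order + 1, 0, baseline_scale)
    y <- y + drop(outer(u, 0:baseline_order, `^`) %*% coef)
  }
  if (noise_sd > 0) y <- y + rnorm(length(axis), 0, noise_sd)
  y
}

#' Generate the synthetic FTIR cohort
#'
#' One spectrum per (passage, biological replicate, technical replicate).
#' Biological replicates of a passage share a lognormal per-band amplitude
#' perturbation; technical replicates of a biological replicate differ only
#' by additive noise, multiplicative scatter and baseline.
#'
#' @param design a [cohort_design()].
#' @return a [spectra_set()] with sample table columns `sample_id`,
#'   `passage`, `bio`, `tech`.
#' @export
generate_ftir_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  axis <- design_axis(design)
  with_local_seed(design$seed, {
    rows <- list(); meta <- list(); k <- 0L
    for (p in design$passages) {
      for (b in seq_len(design$n_bio)) {
        mult <- exp(rnorm(length(design$bands), 0, design$bio_sdlog))
        for (te in seq_len(design$n_tech)) {
          k <- k + 1L
          rows[[k]] <- render_spectrum(design$bands, axis, p,
                                       noise_sd = design$noise_sd,
                                       baseline_order = design$baseline_order,
                                       baseline_scale = design$baseline_scale,
                                       scatter_sd = design$scatter_sd,
                                       mult = mult)
          meta[[k]] <- tibble(sample_id = sprintf("P%02d_B%d_T%d", p, b, te),
                              passage = p, bio = b, tech = te)
        }
      }
    }
    spectra_set(axis, do.call(rbind, rows), dplyr::bind_rows(meta),
                modality = "ftir", stages = "simulated")
  })
}

#' Generate a synthetic NMR cohort for one metabolome fraction
#'
#' Emulates the NMR study arm: passages 5, 7, 11 and 17 with two biological
#' replicates each, on a 0.2-9.8 ppm axis at 0.005 ppm spacing. The medium
#' (exometabolome) fraction injects a rising lactate trend; see
#' [nmr_band_library()] for the per-fraction libraries.
#'
#' @param fraction `"aqueous"`, `"lipid"` or `"medium"`.
#' @param passages passages sampled (default `c(5, 7, 11, 17)`).
#' @param n_reps biological replicates per passage (default 2).
#' @param bands band library; defaults to `nmr_band_library(fraction, ...)`.
#' @param axis_lo,axis_hi,axis_step ppm axis (stored descending).
#' @param noise_sd,bio_sdlog noise model (no baseline/scatter for processed
#'   NMR matrices).
#' @param aqueous_trend passed to [nmr_band_library()].
#' @param seed integer seed.
#' @return a [spectra_set()] with `modality = paste0("nmr_", fraction)`.
#' @export
generate_nmr_cohort <- function(fraction = c("aqueous", "lipid", "medium"),
                                passages = c(5, 7, 11, 17), n_reps = 2,
                                bands = NULL,
                                axis_lo = 0.2, axis_hi = 9.8,
                                axis_step = 0.005,
                                noise_sd = 0.02, bio_sdlog = 0.08,
                                aqueous_trend = c("results", "old_up"),
                                seed = 1L) {
  fraction <- match.arg(fraction)
  if (is.null(bands)) bands <- nmr_band_library(fraction, aqueous_trend)
  axis <- seq(axis_hi, axis_lo, by = -axis_step)
  with_local_seed(seed, {
    rows <- list(); meta <- list(); k <- 0L
    for (p in passages) {
      for (r in seq_len(n_reps)) {
        k <- k + 1L
        mult <- exp(rnorm(length(bands), 0, bio_sdlog))
        rows[[k]] <- render_spectrum(bands, axis, p, noise_sd = noise_sd,
                                     mult = mult)
        meta[[k]] <- tibble(sample_id = sprintf("%s_P%02d_R%d", fraction, p, r),
                            passage = p, replicate = r, fraction = fraction)
      }
    }
    spectra_set(axis, do.call(rbind, rows), dplyr::bind_rows(meta),
                modality = paste0("nmr_", fraction), stages = "simulated")
  })
}

#' Parameterize the synthetic imaging cohort
#'
#' @param passages passages imaged (default `c(5, 7, 11, 17)`).
#' @param n_experiments independent experiments per passage.
#' @param nuclei_per_experiment nuclei quantified per experiment.
#' @param z_slices optical sections per stack.
#' @param image_dim (rows, cols) of each slice.
#' @param signal_by_passage named numeric: mean nuclear signal above
#'   background per passage; the default declines P5 ~ P7 > P11 > P17,
#'   emulating the lamin-B1 drop toward senescence.
#' @param background background intensity level.
#' @param noise_sd additive Gaussian noise sd.
#' @param nucleus_radii (row, col) semi-axes of the elliptical nucleus, px.
#' @param signal_sdlog lognormal spread of per-nucleus signal.
#' @param seed integer seed.
#' @return object of class `imaging_design`.
#' @export
imaging_design <- function(passages = c(5, 7, 11, 17), n_experiments = 3,
                           nuclei_per_experiment = 30, z_slices = 5,
                           image_dim = c(48, 48),
                           signal_by_passage = c("5" = 100, "7" = 95,
                                                 "11" = 60, "17" = 30),
                           background = 10, noise_sd = 2,
                           nucleus_radii = c(9, 7), signal_sdlog = 0.10,
                           seed = 1L) {
  if (n_experiments < 1 || nuclei_per_experiment < 1 || z_slices < 1) {
    abort("counts must be >= 1")
  }
  if (background < 0 || any(signal_by_passage < 0)) {
    abort("intensities must be >= 0")
  }
  if (any(2 * nucleus_radii + 2 > image_dim)) {
    abort("nucleus larger than image")
  }
  structure(list(passages = passages, n_experiments = n_experiments,
                 nuclei_per_experiment = nuclei_per_experiment,
                 z_slices = z_slices, image_dim = image_dim,
                 signal_by_passage = signal_by_passage,
                 background = background, noise_sd = noise_sd,
                 nucleus_radii = nucleus_radii, signal_sdlog = signal_sdlog,
                 seed = as.integer(seed)),
            class = "imaging_design")
}

# One elliptical nucleus mask centered mid-image.
ellipse_mask <- function(dim, radii, center = (dim + 1) / 2) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c_ <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c_ - center[2]) / radii[2])^2 <= 1
}

#' Generate synthetic nuclear fluorescence z-stacks
#'
#' Each stack holds one elliptical nucleus of known area and per-slice signal
#' over a uniform background, plus additive Gaussian noise. The ground-truth
#' corrected total cell fluorescence of a nucleus is
#' `z_slices * area_px * signal` (sum projection of the signal above
#' background), recorded alongside each stack.
#'
#' @param design an [imaging_design()].
#' @return list with `stacks` (list of list(stack = z,row,col array,
#'   nucleus_mask, meta row)) and `truth` (tibble of per-nucleus ground-truth
#'   CTCF with passage/experiment labels).
#' @export
generate_nucleus_stacks <- function(design = imaging_design()) {
  stopifnot(inherits(design, "imaging_design"))
  dm <- design$image_dim
  mask <- ellipse_mask(dm, design$nucleus_radii)
  area <- sum(mask)
  with_local_seed(design$seed, {
    stacks <- list(); truth <- list(); k <- 0L
    for (p in design$passages) {
      s_mean <- design$signal_by_passage[[as.character(p)]]
      if (is.null(s_mean)) abort(paste("no signal level for passage", p))
      for (e in seq_len(design$n_experiments)) {
        for (n in seq_len(design$nuclei_per_experiment)) {
          k <- k + 1L
          s <- s_mean * exp(rnorm(1, 0, design$signal_sdlog))
          slice <- matrix(design$background, dm[1], dm[2])
          slice[mask] <- slice[mask] + s
          stack <- array(rep(slice, design$z_slices),
                         dim = c(dm[1], dm[2], design$z_slices))
          stack <- aperm(stack, c(3, 1, 2))  # (z, row, col)
          if (design$noise_sd > 0) {
            stack <- stack + array(rnorm(length(stack), 0, design$noise_sd),
                                   dim = dim(stack))
            stack[stack < 0] <- 0
          }
          id <- sprintf("P%02d_E%d_N%02d", p, e, n)
          stacks[[k]] <- list(stack = stack, nucleus_mask = mask,
                              nucleus_id = id)
          truth[[k]] <- tibble(nucleus_id = id, passage = p, experiment = e,
                               signal = s, area_px = area,
                               ctcf_truth = design$z_slices * area * s)
        }
      }
    }
    list(stacks = stacks, truth = dplyr::bind_rows(truth))
  })
}
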