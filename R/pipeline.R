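#' Configure the end-to-end senescence-profiling pipeline
#'
#' One object gathering every stage's parameters: the FTIR cohort design,
#' the per-region PLS factor counts (3 for the three main regions, 4 for the
#' amide I window), NMR fractions, the imaging design, cross-validation
#' segments and the master seed. Per-stage seeds are derived from the master
#' seed by fixed small offsets, so a rerun with the same config is
#' bit-identical and no hidden global random state is used.
#'
#' @param seed master integer seed.
#' @param ftir_design a [cohort_design()]; its seed is re-derived from
#'   `seed`.
#' @param regions named list `list("lo_hi" = factors, ...)`; every analyzed
#'   region must carry a factor count.
#' @param nmr_fractions character subset of aqueous/lipid/medium.
#' @param imaging an [imaging_design()]; seed re-derived from `seed`.
#' @param n_segments cross-validation segments.
#' @param aqueous_trend passed to [generate_nmr_cohort()].
#' @return object of class `senespec_config`.
#' @export
senescence_config <- function(seed = 1L,
                              ftir_design = cohort_design(),
                              regions = list("3050_2800" = 3,
                                             "1800_1500" = 3,
                                             "1200_900" = 3,
                                             "1700_1600" = 4),
                              nmr_fractions = c("aqueous", "lipid", "medium"),
                              imaging = imaging_design(),
                              n_segments = 10,
                              aqueous_trend = "results") {
  bad <- vapply(regions, function(f) !is.numeric(f) || length(f) != 1 || f < 1,
                logical(1))
  if (any(bad) || is.null(names(regions)) || any(!nzchar(names(regions)))) {
    abort("every region must be named 'lo_hi' and carry a factor count")
  }
  for (nm in names(regions)) {
    b <- region_bounds(nm)
    if (b[1] >= b[2]) abort(paste("invalid region name:", nm))
  }
  ftir_design$seed <- seed + 101L
  imaging$seed <- seed + 301L
  structure(list(seed = as.integer(seed), ftir_design = ftir_design,
                 regions = regions, nmr_fractions = nmr_fractions,
                 imaging = imaging, n_segments = n_segments,
                 aqueous_trend = aqueous_trend),
            class = "senespec_config")
}

region_bounds <- function(name) {
  v <- sort(suppressWarnings(as.numeric(strsplit(name, "_")[[1]])))
  if (length(v) != 2 || anyNA(v)) abort(paste("invalid region name:", name))
  v
}

#' Run the full senescence-profiling pipeline
#'
#' simulate -> FTIR preprocess + per-region PLS -> band indices + group
#' stats -> NMR fraction reports -> CTCF quantification + group stats, under
#' one seed. Any stage failure aborts with the stage name.
#'
#' @param config a [senescence_config()].
#' @return object of class `senespec_report`: list with `ftir` (per-region
#'   `senes_pls` models), `indices` (IndexTable tibble), `index_stats`,
#'   `nmr` (per-fraction `nmr_report`), `ctcf` (per-nucleus tibble),
#'   `ctcf_summary`, `ctcf_stats`, `manifest`.
#' @export
run_senescence_pipeline <- function(config = senescence_config()) {
  stopifnot(inherits(config, "senespec_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  cohort <- stage("simulate_ftir", generate_ftir_cohort(config$ftir_design))

  ftir <- list()
  for (nm in names(config$regions)) {
    b <- region_bounds(nm)
    ftir[[nm]] <- stage(paste0("ftir_pls_", nm), {
      proc <- ftir_preprocess(cohort, b[1], b[2])
      pls_passage_model(proc, n_factors = config$regions[[nm]],
                        n_segments = config$n_segments,
                        seed = config$seed + 201L)
    })
  }

  indices <- stage("band_indices", compute_band_indices_regions(cohort))
  key_passages <- intersect(c(5, 7, 11, 17), unique(indices$passage))
  idx_cols <- c("acyl_chain", "unsaturation", "triglycerides",
                "total_protein", "antiparallel_ratio",
                "intermolecular_ratio", "fibril_ratio", "cholesterol_esters")
  index_stats <- stage("index_stats", {
    sub <- indices[indices$passage %in% key_passages, ]
    lapply(setNames(idx_cols, idx_cols), function(cl) {
      select_and_compare(sub, cl, "passage")
    })
  })

  nmr <- list()
  for (fr in config$nmr_fractions) {
    nmr[[fr]] <- stage(paste0("nmr_", fr), {
      run_fraction_analysis(
        generate_nmr_cohort(fr, seed = config$seed + 401L,
                            aqueous_trend = config$aqueous_trend),
        seed = config$seed + 402L)
    })
  }

  img <- stage("simulate_imaging", generate_nucleus_stacks(config$imaging))
  ctcf <- stage("ctcf", quantify_ctcf(img$stacks, img$truth))
  ctcf_summary <- summarize_ctcf(ctcf)
  ctcf_stats <- stage("ctcf_stats", select_and_compare(ctcf, "ctcf", "passage"))

  manifest <- list(
    seed = config$seed,
    ftir_regions = names(config$regions),
    ftir_factors = unlist(config$regions),
    nmr_fractions = config$nmr_fractions,
    imaging_cohorts = 1L,
    n_ftir_spectra = nrow(cohort$intensities),
    n_nuclei = nrow(ctcf),
    stages = c("simulate", "ftir_preprocess", "ftir_pls", "band_indices",
               "group_stats", "nmr", "ctcf")
  )
  structure(list(ftir = ftir, indices = as_tibble(indices),
                 index_stats = index_stats, nmr = nmr, ctcf = ctcf,
                 ctcf_summary = ctcf_summary, ctcf_stats = ctcf_stats,
                 manifest = manifest),
            class = "senespec_report")
}

#' @export
print.senespec_report <- function(x, ...) {
  cat("<senespec_report>\n FTIR PLS models:\n")
  for (nm in names(x$ftir)) {
    m <- x$ftir[[nm]]
    cat(sprintf("  %s: %d factors, R_cal = %.3f, R_cv = %.3f\n",
                nm, m$n_factors, m$r_cal, m$r_cv))
  }
  cat(sprintf(" indices: %d samples x 8 indices\n", nrow(x$indices)))
  for (fr in names(x$nmr)) {
    cat(sprintf(" NMR %s: R_cal = %.3f; top VIP: %s\n", fr,
                x$nmr[[fr]]$model$r_cal,
                paste(unique(x$nmr[[fr]]$top_assignments$metabolite),
                      collapse = ", ")))
  }
  cat(sprintf(" CTCF: %d nuclei, %s route, omnibus p = %.3g\n",
              nrow(x$ctcf), x$ctcf_stats$test, x$ctcf_stats$omnibus_p))
  invisible(x)
}
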