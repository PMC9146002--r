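test_that("trend multipliers interpolate piecewise-linearly and clamp", {
  const <- trend_spec("constant", data.frame(passage = 5, mult = 1))
  b <- band_spec("x", 1650, 10, 0.7, trend = const)
  expect_equal(trend_amplitude(b, 4), 0.7)
  expect_equal(trend_amplitude(b, 17), 0.7)

  v <- trend_spec("v_shape",
                  data.frame(passage = c(5, 11, 17), mult = c(1, 0.5, 1)))
  bv <- band_spec("v", 1650, 10, 2, trend = v)
  expect_equal(trend_amplitude(bv, 8), 0.75 * 2)
  expect_equal(trend_amplitude(bv, 11), 0.5 * 2)   # exact at knots
  expect_equal(trend_amplitude(bv, 4), 2)          # clamped to knot hull

  mono <- trend_spec("monotone_increasing",
                     data.frame(passage = c(5, 17), mult = c(1, 2)))
  expect_equal(trend_multiplier(mono, 11), 1.5)
})

test_that("malformed trends and bands are rejected", {
  expect_error(trend_spec("v_shape",
                          data.frame(passage = c(5, 11, 17),
                                     mult = c(0.5, 1, 2))),
               "interior")
  expect_error(trend_spec("constant", data.frame(passage = c(5, 5),
                                                 mult = c(1, 1))),
               "increasing")
  expect_error(trend_spec("constant", data.frame(passage = 5, mult = -1)))
  expect_error(band_spec("b", 1650, 0, 1), "width")
  expect_error(band_spec("b", 1650, 10, -1))
  expect_error(band_spec("b", 1650, 10, 1, shape = "pseudo_voigt", mix = 2))
})

test_that("rendered spectra match the analytic band sum and are deterministic", {
  axis <- seq(1800, 1500, by = -2)
  bands <- list(band_spec("g", 1650, 12, 0.8))
  y <- render_spectrum(bands, axis, 5)
  # unimodal peak at the band center sample
  expect_equal(axis[which.max(y)], 1650)
  expect_equal(y, 0.8 * exp(-log(2) * ((axis - 1650) / 12)^2))

  y1 <- render_spectrum(bands, axis, 5)
  expect_identical(y, y1)  # zero noise: identical calls

  expect_error(render_spectrum(list(), axis, 5), "empty")
  expect_error(render_spectrum(bands, c(1, 1, 2), 5), "monotone")
})

test_that("render noise follows the stated model (Monte Carlo)", {
  axis <- seq(110, 100, by = -1)
  bands <- list(band_spec("far", 1000, 5, 1))  # no support near the axis
  vals <- withr::with_seed(42, {
    replicate(3000, render_spectrum(bands, axis, 5, noise_sd = 0.01)[4])
  })
  expect_lt(abs(sd(vals) - 0.01) / 0.01, 0.05)
})

test_that("FTIR cohort has the exact replicate structure and is reproducible", {
  d <- cohort_design(seed = 7)
  expect_equal(length(d$passages) * d$n_bio * d$n_tech, 14 * 5 * 3)
  co <- generate_ftir_cohort(d)
  expect_equal(nrow(co$intensities), 210)
  expect_equal(nrow(co$samples), 210)
  expect_equal(dplyr::n_distinct(co$samples$passage), 14)
  co2 <- generate_ftir_cohort(cohort_design(seed = 7))
  expect_identical(co$intensities, co2$intensities)
  co3 <- generate_ftir_cohort(cohort_design(seed = 8))
  expect_false(identical(co$intensities, co3$intensities))
})

test_that("noise-free spectra peak at every generating band center", {
  # well-separated library: raw-absorbance maxima are resolvable (overlapping
  # doublets of the default library merge in raw spectra by construction and
  # are read from second derivatives instead)
  bands <- list(
    band_spec("a", 2922, 9, 0.55,
              trend = trend_spec("v_shape",
                                 data.frame(passage = c(5, 11, 17),
                                            mult = c(1, 0.5, 0.9)))),
    band_spec("b", 1741, 10, 0.30),
    band_spec("c", 1648, 9, 0.60,
              trend = trend_spec("monotone_increasing",
                                 data.frame(passage = c(5, 17),
                                            mult = c(1, 1.3)))),
    band_spec("d", 1085, 12, 0.50),
    band_spec("e", 970, 10, 0.20))
  d <- quiet_design(passages = c(5, 11, 17), n_bio = 1, n_tech = 1,
                    bands = bands)
  co <- generate_ftir_cohort(d)
  step <- abs(diff(co$axis[1:2]))
  for (i in seq_len(3)) {
    y <- co$intensities[i, ]
    # plateau-tolerant: centers between grid points give two equal top samples
    maxima <- which(diff(sign(diff(y))) < 0) + 1L
    for (b in d$bands) {
      expect_lte(min(abs(co$axis[maxima] - b$center)), step,
                 label = sprintf("band %s passage %d", b$name,
                                 co$samples$passage[i]))
    }
  }
})

test_that("NMR cohorts have the study structure and the lactate trend", {
  med <- generate_nmr_cohort("medium", seed = 2)
  expect_equal(nrow(med$intensities), 8)          # 4 passages x 2 replicates
  expect_setequal(unique(med$samples$passage), c(5, 7, 11, 17))

  quiet <- generate_nmr_cohort("medium", noise_sd = 0, bio_sdlog = 0, seed = 2)
  win <- quiet$axis >= 1.25 & quiet$axis <= 1.35
  by_p <- tapply(rowSums(quiet$intensities[, win]), quiet$samples$passage, mean)
  expect_gt(by_p[["17"]], by_p[["5"]])

  expect_error(generate_nmr_cohort("serum"))
})

test_that("assignment of noise-free medium peaks recovers lactate at both shifts", {
  quiet <- generate_nmr_cohort("medium", noise_sd = 0, bio_sdlog = 0, seed = 1)
  y <- quiet$intensities[1, ]
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] > 0.05]
  asg <- assign_peaks(quiet$axis[peaks], "medium")
  lact <- asg[asg$metabolite == "lactate", ]
  expect_setequal(round(lact$matched_shift, 2), c(1.30, 4.10))
})

test_that("nucleus stacks carry exact closed-form ground truth", {
  d <- imaging_design(passages = 5, n_experiments = 1,
                      nuclei_per_experiment = 2, noise_sd = 0,
                      signal_sdlog = 0, z_slices = 4, seed = 9)
  out <- generate_nucleus_stacks(d)
  it <- out$stacks[[1]]
  tr <- out$truth[1, ]
  img <- z_project_sum(it$stack)
  bg <- background_annulus(it$nucleus_mask)
  # noise-free: CTCF = z_slices * area * signal exactly
  expect_equal(compute_ctcf(img, it$nucleus_mask, bg), tr$ctcf_truth)
  expect_equal(tr$ctcf_truth, 4 * tr$area_px * tr$signal)

  out2 <- generate_nucleus_stacks(imaging_design(passages = 5,
                                                 n_experiments = 1,
                                                 nuclei_per_experiment = 2,
                                                 noise_sd = 0,
                                                 signal_sdlog = 0,
                                                 z_slices = 4, seed = 9))
  expect_identical(out$stacks[[2]]$stack, out2$stacks[[2]]$stack)
})

test_that("imaging ground truth follows the declining lamin-B1 trend", {
  out <- generate_nucleus_stacks(imaging_design(seed = 4))
  m <- tapply(out$truth$ctcf_truth, out$truth$passage, mean)
  expect_true(m[["5"]] > m[["11"]] && m[["11"]] > m[["17"]])
  expect_equal(nrow(out$truth), 4 * 3 * 30)
  expect_error(imaging_design(image_dim = c(10, 10)), "larger")
})
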