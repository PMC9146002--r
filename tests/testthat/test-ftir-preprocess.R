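test_that("CSV round-trip preserves spectra and metadata", {
  s <- random_set(n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  r <- read_spectra(path)
  expect_equal(unname(r$intensities), unname(s$intensities), tolerance = 1e-9)
  expect_equal(r$axis, s$axis)
  expect_equal(r$samples$passage, s$samples$passage)
})

test_that("malformed spectra inputs are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("axis,s1", "100,0.1", "100,0.2", "120,0.3"), path)  # repeated
  expect_error(read_spectra(path), "monotone")
  expect_error(read_spectra("does-not-exist.csv"), "no such file")
  expect_error(spectra_set(c(1, 2, 3), matrix(1, 1, 3),
                           tibble::tibble(id = "a")), "sample_id")
  expect_error(spectra_set(c(1, 2, 3), matrix(1, 2, 3),
                           tibble::tibble(sample_id = c("a", "a"))), "unique")
})

test_that("JCAMP-DX XYDATA spectra are parsed with factors applied", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=demo", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
               "##XFACTOR=1", "##YFACTOR=0.5",
               "##FIRSTX=1000", "##LASTX=1008", "##NPOINTS=5",
               "##XYDATA=(X++(Y..Y))",
               "1000 2 4 6", "1006 8 10",
               "##END="), path)
  s <- read_spectra(path, format = "jcampdx")
  expect_equal(s$axis, seq(1000, 1008, by = 2))
  expect_equal(unname(s$intensities[1, ]), c(1, 2, 3, 4, 5))
})

test_that("region extraction keeps inclusive bounds and channel order", {
  axis <- seq(3050, 2800, by = -4)
  s <- one_spectrum(axis, seq_along(axis))
  expect_equal(length(extract_region(s, 2800, 3050)$axis), length(axis))

  full <- one_spectrum(seq(4000, 900, by = -4), rep(1, 776))
  r <- extract_region(full, 1500, 1800)
  expect_equal(length(r$axis), 76)  # multiples of 4 in [1500, 1800]
  expect_true(all(diff(r$axis) < 0))
  expect_error(extract_region(full, 5000, 6000), "no channels")
  expect_error(extract_region(full, 1800, 1500), "lo < hi")
})

test_that("rubberband baseline removes convex baselines and affine offsets", {
  axis <- seq(1800, 1500, by = -2)
  u <- (axis - 1650) / 150
  convex <- 0.5 + 0.3 * u^2           # pure convex baseline, no bands
  s <- baseline_correct(one_spectrum(axis, convex))
  expect_lt(max(abs(s$intensities)), 1e-12)

  band <- single_gaussian()
  base <- baseline_correct(one_spectrum(axis, band))$intensities[1, ]
  shifted <- baseline_correct(one_spectrum(axis, band + 0.2 - 0.001 * axis))
  expect_equal(shifted$intensities[1, ], base, tolerance = 1e-10)

  # single band on zero baseline: correction leaves the band intact
  expect_lt(max(abs(base - band)), 1e-8)

  flat <- baseline_correct(one_spectrum(axis, rep(2, length(axis))))
  expect_equal(unname(flat$intensities[1, ]), rep(0, length(axis)))
})

test_that("area normalization hits unit integral, is idempotent and scale-free", {
  axis <- seq(1850, 1800, by = -2)   # span 50
  s <- area_normalize(one_spectrum(axis, rep(2, length(axis))))
  expect_equal(unname(s$intensities[1, ]), rep(0.02, length(axis)))

  r <- random_set(n = 4, seed = 3)
  n1 <- area_normalize(r)
  trapz <- function(x, y) { o <- order(x)
    sum(diff(x[o]) * (abs(y[o])[-1] + abs(y[o])[-length(y)]) / 2) }
  for (i in 1:4) {
    expect_equal(trapz(n1$axis, n1$intensities[i, ]), 1, tolerance = 1e-10)
  }
  n2 <- area_normalize(n1)
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-12)

  r5 <- r; r5$intensities <- 5 * r5$intensities
  expect_equal(area_normalize(r5)$intensities, n1$intensities,
               tolerance = 1e-12)
  expect_error(area_normalize(one_spectrum(axis, rep(0, length(axis)))),
               "zero spectrum")
})

test_that("SG second derivative is exact on polynomials and signs bands", {
  axis <- seq(100, 10, by = -1)
  q <- second_derivative(one_spectrum(axis, axis^2))
  expect_equal(unname(q$intensities[1, ]), rep(2, length(axis)),
               tolerance = 1e-8)

  cub <- second_derivative(one_spectrum(axis, axis^3 - 4 * axis), polyorder = 3)
  expect_equal(unname(cub$intensities[1, ]), 6 * axis, tolerance = 1e-6)

  gx <- seq(1800, 1500, by = -2)
  g <- second_derivative(one_spectrum(gx, single_gaussian(axis = gx)))
  i0 <- which(gx == 1650)
  expect_lt(g$intensities[1, i0], 0)
  expect_equal(which.min(g$intensities[1, ]), i0)

  expect_error(second_derivative(one_spectrum(gx[1:5], rnorm(5)),
                                 half_window = 5), "window")
  expect_error(second_derivative(one_spectrum(gx, single_gaussian(axis = gx)),
                                 polyorder = 1), "polyorder")
})

test_that("Q-residual outlier screen flags exactly an injected spike", {
  # structured normal variation (amplitude, tilt, width) spans the retained
  # components; the spike lies outside that subspace
  axis <- seq(2000, 1500, by = -10)
  base <- single_gaussian(1750, 50, 1, axis)
  shapes <- cbind(base, axis / 2000, single_gaussian(1650, 30, 1, axis))
  m <- withr::with_seed(11, {
    coefs <- cbind(rnorm(21, 0, 0.2), rnorm(21, 0, 0.1), rnorm(21, 0, 0.05))
    sweep(coefs %*% t(shapes), 2, base, "+") +
      matrix(rnorm(21 * length(axis), 0, 1e-3), 21)
  })
  m[13, 25] <- m[13, 25] + 0.1  # spike in one sample, off the model subspace
  s <- spectra_set(axis, m, tibble::tibble(sample_id = paste0("s", 1:21)))
  fl <- detect_outliers(s, n_components = 3)
  expect_identical(unname(which(fl$outlier)), 13L)

  kept <- remove_outliers(s, fl)
  expect_equal(nrow(kept$intensities), 20)
})

test_that("Q-residuals are zero for in-subspace samples and identical spectra", {
  axis <- seq(100, 10, by = -10)
  m <- matrix(rep(1:10, each = 7), nrow = 7)
  s <- spectra_set(axis, m, tibble::tibble(sample_id = paste0("s", 1:7)))
  fl <- detect_outliers(s, n_components = 2)
  expect_true(all(fl$q_residual < 1e-20))
  expect_false(any(fl$outlier))

  # rank-2 data, sample exactly in the retained plane
  withr::with_seed(2, {
    u <- matrix(rnorm(20), 10, 2); v <- matrix(rnorm(16), 2, 8)
  })
  X <- u %*% v
  pca <- pca_fit(X, 2)
  expect_lt(max(q_residuals(pca, X)), 1e-10)
})

test_that("the preprocessing chain records stage provenance in order", {
  co <- generate_ftir_cohort(quiet_design(passages = c(5, 17), n_bio = 2,
                                          n_tech = 1))
  proc <- ftir_preprocess(co, 1500, 1800, remove_outliers = FALSE)
  expect_match(proc$stages[2], "region")
  expect_match(proc$stages[3], "baseline")
  expect_match(proc$stages[4], "area_normalize")
  expect_match(proc$stages[5], "sg_d2")
})
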