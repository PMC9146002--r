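test_that("PLS1 recovers a perfect single-variable relation with one factor", {
  # centered, mutually orthogonal columns: the single weight vector is exact
  X <- withr::with_seed(1, {
    qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE)))
  })
  y <- 2 * X[, 2] + 1
  m <- pls1_fit(X, y, 1)
  expect_equal(m$r_cal, 1, tolerance = 1e-10)
  expect_equal(unname(predict(m, X)), y, tolerance = 1e-8)
})

test_that("orthogonal response stops at zero factors with zero beta", {
  # columns orthogonal to centered y by construction
  y <- c(-1, 1, -1, 1)
  X <- cbind(c(1, 1, -1, -1), c(2, 2, 2, 2) + c(1, 1, -1, -1))
  expect_warning(m <- pls1_fit(X, y, 2), "exhausted")
  expect_equal(m$n_factors, 0)
  expect_equal(m$beta, c(0, 0))
  expect_equal(unname(predict(m, X)), rep(mean(y), 4))
})

test_that("full-rank PLS equals ordinary least squares (oracle, 100 problems)", {
  for (k in 1:100) {
    withr::with_seed(1000 + k, {
      X <- matrix(rnorm(100), 20, 5)
      y <- rnorm(20)
    })
    m <- pls1_fit(X, y, 5)
    ols <- lm.fit(cbind(1, X), y)$coefficients  # normal-equations oracle
    expect_equal(unname(m$beta), unname(ols[-1]), tolerance = 1e-8)
    expect_equal(m$intercept, unname(ols[1]), tolerance = 1e-8)
  }
})

test_that("NIPALS and kernel-algorithm PLS1 agree (dual-route fidelity)", {
  for (k in 1:20) {
    withr::with_seed(200 + k, {
      X <- matrix(rnorm(30 * 12), 30, 12)
      y <- X %*% rnorm(12) + rnorm(30)
    })
    for (sc in c("none", "pareto")) {
      m <- pls1_fit(X, y, 3, scaling = sc)
      kk <- kernel_pls1(X, y, 3, scaling = sc)
      expect_equal(m$beta, kk$beta, tolerance = 1e-8)
      expect_equal(m$intercept, kk$intercept, tolerance = 1e-8)
    }
  }
})

test_that("scores are orthogonal and R_cal non-decreasing in factor count", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    y <- X %*% rnorm(10) + rnorm(40, 0, 2)
  })
  m <- pls1_fit(X, y, 5)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  r <- vapply(1:5, function(a) pls1_fit(X, y, a)$r_cal, numeric(1))
  expect_true(all(diff(r) > -1e-12))
})

test_that("predictions are equivariant under variable permutation", {
  withr::with_seed(6, {
    X <- matrix(rnorm(25 * 8), 25, 8)
    y <- X %*% rnorm(8) + rnorm(25)
  })
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  m1 <- pls1_fit(X, y, 3)
  m2 <- pls1_fit(X[, perm], y, 3)
  expect_equal(m1$beta[perm], m2$beta, tolerance = 1e-10)
  expect_equal(predict(m1, X), predict(m2, X[, perm]), tolerance = 1e-10)
})

test_that("single-factor prediction agrees between beta and score paths", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- X %*% rnorm(6) + rnorm(30)
  })
  m <- pls1_fit(X, y, 1)
  Xc <- sweep(X, 2, m$x_center)
  path <- drop(Xc %*% m$weights[, 1]) * m$y_loadings[1] + m$y_center
  expect_equal(unname(m$fitted), unname(path), tolerance = 1e-8)
})

test_that("VIP satisfies its normalization and limit cases", {
  withr::with_seed(8, {
    X <- matrix(rnorm(30 * 7), 30, 7)
    y <- X %*% rnorm(7) + rnorm(30)
  })
  m <- pls1_fit(X, y, 3)
  expect_equal(sum(m$vip^2), 7, tolerance = 1e-10)

  # one variable carries all covariance with y
  X1 <- withr::with_seed(9, cbind(rnorm(50), matrix(0, 50, 3)))
  y1 <- 3 * X1[, 1]
  m1 <- suppressWarnings(pls1_fit(X1, y1, 1))
  expect_equal(m1$vip, c(2, 0, 0, 0), tolerance = 1e-10)  # sqrt(p) and zeros

  # two equally informative independent variables
  withr::with_seed(10, {
    a <- rnorm(2000); b <- rnorm(2000)
  })
  X2 <- cbind(a, b); y2 <- a + b
  m2 <- pls1_fit(X2, y2, 1)
  expect_equal(unname(m2$vip), c(1, 1), tolerance = 0.05)
})

test_that("Pareto scaling halves the spread of a sd-4 column", {
  x <- rep(c(0, 8), 8)                       # sd exactly 4 (n-1 basis)... check
  X <- cbind(a = x * (4 / sd(x)), b = rnorm(16))
  Xp <- pareto_scale(X)
  expect_equal(sd(Xp[, 1]), 2, tolerance = 1e-12)
  # scaled column variance equals the original sd
  withr::with_seed(11, Xr <- matrix(rnorm(200, sd = 3), 20, 10))
  Xrp <- pareto_scale(Xr)
  expect_equal(apply(Xrp, 2, var), apply(Xr, 2, sd), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(pareto_scale(cbind(rep(1, 5), rnorm(5))), "constant")
})

test_that("cross-validation is seeded, exact on noise-free relations", {
  withr::with_seed(12, {
    X <- matrix(rnorm(60 * 10), 60, 10)
  })
  y <- drop(X %*% c(1, -2, rep(0, 8)))
  cv1 <- cross_validate(X, y, 8, 10, seed = 3)
  cv2 <- cross_validate(X, y, 8, 10, seed = 3)
  expect_identical(cv1$r_cv, cv2$r_cv)
  expect_gt(cv1$r_cv, 0.999)
  expect_error(cross_validate(X, y, 2, n_segments = 100), "exceed")
})

test_that("PCA explains total variance at full rank and matches svd loadings", {
  withr::with_seed(13, X <- matrix(rnorm(15 * 6), 15, 6))
  p <- pca_fit(X, 6)
  expect_equal(sum(p$explained_variance), p$total_variance, tolerance = 1e-10)
  sv <- svd(scale(X, scale = FALSE))
  for (j in 1:3) {
    expect_equal(abs(sum(p$loadings[, j] * sv$v[, j])), 1, tolerance = 1e-8)
  }
  # brute-force Q oracle on random 20 x 50 matrices
  withr::with_seed(14, X2 <- matrix(rnorm(20 * 50), 20, 50))
  k <- 3
  mdl <- pca_fit(X2, k)
  Xc <- scale(X2, scale = FALSE)
  s2 <- svd(Xc)
  recon <- s2$u[, 1:k] %*% diag(s2$d[1:k]) %*% t(s2$v[, 1:k])
  q_oracle <- rowSums((Xc - recon)^2)
  expect_equal(q_residuals(mdl, X2), q_oracle, tolerance = 1e-8)
})

test_that("tidy and glance expose the model as tibbles", {
  co <- generate_ftir_cohort(quiet_design(passages = c(5, 11, 17), n_bio = 2,
                                          n_tech = 1))
  proc <- ftir_preprocess(co, 1500, 1800, remove_outliers = FALSE)
  m <- pls_passage_model(proc, 2, n_segments = 6)
  td <- tidy(m)
  expect_true(all(c("axis", "beta", "vip") %in% names(td)))
  expect_equal(nrow(td), length(proc$axis))
  gl <- glance(m)
  expect_equal(gl$n_factors, 2)
  expect_true(gl$r_cal <= 1 && gl$r_cal >= -1)
})
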