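#' Pareto-scale a matrix
#'
#' Mean-centers each column and divides by the square root of its standard
#' deviation — the standard compromise between no scaling and unit-variance
#' scaling in NMR metabolomics (a column of sd v ends up with sd sqrt(v)).
#' Constant columns are mapped to zeros with a warning.
#'
#' @param X numeric matrix (samples x variables).
#' @return matrix of the same shape with attributes `center` and `scale`.
#' @export
pareto_scale <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sc <- sqrt(sdev)
  if (any(sdev == 0)) {
    warn(sprintf("%d constant column(s) mapped to zero", sum(sdev == 0)))
    sc[sdev == 0] <- Inf
  }
  out <- sweep(sweep(X, 2, mu), 2, sc, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sc
  out
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Univariate-response partial least squares by the NIPALS algorithm with
#' X-deflation per factor: weights `w_a = X'y / |X'y|`, scores `t_a = X w_a`,
#' X-loadings `p_a = X't_a / t_a't_a`, y-loadings `q_a = t_a'y / t_a't_a`.
#' Data are mean-centered (and optionally Pareto-scaled) internally; the
#' returned regression vector `beta` and `intercept` act on the raw scale, so
#' `predict()` is simply `X %*% beta + intercept`. If the residual covariance
#' `|X'y|` vanishes before `n_factors` are extracted, fitting stops early
#' with a warning and the model keeps the factors found.
#'
#' @param X numeric matrix, samples x variables.
#' @param y numeric response (here: passage numbers); must have variance.
#' @param n_factors number of latent factors, at most `min(n - 1, p)`.
#' @param scaling `"none"` (mean-centering only; the FTIR default) or
#'   `"pareto"` (the NMR default).
#' @return object of class `senes_pls` with elements `weights`, `loadings`,
#'   `y_loadings`, `scores`, `beta`, `intercept`, `r_cal`, `fitted`, `vip`,
#'   `n_factors`.
#' @export
pls1_fit <- function(X, y, n_factors = 3,
                     scaling = c("none", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (var(y) == 0) abort("response has no variance")
  if (n_factors > min(n - 1L, p)) abort("n_factors exceeds min(n - 1, p)")
  x_center <- colMeans(X)
  x_scale <- rep(1, p)
  if (scaling == "pareto") {
    sdev <- apply(X, 2, sd)
    x_scale <- sqrt(sdev)
    x_scale[sdev == 0] <- Inf
  }
  y_center <- mean(y)
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yc <- y - y_center

  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_factors)) {
    s <- drop(crossprod(Xd, yd))
    ns <- sqrt(sum(s^2))
    if (ns < 1e-12 * max(1, sqrt(sum(yc^2)))) {
      warn(sprintf("PLS covariance exhausted: stopping at %d factor(s)", a - 1L))
      break
    }
    w <- s / ns
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_a <- drop(crossprod(Xd, t_)) / tt
    q_a <- sum(t_ * yd) / tt
    W <- cbind(W, w); P <- cbind(P, p_a); Tm <- cbind(Tm, t_)
    q <- c(q, q_a)
    Xd <- Xd - tcrossprod(t_, p_a)
    yd <- yd - q_a * t_
  }
  A <- ncol(W)
  if (A > 0) {
    R <- W %*% solve(crossprod(P, W))        # beta in centered/scaled space
    beta_s <- drop(R %*% q)
  } else {
    beta_s <- numeric(p)
  }
  beta <- beta_s / x_scale
  intercept <- y_center - sum(x_center * beta)
  fitted <- drop(X %*% beta) + intercept
  r_cal <- if (A > 0) cor(fitted, y) else NA_real_
  m <- structure(list(n_factors = A, requested_factors = n_factors,
                      weights = W, loadings = P, y_loadings = q,
                      scores = Tm, beta = beta, intercept = intercept,
                      x_center = x_center, x_scale = x_scale,
                      y_center = y_center, scaling = scaling,
                      fitted = fitted, y = y, r_cal = r_cal,
                      r_cv = NA_real_),
                 class = "senes_pls")
  m$vip <- if (A > 0) vip(m) else rep(NA_real_, p)
  m
}

#' Predict from a fitted PLS1 model
#'
#' @param object a `senes_pls` model.
#' @param newdata matrix with the same variable count as the training data.
#' @param ... unused.
#' @return numeric predictions `newdata %*% beta + intercept`.
#' @export
predict.senes_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    abort("newdata variable count does not match the model")
  }
  drop(newdata %*% object$beta) + object$intercept
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#' weights and `SSY_a = q_a^2 t_a't_a` the response variance captured by
#' factor a. Satisfies `sum_j VIP_j^2 = p`.
#'
#' @param model a fitted `senes_pls` with at least one factor.
#' @return numeric vector of per-variable scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "senes_pls"))
  if (model$n_factors < 1) abort("VIP requires a model with >= 1 factor")
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  W2 <- sweep(model$weights^2, 2, colSums(model$weights^2), "/")
  p <- nrow(model$weights)
  sqrt(p * drop(W2 %*% ssy) / sum(ssy))
}

#' Cross-validate a PLS1 model
#'
#' Random internal segment cross-validation: rows are partitioned into
#' `n_segments` random segments (seeded); each segment is predicted by a
#' model fit on the remaining rows; `R_cv` is the Pearson correlation of the
#' pooled out-of-segment predictions with the reference values (pooled
#' globally, never per segment).
#'
#' @param X,y,n_factors,scaling as in [pls1_fit()].
#' @param n_segments number of segments (default 10), at most `nrow(X)`.
#' @param seed integer seed for the partition.
#' @return list with `r_cv`, `predicted`, `segment`.
#' @export
cross_validate <- function(X, y, n_factors = 3, n_segments = 10, seed = 1L,
                           scaling = c("none", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_segments > n) abort("n_segments must not exceed the sample count")
  seg <- with_local_seed(seed, sample(rep(seq_len(n_segments), length.out = n)))
  pred <- numeric(n)
  for (k in seq_len(n_segments)) {
    hold <- seg == k
    a_k <- min(n_factors, sum(!hold) - 1L)
    fit <- pls1_fit(X[!hold, , drop = FALSE], y[!hold], a_k, scaling)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  list(r_cv = cor(pred, y), predicted = pred, segment = seg)
}

#' Kernel-algorithm PLS1 regression vector
#'
#' Independent route to the same PLS1 solution via the improved kernel
#' algorithm, which works entirely from the cross-product matrices `X'X` and
#' `X'y` without deflating X. Algebraically equivalent to NIPALS for a
#' univariate response; used as a fidelity cross-check.
#'
#' @param X,y,n_factors,scaling as in [pls1_fit()].
#' @return list with `beta` and `intercept` on the raw scale.
#' @export
kernel_pls1 <- function(X, y, n_factors = 3, scaling = c("none", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  x_center <- colMeans(X)
  x_scale <- rep(1, p)
  if (scaling == "pareto") {
    sdev <- apply(X, 2, sd)
    x_scale <- sqrt(sdev); x_scale[sdev == 0] <- Inf
  }
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  s <- drop(crossprod(Xc, yc))
  Rm <- Pm <- matrix(0, p, 0)
  qv <- numeric(0)
  for (a in seq_len(n_factors)) {
    ns <- sqrt(sum(s^2))
    if (ns < 1e-12) break
    w <- s / ns
    r <- w
    if (a > 1L) for (b in seq_len(a - 1L)) r <- r - sum(Pm[, b] * r) * Rm[, b]
    tt <- drop(crossprod(r, XtX %*% r))
    p_a <- drop(XtX %*% r) / tt
    q_a <- sum(r * s) / tt
    s <- s - q_a * tt * p_a
    Rm <- cbind(Rm, r); Pm <- cbind(Pm, p_a); qv <- c(qv, q_a)
  }
  beta_s <- if (ncol(Rm) > 0) drop(Rm %*% qv) else numeric(p)
  beta <- beta_s / x_scale
  list(beta = beta, intercept = mean(y) - sum(x_center * beta))
}

#' Fit a PCA model
#'
#' Mean-centered principal components via singular value decomposition.
#'
#' @param X numeric matrix, samples x variables.
#' @param n_components retained components, at most `min(n - 1, p)`.
#' @return object of class `senes_pca` with `center`, `loadings`
#'   (orthonormal columns), `explained_variance`, `total_variance`.
#' @export
pca_fit <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- min(n_components, n - 1L, ncol(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = k)
  structure(list(center = mu, loadings = sv$v,
                 explained_variance = sv$d[seq_len(k)]^2 / (n - 1L),
                 total_variance = sum(Xc^2) / (n - 1L),
                 n_components = k),
            class = "senes_pca")
}

#' Q-residuals of samples against a PCA model
#'
#' Squared reconstruction error outside the retained component subspace.
#'
#' @param model a `senes_pca`.
#' @param X matrix of samples (same variables as the training data).
#' @return numeric vector, one Q per row of `X`.
#' @export
q_residuals <- function(model, X) {
  stopifnot(inherits(model, "senes_pca"))
  Xc <- sweep(as.matrix(X), 2, model$center)
  Tm <- Xc %*% model$loadings
  E <- Xc - tcrossprod(Tm, model$loadings)
  rowSums(E^2)
}

#' Fit and cross-validate a PLS model on a processed spectra set
#'
#' Convenience wrapper used by the pipeline: pulls the intensity matrix and
#' passage column from a [spectra_set()], fits [pls1_fit()], attaches `R_cv`
#' from [cross_validate()], and keeps the axis for tidy output.
#'
#' @param s processed [spectra_set()] whose sample table has a `passage`
#'   column.
#' @param n_factors latent factors (default 3).
#' @param n_segments,seed cross-validation controls.
#' @param scaling `"none"` or `"pareto"`.
#' @return `senes_pls` with `r_cv` and `axis` filled in.
#' @export
pls_passage_model <- function(s, n_factors = 3, n_segments = 10, seed = 1L,
                              scaling = c("none", "pareto")) {
  stopifnot(inherits(s, "spectra_set"))
  scaling <- match.arg(scaling)
  if (!"passage" %in% names(s$samples)) abort("sample table lacks 'passage'")
  m <- pls1_fit(s$intensities, s$samples$passage, n_factors, scaling)
  cv <- cross_validate(s$intensities, s$samples$passage, n_factors,
                       min(n_segments, nrow(s$intensities)), seed, scaling)
  m$r_cv <- cv$r_cv
  m$cv_predicted <- cv$predicted
  m$axis <- s$axis
  m
}

#' @export
print.senes_pls <- function(x, ...) {
  cat(sprintf("<senes_pls> %d factor(s), %d variables; R_cal = %.3f, R_cv = %.3f\n",
              x$n_factors, length(x$beta), x$r_cal, x$r_cv))
  invisible(x)
}

#' Tidy a PLS model to one row per variable
#'
#' @param x a `senes_pls`.
#' @param ... unused.
#' @return tibble with `axis` (when known), `beta`, `vip`.
#' @export
tidy.senes_pls <- function(x, ...) {
  tb <- tibble(term = seq_along(x$beta), beta = x$beta, vip = x$vip)
  if (!is.null(x$axis)) tb <- dplyr::mutate(tb, axis = x$axis, .before = 1)
  tb
}

#' One-row model summary
#'
#' @param x a `senes_pls`.
#' @param ... unused.
#' @return tibble with factor count, R_cal, R_cv.
#' @export
glance.senes_pls <- function(x, ...) {
  tibble(n_factors = x$n_factors, r_cal = x$r_cal, r_cv = x$r_cv,
         n_samples = length(x$y), n_variables = length(x$beta),
         scaling = x$scaling)
}
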