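#' Significance stars for adjusted p-values
#'
#' Thresholds 0.05 / 0.01 / 0.001 / 0.0001 mapped to `*` ... `****`;
#' `"ns"` otherwise.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf), right = FALSE,
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

# Dunn's multiple-comparison z test on ranks, with tie correction; p-values
# adjusted by `method` (Bonferroni by default, matching the usual follow-up
# to Kruskal-Wallis in biology stats software).
dunn_pairwise <- function(values, groups, method = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble(group1 = a, group2 = b, statistic = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- pmin(1, p.adjust(res$p_value, method = method))
  res
}

#' Compare a measurement across passages
#'
#' Routing follows the distribution of the data: Shapiro-Wilk normality is
#' assessed per group at `normality_alpha`; if every group is consistent
#' with normality the parametric route is taken (one-way ANOVA followed by
#' Tukey's HSD), otherwise the non-parametric route (Kruskal-Wallis followed
#' by Dunn's test with Bonferroni adjustment). A group with zero variance
#' forces the non-parametric route with a warning (ANOVA assumptions cannot
#' hold). The result records which route was taken.
#'
#' @param df data frame with the measurement and grouping columns.
#' @param value name of the measurement column.
#' @param group name of the grouping column (default `"passage"`).
#' @param alpha significance level used for the stars (display only).
#' @param normality_alpha per-group Shapiro-Wilk threshold (default 0.05).
#' @param adjust p-adjustment for Dunn's test (default `"bonferroni"`).
#' @return object of class `comparison_result`: list with `test`
#'   (`"anova_tukey"` or `"kruskal_dunn"`), `omnibus_statistic`, `omnibus_p`,
#'   `pairwise` tibble (`group1`, `group2`, `p_adjusted`, `stars`),
#'   `normality` tibble.
#' @export
select_and_compare <- function(df, value, group = "passage", alpha = 0.05,
                               normality_alpha = 0.05,
                               adjust = "bonferroni") {
  v <- df[[value]]; g <- factor(df[[group]])
  ok <- stats::complete.cases(v, g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(tapply(v, g, length) < 3)) abort("each group needs >= 3 values")
  norm <- purrr::map_dfr(levels(g), function(lv) {
    x <- v[g == lv]
    p <- if (var(x) == 0) NA_real_ else shapiro.test(x)$p.value
    tibble(group = lv, n = length(x), shapiro_p = p)
  })
  if (anyNA(norm$shapiro_p)) {
    warn("a group has zero variance; falling back to Kruskal-Wallis")
    normal <- FALSE
  } else {
    normal <- all(norm$shapiro_p > normality_alpha)
  }
  if (normal) {
    fit <- aov(v ~ g)
    sm <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    pw <- tibble(
      pair = rownames(tk),
      p_adjusted = tk[, "p adj"]) |>
      tidyr::separate(.data$pair, c("group1", "group2"), sep = "-")
    test <- "anova_tukey"
    stat <- sm[["F value"]][1]; omni_p <- sm[["Pr(>F)"]][1]
  } else {
    kw <- kruskal.test(v, g)
    pw <- dunn_pairwise(v, g, adjust) |>
      dplyr::select("group1", "group2", "p_adjusted")
    test <- "kruskal_dunn"
    stat <- unname(kw$statistic); omni_p <- kw$p.value
  }
  pw$stars <- significance_stars(pw$p_adjusted)
  structure(list(test = test, omnibus_statistic = stat, omnibus_p = omni_p,
                 pairwise = as_tibble(pw), normality = norm, alpha = alpha,
                 value = value),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s on '%s': omnibus p = %.3g (%s)\n",
              x$test, x$value, x$omnibus_p,
              significance_stars(x$omnibus_p)))
  print(x$pairwise)
  invisible(x)
}

#' Tidy pairwise comparisons
#'
#' @param x a `comparison_result`.
#' @param ... unused.
#' @return tibble of pairwise comparisons with stars.
#' @export
tidy.comparison_result <- function(x, ...) x$pairwise

#' Population doubling time
#'
#' `PDT = elapsed_hours * ln(2) / ln(n_end / n_start)`: the time for a
#' culture to double in number given exponential growth between two counts.
#' Invariant under rescaling both counts by a common factor.
#'
#' @param n_start,n_end cell counts; requires `n_end > n_start > 0`.
#' @param elapsed_hours culture interval in hours; > 0.
#' @return doubling time in hours.
#' @export
population_doubling_time <- function(n_start, n_end, elapsed_hours) {
  if (any(n_start <= 0)) abort("n_start must be > 0")
  if (any(n_end <= n_start)) abort("n_end must exceed n_start (no doubling)")
  if (any(elapsed_hours <= 0)) abort("elapsed_hours must be > 0")
  elapsed_hours * log(2) / log(n_end / n_start)
}
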