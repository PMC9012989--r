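#' Face-chest temperature-difference features
#'
#' The per-participant features the knowledge-mining rules point to:
#' differences between the face (ROI9 + ROI10) and the chest (ROI13 +
#' ROI14), after excluding background zeros. By default the two side ROIs
#' are pooled pixel-wise; `pool = FALSE` instead averages the per-side
#' statistics before differencing.
#'
#' @param roiset an [segment()] result.
#' @param pool pool pixels across the left/right ROIs (default) or average
#'   per-side summary statistics.
#' @return Named numeric vector `c(d_avg, d_max, d_min)` in degC
#'   (face minus chest).
#' @export
face_chest_delta <- function(roiset, pool = TRUE) {
  stopifnot(inherits(roiset, "roi_set"))
  need <- c("ROI9", "ROI10", "ROI13", "ROI14")
  if (!all(need %in% names(roiset)))
    ta_error("face/chest ROIs missing from the ROI set", "feature_error")
  nz <- lapply(roiset[need], function(q) q$temps[q$temps != 0])
  if (any(vapply(nz, length, 0L) == 0L) && !pool)
    ta_error("an individual face/chest ROI is entirely background", "feature_error")
  if (pool) {
    face <- c(nz$ROI9, nz$ROI10)
    chest <- c(nz$ROI13, nz$ROI14)
    if (!length(face) || !length(chest))
      ta_error("pooled face or chest region is entirely background", "feature_error")
    c(d_avg = mean(face) - mean(chest),
      d_max = max(face) - max(chest),
      d_min = min(face) - min(chest))
  } else {
    s <- function(f) mean(vapply(nz[c("ROI9", "ROI10")], f, numeric(1))) -
      mean(vapply(nz[c("ROI13", "ROI14")], f, numeric(1)))
    c(d_avg = s(mean), d_max = s(max), d_min = s(min))
  }
}

#' Independent two-sample t test
#'
#' Welch (unequal variances, Welch-Satterthwaite fractional df) or pooled
#' (equal variances, df = nA + nB - 2) variant, with the two-sided p value
#' and the 95% confidence interval of the mean difference. The computation
#' is delegated to [stats::t.test()].
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param conf.level confidence level for the interval (default 0.95).
#' @return An object of class `t_test_result`: `t`, `df`, `p`, `mean_diff`,
#'   `se`, `ci` (low, high) and `variant`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "pooled"),
                         conf.level = 0.95) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    ta_error("each group needs at least 2 observations", "input_error")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    ta_error("both groups are constant: standard error is zero", "degenerate_input_error")
  tt <- stats::t.test(a, b, var.equal = variant == "pooled",
                      conf.level = conf.level)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(a) - mean(b),
                 se = unname(tt$stderr), ci = as.numeric(tt$conf.int),
                 variant = variant, conf.level = conf.level),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.3f, df = %.3f, p = %.4g\n",
              x$variant, x$t, x$df, x$p))
  cat(sprintf("  mean difference %.3f degC (SE %.3f), %g%% CI [%.3f, %.3f]\n",
              x$mean_diff, x$se, 100 * x$conf.level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Brown-Forsythe selection between the t-test variants
#'
#' A Levene-style test on the absolute deviations from the group medians:
#' if group variances differ at `alpha`, the Welch variant is recommended,
#' otherwise the pooled one (the convention of spreadsheet-style outputs
#' that print both rows).
#'
#' @inheritParams two_sample_t
#' @param alpha significance level of the homogeneity test (default 0.05).
#' @return List with the homogeneity `p` value and the recommended
#'   `variant`.
#' @export
select_t_variant <- function(a, b, alpha = 0.05) {
  z <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  # tiny or degenerate groups make the F test uninformative; fall through
  # to the pooled recommendation in that case
  p <- suppressWarnings(stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1])
  list(p = p, variant = if (is.finite(p) && p < alpha) "welch" else "pooled")
}

#' Confidence interval from summary statistics
#'
#' `mean_diff +- t_{df, (1 + level) / 2} * se`: recomputes a reported
#' confidence interval from a printed (mean difference, standard error,
#' degrees of freedom) triple.
#'
#' @param mean_diff mean difference (degC).
#' @param se standard error of the difference (degC), >= 0.
#' @param df degrees of freedom (> 0, fractional allowed).
#' @param level confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' ci_from_summary(2.74, 0.33, 83.4)
#' @export
ci_from_summary <- function(mean_diff, se, df, level = 0.95) {
  if (!is.finite(se) || se < 0) ta_error("se must be >= 0", "parameter_error")
  if (!is.finite(df) || df <= 0) ta_error("df must be > 0", "parameter_error")
  h <- stats::qt((1 + level) / 2, df) * se
  c(low = mean_diff - h, high = mean_diff + h)
}

#' Post-hoc power of a two-sample t test from summary statistics
#'
#' Recovers the pooled per-group SD from the standard error of the
#' difference (`sd = se_diff * sqrt(n / 2)`), forms Cohen's d, and evaluates
#' the power of the two-sided test from the noncentral t distribution
#' (via [stats::power.t.test()] with `strict = TRUE`, so a zero effect gives
#' power exactly `alpha`).
#'
#' @param mean_diff observed mean difference (degC).
#' @param se_diff standard error of the difference (degC), > 0.
#' @param n_per_group per-group sample size, >= 2.
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `power_result`: `d`, `n`, `alpha`, `power`.
#' @examples
#' power_two_sample(2.74, 0.33, 43)
#' @export
power_two_sample <- function(mean_diff, se_diff, n_per_group, alpha = 0.05) {
  if (!is.finite(se_diff) || se_diff <= 0)
    ta_error("se_diff must be > 0", "parameter_error")
  if (n_per_group < 2) ta_error("n_per_group must be >= 2", "parameter_error")
  sd_pooled <- se_diff * sqrt(n_per_group / 2)
  pw <- stats::power.t.test(n = n_per_group, delta = abs(mean_diff),
                            sd = sd_pooled, sig.level = alpha,
                            type = "two.sample", alternative = "two.sided",
                            strict = TRUE)$power
  structure(list(d = mean_diff / sd_pooled, n = n_per_group, alpha = alpha,
                 power = pw),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("two-sample power: d = %.3f, n = %d/group, alpha = %.3g -> power %.4f\n",
              x$d, x$n, x$alpha, x$power))
  invisible(x)
}

#' Face-chest verification statistics for two cohorts
#'
#' For each of the three difference features, both t-test variants plus the
#' variant selector and the post-hoc power, in the layout of a standard
#' independent-samples t-test table.
#'
#' @param features_a,features_b data.frames (or matrices) with columns
#'   `d_avg`, `d_max`, `d_min`, one row per participant (group A is the
#'   case group, so differences are reported as A - B).
#' @return A named list (one entry per feature) of lists with `welch`,
#'   `pooled`, `selected` and `power` (power uses the Welch row's SE).
#' @export
verification_stats <- function(features_a, features_b) {
  features_a <- as.data.frame(features_a)
  features_b <- as.data.frame(features_b)
  out <- lapply(c("d_avg", "d_max", "d_min"), function(f) {
    a <- features_a[[f]]; b <- features_b[[f]]
    w <- two_sample_t(a, b, "welch")
    p <- two_sample_t(a, b, "pooled")
    sel <- select_t_variant(a, b)
    n <- min(length(a), length(b))
    list(welch = w, pooled = p, selected = sel$variant,
         levene_p = sel$p,
         power = power_two_sample(w$mean_diff, w$se, n))
  })
  stats::setNames(out, c("d_avg", "d_max", "d_min"))
}
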