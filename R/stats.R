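#' Descriptive summary with t-based confidence interval
#'
#' Sample mean, sample standard deviation (n-1 denominator) and the
#' two-sided Student-t confidence interval for the mean,
#' `mean +/- t(n-1, 1-alpha/2) * sd / sqrt(n)`.
#'
#' @param values Numeric sample, n >= 2.
#' @param confidence Confidence level (default 0.95).
#' @return Tibble with columns `n`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `confidence`.
#' @export
describe <- function(values, confidence = 0.95) {
  if (length(values) < 2L || anyNA(values)) {
    abort("Need at least 2 non-missing values to describe.",
          class = "icgquant_insufficient_data")
  }
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  half <- qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
  tibble(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half,
         confidence = confidence)
}

#' Pooled (equal-variance) two-sample t-test
#'
#' Unpaired two-sided t-test assuming equal group variances, with
#' `df = n_a + n_b - 2` and the confidence interval for the difference in
#' means (`group_a` minus `group_b`) built from the pooled standard
#' deviation. When the pooled variance is zero with unequal means the test
#' statistic is infinite; the result is returned with `infinite_t = TRUE`
#' rather than an error.
#'
#' @param group_a,group_b Numeric samples, each n >= 2.
#' @param alpha Significance level for the CI (default 0.05).
#' @return List of class `pooled_t_result`: `mean_diff`, `t_stat`, `df`,
#'   `p_two_sided`, `ci_low`, `ci_high`, `alpha`, `infinite_t`.
#' @export
pooled_t_test <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L ||
      anyNA(group_a) || anyNA(group_b)) {
    abort("Each group needs at least 2 non-missing values.",
          class = "icgquant_insufficient_data")
  }
  na <- length(group_a); nb <- length(group_b)
  diff <- mean(group_a) - mean(group_b)
  pooled_var <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (pooled_var == 0) {
    inf <- diff != 0
    return(structure(list(
      mean_diff = diff,
      t_stat = if (inf) sign(diff) * Inf else 0,
      df = na + nb - 2L,
      p_two_sided = if (inf) 0 else 1,
      ci_low = diff, ci_high = diff,
      alpha = alpha, infinite_t = inf
    ), class = "pooled_t_result"))
  }
  ht <- t.test(group_a, group_b, var.equal = TRUE, conf.level = 1 - alpha)
  structure(list(
    mean_diff = diff,
    t_stat = unname(ht$statistic),
    df = as.integer(unname(ht$parameter)),
    p_two_sided = ht$p.value,
    ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
    alpha = alpha, infinite_t = FALSE
  ), class = "pooled_t_result")
}

#' @export
print.pooled_t_result <- function(x, ...) {
  cat(sprintf("<pooled t> diff %.4f, t = %.3f (df %d), p = %.3f, %d%% CI [%.5f, %.5f]\n",
              x$mean_diff, x$t_stat, x$df, x$p_two_sided,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  invisible(x)
}

#' One-way (unbalanced) analysis of variance
#'
#' Standard between/within sum-of-squares decomposition over k groups of
#' possibly unequal size; `F = MSB / MSW` referred to the F distribution on
#' `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups List of numeric samples (k >= 2, total N > k).
#' @return List of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("Provide a list of at least 2 groups.",
          class = "icgquant_insufficient_data")
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) {
    abort("Every group needs at least 1 observation.",
          class = "icgquant_insufficient_data")
  }
  k <- length(groups); N <- sum(sizes)
  if (N <= k) {
    abort("Within-group variance undefined: every group is a singleton.",
          class = "icgquant_insufficient_data")
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_len(k), sizes))
  ht <- oneway.test(values ~ fac, var.equal = TRUE)
  structure(list(
    f_stat = unname(ht$statistic),
    df_between = as.integer(unname(ht$parameter["num df"])),
    df_within = as.integer(unname(ht$parameter["denom df"])),
    p = ht$p.value
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova> F(%d, %d) = %.4f, p = %.3f\n",
              x$df_between, x$df_within, x$f_stat, x$p))
  invisible(x)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' the sample's own mean and standard deviation. Because the reference
#' parameters are estimated from the same data, the classical KS p-value is
#' conservative (too large); this is the common statistics-package default
#' and is kept as such, with the caveat recorded in the result. Set
#' `lilliefors = TRUE` for the Lilliefors-corrected p-value (requires the
#' \pkg{nortest} package).
#'
#' @param values Numeric sample, n >= 4.
#' @param lilliefors Use the Lilliefors correction for estimated parameters.
#' @return List of class `normality_result`: `ks_stat`, `p`, `n`, `method`,
#'   `caveat`.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  if (length(values) < 4L || anyNA(values)) {
    abort("Need at least 4 non-missing values for the normality screen.",
          class = "icgquant_insufficient_data")
  }
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      abort("`lilliefors = TRUE` requires the 'nortest' package.",
            class = "icgquant_bad_spec")
    }
    ht <- nortest::lillie.test(values)
    method <- "Lilliefors-corrected Kolmogorov-Smirnov"
    caveat <- NULL
  } else {
    ht <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
    method <- "one-sample Kolmogorov-Smirnov, estimated parameters"
    caveat <- paste("Reference mean/sd estimated from the sample;",
                    "p-value is conservative (no Lilliefors correction).")
  }
  structure(list(
    ks_stat = unname(ht$statistic),
    p = ht$p.value,
    n = length(values),
    method = method,
    caveat = caveat
  ), class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<ks normality> D = %.4f, p = %.3f (n = %d; %s)\n",
              x$ks_stat, x$p, x$n, x$method))
  invisible(x)
}

#' Pre- vs post-ischemia comparison table for one segment
#'
#' For each post-ischemia observation time, compares the segment's
#' pre-ischemia group against that time's group with the pooled two-sample
#' t-test, and reports group size, mean and SD together with the p-value
#' and the confidence interval for the difference (pre minus post). This is
#' the per-segment comparison table of a pre/post study report. No
#' multiple-testing correction is applied; a note is emitted when more than
#' two comparisons are run.
#'
#' @inheritParams group_mean
#' @param alpha Significance level for the CIs.
#' @return Tibble with one reference row (the pre group) and one row per
#'   post time: `comparison`, `n`, `mean`, `sd`, `p`, `ci_low`, `ci_high`.
#' @export
segment_comparisons <- function(study, segment, alpha = 0.05) {
  study <- as_study_matrix(study)
  pre <- study$saturation[study$segment == segment & study$time_label == "pre"]
  if (length(pre) < 2L) {
    abort(sprintf("Need >= 2 pre-ischemia observations for segment '%s'.", segment),
          class = "icgquant_insufficient_data")
  }
  rows <- list(tibble(
    comparison = "pre", n = length(pre), mean = mean(pre), sd = sd(pre),
    p = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  times_present <- POST_LABELS[POST_LABELS %in%
                                 study$time_label[study$segment == segment]]
  for (tl in times_present) {
    g <- study$saturation[study$segment == segment & study$time_label == tl]
    tt <- pooled_t_test(pre, g, alpha = alpha)
    rows[[length(rows) + 1L]] <- tibble(
      comparison = paste0("pre vs ", tl), n = length(g),
      mean = mean(g), sd = sd(g),
      p = tt$p_two_sided, ci_low = tt$ci_low, ci_high = tt$ci_high)
  }
  if (length(times_present) > 2L) {
    inform(sprintf(
      "%d uncorrected comparisons for segment '%s'; no multiple-testing adjustment applied.",
      length(times_present), segment))
  }
  dplyr::bind_rows(rows)
}

#' One-way ANOVA over observation times for one segment
#'
#' Tests stability of the segment's mean intensity across observation
#' times. With `include_pre = TRUE` the pre-ischemia group enters as a
#' sixth group (stability of the whole experiment); with `FALSE` only the
#' post-ischemia times are compared (stability within the ischemia period).
#'
#' @inheritParams group_mean
#' @param include_pre Include the pre-ischemia group.
#' @return An `anova_result` (see [one_way_anova()]).
#' @export
anova_by_time <- function(study, segment, include_pre = FALSE) {
  study <- as_study_matrix(study)
  labels <- if (include_pre) TIME_LABELS else POST_LABELS
  groups <- lapply(labels, function(tl) {
    study$saturation[study$segment == segment & study$time_label == tl]
  })
  groups <- groups[lengths(groups) > 0L]
  one_way_anova(groups)
}
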