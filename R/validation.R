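#' Pearson correlation with Fisher-z confidence interval
#'
#' Pairs with either value missing are dropped (and counted); the 95%
#' confidence interval is the Fisher transform interval
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{0.975} / \sqrt{n - 3})}.
#'
#' @param x,y Numeric vectors of equal length.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `r`, `n`, `conf_low`, `conf_high`, `n_dropped`.
#' @export
#' @examples
#' pearson_cor(1:10, (1:10) + rnorm(10))
pearson_cor <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) abort("pearson_cor: need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("pearson_cor: zero variance in one of the vectors")
  }
  r <- cor(x[ok], y[ok])
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    r = r, n = n,
    conf_low = tanh(z - crit * se), conf_high = tanh(z + crit * se),
    n_dropped = length(x) - n
  )
}

icc_band <- function(icc) {
  dplyr::case_when(
    icc > 0.9 ~ "excellent",
    icc >= 0.75 ~ "good",
    icc >= 0.5 ~ "moderate",
    TRUE ~ "poor"
  )
}

#' Test-retest intraclass correlation
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC —
#' ICC(A,1) in the McGraw & Wong taxonomy, the standard test-retest choice
#' under the good (0.75-0.9) / excellent (> 0.9) interpretation bands —
#' computed from the two-way ANOVA mean squares over subjects with both
#' occasions: \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#' \frac{k}{n}(MS_C - MS_E)}} with the F-distribution confidence interval of
#' McGraw & Wong (1996). A one-way random-effects form, ICC(1), is available
#' as an option. Subjects missing either occasion are excluded (and
#' counted); fewer than two complete subjects is an error.
#'
#' @param test,retest Paired numeric vectors (one entry per subject), or a
#'   data frame as `test` with columns `test` and `retest`.
#' @param form `"ICC(A,1)"` (default) or `"ICC(1)"`.
#' @param conf_level Confidence level.
#' @return A one-row tibble: `icc`, `conf_low`, `conf_high`, `n_subjects`,
#'   `n_excluded`, `band`, `form`.
#' @export
icc_test_retest <- function(test, retest = NULL, form = c("ICC(A,1)", "ICC(1)"),
                            conf_level = 0.95) {
  form <- match.arg(form)
  if (is.data.frame(test)) {
    retest <- test$retest
    test <- test$test
  }
  stopifnot(length(test) == length(retest))
  ok <- !is.na(test) & !is.na(retest)
  n_excluded <- sum(!ok)
  x <- cbind(test[ok], retest[ok])
  n <- nrow(x)
  if (n < 2) abort("icc_test_retest: need at least 2 subjects with both occasions")
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  # residual SS computed directly (not by subtraction), so identical
  # occasions give exactly zero
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level

  if (form == "ICC(1)") {
    msw <- (ss_cols + ss_err) / (n * (k - 1))
    icc <- (msr - msw) / (msr + (k - 1) * msw)
    fl <- (msr / msw) / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- (msr / msw) * qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    icc <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      lo <- hi <- 1 # perfect agreement: degenerate interval
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      if (!is.finite(a) || !is.finite(b)) {
        lo <- hi <- icc
      } else {
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        f_u <- qf(1 - alpha / 2, n - 1, v)
        f_l <- qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msr - f_u * mse) /
          (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
        hi <- n * (f_l * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * f_l * msr)
      }
    }
  }
  tibble::tibble(
    icc = icc, conf_low = min(lo, icc), conf_high = max(hi, icc),
    n_subjects = n, n_excluded = n_excluded,
    band = icc_band(icc), form = form
  )
}

#' Compare severity between age groups
#'
#' Two-sample t-test of global severity between the under-7 and 7-and-over
#' groups (Welch by default; a pooled-variance Student test is available).
#'
#' @param scores Numeric severity scores.
#' @param groups Factor/character group labels of the same length.
#' @param flavor `"welch"` (default) or `"pooled"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   group means and sizes, `flavor`.
#' @export
age_group_t_test <- function(scores, groups, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  ok <- !is.na(scores) & !is.na(groups)
  scores <- scores[ok]
  groups <- as.character(groups[ok])
  lev <- unique(groups)
  if (length(lev) != 2) abort("age_group_t_test: need exactly two groups")
  a <- scores[groups == lev[1]]
  b <- scores[groups == lev[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("age_group_t_test: each group needs at least 2 members")
  }
  tt <- t.test(a, b, var.equal = (flavor == "pooled"))
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_diff = mean(a) - mean(b),
    group1 = lev[1], n1 = length(a), mean1 = mean(a),
    group2 = lev[2], n2 = length(b), mean2 = mean(b),
    flavor = flavor
  )
}

#' External-validation report for severity scores
#'
#' Assembles the convergent-validity statistics: Pearson correlations (with
#' Fisher-z intervals, pairwise-complete) of global severity against each
#' available external correlate (EEG alpha/delta and theta/delta ratios,
#' quality-of-life total, caregiver behavior domain), the age-group t-test,
#' a histogram of the severity distribution overall and by age group, and
#' least-squares scatter plots against each correlate. Correlates entirely
#' missing from the cohort are omitted with a note.
#'
#' @param cohort Cohort tibble (baseline rows used).
#' @param scores A tibble with `subject_id` and a severity column (`severity`
#'   from [apply_weights()] or `global` from [factor_scores()]).
#' @param score_col Name of the severity column in `scores`.
#' @param t_test_flavor Passed to [age_group_t_test()].
#' @return An object of class `cdd_validation_report`: list with
#'   `correlations` (tibble), `age_t_test` (tibble), `omitted` (character),
#'   `plots` (list of ggplots), `n`.
#' @export
validation_report <- function(cohort, scores, score_col = NULL,
                              t_test_flavor = c("welch", "pooled")) {
  base <- if ("visit" %in% names(cohort)) {
    dplyr::filter(cohort, .data$visit == "baseline")
  } else {
    cohort
  }
  if (is.null(score_col)) {
    score_col <- intersect(c("severity", "global", "score"), names(scores))[1]
    if (is.na(score_col)) abort("validation_report: no severity column found in scores")
  }
  dat <- dplyr::inner_join(
    base,
    dplyr::select(scores, "subject_id", score = dplyr::all_of(score_col)),
    by = "subject_id"
  )
  correlates <- c("eeg_alpha_delta", "eeg_theta_delta", "qol_total", "behavior")
  have <- intersect(correlates, names(dat))
  have <- have[vapply(have, function(v) sum(!is.na(dat[[v]]) & !is.na(dat$score)) >= 3,
                      logical(1))]
  omitted <- setdiff(correlates, have)
  if (length(omitted) > 0) {
    inform(paste0("validation_report: omitted (absent or too sparse): ",
                  paste(omitted, collapse = ", ")))
  }
  correlations <- purrr::map_dfr(have, function(v) {
    dplyr::mutate(pearson_cor(dat$score, dat[[v]]), correlate = v,
                  .before = 1)
  })
  age_tt <- if ("age_group" %in% names(dat) &&
                length(unique(na.omit(dat$age_group))) == 2) {
    age_group_t_test(dat$score, dat$age_group, flavor = t_test_flavor)
  } else {
    NULL
  }
  plots <- list(distribution = plot_severity_distribution(dat, score_col = "score"))
  for (v in have) {
    plots[[v]] <- plot_severity_scatter(dat, correlate = v, score_col = "score")
  }
  structure(
    list(correlations = correlations, age_t_test = age_tt,
         omitted = omitted, plots = plots, n = nrow(dat)),
    class = "cdd_validation_report"
  )
}

#' @export
print.cdd_validation_report <- function(x, ...) {
  cat("<cdd_validation_report> n =", x$n, "\n")
  if (nrow(x$correlations) > 0) print(x$correlations)
  if (!is.null(x$age_t_test)) {
    cat(sprintf("age-group t-test (%s): t = %.3f, p = %.3f\n",
                x$age_t_test$flavor, x$age_t_test$statistic,
                x$age_t_test$p_value))
  }
  if (length(x$omitted) > 0) {
    cat("omitted correlates:", paste(x$omitted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname validation_report
#' @param x A `cdd_validation_report`.
#' @param ... Unused.
#' @method tidy cdd_validation_report
#' @export
tidy.cdd_validation_report <- function(x, ...) x$correlations

#' Table of test-retest reliabilities
#'
#' Computes the ICC (with confidence interval and interpretation band) for
#' each of the nine component scores and for the global severity score, over
#' subjects with both a baseline and a retest visit. The global score is the
#' weighted average of the harmonized components under `weights`, computed
#' per visit.
#'
#' @param cohort Cohort tibble containing baseline and retest rows.
#' @param weights Weight set for the global score (default: published).
#' @param form ICC form, see [icc_test_retest()].
#' @return A tibble with one row per score plus `"global_severity"`.
#' @export
reliability_table <- function(cohort, weights = cdd_published_weights(),
                              form = "ICC(A,1)") {
  vars <- intersect(cdd_score_names(), names(cohort))
  h <- harmonize(cohort)
  wide <- function(v) {
    tidyr::pivot_wider(
      dplyr::select(h, "subject_id", "visit", value = dplyr::all_of(v)),
      names_from = "visit", values_from = "value"
    )
  }
  rows <- purrr::map_dfr(vars, function(v) {
    d <- wide(v)
    if (!all(c("baseline", "retest") %in% names(d))) return(NULL)
    dplyr::mutate(
      icc_test_retest(d$baseline, d$retest, form = form),
      score = v, .before = 1
    )
  })
  sev <- apply_weights(h, weights, missing = "renormalize")
  sev_wide <- tidyr::pivot_wider(
    dplyr::select(sev, "subject_id", "visit", "severity"),
    names_from = "visit", values_from = "severity"
  )
  if (all(c("baseline", "retest") %in% names(sev_wide))) {
    rows <- dplyr::bind_rows(
      rows,
      dplyr::mutate(icc_test_retest(sev_wide$baseline, sev_wide$retest, form = form),
                    score = "global_severity", .before = 1)
    )
  }
  rows
}
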