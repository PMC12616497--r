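#' Write / read a cohort table as CSV
#'
#' The CSV has one row per (subject, visit), empty cells for missing values,
#' and a provenance header of `#`-prefixed comment lines (package version,
#' generator seed when known, config hash) that [read_cohort()] skips.
#' Reading validates the table: values outside a score's declared range and
#' duplicated (subject, visit) pairs are errors naming the offending
#' row/column; unknown columns are kept with a warning.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @param extra_header Optional named character vector of additional
#'   provenance fields.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path, extra_header = NULL) {
  hdr <- c(
    package = paste0("cddseverity ", as.character(utils::packageVersion("cddseverity"))),
    seed = as.character(attr(cohort, "config_seed") %||% NA),
    extra_header
  )
  lines <- paste0("# ", names(hdr), ": ", unname(hdr))
  body <- readr::format_csv(cohort, na = "")
  writeLines(c(lines, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- readr::read_csv(path, comment = "#", na = c("", "NA"),
                       show_col_types = FALSE,
                       locale = readr::locale(encoding = "UTF-8"))
  info <- cdd_variables()
  known <- c("subject_id", "visit", "age_group", "sex", info$variable)
  unknown <- setdiff(names(d), known)
  if (length(unknown) > 0) {
    warn(paste0("read_cohort: unknown column(s) kept as-is: ",
                paste(unknown, collapse = ", ")))
  }
  for (v in intersect(info$variable, names(d))) {
    lo <- info$min[info$variable == v]
    hi <- info$max[info$variable == v]
    bad <- which(!is.na(d[[v]]) & (d[[v]] < lo | d[[v]] > hi))
    if (length(bad) > 0) {
      abort(sprintf("read_cohort: value %g out of range [%g, %g] in column '%s', row %d",
                    d[[v]][bad[1]], lo, hi, v, bad[1]))
    }
  }
  if (all(c("subject_id", "visit") %in% names(d))) {
    dup <- duplicated(d[, c("subject_id", "visit")])
    if (any(dup)) {
      abort(sprintf("read_cohort: duplicate (subject_id, visit) pair at row %d",
                    which(dup)[1]))
    }
  }
  d
}

#' Run the full severity pipeline
#'
#' Chains every stage end to end: inclusion filtering, harmonization, FIML
#' model fitting, factor scoring, standardization, regression-based weight
#' derivation, weighted-average scoring, test-retest reliability (when
#' retest rows exist) and the external-validation report. With `output_dir`
#' set, writes the fit report (`fit_report.json`), the derived weights
#' (`weights.csv`), per-subject scores (`scores.csv`), the validation report
#' (`validation.json`), the reliability table (`reliability.csv`, if
#' applicable) and the distribution/scatter figures (PNG). Identical input
#' and options give identical outputs; every stage is deterministic given
#' the cohort.
#'
#' @param cohort Cohort tibble or path to a cohort CSV.
#' @param model A [sem_model()]; default [default_cdd_model()].
#' @param output_dir Optional directory for the output bundle.
#' @param inclusion_rule,min_scores Passed to [filter_inclusion()].
#' @param icc_form Passed to [reliability_table()].
#' @param t_test_flavor Passed to [validation_report()].
#' @param options Passed to [fit_sem()].
#' @param write_figures Write PNG figures when `output_dir` is set.
#' @return Invisibly, a list with `fit`, `factor_scores`, `scores` (tibble
#'   with standardized factor score and weighted-average severity),
#'   `weights`, `validation`, `reliability` (or `NULL`), `n_excluded`.
#' @export
run_pipeline <- function(cohort, model = default_cdd_model(),
                         output_dir = NULL,
                         inclusion_rule = c("variables", "instruments"),
                         min_scores = 2,
                         icc_form = "ICC(A,1)",
                         t_test_flavor = c("welch", "pooled"),
                         options = fit_options(),
                         write_figures = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  inclusion_rule <- match.arg(inclusion_rule)

  included <- filter_inclusion(cohort, rule = inclusion_rule,
                               min_scores = min_scores)
  n_excluded <- attr(included, "n_excluded")
  harmonized <- harmonize(included)

  fit <- fit_sem(model, harmonized, options = options)
  fs <- factor_scores(model, fit, harmonized)
  fs$global_std <- standardize(fs$global)

  weights <- derive_weights(harmonized, fs)
  wavg <- apply_weights(harmonized, weights, missing = "renormalize")
  scores <- dplyr::left_join(
    dplyr::select(fs, "subject_id", "global_std", "n_observed"),
    dplyr::select(wavg, "subject_id", weighted_severity = "severity"),
    by = "subject_id"
  )
  scores <- dplyr::left_join(
    scores,
    dplyr::select(included, "subject_id",
                  dplyr::any_of(c("age_group", "sex"))),
    by = "subject_id"
  )

  validation <- validation_report(included,
                                  dplyr::rename(scores, severity = "global_std"),
                                  score_col = "severity",
                                  t_test_flavor = t_test_flavor)
  reliability <- if ("visit" %in% names(cohort) &&
                     any(cohort$visit == "retest")) {
    reliability_table(cohort, weights = weights, form = icc_form)
  } else {
    NULL
  }

  result <- list(fit = fit, factor_scores = fs, scores = scores,
                 weights = weights, validation = validation,
                 reliability = reliability, n_excluded = n_excluded)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(package = as.character(utils::packageVersion("cddseverity")),
                 n_excluded = n_excluded, inclusion_rule = inclusion_rule)
    jsonlite::write_json(
      c(meta, list(
        parameters = as.list(fit$theta),
        loglik = fit$loglik, loglik_saturated = fit$loglik_saturated,
        loglik_baseline = fit$loglik_baseline,
        chi_square = fit$chi_square, df = fit$df,
        chi_square_over_df = fit$chi_square_over_df,
        rmsea = fit$rmsea, cfi = fit$cfi, tli = fit$tli,
        n_used = fit$n_used, converged = fit$converged,
        n_iterations = fit$n_iterations
      )),
      file.path(output_dir, "fit_report.json"),
      auto_unbox = TRUE, digits = NA
    )
    write_weights(weights, file.path(output_dir, "weights.csv"))
    readr::write_csv(scores, file.path(output_dir, "scores.csv"))
    jsonlite::write_json(
      list(meta = meta,
           correlations = validation$correlations,
           age_t_test = validation$age_t_test,
           omitted = validation$omitted),
      file.path(output_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    if (!is.null(reliability)) {
      readr::write_csv(reliability, file.path(output_dir, "reliability.csv"))
    }
    if (write_figures) {
      ggplot2::ggsave(file.path(output_dir, "severity_distribution.png"),
                      validation$plots$distribution, width = 6, height = 7,
                      dpi = 150)
      for (v in setdiff(names(validation$plots), "distribution")) {
        ggplot2::ggsave(file.path(output_dir, paste0("scatter_", v, ".png")),
                        validation$plots[[v]], width = 6, height = 5,
                        dpi = 150)
      }
    }
  }
  invisible(result)
}
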