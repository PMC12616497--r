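#' Harmonize scores to a common severity-oriented 0-100 scale
#'
#' Linearly maps each score onto 0-100 and flips the direction of
#' higher-is-better instruments so that, after harmonization, higher always
#' means greater severity: \eqn{x' = 100 (x - min) / (max - min)}, then
#' \eqn{x' \leftarrow 100 - x'} for `"higher_better"` variables. The flip is
#' an involution: applying it twice restores the original value. Values
#' outside the declared range are an error naming the offending variable.
#'
#' @param cohort Cohort tibble.
#' @param orientation Named character vector (`"higher_better"` /
#'   `"higher_severity"`); defaults to the instrument card in
#'   [cdd_variables()].
#' @param ranges Named list of `c(min, max)`; same default.
#' @param vars Variables to harmonize (default: the nine modeled scores
#'   present in the cohort).
#' @return The cohort with the selected columns replaced by harmonized
#'   values.
#' @export
harmonize <- function(cohort, orientation = NULL, ranges = NULL, vars = NULL) {
  info <- cdd_variables()
  if (is.null(vars)) vars <- intersect(cdd_score_names(), names(cohort))
  if (is.null(orientation)) {
    orientation <- setNames(info$direction, info$variable)
  }
  if (is.null(ranges)) {
    ranges <- setNames(purrr::map2(info$min, info$max, c), info$variable)
  }
  out <- cohort
  for (v in vars) {
    r <- ranges[[v]]
    if (is.null(r)) abort(paste0("no harmonization range declared for '", v, "'"))
    x <- out[[v]]
    bad <- which(!is.na(x) & (x < r[1] | x > r[2]))
    if (length(bad) > 0) {
      abort(sprintf("harmonize: value %g in '%s' (row %d) outside declared range [%g, %g]",
                    x[bad[1]], v, bad[1], r[1], r[2]))
    }
    h <- 100 * (x - r[1]) / (r[2] - r[1])
    if (identical(orientation[[v]], "higher_better")) h <- 100 - h
    out[[v]] <- h
  }
  out
}

#' Standardize a score vector to mean 0, SD 1
#'
#' Subtracts the sample mean and divides by the sample standard deviation
#' (n - 1 denominator), ignoring missing values. A vector without at least
#' two distinct non-missing values is an error rather than a silent NaN.
#'
#' @param x Numeric vector.
#' @return The standardized vector (missing entries stay missing).
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2 || length(unique(x[ok])) < 2) {
    abort("standardize: need at least two distinct non-missing values")
  }
  s <- sd(x[ok])
  if (s == 0) abort("standardize: zero variance")
  (x - mean(x[ok])) / s
}

new_weight_set <- function(weights, provenance, seed = NA_integer_) {
  vars <- cdd_score_names()
  w <- weights[vars]
  if (anyNA(w)) abort("weight set must cover all nine scores")
  structure(
    tibble::tibble(variable = vars, weight = unname(w)),
    provenance = provenance, seed = seed,
    class = c("cdd_weight_set", class(tibble::tibble()))
  )
}

#' The published component weightings for global severity
#'
#' The shipped default weight set for the weighted-average severity score:
#' motor 0.467, insomnia 0.007, daytime sleepiness 0.012, seizures 0.012,
#' alertness 0.111, clinician communication 0.105, CSBS 0.142, vision 0.091,
#' feeding 0.052. The printed values sum to 0.999 from rounding; they are
#' renormalized by their sum at load, preserving the printed ratios, so the
#' returned set satisfies the unit-sum invariant exactly.
#'
#' @return A `cdd_weight_set` tibble (`variable`, `weight`) with provenance
#'   `"published-default"`.
#' @export
#' @examples
#' sum(cdd_published_weights()$weight)
cdd_published_weights <- function() {
  printed <- c(motor = 0.467, vision = 0.091, feeding = 0.052,
               communication_clin = 0.105, csbs = 0.142,
               insomnia = 0.007, sleepiness = 0.012, seizures = 0.012,
               alertness = 0.111)
  new_weight_set(printed / sum(printed), provenance = "published-default")
}

#' Derive component weightings from fitted severity scores
#'
#' Regresses the standardized global severity factor score on the nine
#' harmonized observed scores by ordinary least squares over complete cases
#' only, then rescales the slope coefficients by their sum (the intercept is
#' discarded) so the weights sum to one and the weighted average lives on
#' the common 0-100 component metric. Negative slopes are kept (with a
#' warning), since truncation would break the least-squares reconstruction
#' of the factor score.
#'
#' @param cohort Harmonized cohort tibble (see [harmonize()]), baseline rows.
#' @param scores Factor-score tibble from [factor_scores()] (column
#'   `global`), joined by `subject_id`.
#' @param standardize_score Standardize the global score over the regression
#'   sample first (default `TRUE`; the weights are invariant to this).
#' @return A `cdd_weight_set` with provenance `"derived"`; the unscaled OLS
#'   slopes and the complete-case count are attached as attributes
#'   `"raw_coefficients"` and `"n_complete"`.
#' @export
derive_weights <- function(cohort, scores, standardize_score = TRUE) {
  vars <- cdd_score_names()
  dat <- dplyr::inner_join(
    dplyr::select(cohort, "subject_id", dplyr::all_of(vars)),
    dplyr::select(scores, "subject_id", "global"),
    by = "subject_id"
  )
  dat <- dat[complete.cases(dat[, c(vars, "global")]), ]
  if (nrow(dat) <= length(vars)) {
    abort("derive_weights: not enough complete cases for the regression")
  }
  y <- if (standardize_score) standardize(dat$global) else dat$global
  X <- as.matrix(dat[, vars])
  fit <- lm(y ~ X)
  b <- coef(fit)[-1]
  names(b) <- vars
  if (anyNA(b)) abort("derive_weights: rank-deficient design matrix")
  s <- sum(b)
  if (abs(s) < 1e-10) {
    abort("derive_weights: coefficients sum to ~0, unit-sum rescaling undefined")
  }
  if (any(b < 0)) {
    warn(sprintf("derive_weights: %d negative coefficient(s) kept; the weighted-average interpretation is weakened",
                 sum(b < 0)))
  }
  out <- new_weight_set(b / s, provenance = "derived")
  attr(out, "raw_coefficients") <- b
  attr(out, "n_complete") <- nrow(dat)
  out
}

#' Weighted-average global severity score
#'
#' Applies a unit-sum weight set to harmonized component scores: the dot
#' product of the nine scores with their weights, returned on the same 0-100
#' severity metric as the components. By default any missing component is an
#' error listing what is absent; `missing = "renormalize"` instead rescales
#' the weights of the observed components to sum to one — an extrapolation
#' beyond the published scoring rule, flagged per subject in the
#' `n_components` column.
#'
#' @param cohort Harmonized cohort tibble (baseline and/or retest rows).
#' @param weights A `cdd_weight_set` ([cdd_published_weights()] or
#'   [derive_weights()]).
#' @param missing `"error"` (default) or `"renormalize"`.
#' @return A tibble `subject_id`, `visit` (if present), `severity`,
#'   `n_components`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_subjects = 20, seed = 1,
#'                                            missing_rates = c(clinician = 0)))
#' apply_weights(harmonize(cohort), cdd_published_weights())
apply_weights <- function(cohort, weights, missing = c("error", "renormalize")) {
  missing <- match.arg(missing)
  vars <- weights$variable
  X <- as.matrix(as.data.frame(cohort)[, vars, drop = FALSE])
  w <- weights$weight
  pres <- !is.na(X)
  n_comp <- rowSums(pres)
  if (missing == "error" && any(n_comp < length(vars))) {
    i <- which(n_comp < length(vars))[1]
    abort(sprintf("apply_weights: row %d is missing component(s): %s (use missing = \"renormalize\" to rescale)",
                  i, paste(vars[!pres[i, ]], collapse = ", ")))
  }
  Xz <- X
  Xz[!pres] <- 0
  wsum <- pres %*% w
  sev <- as.vector((Xz %*% w) / wsum)
  sev[n_comp == 0] <- NA_real_
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(cohort)) cohort$subject_id
                 else as.character(seq_len(nrow(X))),
    severity = sev, n_components = n_comp
  )
  if ("visit" %in% names(cohort)) {
    out <- dplyr::mutate(out, visit = cohort$visit, .after = "subject_id")
  }
  out
}

#' @export
print.cdd_weight_set <- function(x, ...) {
  cat("<cdd_weight_set> provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

#' @rdname derive_weights
#' @param x A `cdd_weight_set`.
#' @param ... Unused.
#' @method tidy cdd_weight_set
#' @export
tidy.cdd_weight_set <- function(x, ...) {
  tibble::tibble(variable = x$variable, weight = x$weight,
                 provenance = attr(x, "provenance"))
}

#' Read or write a weight set as CSV
#'
#' @param weights A `cdd_weight_set`.
#' @param path File path.
#' @return `read_weights()` returns a `cdd_weight_set`; `write_weights()`
#'   returns `path` invisibly.
#' @export
write_weights <- function(weights, path) {
  readr::write_csv(tidy(weights), path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  w <- setNames(d$weight, d$variable)
  new_weight_set(w / sum(w),
                 provenance = if ("provenance" %in% names(d)) d$provenance[1] else "file")
}
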