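#' Configuration for the synthetic CDD cohort generator
#'
#' Builds the parameter set from which [generate_cohort()] simulates a cohort
#' with the statistical structure the severity analysis assumes: a standard
#' normal latent Global severity driven by two correlated exogenous latents
#' (Communication, Comorbidities), nine bounded observed scores loading on
#' those latents, external correlates linear in Global, instrument-block
#' missingness, and demographic covariates that are independent of severity.
#'
#' Defaults reproduce the published cohort's structure: n = 206 subjects,
#' per-instrument missingness of 4% (caregiver CCSA), 20% (CSBS), 28%
#' (clinician CCSA), 30% (quality of life), 39% (sleep questionnaire),
#' a 78% missing rate for the EEG ratios (45 of 206 assessed), a retest
#' subgroup of 18/206, 51.5% of subjects under 7 years, 82% female, and
#' external-correlate targets r = 0.61 (alpha/delta), 0.68 (QoL), -0.21
#' (behavior). Observed-score means match the published cohort; SDs are the
#' published SDs shrunk where necessary so that under the Gaussian generating
#' model fewer than 1% of draws fall outside the declared scale range
#' (boundary clipping is logged in the `clip_fraction` attribute).
#'
#' @param n_subjects Number of baseline subjects.
#' @param seed Integer seed; the same config and seed give a byte-identical
#'   table. The retest stage derives its own stream as `seed + 500009`.
#' @param structural_coefficients Named list/vector with
#'   `global_on_communication`, `global_on_comorbidities`, `exo_cov`
#'   (covariance of the two unit-variance exogenous latents). The Global
#'   disturbance variance is set so Var(Global) = 1 exactly.
#' @param loadings,residual_sds Named numeric vectors over the nine scores
#'   (see [cdd_variables()]); loadings of the latent on the unbounded signal
#'   scale, and signal residual SDs.
#' @param scale_means,scale_sds Target mean/SD of each raw score on its
#'   instrument scale.
#' @param scale_ranges Named list of `c(min, max)` per score.
#' @param orientation Named character vector, `"higher_severity"` or
#'   `"higher_better"` per score; `"higher_better"` scores decrease with the
#'   latent severity.
#' @param missing_rates Named vector of per-instrument missing proportions
#'   (`clinician`, `caregiver`, `sleep`, `csbs`, `qol`, `eeg`); all scores of
#'   an instrument go missing together, with the realized count fixed at
#'   `round(rate * n)`.
#' @param missing_mechanism `"mcar"` (default) or `"mar"`; under MAR the
#'   probability of being selected as missing increases with latent Global
#'   severity through a logistic tilt of slope `mar_slope`, keeping the
#'   marginal rate exact.
#' @param mar_slope Severity tilt for MAR missingness.
#' @param retest_fraction Fraction of baseline subjects with a retest visit.
#' @param retest_noise_sd Measurement noise SD (raw-score units) added at the
#'   retest occasion, scalar or named per score. `NULL` (default) targets a
#'   test-retest ICC of 0.9 per score via [retest_sd_for_icc()].
#' @param external_targets Named vector of target Pearson correlations for
#'   `eeg_alpha_delta`, `eeg_theta_delta`, `qol_total`, `behavior`.
#' @param external_anchor `"latent"`: targets refer to the correlation with
#'   the latent Global itself; `"composite"`: with the harmonized weighted
#'   composite under `composite_weights`, correcting the generating slope for
#'   attenuation (see [implied_composite_cor()]).
#' @param composite_weights A weight set (see [cdd_published_weights()]) used
#'   when `external_anchor = "composite"`.
#' @param age_mix Proportion of subjects under 7 years.
#' @param female_fraction Proportion female. Demographics are independent of
#'   the latents, so downstream age-group comparisons are null by design.
#' @param standardized If `TRUE`, skip the affine scale mapping and emit the
#'   unbounded signal `loading x latent + noise` directly (orientation
#'   ignored). Used for parameter-recovery studies where fitted loadings are
#'   compared with generating loadings on a common scale.
#' @return A validated object of class `cdd_generator_config`.
#' @export
generator_config <- function(
    n_subjects = 206,
    seed = 1,
    structural_coefficients = list(global_on_communication = 0.6,
                                   global_on_comorbidities = 0.5,
                                   exo_cov = 0.4),
    loadings = c(motor = 1, vision = 0.8, feeding = 0.6,
                 communication_clin = 1, csbs = 0.9,
                 insomnia = 1, sleepiness = 0.9, seizures = 0.7,
                 alertness = 0.8),
    residual_sds = c(motor = 0.35, vision = 0.6, feeding = 0.9,
                     communication_clin = 0.5, csbs = 0.6,
                     insomnia = 1.8, sleepiness = 1.7, seizures = 1.5,
                     alertness = 0.7),
    scale_means = NULL,
    scale_sds = NULL,
    scale_ranges = NULL,
    orientation = NULL,
    missing_rates = c(clinician = 0.28, caregiver = 0.04, sleep = 0.39,
                      csbs = 0.20, qol = 0.30, eeg = 1 - 45 / 206),
    missing_mechanism = c("mcar", "mar"),
    mar_slope = 1,
    retest_fraction = 18 / 206,
    retest_noise_sd = NULL,
    external_targets = c(eeg_alpha_delta = 0.61, eeg_theta_delta = 0.55,
                         qol_total = 0.68, behavior = -0.21),
    external_anchor = c("latent", "composite"),
    composite_weights = NULL,
    age_mix = 106 / 206,
    female_fraction = 0.82,
    standardized = FALSE) {
  info <- cdd_variables()
  vars <- cdd_score_names()
  if (is.null(scale_means)) {
    scale_means <- setNames(info$mean, info$variable)
  }
  if (is.null(scale_ranges)) {
    scale_ranges <- setNames(purrr::map2(info$min, info$max, c), info$variable)
  }
  if (is.null(orientation)) {
    orientation <- setNames(info$direction, info$variable)
  }
  if (is.null(scale_sds)) {
    # shrink printed SDs so Gaussian draws stay inside the scale range
    # (< 1% clipped: mean +/- 2.81 SD within bounds)
    scale_sds <- purrr::map_dbl(setNames(info$variable, info$variable), function(v) {
      r <- scale_ranges[[v]]
      m <- scale_means[[v]]
      s <- info$sd[info$variable == v]
      if (is.null(r) || length(r) != 2) return(s) # caught by validation
      bound <- min(m - r[1], r[2] - m) / 2.81
      if (is.finite(bound)) min(s, bound) else s
    })
  }
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      structural_coefficients = as.list(structural_coefficients),
      loadings = loadings[vars], residual_sds = residual_sds[vars],
      scale_means = scale_means, scale_sds = scale_sds,
      scale_ranges = scale_ranges, orientation = orientation,
      missing_rates = missing_rates,
      missing_mechanism = match.arg(missing_mechanism),
      mar_slope = mar_slope,
      retest_fraction = retest_fraction, retest_noise_sd = retest_noise_sd,
      external_targets = external_targets,
      external_anchor = match.arg(external_anchor),
      composite_weights = composite_weights,
      age_mix = age_mix, female_fraction = female_fraction,
      standardized = isTRUE(standardized)
    ),
    class = "cdd_generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  vars <- cdd_score_names()
  num_ok <- function(x) all(is.finite(x))
  if (anyNA(cfg$loadings[vars]) || anyNA(cfg$residual_sds[vars])) {
    abort("loadings/residual_sds must name all nine scores")
  }
  if (!num_ok(unlist(cfg$structural_coefficients)) ||
      !num_ok(cfg$loadings) || !num_ok(cfg$residual_sds)) {
    abort("generator config contains non-finite values")
  }
  if (any(cfg$residual_sds <= 0)) abort("residual_sds must be positive")
  if (any(cfg$missing_rates < 0 | cfg$missing_rates > 1)) {
    abort("missing_rates must lie in [0, 1]")
  }
  if (cfg$retest_fraction < 0 || cfg$retest_fraction > 1) {
    abort("retest_fraction must lie in [0, 1]")
  }
  for (v in vars) {
    r <- cfg$scale_ranges[[v]]
    if (is.null(r) || length(r) != 2 || !(r[1] < r[2])) {
      abort(paste0("scale range for '", v, "' must be (min, max) with min < max"))
    }
  }
  sc <- cfg$structural_coefficients
  if (abs(sc$exo_cov) >= 1) abort("exo_cov must lie in (-1, 1)")
  if (global_disturbance_var(cfg) <= 0) {
    abort("structural coefficients imply Var(Global) > 1; reduce them or exo_cov")
  }
  invisible(cfg)
}

# Var of the Global disturbance keeping Var(Global) = 1.
global_disturbance_var <- function(cfg) {
  sc <- cfg$structural_coefficients
  b1 <- sc$global_on_communication
  b2 <- sc$global_on_comorbidities
  1 - (b1^2 + b2^2 + 2 * b1 * b2 * sc$exo_cov)
}

#' Closed-form moments implied by a generator configuration
#'
#' `implied_latent_cov()` returns the 3 x 3 covariance (here also correlation)
#' matrix of (communication, comorbidities, global). `implied_cor_matrix()`
#' returns the 9 x 9 population correlation matrix of the observed scores,
#' including orientation sign flips. `implied_global_cor()` returns each
#' score's population correlation with latent Global. These are the analytic
#' counterparts against which Monte-Carlo output of [generate_cohort()] is
#' checked; boundary clipping (kept below ~1% by the default scale SDs) is
#' ignored.
#'
#' @param config A [generator_config()].
#' @return A matrix (or named vector for `implied_global_cor()`).
#' @export
implied_latent_cov <- function(config) {
  sc <- config$structural_coefficients
  b1 <- sc$global_on_communication
  b2 <- sc$global_on_comorbidities
  ps <- sc$exo_cov
  cg_comm <- b1 + b2 * ps
  cg_com <- b2 + b1 * ps
  m <- matrix(c(1, ps, cg_comm,
                ps, 1, cg_com,
                cg_comm, cg_com, 1), 3, 3)
  dimnames(m) <- rep(list(c("communication", "comorbidities", "global")), 2)
  m
}

# Per-score latent assignment, signal SD, and cor(signal, each latent).
signal_structure <- function(config) {
  info <- cdd_variables(modeled_only = TRUE)
  lat_cov <- implied_latent_cov(config)
  lam <- config$loadings
  sds <- sqrt(lam^2 + config$residual_sds^2)
  tibble::tibble(
    variable = info$variable,
    latent = info$latent,
    loading = lam[info$variable],
    signal_sd = sds[info$variable],
    cor_global = lam[info$variable] * lat_cov[info$latent, "global"] /
      sds[info$variable]
  )
}

# correlation matrix of the latent-linear signals, before orientation flips
signal_cor_matrix <- function(config) {
  ss <- signal_structure(config)
  lat_cov <- implied_latent_cov(config)
  p <- nrow(ss)
  R <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      R[i, j] <- ss$loading[i] * ss$loading[j] *
        lat_cov[ss$latent[i], ss$latent[j]] / (ss$signal_sd[i] * ss$signal_sd[j])
    }
  }
  dimnames(R) <- list(ss$variable, ss$variable)
  R
}

#' @rdname implied_latent_cov
#' @export
implied_cor_matrix <- function(config) {
  ss <- signal_structure(config)
  R <- signal_cor_matrix(config)
  if (!config$standardized) {
    dir <- ifelse(config$orientation[ss$variable] == "higher_better", -1, 1)
    R <- R * tcrossprod(dir)
    diag(R) <- 1
  }
  dimnames(R) <- list(ss$variable, ss$variable)
  R
}

#' @rdname implied_latent_cov
#' @export
implied_global_cor <- function(config) {
  ss <- signal_structure(config)
  out <- ss$cor_global
  if (!config$standardized) {
    out <- out * ifelse(config$orientation[ss$variable] == "higher_better", -1, 1)
  }
  setNames(out, ss$variable)
}

#' Population correlation between latent Global and a weighted composite
#'
#' Computes, in closed form under the generating model, the correlation
#' between the latent Global severity and the unit-sum weighted average of
#' the nine harmonized scores. Used to correct external-correlate generating
#' slopes for attenuation when targets are anchored on the composite rather
#' than the latent.
#'
#' @param config A [generator_config()].
#' @param weights A weight set (tibble with `variable`, `weight`), e.g.
#'   [cdd_published_weights()].
#' @return A single correlation.
#' @export
implied_composite_cor <- function(config, weights = cdd_published_weights()) {
  ss <- signal_structure(config)
  vars <- ss$variable
  w <- setNames(weights$weight, weights$variable)[vars]
  if (anyNA(w)) abort("weights must cover all nine scores")
  R <- signal_cor_matrix(config) # severity-oriented scale, no direction flips
  if (config$standardized) {
    d <- ss$signal_sd
  } else {
    span <- vapply(config$scale_ranges[vars], function(r) r[2] - r[1], numeric(1))
    d <- (100 / span) * config$scale_sds[vars]
  }
  cov_h <- R * tcrossprod(d)
  cov_g <- ss$cor_global * d
  sum(w * cov_g) / sqrt(drop(t(w) %*% cov_h %*% w))
}

#' Retest noise for a target test-retest ICC
#'
#' Under the generator's retest model (retest = baseline + fresh Gaussian
#' occasion noise), the population two-way absolute-agreement single-measure
#' ICC of a score with baseline variance `v` and occasion-noise SD `s` is
#' \eqn{v / (v + s^2/2)}. `retest_sd_for_icc()` inverts this,
#' `implied_indicator_icc()` evaluates it for every score of a config.
#'
#' @param icc Target ICC in (0, 1].
#' @param v Baseline score variance.
#' @return Noise SD, or a named vector of ICCs.
#' @export
retest_sd_for_icc <- function(icc, v) {
  stopifnot(icc > 0, icc <= 1, v > 0)
  sqrt(2 * v * (1 / icc - 1))
}

#' @rdname retest_sd_for_icc
#' @param config A [generator_config()].
#' @param retest_sds Named vector of occasion-noise SDs (raw-score units);
#'   defaults to the config's resolved values.
#' @export
implied_indicator_icc <- function(config, retest_sds = NULL) {
  if (is.null(retest_sds)) retest_sds <- resolve_retest_sds(config)
  v <- baseline_score_var(config)
  icc <- v / (v + retest_sds[names(v)]^2 / 2)
  setNames(icc, names(v))
}

baseline_score_var <- function(config) {
  vars <- cdd_score_names()
  if (config$standardized) {
    setNames(config$loadings[vars]^2 + config$residual_sds[vars]^2, vars)
  } else {
    setNames(config$scale_sds[vars]^2, vars)
  }
}

resolve_retest_sds <- function(config) {
  vars <- cdd_score_names()
  v <- baseline_score_var(config)
  if (is.null(config$retest_noise_sd)) {
    return(setNames(retest_sd_for_icc(0.9, v), vars))
  }
  s <- config$retest_noise_sd
  if (length(s) == 1 && is.null(names(s))) {
    return(setNames(rep(as.numeric(s), length(vars)), vars))
  }
  out <- s[vars]
  if (anyNA(out)) abort("retest_noise_sd must be scalar or name all nine scores")
  out
}

#' Simulate a synthetic CDD cohort
#'
#' Draws `n_subjects` baseline rows from the generating model described in
#' [generator_config()]: standard normal latent Global severity, nine bounded
#' observed scores, external correlates linear in Global, instrument-block
#' missingness with exact realized counts `round(rate * n)`, and
#' severity-independent demographics. Identical config and seed give an
#' identical table.
#'
#' The true latent values are attached as the `"latents"` attribute (a tibble
#' keyed by `subject_id`) for simulation studies; the fraction of raw draws
#' clipped at a scale boundary is attached as `"clip_fraction"`.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per subject: `subject_id`, `visit`
#'   (`"baseline"`), `age_group` (`"under7"`/`"over7"`), `sex`, the nine
#'   scores, and `eeg_alpha_delta`, `eeg_theta_delta`, `qol_total`,
#'   `behavior`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_subjects = 50, seed = 7))
#' dplyr::glimpse(cohort)
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_subjects
  if (n < 1) abort("n_subjects must be at least 1")
  vars <- cdd_score_names()
  info <- cdd_variables()

  local_seed(config$seed, {
    sc <- config$structural_coefficients
    z1 <- rnorm(n); z2 <- rnorm(n)
    comm <- z1
    com <- sc$exo_cov * z1 + sqrt(1 - sc$exo_cov^2) * z2
    glob <- sc$global_on_communication * comm +
      sc$global_on_comorbidities * com +
      rnorm(n, sd = sqrt(global_disturbance_var(config)))
    eta <- cbind(communication = comm, comorbidities = com, global = glob)

    ss <- signal_structure(config)
    clipped <- 0L
    scores <- purrr::map(setNames(vars, vars), function(v) {
      row <- ss[ss$variable == v, ]
      s <- row$loading * eta[, row$latent] + rnorm(n, sd = config$residual_sds[[v]])
      if (config$standardized) return(s)
      dir <- if (config$orientation[[v]] == "higher_better") -1 else 1
      x <- config$scale_means[[v]] +
        config$scale_sds[[v]] * dir * s / row$signal_sd
      r <- config$scale_ranges[[v]]
      clipped <<- clipped + sum(x < r[1] | x > r[2])
      pmin(pmax(x, r[1]), r[2])
    })

    comp_cor <- if (config$external_anchor == "composite") {
      implied_composite_cor(config, config$composite_weights %||%
                              cdd_published_weights())
    } else {
      1
    }
    externals <- purrr::imap(config$external_targets, function(r_target, v) {
      r_star <- r_target / comp_cor
      if (abs(r_star) >= 1) {
        abort(paste0("external target for '", v,
                     "' is unattainable after attenuation correction"))
      }
      e <- r_star * glob + sqrt(1 - r_star^2) * rnorm(n)
      vinfo <- info[info$variable == v, ]
      pmin(pmax(vinfo$mean + vinfo$sd * e, vinfo$min), vinfo$max)
    })

    cohort <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      visit = "baseline",
      age_group = ifelse(seq_len(n) %in% sample.int(n, round(config$age_mix * n)),
                         "under7", "over7"),
      sex = ifelse(seq_len(n) %in% sample.int(n, round(config$female_fraction * n)),
                   "F", "M"),
      !!!scores, !!!externals
    )

    # instrument-block missingness with exact realized counts
    blocks <- split(info$variable, info$instrument)
    for (instr in names(config$missing_rates)) {
      cols <- intersect(blocks[[instr]] %||% character(), names(cohort))
      k <- round(config$missing_rates[[instr]] * n)
      if (length(cols) == 0 || k == 0) next
      idx <- if (config$missing_mechanism == "mar") {
        sample.int(n, k, prob = plogis(config$mar_slope * glob))
      } else {
        sample.int(n, k)
      }
      cohort[idx, cols] <- NA_real_
    }

    attr(cohort, "latents") <- tibble::tibble(
      subject_id = cohort$subject_id,
      communication = comm, comorbidities = com, global = glob
    )
    attr(cohort, "clip_fraction") <- clipped / (n * length(vars))
    attr(cohort, "config_seed") <- config$seed
    if (attr(cohort, "clip_fraction") > 0.01) {
      warn(sprintf("%.1f%% of generated scores were clipped at a scale boundary",
                   100 * attr(cohort, "clip_fraction")))
    }
    cohort
  })
}

#' Add retest visits to a synthetic cohort
#'
#' Selects `round(retest_fraction * n)` baseline subjects (deterministically
#' many; the subset is drawn from the stream seeded by `config$seed +
#' 500009`) and appends, for each, a retest row whose nine scores equal the
#' baseline scores plus fresh Gaussian occasion noise, clipped to the scale
#' range. The baseline row's missingness pattern and external correlates are
#' carried over unchanged, modeling a stable subject re-measured about four
#' weeks later. With `retest_noise_sd = 0` the retest rows are identical to
#' baseline, so every downstream ICC is exactly 1.
#'
#' @param cohort A baseline cohort from [generate_cohort()].
#' @param config The [generator_config()] used to generate it.
#' @return The cohort with retest rows appended (`visit == "retest"`).
#' @export
generate_retest_pairs <- function(cohort, config) {
  base <- dplyr::filter(cohort, .data$visit == "baseline")
  if (nrow(base) == 0) abort("cohort has no baseline rows")
  k <- round(config$retest_fraction * nrow(base))
  if (k == 0) return(cohort)
  sds <- resolve_retest_sds(config)
  vars <- cdd_score_names()

  local_seed(config$seed + 500009L, {
    chosen <- sort(sample.int(nrow(base), k))
    retest <- base[chosen, ]
    retest$visit <- "retest"
    for (v in vars) {
      x <- retest[[v]] + rnorm(k, sd = sds[[v]])
      if (!config$standardized) {
        r <- config$scale_ranges[[v]]
        x <- pmin(pmax(x, r[1]), r[2])
      }
      x[is.na(retest[[v]])] <- NA_real_
      retest[[v]] <- x
    }
    out <- dplyr::bind_rows(cohort, retest)
    for (a in c("latents", "clip_fraction", "config_seed")) {
      attr(out, a) <- attr(cohort, a)
    }
    out
  })
}

#' Generating parameter vector for the default model
#'
#' Maps a generator configuration onto the free-parameter layout of
#' [default_cdd_model()], on the unbounded signal scale
#' (`standardized = TRUE` generation): free loadings, structural
#' coefficients, unit exogenous latent variances, the Global disturbance
#' variance, the exogenous covariance, residual variances, zero intercepts.
#' Used as ground truth in parameter-recovery studies.
#'
#' @param config A [generator_config()].
#' @return A named numeric vector matching `default_cdd_model()$layout`.
#' @export
generating_parameters <- function(config) {
  model <- default_cdd_model()
  lay <- model$layout
  sc <- config$structural_coefficients
  theta <- numeric(nrow(lay))
  names(theta) <- lay$name
  for (i in seq_len(nrow(lay))) {
    nm <- lay$name[i]
    theta[i] <- switch(
      lay$type[i],
      loading = {
        ind <- sub("~.*", "", nm)
        config$loadings[[ind]]
      },
      structural = if (grepl("communication", nm)) sc$global_on_communication
                   else sc$global_on_comorbidities,
      lvar = if (grepl("global", nm)) global_disturbance_var(config) else 1,
      lcov = sc$exo_cov,
      resid = {
        ind <- sub("^var\\(e\\.(.*)\\)$", "\\1", nm)
        config$residual_sds[[ind]]^2
      },
      intercept = 0
    )
  }
  theta
}
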