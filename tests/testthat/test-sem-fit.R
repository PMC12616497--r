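test_that("the inclusion rule keeps rows with at least two reported scores", {
  vars <- cdd_score_names()
  counts <- c(0, 1, 2, 5, 9)
  rows <- lapply(counts, function(k) {
    x <- setNames(as.list(rep(NA_real_, 9)), vars)
    if (k > 0) x[seq_len(k)] <- 50
    tibble::as_tibble(x)
  })
  coh <- dplyr::bind_cols(tibble::tibble(subject_id = paste0("S", counts)),
                          dplyr::bind_rows(rows))
  kept <- filter_inclusion(coh, quiet = TRUE)
  expect_identical(nrow(kept), 3L)
  expect_identical(attr(kept, "n_excluded"), 2L)
  # complete cohort passes through unchanged
  full <- generate_cohort(generator_config(n_subjects = 30, seed = 1,
                                           missing_rates = no_missing))
  expect_identical(nrow(filter_inclusion(full, quiet = TRUE)), 30L)
  # instrument-level variant: two scores from one instrument are not enough
  one_instr <- coh[3, ]
  one_instr[, vars] <- NA_real_
  one_instr$insomnia <- 40
  one_instr$sleepiness <- 40 # both from the sleep questionnaire
  expect_identical(nrow(filter_inclusion(one_instr, rule = "instruments",
                                         quiet = TRUE)), 0L)
  expect_identical(nrow(filter_inclusion(one_instr, rule = "variables",
                                         quiet = TRUE)), 1L)
})

test_that("the inclusion count matches a brute-force row scan on study-like data", {
  coh <- generate_cohort(generator_config(n_subjects = 206, seed = 31))
  kept <- filter_inclusion(coh, quiet = TRUE)
  manual <- sum(rowSums(!is.na(coh[, cdd_score_names()])) >= 2)
  expect_identical(nrow(kept), as.integer(manual))
})

test_that("FIML log-likelihood reproduces closed forms", {
  # a single standard-normal observation at the mean: -log(2*pi)/2
  m <- sem_model(
    observed = c("a", "b"), latents = "f",
    measurement = tibble::tibble(latent = "f", indicator = c("a", "b"),
                                 fixed = NA_real_),
    structural = tibble::tibble(from = character(), to = character()),
    latent_variances = tibble::tibble(latent = "f", fixed = 1)
  )
  theta <- c(0, 0, 1, 1, 0, 0) # diagonal unit covariance, zero means
  one_obs <- tibble::tibble(a = 0, b = NA_real_)
  expect_equal(fiml_loglik(m, theta, one_obs), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # complete data: equals the full-covariance multivariate normal form
  coh <- complete_standardized_cohort(100, seed = 37)
  md <- default_cdd_model()
  th <- generating_parameters(generator_config(standardized = TRUE))
  expect_equal(fiml_loglik(md, th, coh), fiml_loglik_rowwise(md, th, coh),
               tolerance = 1e-10)
})

test_that("pattern-grouped likelihood equals per-row evaluation on random masks", {
  md <- default_cdd_model()
  th <- generating_parameters(generator_config(standardized = TRUE))
  set.seed(41)
  for (rep in 1:10) {
    coh <- complete_standardized_cohort(40, seed = 400 + rep)
    Y <- as.matrix(coh[, md$observed])
    mask <- matrix(runif(length(Y)) < 0.3, nrow(Y))
    mask[, 1] <- mask[, 1] & rowSums(!mask[, -1]) > 0 # keep >= 1 observed
    Y[mask] <- NA
    coh[, md$observed] <- as.data.frame(Y)
    grouped <- fiml_loglik(md, th, coh)
    rowwise <- fiml_loglik_rowwise(md, th, coh)
    expect_equal(grouped, rowwise, tolerance = 1e-8 / abs(rowwise))
  }
})

test_that("an inadmissible covariance is signalled, not a crash", {
  md <- default_cdd_model()
  th <- generating_parameters(generator_config(standardized = TRUE))
  th[md$layout$type == "resid"] <- 0 # singular pattern submatrices
  coh <- complete_standardized_cohort(10, seed = 43)
  ll <- suppressWarnings(fiml_loglik(md, th, coh))
  expect_identical(ll, -Inf)
})

test_that("fitting recovers generating parameters and respects nesting", {
  cfg <- generator_config(n_subjects = 1000, seed = 47, standardized = TRUE,
                          missing_rates = no_missing)
  coh <- generate_cohort(cfg)
  md <- default_cdd_model()
  fit <- fit_sem(md, coh)
  expect_true(fit$converged)
  th <- generating_parameters(cfg)
  free_load <- grep("~", names(th))
  expect_lt(mean(abs(fit$theta[free_load] - th[free_load])), 0.1)
  # likelihood ordering: baseline <= model <= saturated
  expect_lte(fit$loglik_baseline, fit$loglik + 1e-6)
  expect_lte(fit$loglik, fit$loglik_saturated + 1e-6)
  expect_gte(fit$chi_square, 0)
  expect_equal(fit$chi_square,
               2 * (fit$loglik_saturated - fit$loglik), tolerance = 1e-8)
  # optimizer monotonicity: final loglik at least the documented start's
  Y <- as.matrix(coh[, md$observed])
  start <- cddseverity:::start_values(md, Y)
  expect_gte(fit$loglik, fiml_loglik(md, start, coh))
})

test_that("fitting under instrument-block missingness stays near complete-data truth", {
  cfg <- generator_config(n_subjects = 1000, seed = 53, standardized = TRUE,
                          missing_rates = c(clinician = 0.3, caregiver = 0.3,
                                            sleep = 0.3, csbs = 0.3,
                                            qol = 0, eeg = 0))
  coh <- filter_inclusion(generate_cohort(cfg), quiet = TRUE)
  fit <- fit_sem(default_cdd_model(), coh)
  expect_true(fit$converged)
  th <- generating_parameters(cfg)
  free_load <- grep("~", names(th))
  expect_lt(mean(abs(fit$theta[free_load] - th[free_load])), 0.15)
  expect_lte(fit$loglik_baseline, fit$loglik)
  expect_lte(fit$loglik, fit$loglik_saturated)
})

test_that("a just-identified model self-fits with zero misfit", {
  m <- just_identified_model()
  expect_equal(model_df(m)$df, 0)
  set.seed(59)
  f <- rnorm(400)
  coh <- tibble::tibble(y1 = f + rnorm(400, sd = 0.5),
                        y2 = 0.8 * f + rnorm(400, sd = 0.5),
                        y3 = 1.2 * f + rnorm(400, sd = 0.5))
  fit <- suppressWarnings(fit_sem(m, coh))
  expect_lt(fit$chi_square, 1e-4)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$cfi, 1)
})

test_that("fit indices follow their closed forms", {
  # exact-fit boundary
  idx <- fit_indices(24, 24, 500, 36, 206)
  expect_identical(idx$rmsea, 0)
  # plug-in: chi2 = 121, df = 100, n = 206 -> sqrt(21 / 20500)
  idx2 <- fit_indices(121, 100, 2000, 120, 206)
  expect_equal(idx2$rmsea, sqrt(21 / (100 * 205)), tolerance = 1e-12)
  expect_equal(idx2$chi_square_over_df, 1.21, tolerance = 1e-12)
  # n convention option
  idx2b <- fit_indices(121, 100, 2000, 120, 206, rmsea_n = "n")
  expect_equal(idx2b$rmsea, sqrt(21 / (100 * 206)), tolerance = 1e-12)
  # zero misfit numerator -> CFI 1
  idx3 <- fit_indices(0, 24, 1000, 36, 206)
  expect_identical(idx3$cfi, 1)
  # TLI formula and the undefined-baseline case
  expect_equal(idx2$tli,
               ((2000 / 120) - 1.21) / ((2000 / 120) - 1), tolerance = 1e-12)
  expect_warning(idx4 <- fit_indices(30, 24, 30, 36, 206), "TLI undefined")
  expect_true(is.na(idx4$tli))
})

test_that("factor scores are conditional expectations with expected properties", {
  cfg <- generator_config(n_subjects = 500, seed = 61, standardized = TRUE,
                          missing_rates = no_missing)
  coh <- generate_cohort(cfg)
  md <- default_cdd_model()
  fit <- fit_sem(md, coh)
  # a subject at exactly the model-implied mean scores 0 on every latent
  mom <- implied_moments(md, fit$theta)
  at_mean <- tibble::as_tibble(as.list(mom$mu))
  fs0 <- factor_scores(md, fit, at_mean)
  expect_equal(unlist(fs0[, md$latents]), setNames(rep(0, 3), md$latents),
               tolerance = 1e-10)
  # complete data: equals the textbook regression-method formula
  fs <- factor_scores(md, fit, coh)
  A <- mom$psi_eta %*% t(mom$lambda) %*% solve(mom$sigma)
  oracle <- t(A %*% (t(as.matrix(coh[, md$observed])) - mom$mu))
  expect_equal(as.matrix(fs[, md$latents]), unname(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  # identical observed subvectors give identical scores
  two <- coh[c(1, 1), ]
  fs2 <- factor_scores(md, fit, two)
  expect_identical(fs2$global[1], fs2$global[2])
  # zero observed indicators -> missing score
  none <- coh[1, ]
  none[, md$observed] <- NA_real_
  expect_true(is.na(factor_scores(md, fit, none)$global))
  # greater severity on motor implies greater Global score
  expect_gt(cor(fs$global, coh$motor), 0)
})

test_that("tidy and glance expose the fitted parameters and indices", {
  coh <- complete_standardized_cohort(300, seed = 67)
  fit <- fit_sem(default_cdd_model(), coh)
  td <- tidy(fit)
  expect_identical(nrow(td), 30L)
  expect_named(td, c("term", "type", "estimate"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("rmsea", "cfi", "tli", "chi_square_over_df") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
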