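test_that("harmonization maps endpoints, directions and involutions correctly", {
  coh <- tibble::tibble(subject_id = "S1", csbs = 57, motor = 30, vision = 0)
  # default orientation (instrument card): CSBS higher = more severe -> 100
  h <- harmonize(coh)
  expect_equal(h$csbs, 100)
  # under the inverted reading (higher CSBS = better communication) -> 0
  flip <- harmonize(coh, orientation = c(csbs = "higher_better",
                                         motor = "higher_better",
                                         vision = "higher_better"))
  expect_equal(flip$csbs, 0)
  # a 0-100 higher-severity variable passes through unchanged
  qol <- tibble::tibble(qol_total = c(0, 12.5, 100))
  expect_equal(harmonize(qol, vars = "qol_total")$qol_total, c(0, 12.5, 100))
  # direction flip is an involution
  again <- harmonize(flip, orientation = c(csbs = "higher_better",
                                           motor = "higher_better",
                                           vision = "higher_better"),
                     ranges = list(csbs = c(0, 100), motor = c(0, 100),
                                   vision = c(0, 100)))
  expect_equal(again$csbs, coh$csbs / 57 * 100)
  expect_equal(again$motor, coh$motor)
  # out-of-range values are named
  expect_error(harmonize(tibble::tibble(csbs = 60)), "csbs")
})

test_that("standardization is exact and matches a two-pass oracle", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(50, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    z <- standardize(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    oracle <- (x - sum(x) / length(x)) /
      sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))
    expect_equal(z, oracle, tolerance = 1e-12)
  }
  expect_error(standardize(rep(2, 10)), "distinct")
  expect_error(standardize(c(1, NA)), "distinct")
})

test_that("published default weights preserve printed ratios and sum to one", {
  w <- cdd_published_weights()
  expect_lt(abs(sum(w$weight) - 1), 1e-10)
  printed <- c(motor = 0.467, insomnia = 0.007, sleepiness = 0.012,
               seizures = 0.012, alertness = 0.111,
               communication_clin = 0.105, csbs = 0.142,
               vision = 0.091, feeding = 0.052)
  wv <- setNames(w$weight, w$variable)
  expect_equal(wv[names(printed)], printed / sum(printed), tolerance = 1e-12)
  expect_identical(attr(w, "provenance"), "published-default")
})

test_that("derived weights equal the normal-equations solution rescaled to unit sum", {
  cfg <- generator_config(n_subjects = 400, seed = 73,
                          missing_rates = no_missing)
  coh <- harmonize(generate_cohort(cfg))
  md <- default_cdd_model()
  fit <- fit_sem(md, coh)
  fs <- factor_scores(md, fit, coh)
  w <- suppressWarnings(derive_weights(coh, fs))
  expect_lt(abs(sum(w$weight) - 1), 1e-10)
  # independent oracle: solve the normal equations directly
  vars <- cdd_score_names()
  X <- cbind(1, as.matrix(coh[, vars]))
  y <- standardize(fs$global)
  b <- solve(t(X) %*% X, t(X) %*% y)[-1]
  expect_equal(unname(setNames(w$weight, w$variable)[vars]),
               unname(b / sum(b)), tolerance = 1e-8)
  expect_identical(attr(w, "n_complete"), 400L)
})

test_that("rescaling arithmetic and degenerate regressions behave as specified", {
  # raw coefficients (2, 1, 1) -> weights (0.5, 0.25, 0.25): build a cohort
  # whose factor score is exactly 2*a + b + c by construction
  set.seed(79)
  n <- 60
  d <- tibble::tibble(subject_id = as.character(1:n),
                      motor = rnorm(n), vision = rnorm(n), feeding = rnorm(n))
  for (v in setdiff(cdd_score_names(), c("motor", "vision", "feeding"))) {
    d[[v]] <- rnorm(n, sd = 1e-8) # negligible, near-constant contribution
  }
  scores <- tibble::tibble(subject_id = d$subject_id,
                           global = 2 * d$motor + d$vision + d$feeding)
  w <- suppressWarnings(derive_weights(d, scores))
  wv <- setNames(w$weight, w$variable)
  expect_equal(unname(wv[c("motor", "vision", "feeding")]),
               c(0.5, 0.25, 0.25), tolerance = 1e-6)
})

test_that("the weighted average respects unit-sum algebra", {
  w <- cdd_published_weights()
  # all components 50 -> exactly 50 for any unit-sum weights
  flat <- tibble::as_tibble(setNames(as.list(rep(50, 9)), cdd_score_names()))
  expect_equal(apply_weights(flat, w)$severity, 50, tolerance = 1e-12)
  # motor 100, others 0: the motor weight in percent
  spike <- tibble::as_tibble(setNames(as.list(rep(0, 9)), cdd_score_names()))
  spike$motor <- 100
  got <- apply_weights(spike, w)$severity
  expect_equal(got, 100 * 0.467 / 0.999, tolerance = 1e-12)
  expect_lt(abs(got - 46.7), 0.06) # printed Table value up to rounding renorm
  # multiply-accumulate oracle on random vectors
  set.seed(83)
  for (i in 1:5) {
    x <- runif(9, 0, 100)
    row <- tibble::as_tibble(setNames(as.list(x), cdd_score_names()))
    expect_equal(apply_weights(row, w)$severity, sum(x * w$weight),
                 tolerance = 1e-12)
    # shift equivariance: adding c to all components shifts the score by c
    row_c <- tibble::as_tibble(setNames(as.list(x + 7), cdd_score_names()))
    expect_equal(apply_weights(row_c, w)$severity,
                 apply_weights(row, w)$severity + 7, tolerance = 1e-10)
  }
})

test_that("missing components are refused by default and renormalized on request", {
  w <- cdd_published_weights()
  row <- tibble::as_tibble(setNames(as.list(rep(50, 9)), cdd_score_names()))
  row$csbs <- NA_real_
  expect_error(apply_weights(row, w), "csbs")
  renorm <- apply_weights(row, w, missing = "renormalize")
  expect_equal(renorm$severity, 50, tolerance = 1e-10)
  expect_equal(renorm$n_components, 8)
})

test_that("the weighted-average score reconstructs the factor score on complete data", {
  cfg <- generator_config(n_subjects = 300, seed = 89,
                          missing_rates = no_missing)
  coh <- harmonize(generate_cohort(cfg))
  md <- default_cdd_model()
  fit <- fit_sem(md, coh)
  fs <- factor_scores(md, fit, coh)
  w <- suppressWarnings(derive_weights(coh, fs))
  sev <- apply_weights(coh, w)
  expect_gt(cor(sev$severity, fs$global), 1 - 1e-8)
})

test_that("derived weights rank the strongest severity indicators on top", {
  cfg0 <- generator_config()
  top_implied <- names(sort(abs(implied_global_cor(cfg0)), decreasing = TRUE))[1:3]
  md <- default_cdd_model()
  hits <- 0
  seeds <- 1:8
  for (s in seeds) {
    cfg <- generator_config(n_subjects = 600, seed = 9000 + s,
                            missing_rates = no_missing)
    coh <- harmonize(generate_cohort(cfg))
    fit <- fit_sem(md, coh)
    fs <- factor_scores(md, fit, coh)
    w <- suppressWarnings(derive_weights(coh, fs))
    top_derived <- w$variable[order(-w$weight)][1:3]
    hits <- hits + setequal(top_derived, top_implied)
  }
  expect_gte(hits / length(seeds), 0.75)
})

test_that("weight files round-trip through CSV", {
  w <- cdd_published_weights()
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(w2$weight, w$weight, tolerance = 1e-12)
})
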