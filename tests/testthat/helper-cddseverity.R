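# Shared fixtures and independent oracles, built in code at test time.

no_missing <- c(clinician = 0, caregiver = 0, sleep = 0, csbs = 0,
                qol = 0, eeg = 0)

# complete cohort on the unbounded signal scale (loadings comparable to
# generating values)
complete_standardized_cohort <- function(n, seed) {
  generate_cohort(generator_config(n_subjects = n, seed = seed,
                                   standardized = TRUE,
                                   missing_rates = no_missing))
}

# brute-force multivariate normal log-density for one observation
dmvnorm_log <- function(y, mu, sigma) {
  k <- length(y)
  d <- y - mu
  -0.5 * (k * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus +
            drop(t(d) %*% solve(sigma) %*% d))
}

# per-row (ungrouped) FIML log-likelihood oracle
fiml_loglik_rowwise <- function(model, theta, cohort) {
  mom <- implied_moments(model, theta)
  Y <- as.matrix(as.data.frame(cohort)[, model$observed])
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (length(o) == 0) next
    ll <- ll + dmvnorm_log(Y[i, o], mom$mu[o],
                           mom$sigma[o, o, drop = FALSE])
  }
  as.numeric(ll)
}

# one-latent, three-indicator model: 9 free parameters = 9 moments, so the
# model is just-identified (df = 0)
just_identified_model <- function() {
  sem_model(
    observed = c("y1", "y2", "y3"),
    latents = "f",
    measurement = tibble::tibble(latent = "f", indicator = c("y1", "y2", "y3"),
                                 fixed = c(1, NA, NA)),
    structural = tibble::tibble(from = character(), to = character()),
    name = "one_factor"
  )
}

# ANOVA mean-squares ICC(A,1) oracle via base aov()
icc_a1_oracle <- function(test, retest) {
  n <- length(test)
  d <- data.frame(
    y = c(test, retest),
    subject = factor(rep(seq_len(n), 2)),
    occasion = factor(rep(1:2, each = n))
  )
  ms <- summary(aov(y ~ subject + occasion, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# from-scratch Welch t statistic and p value
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
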