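#' Apply the cohort inclusion rule
#'
#' Keeps baseline rows with at least `min_scores` non-missing values among
#' the nine modeled scores. The count can alternatively be taken over
#' distinct instruments (`rule = "instruments"`): a subject then qualifies
#' when scores from at least two different questionnaires are present.
#' The number of excluded rows is reported and attached as the
#' `"n_excluded"` attribute.
#'
#' @param cohort A cohort tibble (see [generate_cohort()] / [read_cohort()]).
#' @param rule Count non-missing `"variables"` (default) or distinct
#'   `"instruments"`.
#' @param min_scores Minimum count required for inclusion.
#' @param quiet Suppress the exclusion message.
#' @return The filtered cohort.
#' @export
filter_inclusion <- function(cohort, rule = c("variables", "instruments"),
                             min_scores = 2, quiet = FALSE) {
  rule <- match.arg(rule)
  vars <- intersect(cdd_score_names(), names(cohort))
  base <- if ("visit" %in% names(cohort)) {
    dplyr::filter(cohort, .data$visit == "baseline")
  } else {
    cohort
  }
  present <- !is.na(as.matrix(base[, vars]))
  n_ok <- if (rule == "variables") {
    rowSums(present)
  } else {
    instr <- cdd_variables(modeled_only = TRUE)
    instr <- setNames(instr$instrument, instr$variable)[vars]
    apply(present, 1, function(r) length(unique(instr[r])))
  }
  keep <- n_ok >= min_scores
  out <- base[keep, ]
  attr(out, "n_excluded") <- sum(!keep)
  if (!quiet && sum(!keep) > 0) {
    inform(sprintf("filter_inclusion: excluded %d of %d rows (< %d %s)",
                   sum(!keep), nrow(base), min_scores, rule))
  }
  out
}

# Split rows of a numeric matrix by missingness pattern. Returns a list of
# groups, each with `obs` (observed column indices) and `y` (complete
# submatrix). Rows with no observed values are dropped.
pattern_split <- function(Y) {
  pres <- !is.na(Y)
  key <- apply(pres, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Y)), key)
  out <- lapply(groups, function(rows) {
    obs <- which(pres[rows[1], ])
    if (length(obs) == 0) return(NULL)
    list(obs = obs, y = Y[rows, obs, drop = FALSE], rows = rows)
  })
  out[!vapply(out, is.null, logical(1))]
}

# Observed-data multivariate normal log-likelihood over pattern groups.
# Returns -Inf when any pattern submatrix is not positive definite.
loglik_patterns <- function(mu, sigma, patterns) {
  ll <- 0
  for (g in patterns) {
    o <- g$obs
    R <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    z <- backsolve(R, t(g$y) - mu[o], transpose = TRUE)
    m <- nrow(g$y)
    k <- length(o)
    ll <- ll - 0.5 * (m * (k * log(2 * pi) + 2 * sum(log(diag(R)))) +
                        sum(z * z))
  }
  ll
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Evaluates the observed-data log-likelihood of a cohort under the model at
#' parameter vector `theta`: the sum over subjects of the log-density of each
#' subject's observed score subvector under the multivariate normal with the
#' correspondingly subset implied mean and covariance. Subjects are grouped
#' by missingness pattern for efficiency; the grouping does not change the
#' value. Returns `-Inf` (an inadmissible-parameter signal, not an error)
#' when `theta` implies a non-positive-definite covariance for some pattern.
#'
#' @param model A [sem_model()].
#' @param theta Free-parameter vector on the natural scale.
#' @param cohort Cohort tibble (or matrix) containing the model's observed
#'   columns; rows should already satisfy the inclusion rule.
#' @return The scalar log-likelihood.
#' @export
fiml_loglik <- function(model, theta, cohort) {
  Y <- as.matrix(as.data.frame(cohort)[, model$observed, drop = FALSE])
  storage.mode(Y) <- "double"
  mom <- implied_moments(model, theta)
  if (any(build_matrices(model, theta)$theta_d <= 0)) return(-Inf)
  loglik_patterns(mom$mu, mom$sigma, pattern_split(Y))
}

# FIML estimate of unstructured (mu, Sigma) by EM, and its log-likelihood.
# With complete data this is the closed-form ML estimate in one step.
saturated_fiml <- function(Y, tol = 1e-8, max_iter = 500) {
  n <- nrow(Y)
  p <- ncol(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- S * (n - 1) / n
  # ensure a PD start
  ev <- eigen(S, symmetric = TRUE)
  S <- ev$vectors %*% diag(pmax(ev$values, 1e-4), p) %*% t(ev$vectors)
  patterns <- pattern_split(Y)
  complete <- length(patterns) == 1 && length(patterns[[1]]$obs) == p
  ll_old <- -Inf
  for (iter in seq_len(if (complete) 1 else max_iter)) {
    if (complete) {
      mu <- colMeans(Y)
      S <- crossprod(sweep(Y, 2, mu)) / n
      ll <- loglik_patterns(mu, S, patterns)
      return(list(mu = mu, sigma = S, loglik = ll, iterations = 1L))
    }
    T1 <- rep(0, p)
    T2 <- matrix(0, p, p)
    for (g in patterns) {
      o <- g$obs
      mis <- setdiff(seq_len(p), o)
      m <- nrow(g$y)
      if (length(mis) == 0) {
        T1[o] <- T1[o] + colSums(g$y)
        T2[o, o] <- T2[o, o] + crossprod(g$y)
        next
      }
      Soo_inv <- solve(S[o, o, drop = FALSE])
      beta <- S[mis, o, drop = FALSE] %*% Soo_inv
      resid_cov <- S[mis, mis, drop = FALSE] -
        beta %*% S[o, mis, drop = FALSE]
      ey_mis <- t(mu[mis] + beta %*% (t(g$y) - mu[o]))
      T1[o] <- T1[o] + colSums(g$y)
      T1[mis] <- T1[mis] + colSums(ey_mis)
      T2[o, o] <- T2[o, o] + crossprod(g$y)
      cross <- crossprod(g$y, ey_mis)
      T2[o, mis] <- T2[o, mis] + cross
      T2[mis, o] <- T2[mis, o] + t(cross)
      T2[mis, mis] <- T2[mis, mis] + crossprod(ey_mis) + m * resid_cov
    }
    mu <- T1 / n
    S <- T2 / n - tcrossprod(mu)
    S <- (S + t(S)) / 2
    ll <- loglik_patterns(mu, S, patterns)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = S, loglik = ll, iterations = iter)
}

# Independence-model (free means and variances, zero covariances) FIML
# log-likelihood: decouples into per-variable univariate normal ML fits.
baseline_fiml <- function(Y) {
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    y <- y[!is.na(y)]
    if (length(y) == 0) next
    m <- mean(y)
    v <- mean((y - m)^2)
    ll <- ll + sum(dnorm(y, m, sqrt(v), log = TRUE))
  }
  ll
}

#' Optimizer settings for [fit_sem()]
#'
#' @param iter_max Iteration cap for the quasi-Newton search.
#' @param rel_tol Relative objective-change tolerance.
#' @param x_tol Parameter step tolerance.
#' @param grad_tol Gradient max-norm (relative to `1 + |loglik|`) below which
#'   the solution is accepted as converged.
#' @param rmsea_n Denominator convention for RMSEA: `"n-1"` (default) or
#'   `"n"`.
#' @return A list of settings.
#' @export
fit_options <- function(iter_max = 500, rel_tol = 1e-10, x_tol = 1e-8,
                        grad_tol = 1e-5, rmsea_n = c("n-1", "n")) {
  list(iter_max = iter_max, rel_tol = rel_tol, x_tol = x_tol,
       grad_tol = grad_tol, rmsea_n = match.arg(rmsea_n))
}

# Observed-data log-likelihood from per-pattern sufficient statistics:
# algebraically identical to the per-row sum, O(patterns * k^3) per call.
loglik_pattern_stats <- function(mu, sigma, stats) {
  ll <- 0
  for (s in stats) {
    o <- s$obs
    R <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    sinv <- chol2inv(R)
    d <- s$ybar - mu[o]
    k <- length(o)
    ll <- ll - 0.5 * (s$m * (k * log(2 * pi) + 2 * sum(log(diag(R))) +
                               drop(crossprod(d, sinv %*% d))) +
                        sum(sinv * s$W))
  }
  ll
}

# Precompile theta -> (mu, sigma) and z -> theta into pure numeric indexing
# for the optimizer's hot loop (no tibble access per evaluation).
compile_model <- function(model) {
  lay <- model$layout
  p <- length(model$observed)
  m <- length(model$latents)
  meas <- model$measurement
  li <- match(meas$indicator, model$observed)
  lj <- match(meas$latent, model$latents)
  Lambda0 <- matrix(0, p, m)
  fixed_i <- !is.na(meas$fixed)
  Lambda0[cbind(li[fixed_i], lj[fixed_i])] <- meas$fixed[fixed_i]
  load_pos <- cbind(li[!fixed_i], lj[!fixed_i])
  load_idx <- lay$index[lay$type == "loading"]

  struct_pos <- cbind(match(model$structural$to, model$latents),
                      match(model$structural$from, model$latents))
  struct_idx <- lay$index[lay$type == "structural"]

  lv <- model$latent_variances
  Psi0_diag <- ifelse(is.na(lv$fixed), 0, lv$fixed)[match(model$latents, lv$latent)]
  lvar_lat <- match(lv$latent[is.na(lv$fixed)], model$latents)
  lvar_idx <- lay$index[lay$type == "lvar"]

  cv <- model$covariances
  lcov_pos <- cbind(match(cv$latent1, model$latents),
                    match(cv$latent2, model$latents))
  lcov_idx <- lay$index[lay$type == "lcov"]
  # theta index (or NA) holding each covariance's parent variances
  var_theta_of_latent <- rep(NA_integer_, m)
  var_theta_of_latent[lvar_lat] <- lvar_idx
  fixed_var_of_latent <- Psi0_diag

  resid_idx <- lay$index[lay$type == "resid"]
  int_idx <- lay$index[lay$type == "intercept"]
  vtrans <- lay$index[lay$type %in% c("lvar", "resid")]

  lat_var_at <- function(theta, l) {
    ti <- var_theta_of_latent[l]
    if (is.na(ti)) fixed_var_of_latent[l] else theta[ti]
  }

  list(
    theta_from_z = function(z) {
      theta <- z
      theta[vtrans] <- exp(pmin(z[vtrans], 30))
      for (i in seq_along(lcov_idx)) {
        v1 <- lat_var_at(theta, lcov_pos[i, 1])
        v2 <- lat_var_at(theta, lcov_pos[i, 2])
        theta[lcov_idx[i]] <- tanh(z[lcov_idx[i]]) * sqrt(v1 * v2)
      }
      theta
    },
    z_from_theta = function(theta) {
      z <- theta
      for (i in seq_along(lcov_idx)) {
        v1 <- lat_var_at(theta, lcov_pos[i, 1])
        v2 <- lat_var_at(theta, lcov_pos[i, 2])
        z[lcov_idx[i]] <- atanh(max(min(theta[lcov_idx[i]] / sqrt(v1 * v2),
                                        0.999), -0.999))
      }
      z[vtrans] <- log(theta[vtrans])
      z
    },
    moments = function(theta) {
      Lambda <- Lambda0
      if (length(load_idx)) Lambda[load_pos] <- theta[load_idx]
      B <- matrix(0, m, m)
      if (length(struct_idx)) B[struct_pos] <- theta[struct_idx]
      Psi <- matrix(0, m, m)
      diag(Psi) <- Psi0_diag
      if (length(lvar_idx)) diag(Psi)[lvar_lat] <- theta[lvar_idx]
      for (i in seq_along(lcov_idx)) {
        Psi[lcov_pos[i, 1], lcov_pos[i, 2]] <- theta[lcov_idx[i]]
        Psi[lcov_pos[i, 2], lcov_pos[i, 1]] <- theta[lcov_idx[i]]
      }
      imb <- tryCatch(solve(diag(m) - B), error = function(e) NULL)
      if (is.null(imb)) return(NULL)
      LI <- Lambda %*% imb
      sigma <- LI %*% Psi %*% t(LI)
      diag(sigma) <- diag(sigma) + theta[resid_idx]
      list(mu = theta[int_idx], sigma = sigma)
    }
  )
}

# Natural-scale theta <-> unconstrained optimizer scale: variances are
# log-transformed; exogenous covariances are parameterized as
# tanh(z) * sqrt(v1 * v2) so the latent covariance block stays admissible.
theta_to_unconstrained <- function(model, theta) {
  lay <- model$layout
  z <- theta
  vtypes <- lay$type %in% c("lvar", "resid")
  z[vtypes] <- log(theta[vtypes])
  if (any(lay$type == "lcov")) {
    lvars <- latent_variance_lookup(model, theta)
    for (i in which(lay$type == "lcov")) {
      cv <- model$covariances[match(lay$name[i], paste0(
        "cov(", model$covariances$latent1, ",", model$covariances$latent2, ")")), ]
      denom <- sqrt(lvars[[cv$latent1]] * lvars[[cv$latent2]])
      z[i] <- atanh(max(min(theta[i] / denom, 0.999), -0.999))
    }
  }
  z
}

unconstrained_to_theta <- function(model, z) {
  lay <- model$layout
  theta <- z
  vtypes <- lay$type %in% c("lvar", "resid")
  theta[vtypes] <- exp(pmin(z[vtypes], 30))
  if (any(lay$type == "lcov")) {
    lvars <- latent_variance_lookup(model, theta)
    for (i in which(lay$type == "lcov")) {
      cv <- model$covariances[match(lay$name[i], paste0(
        "cov(", model$covariances$latent1, ",", model$covariances$latent2, ")")), ]
      theta[i] <- tanh(z[i]) * sqrt(lvars[[cv$latent1]] * lvars[[cv$latent2]])
    }
  }
  theta
}

latent_variance_lookup <- function(model, theta) {
  lay <- model$layout
  lv <- model$latent_variances
  out <- setNames(lv$fixed, lv$latent)
  free <- lv$latent[is.na(lv$fixed)]
  out[free] <- theta[lay$index[lay$type == "lvar"]]
  out
}

# Documented start values: free loadings 1, structural coefficients 0.5,
# zero latent covariance, latent variances and residual variances at half
# the pattern-pooled sample variance, intercepts at the observed means.
start_values <- function(model, Y) {
  lay <- model$layout
  v_pool <- apply(Y, 2, var, na.rm = TRUE)
  v_pool[!is.finite(v_pool) | v_pool <= 0] <- 1
  names(v_pool) <- model$observed
  theta <- numeric(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    theta[i] <- switch(
      lay$type[i],
      loading = 1,
      structural = 0.5,
      lcov = 0,
      lvar = {
        l <- sub("^var\\((.*)\\)$", "\\1", lay$name[i])
        ind <- model$measurement$indicator[model$measurement$latent == l][1]
        v_pool[[ind]] / 2
      },
      resid = {
        ind <- sub("^var\\(e\\.(.*)\\)$", "\\1", lay$name[i])
        v_pool[[ind]] / 2
      },
      intercept = {
        ind <- sub("^mean\\((.*)\\)$", "\\1", lay$name[i])
        mean(Y[, ind], na.rm = TRUE)
      }
    )
  }
  names(theta) <- lay$name
  theta
}

#' Fit the severity SEM by full-information maximum likelihood
#'
#' Maximizes the observed-data log-likelihood ([fiml_loglik()]) over the
#' model's free parameters by quasi-Newton iteration from documented start
#' values, with variances kept positive through a log transform. The
#' saturated (unstructured-moments, EM-estimated) and baseline (independence)
#' models are fitted by FIML on the same missingness patterns to form the
#' likelihood-ratio chi-square and incremental fit indices.
#'
#' @param model A [sem_model()].
#' @param cohort Cohort tibble already passed through [filter_inclusion()]
#'   (rows with no observed scores are dropped with a message).
#' @param options Settings from [fit_options()].
#' @return An object of class `cdd_sem_fit`: a list with `theta` (named,
#'   natural scale), `loglik`, `loglik_saturated`, `loglik_baseline`,
#'   `chi_square`, `df`, `chi_square_over_df`, `rmsea`, `cfi`, `tli`,
#'   `n_used`, `converged`, `n_iterations`, `gradient_norm`, `model`,
#'   `options`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_sem <- function(model, cohort, options = fit_options()) {
  Y <- as.matrix(as.data.frame(cohort)[, model$observed, drop = FALSE])
  storage.mode(Y) <- "double"
  any_obs <- rowSums(!is.na(Y)) > 0
  if (any(!any_obs)) {
    inform(sprintf("fit_sem: dropping %d row(s) with no observed scores",
                   sum(!any_obs)))
    Y <- Y[any_obs, , drop = FALSE]
  }
  n <- nrow(Y)
  dd <- model_df(model)
  if (n <= dd$q) abort("fewer subjects than free parameters")
  patterns <- pattern_split(Y)

  # per-pattern sufficient statistics: count, mean, centered scatter
  stats <- lapply(patterns, function(g) {
    m <- nrow(g$y)
    ybar <- colMeans(g$y)
    yc <- sweep(g$y, 2, ybar)
    list(obs = g$obs, m = m, ybar = ybar, W = crossprod(yc))
  })
  cm <- compile_model(model)
  negloglik <- function(z) {
    theta <- cm$theta_from_z(z)
    sigma_mu <- cm$moments(theta)
    if (is.null(sigma_mu)) return(1e10)
    ll <- loglik_pattern_stats(sigma_mu$mu, sigma_mu$sigma, stats)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  z0 <- theta_to_unconstrained(model, start_values(model, Y))
  opt <- nlminb(z0, negloglik,
                control = list(iter.max = options$iter_max,
                               eval.max = 10 * options$iter_max,
                               rel.tol = options$rel_tol,
                               x.tol = options$x_tol))
  theta_hat <- unconstrained_to_theta(model, opt$par)
  names(theta_hat) <- model$layout$name
  ll_model <- -opt$objective

  # numerical gradient max-norm at the optimum (unconstrained scale)
  g <- vapply(seq_along(opt$par), function(i) {
    h <- 1e-5 * max(1, abs(opt$par[i]))
    e <- numeric(length(opt$par)); e[i] <- h
    (negloglik(opt$par + e) - negloglik(opt$par - e)) / (2 * h)
  }, numeric(1))
  grad_norm <- max(abs(g)) / (1 + abs(ll_model))
  converged <- opt$convergence == 0 && grad_norm < options$grad_tol * 100
  if (!converged) {
    warn(sprintf("fit_sem: convergence not confirmed (nlminb code %d, %s; relative gradient max-norm %.2e)",
                 opt$convergence, opt$message, grad_norm))
  }

  sat <- saturated_fiml(Y)
  ll_base <- baseline_fiml(Y)
  chisq <- max(2 * (sat$loglik - ll_model), 0)
  chisq_b <- max(2 * (sat$loglik - ll_base), 0)
  p <- ncol(Y)
  df_b <- p * (p + 3) / 2 - 2 * p
  idx <- fit_indices(chisq, dd$df, chisq_b, df_b, n, rmsea_n = options$rmsea_n)

  structure(
    list(
      theta = theta_hat,
      loglik = ll_model,
      loglik_saturated = sat$loglik,
      loglik_baseline = ll_base,
      chi_square = chisq, df = dd$df,
      chi_square_baseline = chisq_b, df_baseline = df_b,
      chi_square_over_df = chisq / dd$df,
      rmsea = idx$rmsea, cfi = idx$cfi, tli = idx$tli,
      n_used = n,
      converged = converged,
      n_iterations = opt$iterations,
      gradient_norm = grad_norm,
      model = model, options = options
    ),
    class = "cdd_sem_fit"
  )
}

#' SEM goodness-of-fit indices
#'
#' Computes the indices used to judge the severity model:
#' \deqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (n - 1))}}
#' \deqn{CFI = 1 - \max(\chi^2 - df, 0) / \max(\chi^2_b - df_b, \chi^2 - df, 0)}
#' \deqn{TLI = \frac{\chi^2_b/df_b - \chi^2/df}{\chi^2_b/df_b - 1}}
#' TLI is reported uncapped (it may exceed 1); when the baseline ratio
#' \eqn{\chi^2_b/df_b \le 1} it is undefined and returned as `NA` with a
#' warning. The RMSEA denominator uses `n - 1` by default; software differs
#' on `n` versus `n - 1` and both are available.
#'
#' @param chi_square,df Target-model likelihood-ratio statistic and degrees
#'   of freedom.
#' @param chi_square_baseline,df_baseline Independence-model statistic and
#'   degrees of freedom.
#' @param n Number of subjects used.
#' @param rmsea_n `"n-1"` or `"n"`.
#' @return A list with `rmsea`, `cfi`, `tli`, `chi_square_over_df`.
#' @export
fit_indices <- function(chi_square, df, chi_square_baseline, df_baseline, n,
                        rmsea_n = c("n-1", "n")) {
  rmsea_n <- match.arg(rmsea_n)
  stopifnot(df >= 0, df_baseline > 0, n > 1)
  denom_n <- if (rmsea_n == "n-1") n - 1 else n
  # a saturated (df = 0) target model fits exactly by construction
  rmsea <- if (df == 0) 0 else sqrt(max(chi_square - df, 0) / (df * denom_n))
  cfi_den <- max(chi_square_baseline - df_baseline, chi_square - df, 0)
  cfi <- if (cfi_den == 0) 1 else 1 - max(chi_square - df, 0) / cfi_den
  base_ratio <- chi_square_baseline / df_baseline
  target_ratio <- if (df == 0) 0 else chi_square / df
  tli <- if (base_ratio <= 1) {
    warn("fit_indices: baseline chi-square/df <= 1, TLI undefined")
    NA_real_
  } else {
    (base_ratio - target_ratio) / (base_ratio - 1)
  }
  list(rmsea = rmsea, cfi = cfi, tli = tli,
       chi_square_over_df = if (df == 0) NA_real_ else chi_square / df)
}

#' Regression-method factor scores under missing data
#'
#' For each subject, the conditional expectation of the latent vector given
#' that subject's observed score subvector under the fitted joint normal:
#' with reduced-form latent covariance \eqn{\Psi_\eta} and loading matrix
#' \eqn{\Lambda}, \deqn{E[\eta \mid y_o] = \Psi_\eta \Lambda_o^T
#' \Sigma_{oo}^{-1} (y_o - \mu_o).} With complete data this is the textbook
#' regression-method factor score; with missing data it conditions on
#' whatever is observed. The Global score is sign-oriented so that greater
#' values track greater severity on the model's first Global indicator; a
#' subject with no observed scores gets `NA`.
#'
#' @param model A [sem_model()].
#' @param fit A converged [fit_sem()] result (or any object with a `theta`
#'   element matching the model layout).
#' @param cohort Cohort tibble with the observed columns (and optionally
#'   `subject_id`).
#' @return A tibble with `subject_id`, one column per latent, and
#'   `n_observed`.
#' @export
factor_scores <- function(model, fit, cohort) {
  theta <- if (is.list(fit)) fit$theta else fit
  mom <- implied_moments(model, theta)
  df <- as.data.frame(cohort)
  Y <- as.matrix(df[, model$observed, drop = FALSE])
  storage.mode(Y) <- "double"
  m <- length(model$latents)
  scores <- matrix(NA_real_, nrow(Y), m,
                   dimnames = list(NULL, model$latents))
  cov_eta_y <- mom$psi_eta %*% t(mom$lambda) # m x p
  for (g in pattern_split(Y)) {
    o <- g$obs
    A <- cov_eta_y[, o, drop = FALSE] %*% solve(mom$sigma[o, o, drop = FALSE])
    scores[g$rows, ] <- t(A %*% (t(g$y) - mom$mu[o]))
  }
  # orient Global toward severity on its first (scale-setting) indicator
  if ("global" %in% model$latents) {
    first_ind <- model$measurement$indicator[model$measurement$latent == "global"][1]
    if (!is.na(first_ind) && cov_eta_y["global", first_ind] < 0) {
      scores[, "global"] <- -scores[, "global"]
      inform("factor_scores: Global sign flipped to track severity on its first indicator")
    }
  }
  out <- tibble::as_tibble(scores)
  out$n_observed <- rowSums(!is.na(Y))
  id <- if ("subject_id" %in% names(df)) df$subject_id else as.character(seq_len(nrow(Y)))
  dplyr::bind_cols(tibble::tibble(subject_id = id), out)
}

#' @export
print.cdd_sem_fit <- function(x, ...) {
  cat("<cdd_sem_fit> ", x$model$name, "\n", sep = "")
  cat(sprintf("  n = %d, loglik = %.2f, chi^2(%d) = %.2f (chi^2/df = %.2f)\n",
              x$n_used, x$loglik, x$df, x$chi_square, x$chi_square_over_df))
  cat(sprintf("  RMSEA = %.3f, CFI = %.3f, TLI = %.3f\n",
              x$rmsea, x$cfi, x$tli))
  cat("  converged:", x$converged, "in", x$n_iterations, "iterations\n")
  invisible(x)
}

#' @rdname fit_sem
#' @param x A `cdd_sem_fit` object.
#' @param ... Unused.
#' @method tidy cdd_sem_fit
#' @export
tidy.cdd_sem_fit <- function(x, ...) {
  lay <- x$model$layout
  tibble::tibble(term = lay$name, type = lay$type,
                 estimate = unname(x$theta))
}

#' @rdname fit_sem
#' @method glance cdd_sem_fit
#' @export
glance.cdd_sem_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, loglik = x$loglik,
    loglik_saturated = x$loglik_saturated,
    loglik_baseline = x$loglik_baseline,
    chi_square = x$chi_square, df = x$df,
    chi_square_over_df = x$chi_square_over_df,
    rmsea = x$rmsea, cfi = x$cfi, tli = x$tli,
    converged = x$converged, n_iterations = x$n_iterations
  )
}
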