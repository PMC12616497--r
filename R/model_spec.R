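#' Declarative structural equation model structure
#'
#' Constructs the declarative description of a reflective SEM: observed
#' indicators, latent factors, measurement loadings (free or fixed for scale
#' identification), structural regressions among latents, and free covariances
#' between exogenous latents. The object carries a parameter layout — a
#' bijection between the free parameters and a flat numeric vector `theta` —
#' used by [implied_moments()], [fiml_loglik()] and [fit_sem()].
#'
#' Each latent must carry exactly one scale constraint: either one fixed
#' loading among its indicators (the convention used by [default_cdd_model()])
#' or a fixed latent/disturbance variance. Every observed variable must load
#' on exactly one latent, and the structural graph must be acyclic.
#'
#' @param observed Character vector of observed indicator names (column names
#'   in the cohort table).
#' @param latents Character vector of latent factor names.
#' @param measurement Data frame with columns `latent`, `indicator`, `fixed`
#'   (`NA` for a free loading, a number for a fixed one).
#' @param structural Data frame with columns `from`, `to`: latent-on-latent
#'   regressions, each a free coefficient.
#' @param covariances Data frame with columns `latent1`, `latent2`: free
#'   covariances between exogenous latents (may have zero rows).
#' @param latent_variances Data frame with columns `latent`, `fixed` (`NA` for
#'   a free variance — a disturbance variance for endogenous latents).
#'   Defaults to all free.
#' @param name Label stored with the model.
#' @return An object of class `sem_model`.
#' @seealso [default_cdd_model()], [parse_model_config()], [implied_moments()]
#' @export
sem_model <- function(observed, latents, measurement, structural,
                      covariances = NULL, latent_variances = NULL,
                      name = "sem_model") {
  measurement <- tibble::as_tibble(measurement)
  structural <- tibble::as_tibble(structural)
  covariances <- if (is.null(covariances)) {
    tibble::tibble(latent1 = character(), latent2 = character())
  } else {
    tibble::as_tibble(covariances)
  }
  if (is.null(latent_variances)) {
    latent_variances <- tibble::tibble(latent = latents, fixed = NA_real_)
  }
  latent_variances <- tibble::as_tibble(latent_variances)

  # canonical row order, so the parameter layout does not depend on how the
  # edges were listed (models round-trip through configs unchanged)
  measurement <- measurement[order(match(measurement$latent, latents),
                                   match(measurement$indicator, observed)), ]
  structural <- structural[order(match(structural$to, latents),
                                 match(structural$from, latents)), ]
  covariances <- covariances[order(match(covariances$latent1, latents),
                                   match(covariances$latent2, latents)), ]
  latent_variances <- latent_variances[order(match(latent_variances$latent,
                                                   latents)), ]

  model <- structure(
    list(
      name = name,
      observed = observed,
      latents = latents,
      measurement = measurement,
      structural = structural,
      covariances = covariances,
      latent_variances = latent_variances
    ),
    class = "sem_model"
  )
  validate_sem_model(model)
  model$layout <- param_layout(model)
  model
}

validate_sem_model <- function(model) {
  m <- model$measurement
  if (!all(m$latent %in% model$latents)) {
    abort("measurement references unknown latent(s)")
  }
  if (!all(m$indicator %in% model$observed)) {
    abort("measurement references unknown indicator(s)")
  }
  dup <- m$indicator[duplicated(m$indicator)]
  if (length(dup) > 0) {
    abort(paste0("indicator assigned to more than one latent: ",
                 paste(unique(dup), collapse = ", ")))
  }
  orphan <- setdiff(model$observed, m$indicator)
  if (length(orphan) > 0) {
    abort(paste0("observed variable(s) with no latent: ",
                 paste(orphan, collapse = ", ")))
  }
  s <- model$structural
  if (nrow(s) > 0) {
    if (!all(c(s$from, s$to) %in% model$latents)) {
      abort("structural edge references unknown latent")
    }
    if (has_cycle(s, model$latents)) abort("structural graph is cyclic")
  }
  # scale identification: one fixed loading or one fixed variance per latent
  lv <- model$latent_variances
  for (l in model$latents) {
    n_fixed_load <- sum(m$latent == l & !is.na(m$fixed))
    n_fixed_var <- sum(lv$latent == l & !is.na(lv$fixed))
    if (n_fixed_load + n_fixed_var == 0) {
      abort(paste0("unidentified latent '", l,
                   "': needs one fixed loading or a fixed variance"))
    }
    if (n_fixed_load + n_fixed_var > 1) {
      abort(paste0("latent '", l, "' has more than one scale constraint"))
    }
  }
  cv <- model$covariances
  if (nrow(cv) > 0) {
    endo <- unique(s$to)
    bad <- cv$latent1 %in% endo | cv$latent2 %in% endo
    if (any(bad)) abort("free covariances are only supported between exogenous latents")
  }
  invisible(model)
}

has_cycle <- function(edges, nodes) {
  adj <- split(edges$to, edges$from)
  state <- setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 visiting, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]] %||% character()) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

# Flat layout of free parameters: one row per free parameter, in a fixed
# order (loadings, structural, latent variances, latent covariances,
# residual variances, intercepts).
param_layout <- function(model) {
  m <- model$measurement
  free_load <- m[is.na(m$fixed), ]
  lv <- model$latent_variances
  free_lvar <- lv[is.na(lv$fixed), ]
  # paste0() promotes zero-length inputs next to constants, so guard each
  glue0 <- function(...) {
    args <- list(...)
    if (any(lengths(args) == 0)) character() else paste0(...)
  }
  layout <- dplyr::bind_rows(
    tibble::tibble(type = "loading",
                   name = glue0(free_load$indicator, "~", free_load$latent)),
    tibble::tibble(type = "structural",
                   name = glue0(model$structural$to, "<-", model$structural$from)),
    tibble::tibble(type = "lvar", name = glue0("var(", free_lvar$latent, ")")),
    tibble::tibble(type = "lcov",
                   name = glue0("cov(", model$covariances$latent1, ",",
                                model$covariances$latent2, ")")),
    tibble::tibble(type = "resid", name = paste0("var(e.", model$observed, ")")),
    tibble::tibble(type = "intercept", name = paste0("mean(", model$observed, ")"))
  )
  layout$index <- seq_len(nrow(layout))
  layout
}

#' Number of free parameters and model degrees of freedom
#'
#' Degrees of freedom are counted against the full first- and second-moment
#' structure of the p observed variables: p means plus p(p+1)/2 covariances,
#' i.e. p(p+3)/2 moments in total.
#'
#' @param model A [sem_model()].
#' @return A list with `q` (free parameters), `moments`, and `df`.
#' @export
model_df <- function(model) {
  p <- length(model$observed)
  q <- nrow(model$layout)
  moments <- p * (p + 3) / 2
  list(q = q, moments = moments, df = moments - q)
}

#' The default CDD global-severity model
#'
#' The canonical three-latent reflective structure used throughout the
#' package: a Communication factor measured by the clinician-rated
#' communication domain and the CSBS-DP ITC total; a Comorbidities factor
#' measured by insomnia, daytime sleepiness, seizures and alertness; and an
#' endogenous Global severity factor regressed on both exogenous factors and
#' measured directly by the motor, vision and feeding domains. Scale
#' identification is by unit first loading: motor is fixed to 1 on Global,
#' the clinician communication domain to 1 on Communication, insomnia to 1 on
#' Comorbidities. The two exogenous factors covary freely.
#'
#' An alternative fully second-order structure (Global regressed *onto* the
#' two factor, i.e. Global -> Communication, Global -> Comorbidities) can be
#' built through [parse_model_config()]; see the packaged
#' `cdd_model_second_order.yaml` config.
#'
#' @return A [sem_model()] with 9 observed variables, 3 latents, 30 free
#'   parameters and 24 degrees of freedom.
#' @export
#' @examples
#' m <- default_cdd_model()
#' model_df(m)
default_cdd_model <- function() {
  info <- cdd_variables(modeled_only = TRUE)
  first <- c(global = "motor", communication = "communication_clin",
             comorbidities = "insomnia")
  measurement <- tibble::tibble(
    latent = info$latent,
    indicator = info$variable,
    fixed = ifelse(info$variable %in% first, 1, NA_real_)
  )
  sem_model(
    observed = info$variable,
    latents = c("communication", "comorbidities", "global"),
    measurement = measurement,
    structural = tibble::tibble(
      from = c("communication", "comorbidities"),
      to = c("global", "global")
    ),
    covariances = tibble::tibble(latent1 = "communication",
                                 latent2 = "comorbidities"),
    name = "cdd_default"
  )
}

#' Model-implied moments
#'
#' Computes the mean vector and covariance matrix of the observed variables
#' implied by the model at a parameter vector `theta`, through the reduced
#' form: with loading matrix \eqn{\Lambda}, structural coefficient matrix
#' \eqn{B}, latent (co)variance matrix \eqn{\Psi} and residual variances
#' \eqn{\Theta}, \deqn{\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T}
#' \Lambda^T + \Theta, \quad \mu(\theta) = \nu.}
#'
#' @param model A [sem_model()].
#' @param theta Numeric vector matching the model's parameter layout
#'   (`model$layout`).
#' @return A list with `mu` (named length-p vector), `sigma` (p x p symmetric
#'   matrix), `lambda`, `psi_eta` (reduced-form latent covariance) and
#'   `admissible` (all residual and latent variances positive, `sigma`
#'   positive semidefinite up to an eigenvalue floor of -1e-8).
#' @export
implied_moments <- function(model, theta) {
  if (length(theta) != nrow(model$layout)) {
    abort(sprintf("theta has length %d but the model has %d free parameters",
                  length(theta), nrow(model$layout)))
  }
  if (any(!is.finite(theta))) abort("theta contains non-finite values")
  mats <- build_matrices(model, theta)
  p <- length(model$observed)
  imb <- solve(diag(length(model$latents)) - mats$B)
  psi_eta <- imb %*% mats$Psi %*% t(imb)
  sigma <- mats$Lambda %*% psi_eta %*% t(mats$Lambda) + diag(mats$theta_d, p)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(model$observed, model$observed)
  admissible <- all(mats$theta_d > 0) &&
    all(diag(mats$Psi) > 0) &&
    min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8
  list(mu = setNames(mats$nu, model$observed), sigma = sigma,
       lambda = mats$Lambda, psi_eta = psi_eta, admissible = admissible)
}

# theta (natural scale) -> Lambda, B, Psi, residual variances, intercepts
build_matrices <- function(model, theta) {
  lay <- model$layout
  p <- length(model$observed)
  m <- length(model$latents)
  th <- function(type) theta[lay$index[lay$type == type]]

  Lambda <- matrix(0, p, m, dimnames = list(model$observed, model$latents))
  meas <- model$measurement
  free_i <- is.na(meas$fixed)
  Lambda[cbind(meas$indicator[!free_i], meas$latent[!free_i])] <- meas$fixed[!free_i]
  Lambda[cbind(meas$indicator[free_i], meas$latent[free_i])] <- th("loading")

  B <- matrix(0, m, m, dimnames = list(model$latents, model$latents))
  if (nrow(model$structural) > 0) {
    B[cbind(model$structural$to, model$structural$from)] <- th("structural")
  }

  Psi <- matrix(0, m, m, dimnames = list(model$latents, model$latents))
  lv <- model$latent_variances
  lvar_free <- is.na(lv$fixed)
  diag_vals <- setNames(lv$fixed, lv$latent)
  diag_vals[lv$latent[lvar_free]] <- th("lvar")
  diag(Psi) <- diag_vals[model$latents]
  cv <- model$covariances
  if (nrow(cv) > 0) {
    vals <- th("lcov")
    for (i in seq_len(nrow(cv))) {
      Psi[cv$latent1[i], cv$latent2[i]] <- vals[i]
      Psi[cv$latent2[i], cv$latent1[i]] <- vals[i]
    }
  }

  list(Lambda = Lambda, B = B, Psi = Psi,
       theta_d = th("resid"), nu = th("intercept"))
}

#' @export
print.sem_model <- function(x, ...) {
  dd <- model_df(x)
  cat("<sem_model> ", x$name, "\n", sep = "")
  cat("  observed:", length(x$observed), "| latents:",
      paste(x$latents, collapse = ", "), "\n")
  cat("  free parameters:", dd$q, "| df:", dd$df, "\n")
  invisible(x)
}

#' Serialize a model to a config list / parse a config into a model
#'
#' The config format has sections `observed` (ordered names), `latents`,
#' `measurement` (one map per latent: indicator -> `"free"` or a fixed
#' number), `structural` (list of `{from, to}`), `covariances` (list of latent
#' pairs) and `latent_variances` (latent -> `"free"` or a fixed number).
#' `parse_model_config()` accepts such a list or a path to a YAML/JSON file,
#' and validates identification and acyclicity. `as_model_config()` /
#' [write_model_config()] invert it, so a model round-trips through its
#' config.
#'
#' @param config A list following the schema, or a file path (`.yaml`/`.yml`
#'   or `.json`).
#' @return A [sem_model()].
#' @export
parse_model_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  need <- c("observed", "latents", "measurement", "structural")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort(paste0("model config missing section(s): ", paste(missing, collapse = ", ")))
  }
  free_or_num <- function(x) {
    if (is.character(x) && identical(tolower(x), "free")) NA_real_ else as.numeric(x)
  }
  meas <- purrr::imap_dfr(config$measurement, function(ind, lat) {
    tibble::tibble(latent = lat, indicator = names(ind),
                   fixed = vapply(ind, free_or_num, numeric(1)))
  })
  struct <- if (length(config$structural) > 0) {
    purrr::map_dfr(config$structural,
                   ~tibble::tibble(from = .x$from, to = .x$to))
  } else {
    tibble::tibble(from = character(), to = character())
  }
  covs <- if (length(config$covariances %||% list()) > 0) {
    purrr::map_dfr(config$covariances,
                   ~tibble::tibble(latent1 = .x[[1]], latent2 = .x[[2]]))
  } else {
    NULL
  }
  lvars <- if (length(config$latent_variances %||% list()) > 0) {
    tibble::tibble(
      latent = names(config$latent_variances),
      fixed = vapply(config$latent_variances, free_or_num, numeric(1))
    )
  } else {
    NULL
  }
  sem_model(
    observed = unlist(config$observed),
    latents = unlist(config$latents),
    measurement = meas, structural = struct, covariances = covs,
    latent_variances = lvars,
    name = config$name %||% "sem_model"
  )
}

#' @rdname parse_model_config
#' @param model A [sem_model()].
#' @export
as_model_config <- function(model) {
  fixed_chr <- function(x) if (is.na(x)) "free" else x
  meas <- lapply(split(model$measurement, model$measurement$latent), function(d) {
    setNames(lapply(d$fixed, fixed_chr), d$indicator)
  })
  list(
    name = model$name,
    observed = as.list(model$observed),
    latents = as.list(model$latents),
    measurement = meas[model$latents[model$latents %in% names(meas)]],
    structural = purrr::pmap(model$structural[c("from", "to")], list),
    covariances = purrr::pmap(model$covariances, function(latent1, latent2) {
      list(latent1, latent2)
    }),
    latent_variances = setNames(
      lapply(model$latent_variances$fixed, fixed_chr),
      model$latent_variances$latent
    )
  )
}

#' @rdname parse_model_config
#' @param path Output file path (`.yaml` or `.json`).
#' @export
write_model_config <- function(model, path) {
  cfg <- as_model_config(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
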