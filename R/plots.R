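#' Histogram of global severity scores, overall and by age group
#'
#' @param data Tibble with a severity column and optionally `age_group`.
#' @param score_col Name of the severity column.
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_severity_distribution <- function(data, score_col = "severity", bins = 20) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[score_col]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::labs(x = "Global severity score (standardized)", y = "Count") +
    ggplot2::theme_minimal()
  if ("age_group" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~age_group, ncol = 1)
  }
  p
}

#' Scatter plot of severity against an external correlate
#'
#' Pairwise-complete points with a least-squares line, the display used for
#' convergent-validity checks against EEG power ratios and quality of life.
#'
#' @param data Tibble containing the severity column and the correlate.
#' @param correlate Column name of the external correlate.
#' @param score_col Name of the severity column.
#' @return A ggplot.
#' @export
plot_severity_scatter <- function(data, correlate, score_col = "severity") {
  d <- data[!is.na(data[[score_col]]) & !is.na(data[[correlate]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[score_col]],
                                  y = .data[[correlate]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black") +
    ggplot2::labs(x = "Global severity score", y = correlate) +
    ggplot2::theme_minimal()
}

#' Plot estimated factor loadings of a fitted severity model
#'
#' Bar chart of the measurement loadings (fixed scale-setting loadings
#' included), grouped by latent factor.
#'
#' @param object A `cdd_sem_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdd_sem_fit
#' @export
autoplot.cdd_sem_fit <- function(object, ...) {
  model <- object$model
  mats <- build_matrices(model, object$theta)
  meas <- model$measurement
  d <- tibble::tibble(
    indicator = meas$indicator,
    latent = meas$latent,
    loading = mats$Lambda[cbind(meas$indicator, meas$latent)],
    fixed = !is.na(meas$fixed)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$indicator, y = .data$loading,
                                  alpha = !.data$fixed)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.45),
                                labels = c(`TRUE` = "free", `FALSE` = "fixed"),
                                name = NULL) +
    ggplot2::facet_wrap(~latent, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
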