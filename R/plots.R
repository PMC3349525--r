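# ggplot2 displays for model curves, fits and recovery experiments.

#' Plot phenotype-class probabilities against the recombination fraction
#'
#' Curves of the four seed-class probabilities over the valid range of `r`,
#' under the disomic model or the tetrasomic model at a given `alpha`.
#'
#' @inheritParams fit_population
#' @param alpha Double-reduction coefficient (tetrasomic model only).
#' @param n_points Number of curve points.
#'
#' @return A ggplot object.
#' @examples
#' plot_phenotype_probs("tetrasomic", alpha = 0.0676)
#' @export
plot_phenotype_probs <- function(model = c("disomic", "tetrasomic"),
                                 alpha = 0, n_points = 200) {
  model <- arg_match(model)
  if (model == "disomic") {
    r <- seq(0, DISOMIC_R_MAX, length.out = n_points)
    probs <- disomic_phenotype_probs(r)
  } else {
    r <- seq(0, TETRASOMIC_R_MAX, length.out = n_points)
    probs <- tetrasomic_phenotype_probs(alpha, r)
  }
  long <- tidyr_pivot(probs, c("yellow", "green", "red", "grey"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$probability,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(yellow = "goldenrod2",
                                            green = "forestgreen",
                                            red = "firebrick",
                                            grey = "grey40")) +
    ggplot2::labs(x = "recombination fraction r",
                  y = "phenotype-class probability",
                  colour = "seed class",
                  title = sprintf("%s model%s", model,
                                  if (model == "tetrasomic")
                                    sprintf(" (alpha = %.4f)", alpha) else "")) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids importing tidyr for one call)
tidyr_pivot <- function(data, cols) {
  dplyr::bind_rows(purrr::map(cols, function(cl) {
    tibble(r = data$r, class = cl, probability = data[[cl]])
  }))
}

#' @rdname fit_population
#' @param object An `rf_fit` (or `rf_recovery`) object.
#' @method autoplot rf_fit
#' @export
autoplot.rf_fit <- function(object, ...) {
  if (object$model == "disomic") {
    r <- seq(1e-4, DISOMIC_R_MAX - 1e-4, length.out = 400)
    ll <- phenotype_loglik(object$counts, disomic_phenotype_probs(r))
  } else {
    r <- seq(1e-4, TETRASOMIC_R_MAX - 1e-4, length.out = 400)
    ll <- phenotype_loglik(object$counts,
                           tetrasomic_phenotype_probs(object$alpha$value, r))
  }
  df <- tibble(r = r, loglik = ll)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$r$value, colour = "firebrick") +
    ggplot2::labs(x = "recombination fraction r",
                  y = "proportional log-likelihood",
                  title = sprintf("%s fit: r = %.4f", object$model,
                                  object$r$value)) +
    ggplot2::theme_minimal()
  if (!is.na(object$r$se)) {
    z <- qnorm(0.975)
    p <- p + ggplot2::geom_vline(
      xintercept = object$r$value + c(-z, z) * object$r$se,
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' @rdname run_recovery
#' @param object An `rf_recovery` object.
#' @param ... Unused.
#' @method autoplot rf_recovery
#' @export
autoplot.rf_recovery <- function(object, ...) {
  ests <- attr(object, "estimates")
  truths <- tibble(term = object$term, truth = object$truth)
  ggplot2::ggplot(ests, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(data = truths,
                        ggplot2::aes(xintercept = .data$truth),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "estimate", y = "replicates",
                  title = "Sampling distribution of the estimators") +
    ggplot2::theme_minimal()
}
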