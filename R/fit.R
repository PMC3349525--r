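# Per-population orchestration and broom-style accessors.

#' Fit one F2 population
#'
#' Fits the phenotype-count likelihood for a single population. Under the
#' disomic model (diploids, and allotetraploids with strict bivalent pairing)
#' this is [mle_disomic()]. Under the tetrasomic model (autotetraploids) the
#' two-step procedure is used: (1) estimate the double-reduction coefficient
#' at the green marker from the green-carrier margin ([mle_alpha_marginal()]);
#' (2) estimate the recombination fraction with alpha held at that value
#' ([mle_r_tetrasomic()]); (3) predict the double-reduction coefficient at the
#' red marker ([predict_double_reduction_red()]). The moment (proportion)
#' comparison estimate is computed alongside for reference.
#'
#' @inheritParams phenotype_loglik
#' @param model `"disomic"` or `"tetrasomic"`.
#'
#' @return An object of class `rf_fit`: a list with elements `model`, `counts`
#'   (named vector), `n`, `r` (an `rf_estimate`), `alpha` (`rf_estimate`,
#'   tetrasomic only, else `NULL`), `beta` (one-row tibble, tetrasomic only),
#'   `moment_r`, and `loglik` (the full four-class log-likelihood at the
#'   estimates). Supports [tidy()], [glance()], [autoplot()] and `print()`.
#'
#' @examples
#' fit_population(c(2805, 322, 333, 791), model = "disomic")
#' fit_population(c(12707, 1868, 2216, 3098), model = "tetrasomic")
#' @export
fit_population <- function(counts, model = c("disomic", "tetrasomic")) {
  model <- arg_match(model)
  n <- as_counts(counts)
  if (model == "disomic") {
    r <- mle_disomic(n)
    alpha <- NULL
    beta <- NULL
  } else {
    alpha <- mle_alpha_marginal(n)
    r <- mle_r_tetrasomic(n, alpha_fixed = alpha$value)
    beta <- predict_double_reduction_red(alpha$value, r$value)
  }
  structure(
    list(model = model, counts = n, n = sum(n), r = r, alpha = alpha,
         beta = beta,
         moment_r = unname(moment_estimate(n, variant = "proportion")),
         loglik = r$loglik),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("F2 phenotype-count fit (%s model), n = %d\n", x$model, x$n))
  cat(sprintf("  counts: yellow %d, green %d, red %d, grey %d\n",
              x$counts[[1]], x$counts[[2]], x$counts[[3]], x$counts[[4]]))
  if (!is.null(x$alpha)) print(x$alpha)
  print(x$r)
  if (!is.null(x$beta)) {
    cat(sprintf("  predicted double reduction at red marker: beta = %.4f\n",
                x$beta$beta))
  }
  cat(sprintf("  moment (proportion) comparison estimate: %.4f\n", x$moment_r))
  invisible(x)
}

#' @rdname fit_population
#' @param x An `rf_fit` object.
#' @param ... Unused.
#' @method tidy rf_fit
#' @export
tidy.rf_fit <- function(x, ...) {
  out <- list()
  if (!is.null(x$alpha)) out <- c(out, list(as_tibble(x$alpha)))
  out <- c(out, list(as_tibble(x$r)))
  dplyr::bind_rows(out)
}

#' @rdname fit_population
#' @method glance rf_fit
#' @export
glance.rf_fit <- function(x, ...) {
  tibble(model = x$model, n = x$n, loglik = x$loglik,
         r = x$r$value, r_se = x$r$se,
         alpha = if (is.null(x$alpha)) NA_real_ else x$alpha$value,
         alpha_se = if (is.null(x$alpha)) NA_real_ else x$alpha$se,
         beta = if (is.null(x$beta)) NA_real_ else x$beta$beta,
         moment_r = x$moment_r,
         at_boundary = x$r$at_boundary ||
           (!is.null(x$alpha) && x$alpha$at_boundary))
}

#' Fit every population in a counts table
#'
#' Maps [fit_population()] over the rows of a counts table (the format read by
#' [read_counts_table()] and emitted by [simulate_counts()]).
#'
#' @param data A data frame with columns `population_id`, `model`, `n_yellow`,
#'   `n_green`, `n_red`, `n_grey`.
#'
#' @return A tibble with one row per population: the [glance()] columns
#'   prefixed by `population_id`, plus a `fit` list-column holding each
#'   `rf_fit` object.
#'
#' @examples
#' arabidopsis_f2_counts() |> fit_populations()
#' @export
fit_populations <- function(data) {
  data <- validate_counts_table(data)
  fits <- purrr::pmap(
    data[c("model", "n_yellow", "n_green", "n_red", "n_grey")],
    function(model, n_yellow, n_green, n_red, n_grey) {
      fit_population(c(n_yellow, n_green, n_red, n_grey), model = model)
    }
  )
  out <- dplyr::bind_cols(
    tibble(population_id = data$population_id),
    dplyr::bind_rows(purrr::map(fits, glance))
  )
  out$fit <- fits
  out
}
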