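# Recomputation of the published estimates block for the three Arabidopsis
# F2 populations, with an optional check against the printed values at
# half-a-unit-in-the-last-printed-digit tolerances.
#
# Two reproduction notes, both established by direct computation (see the
# methods vignette):
#  * The published likelihood ratio 4.096 between the diploid MLE and the
#    earlier estimate r = 0.154 is the ratio implied by the log-likelihoods at
#    their reported 2-decimal precision, exp(-4177.79 + 4179.20) = 4.096; at
#    full precision the ratio is 4.110. The checked row
#    `likelihood_ratio_reported_precision` recomputes the former; the exact
#    ratio is reported, unchecked, as `likelihood_ratio`.
#  * The published comparison log-likelihood -2559.21 for the allotetraploid
#    at r = 0.241 recomputes as -2559.20 under the convention that reproduces
#    every other printed value exactly; the row is checked against the printed
#    value and is expected to fail its 0.005 tolerance by about 0.01.

benchmark_reference <- function() {
  tibble::tribble(
    ~population,       ~quantity,                               ~printed, ~tolerance,
    "diploid",         "r_hat",                                   0.1643,     5e-5,
    "diploid",         "r_se",                                    0.0062,     5e-5,
    "diploid",         "loglik",                                -4177.79,    0.005,
    "allotetraploid",  "r_hat",                                   0.2770,     5e-5,
    "allotetraploid",  "r_se",                                    0.0110,     5e-5,
    "allotetraploid",  "loglik",                                -2553.43,    0.005,
    "autotetraploid",  "alpha_hat",                               0.0676,     5e-5,
    "autotetraploid",  "alpha_se",                                0.0121,     5e-5,
    "autotetraploid",  "r_hat",                                   0.3048,     5e-5,
    "autotetraploid",  "r_se",                                    0.0051,     5e-5,
    "autotetraploid",  "loglik",                                -20815.3,     0.05,
    "autotetraploid",  "beta_hat",                                0.1857,     5e-5,
    "diploid",         "likelihood_ratio_reported_precision",      4.096,     5e-4,
    "diploid",         "moment_r",                                 0.154,     5e-4,
    "allotetraploid",  "moment_r",                                 0.241,     5e-4,
    "autotetraploid",  "moment_r",                                 0.205,     5e-4,
    "diploid",         "loglik_at_moment",                      -4179.20,    0.005,
    "allotetraploid",  "loglik_at_moment",                      -2559.21,    0.005,
    "autotetraploid",  "loglik_at_moment",                      -21010.0,     0.05
  )
}

#' Recompute the published estimates for the three Arabidopsis populations
#'
#' Refits the embedded diploid, allotetraploid and autotetraploid counts
#' ([arabidopsis_f2_counts()]) from scratch and assembles the full estimates
#' block: maximum-likelihood estimates, observed-information standard errors
#' and log-likelihoods for all three populations; the predicted
#' double-reduction coefficient at the red marker; the moment (proportion)
#' comparison estimates with the model log-likelihoods evaluated at them (at
#' their 3-decimal reported precision; the autotetraploid comparison value is
#' the tetrasomic likelihood at `alpha = 0`); and the diploid likelihood ratio
#' against the earlier estimate `r = 0.154`, both at full precision and as
#' implied by the log-likelihoods at their 2-decimal reporting precision.
#'
#' @param check If `TRUE`, compare each quantity against the published value
#'   at half a unit in its last printed digit; adds columns `printed`,
#'   `tolerance`, `pass` and an attribute `all_pass`.
#'
#' @return A tibble with columns `population`, `quantity`, `value` (plus the
#'   check columns when `check = TRUE`).
#'
#' @examples
#' benchmark_estimates()
#' @export
benchmark_estimates <- function(check = FALSE) {
  fits <- fit_populations(arabidopsis_f2_counts())
  rows <- purrr::pmap(fits, function(population_id, model, fit, ...) {
    g <- glance(fit)
    out <- tibble(
      population = population_id,
      quantity = c("r_hat", "r_se", "loglik", "moment_r"),
      value = c(g$r, g$r_se, g$loglik, g$moment_r)
    )
    if (model == "tetrasomic") {
      out <- dplyr::bind_rows(out, tibble(
        population = population_id,
        quantity = c("alpha_hat", "alpha_se", "beta_hat"),
        value = c(g$alpha, g$alpha_se, g$beta)
      ))
    }
    out
  })
  res <- dplyr::bind_rows(rows)

  # Log-likelihood at the comparison (moment) estimates, 3-decimal precision.
  ll_at_moment <- purrr::pmap(fits, function(population_id, model, fit,
                                             moment_r, ...) {
    r0 <- round(moment_r, 3)
    value <- if (model == "disomic") {
      phenotype_loglik(fit$counts, disomic_phenotype_probs(r0))
    } else {
      # comparison analysis ignored double reduction: tetrasomic f at alpha = 0
      phenotype_loglik(fit$counts, tetrasomic_phenotype_probs(0, r0))
    }
    tibble(population = population_id, quantity = "loglik_at_moment",
           value = value)
  })
  res <- dplyr::bind_rows(res, dplyr::bind_rows(ll_at_moment))

  dip <- fits$fit[[which(fits$population_id == "diploid")]]
  lr <- likelihood_ratio(dip$counts, "disomic",
                         list(r = dip$r$value), list(r = 0.154))
  res <- dplyr::bind_rows(res, tibble(
    population = "diploid",
    quantity = c("likelihood_ratio", "likelihood_ratio_reported_precision"),
    value = c(lr$ratio,
              exp(round(lr$loglik_a, 2) - round(lr$loglik_b, 2)))
  ))

  if (!check) return(res)
  ref <- benchmark_reference()
  out <- dplyr::inner_join(ref, res, by = c("population", "quantity"))
  out$pass <- abs(out$value - out$printed) <= out$tolerance
  out <- out[c("population", "quantity", "value", "printed", "tolerance", "pass")]
  attr(out, "all_pass") <- all(out$pass)
  out
}
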