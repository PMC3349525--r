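# Multinomial log-likelihood machinery. Throughout the package the
# log-likelihood is proportional: L = sum_i n_i log f_i in natural logs, with
# the multinomial coefficient omitted (it does not depend on the parameters).
# A class with n_i = 0 contributes nothing whatever f_i is; a class with
# n_i > 0 and f_i = 0 makes the parameter point impossible (L = -Inf).

# n: counts length 4; f: matrix with 4 columns (rows = parameter points).
loglik_rows <- function(n, f) {
  n <- unname(n)
  out <- numeric(nrow(f))
  for (i in which(n > 0)) {
    fi <- f[, i]
    term <- ifelse(fi > 0, n[i] * log(pmax(fi, .Machine$double.xmin)), -Inf)
    out <- out + term
  }
  unname(out)
}

# Score and curvature (d/dr and d^2/dr^2 of L) given f and its derivatives.
score_rows <- function(n, f, d1) {
  n <- unname(n)
  out <- numeric(nrow(f))
  for (i in which(n > 0)) out <- out + n[i] * d1[, i] / f[, i]
  unname(out)
}

curvature_rows <- function(n, f, d1, d2) {
  n <- unname(n)
  out <- numeric(nrow(f))
  for (i in which(n > 0)) {
    out <- out + n[i] * (d2[, i] * f[, i] - d1[, i]^2) / f[, i]^2
  }
  unname(out)
}

disomic_loglik_fn <- function(n) function(r) loglik_rows(n, disomic_f_matrix(r))

tetra_loglik_fn <- function(n, alpha) {
  function(r) loglik_rows(n, tetra_f_matrix(alpha, r))
}

marginal_loglik_fn <- function(ng, n0) {
  function(alpha) {
    p <- green_marginal_probs(alpha)
    loglik_rows(c(ng, n0, 0, 0), cbind(p$p_green, p$p_none, 0, 0))
  }
}

#' Proportional multinomial log-likelihood of phenotype counts
#'
#' Evaluates \eqn{\sum_i n_i \log f_i} (natural log, multinomial coefficient
#' omitted) for the four phenotype classes. Classes with zero counts
#' contribute nothing; a positive count on a zero-probability class yields
#' `-Inf`.
#'
#' @param counts Phenotype counts: a numeric vector `c(yellow, green, red,
#'   grey)` or a one-row data frame with columns `n_yellow`, `n_green`,
#'   `n_red`, `n_grey`.
#' @param probs Class probabilities: a numeric vector of length 4 in the same
#'   class order, or a data frame with columns `yellow`, `green`, `red`,
#'   `grey` (as returned by [disomic_phenotype_probs()] or
#'   [tetrasomic_phenotype_probs()]), evaluated row-wise.
#'
#' @return A numeric vector of log-likelihood values, one per row of `probs`.
#'
#' @examples
#' counts <- c(2805, 322, 333, 791)
#' phenotype_loglik(counts, disomic_phenotype_probs(c(0.154, 0.1643)))
#' @export
phenotype_loglik <- function(counts, probs) {
  n <- as_counts(counts)
  if (is.data.frame(probs)) {
    cols <- c("yellow", "green", "red", "grey")
    if (!all(cols %in% names(probs))) {
      abort("`probs` data frame needs columns yellow, green, red, grey.")
    }
    f <- as.matrix(probs[cols])
  } else if (is.numeric(probs) && length(probs) == 4) {
    f <- matrix(probs, nrow = 1)
  } else {
    abort("`probs` must be 4 probabilities or a data frame of them.")
  }
  if (any(f < -1e-12) || any(abs(rowSums(f) - 1) > 1e-6)) {
    abort("Each row of `probs` must be nonnegative and sum to 1.")
  }
  loglik_rows(n, f)
}

#' Wald standard error from the observed information
#'
#' Computes `sqrt(-1 / L''(theta))` for a scalar log-likelihood at an interior
#' maximum, i.e. the standard error implied by the observed Fisher information
#' (the curvature of the log-likelihood at the data's own maximum, not its
#' expectation). The second derivative is taken by Richardson-extrapolated
#' central differences with base step `h`.
#'
#' @param loglik_fn A function of one numeric argument returning the
#'   log-likelihood.
#' @param theta_hat The maximizer, interior to the domain.
#' @param h Base finite-difference step (default `1e-5`).
#'
#' @return The standard error, a positive scalar. Errors if the estimated
#'   curvature is not negative (`theta_hat` is not a local maximum).
#'
#' @examples
#' ll <- function(theta) -(theta - 0.3)^2 / (2 * 0.01^2)
#' observed_information_se(ll, 0.3)
#' @export
observed_information_se <- function(loglik_fn, theta_hat, h = 1e-5) {
  d2 <- function(h) {
    (loglik_fn(theta_hat + h) - 2 * loglik_fn(theta_hat) +
       loglik_fn(theta_hat - h)) / h^2
  }
  curv <- (4 * d2(h / 2) - d2(h)) / 3
  if (!is.finite(curv) || curv >= 0) {
    abort("Log-likelihood is not locally concave at `theta_hat`; observed information is not positive.")
  }
  sqrt(-1 / curv)
}

#' Likelihood ratio between two parameter points
#'
#' Compares the same data under the same model at two parameter points by
#' `exp(L(a) - L(b))`, using the proportional log-likelihood (the multinomial
#' constant cancels). The difference is computed in log space; the log-ratio
#' is reported alongside the ratio so very unequal fits do not overflow.
#'
#' @inheritParams phenotype_loglik
#' @param model `"disomic"` or `"tetrasomic"`.
#' @param params_a,params_b Named lists of parameter values: `list(r = )` for
#'   the disomic model, `list(alpha = , r = )` for the tetrasomic model.
#'
#' @return A one-row tibble with columns `loglik_a`, `loglik_b`, `log_ratio`,
#'   `ratio`.
#'
#' @examples
#' likelihood_ratio(c(2805, 322, 333, 791), "disomic",
#'                  list(r = 0.1643), list(r = 0.154))
#' @export
likelihood_ratio <- function(counts, model = c("disomic", "tetrasomic"),
                             params_a, params_b) {
  model <- arg_match(model)
  n <- as_counts(counts)
  ll_at <- function(p) {
    if (model == "disomic") {
      check_disomic_r(p$r)
      loglik_rows(n, disomic_f_matrix(p$r))
    } else {
      check_tetrasomic_params(p$alpha, p$r)
      loglik_rows(n, tetra_f_matrix(p$alpha, p$r))
    }
  }
  la <- ll_at(params_a)
  lb <- ll_at(params_b)
  tibble(loglik_a = la, loglik_b = lb, log_ratio = la - lb,
         ratio = exp(la - lb))
}

#' Moment (proportion) comparison estimator of recombination frequency
#'
#' The comparison estimator that equates the single-colour (green-only plus
#' red-only) phenotype classes to recombinants. Two variants are provided:
#' `"proportion"` (the default) simply returns `(n_green + n_red) / n`, which
#' reproduces the previously reported estimates for these data;
#' `"printed_equation"` solves \eqn{2r - r^2 = 2(n_2 + n_3)/n} for
#' \eqn{r \in [0, 1]}, i.e. `r = 1 - sqrt(1 - 2(n2 + n3)/n)`. The two do not
#' agree, and the package takes no position on which the original analysis
#' used; the proportion variant is the one whose values match the published
#' figures.
#'
#' @inheritParams phenotype_loglik
#' @param variant `"proportion"` or `"printed_equation"`.
#'
#' @return A single numeric estimate, with the variant used as its name.
#'
#' @examples
#' moment_estimate(c(2805, 322, 333, 791))
#' moment_estimate(c(2805, 322, 333, 791), variant = "printed_equation")
#' @export
moment_estimate <- function(counts,
                            variant = c("proportion", "printed_equation")) {
  variant <- arg_match(variant)
  n <- as_counts(counts)
  prop <- (n[["green"]] + n[["red"]]) / sum(n)
  value <- if (variant == "proportion") {
    prop
  } else {
    if (2 * prop > 1) {
      abort("printed_equation variant undefined: 2(n_green + n_red)/n exceeds 1.")
    }
    1 - sqrt(1 - 2 * prop)
  }
  set_names(value, variant)
}
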