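# Maximum-likelihood estimators. The disomic score equation and the marginal
# double-reduction score equation have closed-form roots; the tetrasomic
# profile in r is maximized by bracketed root-finding on the analytic score.
# In every case the returned estimate is the log-likelihood argmax over
# {interior stationary points} U {domain endpoints}, so boundary maxima are
# detected rather than extrapolated. Standard errors come from the observed
# information (analytic second derivative at the estimate) and are NA, with a
# warning, when the maximum is on the boundary.

new_rf_estimate <- function(term, value, se, loglik, n_roots_in_domain,
                            at_boundary) {
  structure(
    list(term = term, value = value, se = se, loglik = loglik,
         n_roots_in_domain = n_roots_in_domain, at_boundary = at_boundary),
    class = "rf_estimate"
  )
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (se %s), log-likelihood %.2f%s\n",
              x$term, x$value,
              if (is.na(x$se)) "NA" else sprintf("%.4f", x$se),
              x$loglik,
              if (x$at_boundary) " [at boundary]" else ""))
  invisible(x)
}

#' @method as_tibble rf_estimate
#' @export
as_tibble.rf_estimate <- function(x, ...) {
  tibble(term = x$term, estimate = x$value, std.error = x$se,
         loglik = x$loglik, n_roots_in_domain = x$n_roots_in_domain,
         at_boundary = x$at_boundary)
}

boundary_se_warning <- function(term) {
  warn(sprintf("`%s` is estimated on the domain boundary; the Wald standard error is undefined and reported as NA.",
               term))
}

# Pick the log-likelihood argmax among candidate parameter values.
pick_argmax <- function(candidates, ll_fn) {
  ll <- ll_fn(candidates)
  keep <- is.finite(ll)
  if (!any(keep)) abort("Log-likelihood is -Inf at every candidate; data are inconsistent with the model.")
  i <- which(keep)[which.max(ll[keep])]
  list(value = candidates[i], loglik = ll[i])
}

#' Maximum-likelihood recombination fraction under disomic inheritance
#'
#' Maximizes the proportional multinomial log-likelihood of the four phenotype
#' classes under the disomic model over \eqn{r \in [0, 1/2]}. The score
#' equation is solved in closed form: substituting \eqn{C = (1-r)^2} turns
#' \eqn{\partial L/\partial r = 0} into the quadratic
#' \eqn{n C^2 + (2m + n_4 - n_1) C - 2 n_4 = 0} with \eqn{m = n_2 + n_3},
#' whose admissible roots are compared, together with the endpoints, by
#' log-likelihood. The standard error is the observed-information Wald SE
#' from the analytic second derivative at the estimate.
#'
#' @inheritParams phenotype_loglik
#'
#' @return An object of class `rf_estimate`: a list with elements `term`
#'   (`"r"`), `value`, `se`, `loglik`, `n_roots_in_domain` (interior
#'   stationary points found) and `at_boundary`.
#'
#' @examples
#' mle_disomic(c(2805, 322, 333, 791))
#' @export
mle_disomic <- function(counts) {
  n <- as_counts(counts)
  m <- n[["green"]] + n[["red"]]
  ntot <- sum(n)
  # quadratic in C = (1-r)^2
  a <- ntot
  b <- 2 * m + n[["grey"]] - n[["yellow"]]
  cc <- -2 * n[["grey"]]
  disc <- b^2 - 4 * a * cc
  roots_r <- numeric(0)
  if (disc >= 0) {
    C <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    C <- C[C > 0.25 + 1e-12 & C < 1 - 1e-12]
    roots_r <- 1 - sqrt(C)
  }
  ll_fn <- disomic_loglik_fn(n)
  best <- pick_argmax(c(roots_r, 0, DISOMIC_R_MAX), ll_fn)
  at_boundary <- length(roots_r) == 0 || !any(abs(roots_r - best$value) < 1e-12)
  se <- NA_real_
  if (!at_boundary) {
    curv <- curvature_rows(n, disomic_f_matrix(best$value),
                           disomic_f_d1(best$value), disomic_f_d2(best$value))
    if (curv < 0) se <- sqrt(-1 / curv)
  } else {
    boundary_se_warning("r")
  }
  new_rf_estimate("r", best$value, se, best$loglik,
                  n_roots_in_domain = length(roots_r),
                  at_boundary = at_boundary)
}

#' Double-reduction coefficient from the green-marker margin
#'
#' First step of the two-step tetrasomic fit: collapses the four phenotype
#' classes to carriers (`n_g = n_yellow + n_green`) and non-carriers
#' (`n_0 = n_red + n_grey`) of the green marker, whose probabilities at
#' \eqn{r = 0} depend on `alpha` alone, and maximizes the two-class marginal
#' likelihood over \eqn{\alpha \in [0, 1/4]}. The interior solution is the
#' exact moment inversion \eqn{(2 + \alpha)^2/16 = n_0/n}, i.e.
#' \eqn{\hat\alpha = 4\sqrt{n_0/n} - 2}; values outside the box are returned
#' at the nearest boundary with `at_boundary` set. The standard error is the
#' observed-information SE of the marginal likelihood.
#'
#' @inheritParams phenotype_loglik
#'
#' @return An `rf_estimate` with `term = "alpha"`; `loglik` is the marginal
#'   two-class log-likelihood at the estimate.
#'
#' @examples
#' mle_alpha_marginal(c(12707, 1868, 2216, 3098))
#' @export
mle_alpha_marginal <- function(counts) {
  n <- as_counts(counts)
  ng <- n[["yellow"]] + n[["green"]]
  n0 <- n[["red"]] + n[["grey"]]
  if (ng == 0 || n0 == 0) {
    abort("Both green-carrier and non-carrier counts must be positive to estimate alpha.")
  }
  ntot <- ng + n0
  alpha_raw <- 4 * sqrt(n0 / ntot) - 2
  at_boundary <- alpha_raw < 0 || alpha_raw > ALPHA_MAX
  alpha_hat <- min(max(alpha_raw, 0), ALPHA_MAX)
  ll_fn <- marginal_loglik_fn(ng, n0)
  se <- NA_real_
  if (!at_boundary) {
    # analytic curvature of ng log pg + n0 log p0
    pg <- (12 - 4 * alpha_hat - alpha_hat^2) / 16
    p0 <- (2 + alpha_hat)^2 / 16
    dpg <- -(2 + alpha_hat) / 8
    dp0 <- (2 + alpha_hat) / 8
    curv <- ng * (-1 / 8 / pg - (dpg / pg)^2) + n0 * (1 / 8 / p0 - (dp0 / p0)^2)
    if (curv < 0) se <- sqrt(-1 / curv)
  } else {
    boundary_se_warning("alpha")
  }
  new_rf_estimate("alpha", alpha_hat, se, ll_fn(alpha_hat),
                  n_roots_in_domain = as.integer(!at_boundary),
                  at_boundary = at_boundary)
}

#' Recombination fraction under tetrasomic inheritance, alpha fixed
#'
#' Second step of the two-step tetrasomic fit: with the double-reduction
#' coefficient held at `alpha_fixed`, maximizes the four-class proportional
#' log-likelihood over \eqn{r \in [0, 3/4]}. The analytic score
#' \eqn{\partial L/\partial r} is scanned on a fine grid for sign changes and
#' each bracket is polished by [stats::uniroot()] to a root tolerance of
#' `1e-12`; the estimate is the log-likelihood argmax over roots and
#' endpoints. The standard error is the conditional observed-information SE,
#' `sqrt(-1 / d2L/dr2)` at the estimate with alpha held fixed.
#'
#' @inheritParams phenotype_loglik
#' @param alpha_fixed Double-reduction coefficient at the green marker, held
#'   fixed, in \eqn{[0, 1/4]}.
#'
#' @return An `rf_estimate` with `term = "r"`; `loglik` is the full four-class
#'   tetrasomic log-likelihood at (`alpha_fixed`, estimate).
#'
#' @examples
#' mle_r_tetrasomic(c(12707, 1868, 2216, 3098), alpha_fixed = 0.0676)
#' @export
mle_r_tetrasomic <- function(counts, alpha_fixed) {
  n <- as_counts(counts)
  check_fraction(alpha_fixed, ALPHA_MAX, "alpha_fixed")
  score <- function(r) {
    score_rows(n, tetra_f_matrix(alpha_fixed, r),
               tetra_f_d1(alpha_fixed, r))
  }
  eps <- 1e-9
  grid <- seq(eps, TETRASOMIC_R_MAX - eps, length.out = 1501)
  s <- score(grid)
  s[!is.finite(s)] <- NA_real_
  roots <- numeric(0)
  ok <- which(!is.na(s[-length(s)]) & !is.na(s[-1]) &
                s[-length(s)] * s[-1] <= 0 & s[-length(s)] != 0)
  for (i in ok) {
    root <- uniroot(function(x) score(x), c(grid[i], grid[i + 1]),
                    tol = 1e-12)$root
    roots <- c(roots, root)
  }
  roots <- unique(round(roots, 12))
  ll_fn <- tetra_loglik_fn(n, alpha_fixed)
  best <- pick_argmax(c(roots, 0, TETRASOMIC_R_MAX), ll_fn)
  at_boundary <- length(roots) == 0 || !any(abs(roots - best$value) < 1e-9)
  se <- NA_real_
  if (!at_boundary) {
    curv <- curvature_rows(n, tetra_f_matrix(alpha_fixed, best$value),
                           tetra_f_d1(alpha_fixed, best$value),
                           tetra_f_d2(alpha_fixed, best$value))
    if (curv < 0) se <- sqrt(-1 / curv)
  } else {
    boundary_se_warning("r")
  }
  new_rf_estimate("r", best$value, se, best$loglik,
                  n_roots_in_domain = length(roots),
                  at_boundary = at_boundary)
}
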