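# Independent oracles for the estimation routines: the model probabilities are
# written out directly from the published polynomial forms (not through the
# package's matrix helpers) and maximized by exhaustive grid search with local
# refinement. The estimators under test use closed-form score roots /
# bracketed root-finding instead, so agreement is a genuine cross-check of the
# maximization path.

oracle_disomic_f <- function(r) {
  cbind(3 * (1 - r)^2 / 4 + r * (1 - r) + r^2 / 2,
        r * (2 - r) / 4,
        r * (2 - r) / 4,
        (1 - r)^2 / 4)
}

oracle_tetra_f <- function(alpha, r) {
  g1 <- (2 - alpha) * (1 - r)^2 / 4 + r * (1 - r) / 2 + (1 - alpha) * r^2 / 6
  g2 <- (1 - alpha) * r * (1 - r) / 3 + (10 - alpha) * r^2 / 36
  g3 <- r * (1 - r) / 2 + (8 + alpha) * r^2 / 36
  g4 <- (2 + alpha) * (1 - r)^2 / 4 + (2 + alpha) * r * (1 - r) / 3 +
    (2 + alpha) * r^2 / 6
  cbind(g1 * (2 - g1) + 2 * g2 * g3,
        g2 * (g2 + 2 * g4),
        g3 * (g3 + 2 * g4),
        g4^2)
}

oracle_loglik <- function(n, f) {
  ll <- rep(0, nrow(f))
  for (i in which(n > 0)) {
    ll <- ll + ifelse(f[, i] > 0, n[i] * log(f[, i]), -Inf)
  }
  ll
}

# Grid search + golden-section refinement of the log-likelihood in r.
oracle_mle <- function(n, f_of_r, r_max, step = 1e-5) {
  grid <- seq(0, r_max, by = step)
  ll <- oracle_loglik(n, f_of_r(grid))
  i <- which.max(ll)
  lo <- grid[max(1, i - 2)]
  hi <- grid[min(length(grid), i + 2)]
  opt <- optimize(function(r) oracle_loglik(n, f_of_r(r)), c(lo, hi),
                  maximum = TRUE, tol = 1e-10)
  if (opt$objective >= ll[i]) opt$maximum else grid[i]
}

oracle_mle_disomic <- function(n, step = 1e-5) {
  oracle_mle(n, oracle_disomic_f, 0.5, step)
}

oracle_mle_tetra <- function(n, alpha, step = 1e-5) {
  oracle_mle(n, function(r) oracle_tetra_f(alpha, r), 0.75, step)
}

# Random multinomial count vectors at random true parameters.
random_disomic_counts <- function(k) {
  purrr::map(seq_len(k), function(i) {
    r <- stats::runif(1, 0.02, 0.48)
    n <- round(10^stats::runif(1, 2, 6))
    list(r = r, n = n,
         counts = as.integer(rmultinom(1, n, oracle_disomic_f(r)[1, ])))
  })
}

random_tetra_counts <- function(k) {
  purrr::map(seq_len(k), function(i) {
    alpha <- stats::runif(1, 0, 0.25)
    r <- stats::runif(1, 0.02, 0.73)
    n <- round(10^stats::runif(1, 2, 6))
    list(alpha = alpha, r = r, n = n,
         counts = as.integer(rmultinom(1, n, oracle_tetra_f(alpha, r)[1, ])))
  })
}

# Table-style fixture counts used across tests.
diploid_counts <- c(2805L, 322L, 333L, 791L)
allotetraploid_counts <- c(1484L, 275L, 298L, 320L)
autotetraploid_counts <- c(12707L, 1868L, 2216L, 3098L)
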