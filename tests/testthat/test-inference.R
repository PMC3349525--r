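# Likelihood evaluation, maximum-likelihood estimators, observed-information
# standard errors, likelihood ratios and the comparison estimator.

test_that("proportional log-likelihood follows the sum n_i log f_i convention", {
  expect_equal(phenotype_loglik(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  # zero-count classes drop out even when their probability is zero
  expect_equal(phenotype_loglik(c(10, 0, 0, 5), disomic_phenotype_probs(0)),
               10 * log(3 / 4) + 5 * log(1 / 4))
  # positive count on a zero-probability class excludes the parameter point
  expect_equal(phenotype_loglik(c(10, 1, 0, 5), disomic_phenotype_probs(0)),
               -Inf)
  # vectorized over parameter points, natural log, no multinomial constant
  r <- c(0.154, 0.1643)
  ll <- phenotype_loglik(diploid_counts, disomic_phenotype_probs(r))
  expect_equal(ll, oracle_loglik(diploid_counts, oracle_disomic_f(r)),
               tolerance = 1e-12)
})

test_that("disomic MLE solves the score equation for the fixture populations", {
  fit <- mle_disomic(diploid_counts)
  expect_lt(abs(fit$value - 0.1643), 5e-5)
  expect_lt(abs(fit$se - 0.0062), 5e-5)
  expect_lt(abs(fit$loglik - (-4177.79)), 0.005)
  expect_equal(fit$n_roots_in_domain, 1L)
  expect_false(fit$at_boundary)

  fit2 <- mle_disomic(allotetraploid_counts)
  expect_lt(abs(fit2$value - 0.2770), 5e-5)
  expect_lt(abs(fit2$se - 0.0110), 5e-5)
  expect_lt(abs(fit2$loglik - (-2553.43)), 0.005)
})

test_that("zero recombinants puts the disomic maximum at the r = 0 boundary", {
  expect_warning(fit <- mle_disomic(c(750, 0, 0, 250)), "boundary")
  expect_equal(fit$value, 0)
  expect_true(fit$at_boundary)
  expect_true(is.na(fit$se))
})

test_that("closed-form disomic MLE agrees with the grid-search oracle", {
  set.seed(42)
  cases <- random_disomic_counts(50)
  for (case in cases) {
    fit <- suppressWarnings(mle_disomic(case$counts))
    expect_equal(fit$value, oracle_mle_disomic(case$counts),
                 tolerance = 1e-4 / max(fit$value, 0.01),
                 label = sprintf("disomic oracle (r=%.3f n=%d)", case$r, case$n))
    # score vanishes at interior estimates
    if (!fit$at_boundary) {
      score <- polyrec:::score_rows(as.integer(case$counts),
                                    polyrec:::disomic_f_matrix(fit$value),
                                    polyrec:::disomic_f_d1(fit$value))
      expect_lt(abs(score), 1e-6 * case$n)
    }
  }
})

test_that("marginal double-reduction estimator inverts the carrier margin", {
  fit <- mle_alpha_marginal(autotetraploid_counts)
  expect_lt(abs(fit$value - 0.0676), 5e-5)
  expect_lt(abs(fit$se - 0.0121), 5e-5)
  # self-consistency: p0(alpha_hat) equals the observed non-carrier fraction
  expect_equal(green_marginal_probs(fit$value)$p_none, 5314 / 19889,
               tolerance = 1e-10)
  # closed-form inversion for a round case: p0 = 0.3
  fit2 <- mle_alpha_marginal(c(7000, 0, 0, 3000))
  expect_equal(fit2$value, 4 * sqrt(0.3) - 2, tolerance = 1e-10)
  # and it maximizes the marginal likelihood (grid oracle)
  a_grid <- seq(0, 0.25, by = 1e-6)
  p <- green_marginal_probs(a_grid)
  ll <- 7000 * log(p$p_green) + 3000 * log(p$p_none)
  expect_equal(fit2$value, a_grid[which.max(ll)], tolerance = 2e-6)
  # carrier fraction of exactly 3/4 means no double reduction
  fit3 <- mle_alpha_marginal(c(7500, 0, 0, 2500))
  expect_equal(fit3$value, 0)
  # carrier fraction above 3/4 would need alpha < 0: clamped with a warning
  expect_warning(fit4 <- mle_alpha_marginal(c(7600, 0, 0, 2400)), "boundary")
  expect_equal(fit4$value, 0)
  expect_true(fit4$at_boundary)
  expect_true(is.na(fit4$se))
})

test_that("tetrasomic r estimator matches the fixture and finds a unique root", {
  fit <- mle_r_tetrasomic(autotetraploid_counts, alpha_fixed = 0.0676)
  expect_lt(abs(fit$value - 0.3048), 5e-5)
  expect_lt(abs(fit$se - 0.0051), 5e-5)
  expect_lt(abs(fit$loglik - (-20815.3)), 0.05)
  expect_equal(fit$n_roots_in_domain, 1L)
  expect_warning(fit0 <- mle_r_tetrasomic(c(3000, 0, 0, 1000), 0), "boundary")
  expect_equal(fit0$value, 0)
  expect_true(fit0$at_boundary)
})

test_that("tetrasomic r estimator agrees with the grid-search oracle", {
  set.seed(43)
  cases <- random_tetra_counts(50)
  for (case in cases) {
    fit <- suppressWarnings(mle_r_tetrasomic(case$counts, case$alpha))
    expect_equal(fit$value, oracle_mle_tetra(case$counts, case$alpha,
                                             step = 2e-5),
                 tolerance = 1e-4 / max(fit$value, 0.01),
                 label = sprintf("tetra oracle (a=%.3f r=%.3f n=%d)",
                                 case$alpha, case$r, case$n))
    if (!fit$at_boundary) {
      score <- polyrec:::score_rows(as.integer(case$counts),
                                    polyrec:::tetra_f_matrix(case$alpha, fit$value),
                                    polyrec:::tetra_f_d1(case$alpha, fit$value))
      expect_lt(abs(score), 1e-6 * case$n)
    }
  }
})

test_that("scaling all counts by k preserves the MLE and scales the information", {
  k <- 7
  base <- mle_disomic(diploid_counts)
  scaled <- mle_disomic(diploid_counts * k)
  expect_equal(scaled$value, base$value, tolerance = 1e-10)
  expect_equal(scaled$loglik, k * base$loglik, tolerance = 1e-10)
  expect_equal(scaled$se, base$se / sqrt(k), tolerance = 1e-10)

  base_t <- mle_r_tetrasomic(autotetraploid_counts, 0.0676)
  scaled_t <- mle_r_tetrasomic(autotetraploid_counts * k, 0.0676)
  expect_equal(scaled_t$value, base_t$value, tolerance = 1e-8)
  expect_equal(scaled_t$se, base_t$se / sqrt(k), tolerance = 1e-6)
})

test_that("fit_population orchestrates the per-model estimates", {
  dip <- fit_population(diploid_counts, "disomic")
  expect_null(dip$alpha)
  expect_null(dip$beta)
  expect_lt(abs(dip$r$value - 0.1643), 5e-5)
  expect_equal(dip$moment_r, 655 / 4251)

  auto <- fit_population(autotetraploid_counts, "tetrasomic")
  expect_lt(abs(auto$alpha$value - 0.0676), 5e-5)
  expect_lt(abs(auto$r$value - 0.3048), 5e-5)
  expect_lt(abs(auto$beta$beta - 0.1857), 5e-5)
  # reported loglik is the full four-class likelihood at the estimates
  expect_equal(auto$loglik,
               phenotype_loglik(autotetraploid_counts,
                                tetrasomic_phenotype_probs(auto$alpha$value,
                                                           auto$r$value)))
  td <- tidy(auto)
  expect_equal(td$term, c("alpha", "r"))
  expect_equal(glance(auto)$beta, auto$beta$beta)
})

test_that("r estimator is consistent when alpha is held at the simulation truth", {
  sims <- simulate_counts("tetrasomic", r = 0.10, alpha = 0.05, n = 1e6,
                          replicates = 1, seed = 5)
  fit <- mle_r_tetrasomic(as.numeric(sims[1, 3:6]), alpha_fixed = 0.05)
  expect_lt(abs(fit$value - 0.10), 0.005)
})

test_that("likelihood ratio compares parameter points in log space", {
  lr <- likelihood_ratio(diploid_counts, "disomic",
                         list(r = mle_disomic(diploid_counts)$value),
                         list(r = 0.154))
  expect_gt(lr$ratio, 1)
  same <- likelihood_ratio(diploid_counts, "disomic",
                           list(r = 0.2), list(r = 0.2))
  expect_equal(same$ratio, 1)
  fwd <- likelihood_ratio(diploid_counts, "disomic",
                          list(r = 0.154), list(r = 0.1643))
  expect_equal(fwd$ratio, 1 / likelihood_ratio(diploid_counts, "disomic",
                                               list(r = 0.1643),
                                               list(r = 0.154))$ratio,
               tolerance = 1e-12)
})

test_that("moment estimator variants behave as documented", {
  expect_equal(unname(moment_estimate(diploid_counts)), 655 / 4251)
  expect_equal(unname(moment_estimate(allotetraploid_counts)), 573 / 2377)
  expect_equal(unname(moment_estimate(autotetraploid_counts)), 4084 / 19889)
  expect_equal(unname(moment_estimate(diploid_counts, "printed_equation")),
               1 - sqrt(1 - 2 * 655 / 4251), tolerance = 1e-12)
  # the two variants genuinely differ
  expect_gt(moment_estimate(diploid_counts, "printed_equation"),
            moment_estimate(diploid_counts, "proportion"))
  expect_equal(unname(moment_estimate(c(10, 0, 0, 5), "proportion")), 0)
  expect_equal(unname(moment_estimate(c(10, 0, 0, 5), "printed_equation")), 0)
  expect_error(moment_estimate(c(0, 10, 10, 0), "printed_equation"),
               "exceeds 1")
})

test_that("observed information SE has the Gaussian curvature identity", {
  ll <- function(theta) -(theta - 0.3)^2 / (2 * 0.01^2)
  expect_equal(observed_information_se(ll, 0.3), 0.01, tolerance = 1e-6)
  # numeric route agrees with the analytic SEs used by the fitters
  num <- observed_information_se(
    function(r) phenotype_loglik(diploid_counts, disomic_phenotype_probs(r)),
    mle_disomic(diploid_counts)$value)
  expect_equal(num, mle_disomic(diploid_counts)$se, tolerance = 1e-6)
  expect_error(observed_information_se(function(x) (x - 0.3)^2, 0.3),
               "concave")
})
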