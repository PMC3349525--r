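# Multinomial simulation of phenotype counts and a parameter-recovery
# harness. Sampling is at the phenotype-class level the likelihood models
# (a single multinomial draw per population); no meiosis-level mechanism is
# simulated. Each replicate gets its own RNG substream derived from
# (seed, replicate index) by a fixed linear hash, so replicate k is
# reproducible independently of how many other replicates are drawn or in
# what order.

replicate_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647) * 48271 + i * 69621) %% 2147483647L
}

model_probs <- function(model, r, alpha) {
  if (model == "disomic") {
    check_disomic_r(r)
    as.numeric(disomic_f_matrix(r))
  } else {
    check_tetrasomic_params(alpha, r)
    as.numeric(tetra_f_matrix(alpha, r))
  }
}

#' Simulate phenotype counts
#'
#' Draws F2 populations as single multinomial samples of size `n` over the
#' four phenotype-class probabilities of the chosen model.
#'
#' @param model `"disomic"` or `"tetrasomic"`.
#' @param r True recombination fraction.
#' @param alpha True double-reduction coefficient at the green marker
#'   (tetrasomic model only).
#' @param n Population size (individuals per replicate).
#' @param replicates Number of independent populations to draw.
#' @param seed Integer seed. Replicate `k` depends only on (`seed`, `k`).
#'
#' @return A tibble in the counts-table format ([read_counts_table()]):
#'   columns `population_id`, `model`, `n_yellow`, `n_green`, `n_red`,
#'   `n_grey`, one row per replicate, each row summing to `n`.
#'
#' @examples
#' simulate_counts("disomic", r = 0.1643, n = 4251, replicates = 3, seed = 1)
#' @export
simulate_counts <- function(model = c("disomic", "tetrasomic"), r,
                            alpha = NULL, n, replicates = 1, seed = 1) {
  model <- arg_match(model)
  if (model == "tetrasomic" && is.null(alpha)) {
    abort("`alpha` is required for the tetrasomic model.")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer population size.")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    abort("`replicates` must be >= 1.")
  }
  f <- model_probs(model, r, alpha)
  draws <- purrr::map(seq_len(replicates), function(k) {
    withr_seed <- replicate_seed(seed, k)
    set.seed(withr_seed)
    as.integer(rmultinom(1, size = n, prob = f))
  })
  m <- do.call(rbind, draws)
  tibble(population_id = sprintf("sim_%03d", seq_len(replicates)),
         model = model,
         n_yellow = m[, 1], n_green = m[, 2], n_red = m[, 3], n_grey = m[, 4])
}

#' Parameter-recovery experiment
#'
#' Simulates `replicates` populations at known parameter values, refits each
#' with [fit_population()], and summarises estimator bias, spread and Wald
#' standard-error calibration. Replicates whose fit lands on a parameter
#' boundary are excluded from the moment and coverage summaries (their SEs are
#' undefined) and reported through `boundary_rate`; replicates that fail
#' outright are counted in `n_failed`.
#'
#' @inheritParams simulate_counts
#'
#' @return A tibble of class `rf_recovery`, one row per parameter, with
#'   columns `term`, `truth`, `mean_estimate`, `bias`, `empirical_sd`,
#'   `mean_se`, `coverage_95` (nominal 95% Wald intervals containing the
#'   truth), and attributes `boundary_rate`, `n_failed`, `replicates_used`,
#'   plus an `estimates` attribute holding the per-replicate tidy estimates.
#'
#' @examples
#' run_recovery("disomic", r = 0.1643, n = 4251, replicates = 20, seed = 1)
#' @export
run_recovery <- function(model = c("disomic", "tetrasomic"), r, alpha = NULL,
                         n, replicates = 100, seed = 1) {
  model <- arg_match(model)
  sims <- simulate_counts(model, r = r, alpha = alpha, n = n,
                          replicates = replicates, seed = seed)
  truth <- c(alpha = if (model == "tetrasomic") alpha else NULL, r = r)
  res <- purrr::map(seq_len(nrow(sims)), function(k) {
    counts <- as.numeric(sims[k, c("n_yellow", "n_green", "n_red", "n_grey")])
    tryCatch(
      suppressWarnings({
        fit <- fit_population(counts, model = model)
        est <- tidy(fit)
        est$replicate <- k
        list(est = est, boundary = glance(fit)$at_boundary, failed = FALSE)
      }),
      error = function(e) list(est = NULL, boundary = FALSE, failed = TRUE)
    )
  })
  n_failed <- sum(purrr::map_lgl(res, "failed"))
  boundary <- purrr::map_lgl(res, "boundary")
  ests <- dplyr::bind_rows(purrr::map(res, "est"))
  used <- ests[!ests$replicate %in% which(boundary), ]
  z <- qnorm(0.975)
  summ <- used |>
    dplyr::mutate(truth = unname(truth[.data$term])) |>
    dplyr::group_by(.data$term, .data$truth) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      empirical_sd = sd(.data$estimate),
      mean_se = mean(.data$std.error),
      coverage_95 = mean(abs(.data$estimate - .data$truth) <=
                           z * .data$std.error),
      .groups = "drop"
    )
  structure(
    summ,
    boundary_rate = mean(boundary),
    n_failed = n_failed,
    replicates_used = length(unique(used$replicate)),
    estimates = ests,
    class = c("rf_recovery", class(summ))
  )
}
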