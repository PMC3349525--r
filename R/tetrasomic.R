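# Tetrasomic (multivalent-pairing) two-locus model for an autotetraploid F2.
# Parameters: alpha, the coefficient of double reduction at the proximal
# (green) marker, in [0, 1/4]; r, the recombination fraction, in [0, 3/4].
#
# The F1 parent is simplex at both markers in coupling. A gamete falls in one
# of four classes: carries both marker alleles (g1), green only (g2), red only
# (g3), neither (g4). Random union of gametes then gives the four seed classes
# via the dominance quadratic forms below. Sum(g) = 1 and Sum(f) = 1 are
# algebraic identities (the g_i are a partition of 1 in the basis
# {(1-r)^2, r(1-r), r^2}).

tetra_g_matrix <- function(alpha, r) {
  cbind(
    g_both    = (2 - alpha) * (1 - r)^2 / 4 + r * (1 - r) / 2 +
                (1 - alpha) * r^2 / 6,
    g_green   = (1 - alpha) * r * (1 - r) / 3 + (10 - alpha) * r^2 / 36,
    g_red     = r * (1 - r) / 2 + (8 + alpha) * r^2 / 36,
    g_neither = (2 + alpha) * ((1 - r)^2 / 4 + r * (1 - r) / 3 + r^2 / 6)
  )
}

# d/dr and d^2/dr^2 of the gamete-class probabilities (quadratics in r).
tetra_g_d1 <- function(alpha, r) {
  cbind(
    -(2 - alpha) * (1 - r) / 2 + (1 - 2 * r) / 2 + (1 - alpha) * r / 3,
    (1 - alpha) * (1 - 2 * r) / 3 + (10 - alpha) * r / 18,
    (1 - 2 * r) / 2 + (8 + alpha) * r / 18,
    (2 + alpha) * (-(1 - r) / 2 + (1 - 2 * r) / 3 + r / 3)
  )
}

tetra_g_d2 <- function(alpha, r) {
  z <- rep(0, max(length(alpha), length(r)))
  cbind(
    z + (2 - alpha) / 2 - 1 + (1 - alpha) / 3,
    z - 2 * (1 - alpha) / 3 + (10 - alpha) / 18,
    z - 1 + (8 + alpha) / 18,
    z + (2 + alpha) / 6
  )
}

# Phenotype-class probabilities from a matrix of gamete-class probabilities:
#   f1 = g1(2 - g1) + 2 g2 g3,  f2 = g2(g2 + 2 g4),
#   f3 = g3(g3 + 2 g4),         f4 = g4^2.
phenotype_quadratic <- function(g) {
  cbind(yellow = g[, 1] * (2 - g[, 1]) + 2 * g[, 2] * g[, 3],
        green  = g[, 2] * (g[, 2] + 2 * g[, 4]),
        red    = g[, 3] * (g[, 3] + 2 * g[, 4]),
        grey   = g[, 4]^2)
}

tetra_f_matrix <- function(alpha, r) {
  phenotype_quadratic(tetra_g_matrix(alpha, r))
}

# First and second r-derivatives of the phenotype probabilities via the chain
# rule on the quadratic forms.
tetra_f_d1 <- function(alpha, r, g = tetra_g_matrix(alpha, r),
                       dg = tetra_g_d1(alpha, r)) {
  cbind(
    (2 - 2 * g[, 1]) * dg[, 1] + 2 * (dg[, 2] * g[, 3] + g[, 2] * dg[, 3]),
    2 * (g[, 2] * dg[, 2] + dg[, 2] * g[, 4] + g[, 2] * dg[, 4]),
    2 * (g[, 3] * dg[, 3] + dg[, 3] * g[, 4] + g[, 3] * dg[, 4]),
    2 * g[, 4] * dg[, 4]
  )
}

tetra_f_d2 <- function(alpha, r, g = tetra_g_matrix(alpha, r),
                       dg = tetra_g_d1(alpha, r),
                       d2g = tetra_g_d2(alpha, r)) {
  cbind(
    -2 * dg[, 1]^2 + (2 - 2 * g[, 1]) * d2g[, 1] +
      2 * (d2g[, 2] * g[, 3] + 2 * dg[, 2] * dg[, 3] + g[, 2] * d2g[, 3]),
    2 * (dg[, 2]^2 + g[, 2] * d2g[, 2] +
           d2g[, 2] * g[, 4] + 2 * dg[, 2] * dg[, 4] + g[, 2] * d2g[, 4]),
    2 * (dg[, 3]^2 + g[, 3] * d2g[, 3] +
           d2g[, 3] * g[, 4] + 2 * dg[, 3] * dg[, 4] + g[, 3] * d2g[, 4]),
    2 * (dg[, 4]^2 + g[, 4] * d2g[, 4])
  )
}

#' Gamete-class probabilities under tetrasomic inheritance
#'
#' Probabilities that a gamete from the simplex-coupling autotetraploid F1
#' carries both marker alleles, the green allele only, the red allele only, or
#' neither, as polynomials in the double-reduction coefficient `alpha` at the
#' green (proximal) marker and the recombination fraction `r`.
#'
#' @param alpha Coefficient(s) of double reduction at the green marker, in
#'   \eqn{[0, 1/4]}.
#' @param r Recombination fraction(s), in \eqn{[0, 3/4]}. `alpha` and `r` are
#'   recycled to a common length.
#'
#' @return A tibble with columns `alpha`, `r`, `g_both`, `g_green`, `g_red`,
#'   `g_neither`. Rows sum to 1.
#'
#' @examples
#' tetrasomic_gamete_probs(alpha = 0, r = 0.3)
#' @export
tetrasomic_gamete_probs <- function(alpha, r) {
  check_tetrasomic_params(alpha, r)
  k <- max(length(alpha), length(r))
  alpha <- rep_len(alpha, k)
  r <- rep_len(r, k)
  g <- tetra_g_matrix(alpha, r)
  if (any(g < 0)) {
    abort("Negative gamete-class probability; parameters outside the model's valid region.")
  }
  tibble(alpha = alpha, r = r, g_both = unname(g[, 1]),
         g_green = unname(g[, 2]), g_red = unname(g[, 3]),
         g_neither = unname(g[, 4]))
}

#' Phenotype-class probabilities from gamete-class probabilities
#'
#' Pushes gamete-class probabilities through random union of gametes with
#' dominance at both markers: `yellow = g_both(2 - g_both) + 2 g_green g_red`,
#' `green = g_green(g_green + 2 g_neither)`, `red = g_red(g_red + 2
#' g_neither)`, `grey = g_neither^2`. Whenever the gamete classes sum to 1, so
#' do the phenotype classes.
#'
#' @param gametes A data frame with columns `g_both`, `g_green`, `g_red`,
#'   `g_neither` (as returned by [tetrasomic_gamete_probs()]), each row a
#'   gamete-class distribution summing to 1.
#'
#' @return The input tibble with phenotype-class columns `yellow`, `green`,
#'   `red`, `grey` appended.
#'
#' @examples
#' tetrasomic_gamete_probs(alpha = 0.06, r = 0.3) |> phenotype_from_gametes()
#' @export
phenotype_from_gametes <- function(gametes) {
  cols <- c("g_both", "g_green", "g_red", "g_neither")
  if (!is.data.frame(gametes) || !all(cols %in% names(gametes))) {
    abort("`gametes` must be a data frame with columns g_both, g_green, g_red, g_neither.")
  }
  g <- as.matrix(gametes[cols])
  if (any(g < 0 | g > 1) || any(abs(rowSums(g) - 1) > 1e-8)) {
    abort("Each row of `gametes` must be probabilities summing to 1.")
  }
  f <- phenotype_quadratic(g)
  out <- as_tibble(gametes)
  out$yellow <- unname(f[, 1])
  out$green <- unname(f[, 2])
  out$red <- unname(f[, 3])
  out$grey <- unname(f[, 4])
  out
}

#' Phenotype-class probabilities under tetrasomic inheritance
#'
#' Composition of [tetrasomic_gamete_probs()] and [phenotype_from_gametes()]:
#' the probabilities of the yellow/green/red/grey seed classes in an
#' autotetraploid F2 as functions of the double-reduction coefficient at the
#' green marker and the recombination fraction.
#'
#' @inheritParams tetrasomic_gamete_probs
#'
#' @return A tibble with columns `alpha`, `r`, `yellow`, `green`, `red`,
#'   `grey`; rows sum to 1.
#'
#' @examples
#' tetrasomic_phenotype_probs(alpha = 0.0676, r = 0.3048)
#' @export
tetrasomic_phenotype_probs <- function(alpha, r) {
  g <- tetrasomic_gamete_probs(alpha, r)
  f <- phenotype_from_gametes(g)
  f[c("alpha", "r", "yellow", "green", "red", "grey")]
}

#' Marginal probabilities of carrying the green marker
#'
#' Setting `r = 0` in the tetrasomic phenotype probabilities collapses them to
#' a two-class margin that depends on `alpha` alone: the probability that an
#' F2 individual carries the green fluorescent marker,
#' `p_green = (12 - 4 alpha - alpha^2) / 16`, and its complement
#' `p_none = (2 + alpha)^2 / 16`. This margin is the basis of the first step
#' of the two-step tetrasomic fit (see [mle_alpha_marginal()]).
#'
#' @param alpha Coefficient(s) of double reduction at the green marker, in
#'   \eqn{[0, 1/4]}.
#'
#' @return A tibble with columns `alpha`, `p_green`, `p_none`;
#'   `p_green + p_none = 1`.
#'
#' @examples
#' green_marginal_probs(c(0, 0.0676))
#' @export
green_marginal_probs <- function(alpha) {
  check_fraction(alpha, ALPHA_MAX, "alpha")
  tibble(alpha = alpha,
         p_green = (12 - 4 * alpha - alpha^2) / 16,
         p_none = (2 + alpha)^2 / 16)
}

#' Predict the double-reduction coefficient at the red marker
#'
#' Given the double-reduction coefficient at the proximal (green) marker and
#' the recombination fraction between the markers, predicts the coefficient of
#' double reduction at the distal (red) marker:
#' \deqn{\beta = [\alpha (3 - 4r)^2 + 2r(3 - 2r)] / 9.}
#' The prediction is flagged (not rejected) if it exceeds the theoretical
#' maximum 1/4; on the declared parameter box the formula is in fact bounded
#' by 1/4, so the flag guards only against future extensions of the domain.
#'
#' @inheritParams tetrasomic_gamete_probs
#'
#' @return A tibble with columns `alpha`, `r`, `beta`, `exceeds_upper_bound`.
#'
#' @examples
#' predict_double_reduction_red(alpha = 0.0676, r = 0.3048)
#' @export
predict_double_reduction_red <- function(alpha, r) {
  check_tetrasomic_params(alpha, r)
  k <- max(length(alpha), length(r))
  alpha <- rep_len(alpha, k)
  r <- rep_len(r, k)
  beta <- (alpha * (3 - 4 * r)^2 + 2 * r * (3 - 2 * r)) / 9
  flag <- beta > 0.25 + 1e-12
  if (any(flag)) {
    warn("Predicted double reduction at the red marker exceeds the theoretical maximum 1/4.")
  }
  tibble(alpha = alpha, r = r, beta = beta, exceeds_upper_bound = flag)
}
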