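# Disomic (bivalent-pairing) two-locus model for an F2 in coupling phase.
# Both markers are dominant, so the cross segregates into four seed-colour
# classes: yellow (both markers), green only, red only, grey (neither).
#
# Class probabilities as functions of the recombination fraction r:
#   f_yellow = 3(1-r)^2/4 + r(1-r) + r^2/2   (= (r^2 - 2r + 3)/4)
#   f_green  = f_red = r(2-r)/4
#   f_grey   = (1-r)^2/4
# At r = 0 this is the 3:1 coupling limit; at r = 1/2 the 9:3:3:1 ratio.

# f, f', f'' as 4-column matrices over a vector of r values.
disomic_f_matrix <- function(r) {
  cbind(yellow = (r^2 - 2 * r + 3) / 4,
        green  = r * (2 - r) / 4,
        red    = r * (2 - r) / 4,
        grey   = (1 - r)^2 / 4)
}

disomic_f_d1 <- function(r) {
  cbind((r - 1) / 2, (1 - r) / 2, (1 - r) / 2, (r - 1) / 2)
}

disomic_f_d2 <- function(r) {
  n <- length(r)
  cbind(rep(0.5, n), rep(-0.5, n), rep(-0.5, n), rep(0.5, n))
}

#' Phenotype-class probabilities under disomic inheritance
#'
#' Probabilities of the four seed-fluorescence classes (yellow, green-only,
#' red-only, grey) in an F2 population segregating for two linked dominant
#' markers in coupling phase, under disomic (bivalent) inheritance. This model
#' applies to diploids and to allotetraploids whose homoeologous pairing is
#' excluded.
#'
#' @param r Recombination fraction(s) between the two markers, in
#'   \eqn{[0, 1/2]}.
#'
#' @return A tibble with columns `r`, `yellow`, `green`, `red`, `grey`; one
#'   row per value of `r`. Rows sum to 1.
#'
#' @examples
#' disomic_phenotype_probs(c(0, 0.1643, 0.5))
#' @export
disomic_phenotype_probs <- function(r) {
  check_disomic_r(r)
  f <- disomic_f_matrix(r)
  tibble(r = r, yellow = unname(f[, 1]), green = unname(f[, 2]),
         red = unname(f[, 3]), grey = unname(f[, 4]))
}
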