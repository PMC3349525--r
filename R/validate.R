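# Input validation shared across the probability, inference and simulation
# layers. Parameter boxes: r in [0, 1/2] under disomic inheritance, r in
# [0, 3/4] and alpha in [0, 1/4] under tetrasomic inheritance (the theoretical
# upper bounds for the two meiosis models). Out-of-range values raise errors
# rather than being clipped.

DISOMIC_R_MAX <- 0.5
TETRASOMIC_R_MAX <- 0.75
ALPHA_MAX <- 0.25

check_fraction <- function(x, max, name, call = caller_env()) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", name),
          call = call)
  }
  if (any(x < 0 | x > max)) {
    abort(sprintf("`%s` must lie in [0, %s]; got %s.", name, format(max),
                  format(x[which(x < 0 | x > max)[1]])),
          call = call)
  }
  invisible(x)
}

check_disomic_r <- function(r, call = caller_env()) {
  check_fraction(r, DISOMIC_R_MAX, "r", call = call)
}

check_tetrasomic_params <- function(alpha, r, call = caller_env()) {
  check_fraction(alpha, ALPHA_MAX, "alpha", call = call)
  check_fraction(r, TETRASOMIC_R_MAX, "r", call = call)
  if (length(alpha) != length(r) && length(alpha) != 1 && length(r) != 1) {
    abort("`alpha` and `r` must have compatible lengths.", call = call)
  }
  invisible(NULL)
}

# Coerce phenotype counts to a validated named vector c(yellow, green, red,
# grey). Accepts a plain numeric vector of length 4 (in that class order) or
# a one-row data frame with columns n_yellow, n_green, n_red, n_grey.
as_counts <- function(counts, call = caller_env()) {
  if (is.data.frame(counts)) {
    cols <- c("n_yellow", "n_green", "n_red", "n_grey")
    if (nrow(counts) != 1 || !all(cols %in% names(counts))) {
      abort(paste0("A data-frame `counts` must have exactly one row and ",
                   "columns n_yellow, n_green, n_red, n_grey."), call = call)
    }
    counts <- as.numeric(counts[1, cols])
  }
  if (!is.numeric(counts) || length(counts) != 4 || anyNA(counts)) {
    abort("`counts` must be 4 numbers: yellow, green, red, grey.", call = call)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Phenotype counts must be nonnegative integers.", call = call)
  }
  if (sum(counts) < 1) {
    abort("At least one individual is required (sum of counts >= 1).",
          call = call)
  }
  names(counts) <- c("yellow", "green", "red", "grey")
  counts
}
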