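# Counts-table I/O. The on-disk format is a CSV or TSV with header
# population_id, model, n_yellow, n_green, n_red, n_grey (case-insensitive),
# one row per F2 population. The simulator emits the same format, so
# simulated data round-trip through the reader.

COUNTS_COLS <- c("population_id", "model", "n_yellow", "n_green", "n_red",
                 "n_grey")
MODEL_LABELS <- c("disomic", "tetrasomic")

validate_counts_table <- function(data, call = caller_env()) {
  if (!is.data.frame(data)) abort("Counts table must be a data frame.", call = call)
  names(data) <- tolower(names(data))
  missing_cols <- setdiff(COUNTS_COLS, names(data))
  if (length(missing_cols)) {
    abort(paste0("Counts table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."), call = call)
  }
  data <- as_tibble(data)[COUNTS_COLS]
  if (nrow(data) == 0) return(data)
  if (anyDuplicated(data$population_id)) {
    dup <- data$population_id[duplicated(data$population_id)][1]
    abort(sprintf("Duplicate population_id '%s'.", dup), call = call)
  }
  bad_model <- which(!data$model %in% MODEL_LABELS)
  if (length(bad_model)) {
    abort(sprintf("Row %d: unknown model label '%s' (expected disomic or tetrasomic).",
                  bad_model[1], data$model[bad_model[1]]), call = call)
  }
  for (col in COUNTS_COLS[3:6]) {
    raw <- data[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
      abort(sprintf("Row %d, column %s: '%s' is not a nonnegative integer.",
                    bad[1], col, as.character(raw[bad[1]])), call = call)
    }
    data[[col]] <- as.integer(num)
  }
  data
}

#' Read a phenotype counts table
#'
#' Reads a CSV/TSV of per-population phenotype counts with (case-insensitive)
#' header `population_id, model, n_yellow, n_green, n_red, n_grey` and
#' validates it: counts must be nonnegative integers, model labels must be
#' `disomic` or `tetrasomic`, and population ids must be unique. Errors name
#' the offending row and column.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by file extension; default CSV), `"csv"` or
#'   `"tsv"`.
#'
#' @return A tibble with the six columns above (counts as integers). A file
#'   with only a header yields an empty tibble with a warning.
#'
#' @examples
#' path <- system.file("extdata", "arabidopsis_f2_counts.csv",
#'                     package = "polyrec")
#' read_counts_table(path)
#' @export
read_counts_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  data <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                 progress = FALSE)
  out <- validate_counts_table(data)
  if (nrow(out) == 0) warn(sprintf("Counts table %s has a header but no rows.", path))
  out
}

#' Write a phenotype counts table
#'
#' @param data A counts table (validated with the same rules as
#'   [read_counts_table()]).
#' @param path Output path; extension `.tsv`/`.tab` selects TSV, anything else
#'   CSV, unless `dialect` overrides.
#' @inheritParams read_counts_table
#'
#' @return `data`, invisibly.
#' @export
write_counts_table <- function(data, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- arg_match(dialect)
  data <- validate_counts_table(data)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (dialect == "tsv") readr::write_tsv(data, path) else readr::write_csv(data, path)
  invisible(data)
}

#' Fluorescent-seed F2 phenotype counts for three Arabidopsis populations
#'
#' The published seed-phenotype counts for the diploid, allotetraploid and
#' autotetraploid *Arabidopsis thaliana* F2 populations carrying linked green
#' and red fluorescent seed markers on chromosome III in coupling phase. The
#' diploid and allotetraploid populations segregate disomically; the
#' autotetraploid follows tetrasomic inheritance.
#'
#' @return A counts table (tibble) with one row per population. The same data
#'   ship as a CSV at `system.file("extdata", "arabidopsis_f2_counts.csv",
#'   package = "polyrec")`.
#'
#' @examples
#' arabidopsis_f2_counts()
#' @export
arabidopsis_f2_counts <- function() {
  tibble(
    population_id = c("diploid", "allotetraploid", "autotetraploid"),
    model = c("disomic", "disomic", "tetrasomic"),
    n_yellow = c(2805L, 1484L, 12707L),
    n_green = c(322L, 275L, 1868L),
    n_red = c(333L, 298L, 2216L),
    n_grey = c(791L, 320L, 3098L)
  )
}
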