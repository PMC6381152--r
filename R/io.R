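trial_table_columns <- c(
  "participant_id", "group", "phase", "block", "item_id", "category",
  "category_role", "quadrant", "is_critical", "target",
  "schema_mean_current", "schema_mean_original", "schema_mean_study",
  "response"
)

#' Write a trial table to delimited text
#'
#' UTF-8 CSV with a header row; angles in decimal degrees at full precision;
#' missing responses written as empty fields. This file format is the
#' interchange contract between the simulator and the analysis functions.
#'
#' @param trials Trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  missing <- setdiff(trial_table_columns, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_csv(trials[, intersect(c(trial_table_columns, "sim_component"),
                                      names(trials))],
                   path, na = "")
  invisible(path)
}

#' Read a trial table from delimited text
#'
#' Validates the column set and angle ranges; malformed rows are reported with
#' their (1-based, header-exclusive) row numbers. CRLF line endings are
#' accepted.
#'
#' @param path Input file path.
#' @return A trial tibble.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  # column presence is validated below; silence readr's unmatched-parser chatter
  trials <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      phase = readr::col_character(),
      block = readr::col_integer(),
      item_id = readr::col_character(),
      category = readr::col_character(),
      category_role = readr::col_character(),
      quadrant = readr::col_character(),
      is_critical = readr::col_logical(),
      target = readr::col_double(),
      schema_mean_current = readr::col_double(),
      schema_mean_original = readr::col_double(),
      schema_mean_study = readr::col_double(),
      response = readr::col_double(),
      .default = readr::col_character()
    ),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  ))
  missing <- setdiff(trial_table_columns, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Malformed rows in ", path, ": ",
      paste(sprintf("row %d (%s)", probs$row, probs$expected), collapse = "; ")
    ))
  }
  for (col in c("target", "schema_mean_current", "schema_mean_original",
                "schema_mean_study")) {
    bad <- which(!is.finite(trials[[col]]) | trials[[col]] < 0 | trials[[col]] >= 360)
    if (length(bad)) {
      abort(sprintf("Column `%s` out of range [0, 360) at row(s): %s",
                    col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  bad <- which(!is.na(trials$response) &
                 (trials$response < 0 | trials$response >= 360))
  if (length(bad)) {
    abort(sprintf("Column `response` out of range [0, 360) at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  trials
}
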