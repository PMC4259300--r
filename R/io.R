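#' Read trial-level BIAT data from delimited text
#'
#' Reads a long-format trial file (one row per categorization trial) and
#' validates it: the header must name every required column and every latency
#' must be a positive number. The column set matches the trial model used
#' throughout the package: `session_id`, `focal_polarity`, `block_index`,
#' `trial_index` (0-based within block), `condition`, `latency_ms`, `error`.
#' An optional `topic` column is carried through if present.
#'
#' @param path Path to a CSV (default) or TSV file with a header row.
#' @param delim Field delimiter; `NULL` picks `"\t"` for `.tsv` files and
#'   `","` otherwise.
#' @return A tibble of trials, row order preserved, grouped-ready by
#'   `session_id`.
#' @export
read_trials <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("trial file does not exist: %s", path))
  }
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  trials <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    abort(sprintf("trial file is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  trials <- trials |>
    dplyr::mutate(
      session_id = as.character(.data$session_id),
      block_index = as.integer(.data$block_index),
      trial_index = as.integer(.data$trial_index),
      latency_ms = suppressWarnings(as.numeric(.data$latency_ms)),
      error = parse_flag(.data$error)
    )
  bad <- which(is.na(trials$latency_ms) | trials$latency_ms <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive or non-numeric latency_ms at data row(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  trials
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

score_columns <- c(
  "session_id", "focal_polarity", "transformation",
  "pair1_score", "pair2_score", "score",
  "excluded", "exclusion_reason", "n_trials_used", "mean_latency_ms"
)

#' Write session scores to delimited text
#'
#' Writes the score table produced by [score_sessions()] with a stable column
#' order. Scores survive a write/read round trip at full double precision;
#' excluded sessions keep an empty `score` cell and a populated
#' `exclusion_reason`.
#'
#' @param scores A non-empty score tibble from [score_sessions()].
#' @param path Output path; delimiter chosen as in [read_trials()].
#' @param delim Field delimiter, `NULL` for automatic.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, delim = NULL) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    abort("`scores` must be a non-empty data frame of score records.")
  }
  missing <- setdiff(score_columns, names(scores))
  if (length(missing) > 0) {
    abort(sprintf("score table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(scores[score_columns], path, delim = delim, na = "")
  invisible(path)
}

#' Read a score file written by [write_scores()]
#'
#' @param path Path to the score file.
#' @param delim Field delimiter, `NULL` for automatic.
#' @return A score tibble with the standard column types.
#' @export
read_scores <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("score file does not exist: %s", path))
  }
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      session_id = readr::col_character(),
      focal_polarity = readr::col_character(),
      transformation = readr::col_character(),
      pair1_score = readr::col_double(),
      pair2_score = readr::col_double(),
      score = readr::col_double(),
      excluded = readr::col_logical(),
      exclusion_reason = readr::col_character(),
      n_trials_used = readr::col_integer(),
      mean_latency_ms = readr::col_double()
    )
  )
}
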