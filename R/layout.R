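#' Standard BIAT block layout
#'
#' The standard administration of the Brief Implicit Association Test runs a
#' 16-trial practice block (block 1, a neutral category pairing that is never
#' scored) followed by four 20-trial response blocks (blocks 2--5). Each
#' response block opens with 4 category-only warm-up trials and then 16 trials
#' alternating category and attribute. The two category pairings alternate
#' across blocks: blocks 2 and 4 share one pairing (`condition1`), blocks 3
#' and 5 the other (`condition2`).
#'
#' @return A tibble with one row per block: `block_index`, `n_trials`,
#'   `condition` (`NA` for the unscored practice block), and `scored`.
#' @export
#' @examples
#' biat_block_layout()
biat_block_layout <- function() {
  tibble::tibble(
    block_index = 1:5,
    n_trials = c(16L, 20L, 20L, 20L, 20L),
    condition = c(NA, "condition1", "condition2", "condition1", "condition2"),
    scored = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

trial_columns <- c(
  "session_id", "focal_polarity", "block_index", "trial_index",
  "condition", "latency_ms", "error"
)

#' Validate sessions against an expected block layout
#'
#' Checks every session (and focal polarity) in a trial table against an
#' expected block layout: the set of block indices, the trial count per block,
#' and the alternation of category pairings across the scored blocks.
#' Violations are returned, not raised, so a whole file can be screened in
#' one pass.
#'
#' @param trials A trial tibble as returned by [read_trials()] or
#'   [simulate_biat()].
#' @param layout Expected layout, as returned by [biat_block_layout()].
#' @return A tibble of violations with columns `session_id`,
#'   `focal_polarity`, `block_index`, and `violation`. Zero rows means every
#'   session conforms.
#' @export
validate_sessions <- function(trials, layout = biat_block_layout()) {
  check_trial_frame(trials)
  expected <- layout

  per_block <- trials |>
    dplyr::group_by(.data$session_id, .data$focal_polarity, .data$block_index) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_conditions = dplyr::n_distinct(.data$condition),
      condition = .data$condition[1],
      .groups = "drop"
    )

  joined <- per_block |>
    dplyr::left_join(expected, by = "block_index",
                     suffix = c("", "_expected"))

  violations <- list()

  unknown <- joined |> dplyr::filter(is.na(.data$n_trials_expected))
  if (nrow(unknown) > 0) {
    violations$unknown <- unknown |>
      dplyr::transmute(.data$session_id, .data$focal_polarity,
                       .data$block_index,
                       violation = "block index outside expected layout")
  }

  known <- joined |> dplyr::filter(!is.na(.data$n_trials_expected))

  bad_count <- known |>
    dplyr::filter(.data$n_trials != .data$n_trials_expected)
  if (nrow(bad_count) > 0) {
    violations$count <- bad_count |>
      dplyr::transmute(
        .data$session_id, .data$focal_polarity, .data$block_index,
        violation = sprintf("block has %d trials, expected %d",
                            .data$n_trials, .data$n_trials_expected)
      )
  }

  mixed <- known |>
    dplyr::filter(.data$scored, .data$n_conditions > 1)
  if (nrow(mixed) > 0) {
    violations$mixed <- mixed |>
      dplyr::transmute(.data$session_id, .data$focal_polarity,
                       .data$block_index,
                       violation = "block mixes condition labels")
  }

  # scored blocks must alternate: 2 and 4 share a condition, 3 and 5 the other
  alt <- known |>
    dplyr::filter(.data$scored, .data$n_conditions == 1) |>
    dplyr::group_by(.data$session_id, .data$focal_polarity) |>
    dplyr::filter(dplyr::n() == 4) |>
    dplyr::arrange(.data$block_index, .by_group = TRUE) |>
    dplyr::summarise(
      ok = .data$condition[1] == .data$condition[3] &&
        .data$condition[2] == .data$condition[4] &&
        .data$condition[1] != .data$condition[2],
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(alt) > 0) {
    violations$alt <- alt |>
      dplyr::transmute(.data$session_id, .data$focal_polarity,
                       block_index = NA_integer_,
                       violation = "scored blocks do not alternate conditions")
  }

  bad_index <- trials |>
    dplyr::left_join(expected, by = "block_index") |>
    dplyr::filter(!is.na(.data$n_trials),
                  .data$trial_index < 0 | .data$trial_index >= .data$n_trials) |>
    dplyr::distinct(.data$session_id, .data$focal_polarity, .data$block_index) |>
    dplyr::mutate(violation = "trial index outside 0-based block range")
  if (nrow(bad_index) > 0) violations$index <- bad_index

  if (length(violations) == 0) {
    return(tibble::tibble(session_id = character(), focal_polarity = character(),
                          block_index = integer(), violation = character()))
  }
  dplyr::bind_rows(violations) |>
    dplyr::arrange(.data$session_id, .data$focal_polarity, .data$block_index)
}

check_trial_frame <- function(trials, call = rlang::caller_env()) {
  if (!is.data.frame(trials)) {
    abort("`trials` must be a data frame of trial records.", call = call)
  }
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    abort(sprintf("trial table is missing required column(s): %s",
                  paste(missing, collapse = ", ")), call = call)
  }
  invisible(trials)
}
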