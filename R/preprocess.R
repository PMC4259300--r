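#' Remove implausibly slow trials
#'
#' Trials strictly slower than the cutoff indicate inattention to the task
#' and are removed outright (they are never recoded). The default cutoff is
#' 10,000 ms.
#'
#' @param trials A trial tibble.
#' @param cutoff_ms Positive cutoff in milliseconds.
#' @return The retained trials, original order preserved, with the number of
#'   removed trials in attribute `"removed"`.
#' @export
filter_slow_trials <- function(trials, cutoff_ms = 10000) {
  check_trial_frame(trials)
  stopifnot(cutoff_ms > 0)
  keep <- trials$latency_ms <= cutoff_ms
  out <- trials[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Remove warm-up trials from scored blocks
#'
#' Each response block opens with four category-only warm-up trials
#' (0-based `trial_index < 4`). They are qualitatively different from the
#' alternating trials that follow and are dropped before scoring; on a
#' standard 20-trial block this keeps 16 trials (a 20% reduction).
#' The practice block (block 1) is left untouched: it is never scored.
#'
#' @param trials A trial tibble.
#' @return Trials with warm-up trials of scored blocks removed; removal count
#'   in attribute `"removed"`.
#' @export
remove_warmup_trials <- function(trials) {
  check_trial_frame(trials)
  drop <- trials$block_index >= 2 & trials$trial_index < 4
  out <- trials[!drop, , drop = FALSE]
  attr(out, "removed") <- sum(drop)
  out
}

#' Treat a latency tail by deletion or boundary recoding
#'
#' Applies one tail treatment: trials strictly beyond `boundary_ms` on the
#' given side are either deleted or recoded to the boundary value. A latency
#' exactly at the boundary is untouched in both modes. Recoding preserves the
#' number of trials; deletion returns a subset.
#'
#' @param trials A trial tibble.
#' @param boundary_ms Positive boundary in milliseconds.
#' @param side `"fast"` treats latencies below the boundary, `"slow"` above.
#' @param mode `"recode"` or `"delete"`.
#' @return Treated trials; counts in attributes `"removed"` and `"recoded"`.
#' @export
#' @examples
#' trials <- simulate_biat(biat_sim_params(n_subjects = 2), seed = 1)$trials
#' recoded <- apply_tail_treatment(trials, 2000, "slow", "recode")
#' attr(recoded, "recoded")
apply_tail_treatment <- function(trials, boundary_ms,
                                 side = c("fast", "slow"),
                                 mode = c("recode", "delete")) {
  check_trial_frame(trials)
  side <- rlang::arg_match(side)
  mode <- rlang::arg_match(mode)
  stopifnot(boundary_ms > 0)
  beyond <- if (side == "fast") trials$latency_ms < boundary_ms
            else trials$latency_ms > boundary_ms
  if (mode == "delete") {
    out <- trials[!beyond, , drop = FALSE]
    attr(out, "removed") <- sum(beyond)
    attr(out, "recoded") <- 0L
  } else {
    out <- trials
    out$latency_ms[beyond] <- boundary_ms
    attr(out, "removed") <- 0L
    attr(out, "recoded") <- sum(beyond)
  }
  out
}

#' Apply the error-trial policy
#'
#' With the forced-correction procedure the trial latency already runs from
#' stimulus onset to the eventual correct response, so `"retain"` returns the
#' input unchanged; `"remove"` drops all trials flagged as errors.
#'
#' @param trials A trial tibble.
#' @param policy `"retain"` (default) or `"remove"`.
#' @return Trials after the policy; removal count in attribute `"removed"`.
#' @export
handle_error_trials <- function(trials, policy = c("retain", "remove")) {
  check_trial_frame(trials)
  policy <- rlang::arg_match(policy)
  if (policy == "retain") {
    attr(trials, "removed") <- 0L
    return(trials)
  }
  out <- trials[!trials$error, , drop = FALSE]
  attr(out, "removed") <- sum(trials$error)
  out
}

#' Fraction of fast responses
#'
#' The proportion of trials strictly faster than `fast_definition_ms`,
#' evaluated on pre-recode latencies (recoding to a 400 ms floor would erase
#' the sub-300 ms signal this statistic exists to detect).
#'
#' @param trials A non-empty trial tibble.
#' @param fast_definition_ms Latency defining a fast response (default 300).
#' @return A fraction in \[0, 1\].
#' @export
compute_fast_fraction <- function(trials, fast_definition_ms = 300) {
  check_trial_frame(trials)
  if (nrow(trials) == 0) {
    abort("cannot compute a fast fraction from zero trials.")
  }
  mean(trials$latency_ms < fast_definition_ms)
}

#' Error rate of a trial set
#'
#' @param trials A non-empty trial tibble.
#' @return The fraction of trials flagged as errors.
#' @export
compute_error_rate <- function(trials) {
  check_trial_frame(trials)
  if (nrow(trials) == 0) {
    abort("cannot compute an error rate from zero trials.")
  }
  mean(trials$error)
}

#' Respondent-level exclusion decision for one task
#'
#' A task (one respondent's set of scored-block trials for one focal
#' polarity) is excluded when its fast fraction strictly exceeds the fast
#' threshold ("more than 10% of responses faster than 300 ms" under the
#' defaults), or, when an error-rate rule is configured, when the error rate
#' strictly exceeds that threshold. Both statistics are computed on the
#' trials as given (pass post-cutoff, post-warm-up, pre-recode trials).
#'
#' @param trials Trial tibble for one task.
#' @param config A [biat_config()].
#' @return A list with `exclude` (logical) and `reason` (`NA`, `"fast"`, or
#'   `"error"`; the first triggered rule).
#' @export
apply_respondent_exclusions <- function(trials, config = biat_config()) {
  fast_thr <- config$fast_exclusion_threshold
  if (!is.null(fast_thr)) {
    frac <- compute_fast_fraction(trials, config$fast_definition_ms)
    if (frac > fast_thr) {
      return(list(exclude = TRUE, reason = "fast"))
    }
  }
  err_thr <- config$error_exclusion_threshold
  if (!is.null(err_thr)) {
    rate <- compute_error_rate(trials)
    if (rate > err_thr) {
      return(list(exclude = TRUE, reason = "error"))
    }
  }
  list(exclude = FALSE, reason = NA_character_)
}

#' Run the trial-level stages of the treatment pipeline
#'
#' Applies, in order: the hard slow cutoff, warm-up removal, the error-trial
#' policy, and the fast and slow tail treatments. Respondent-level summary
#' statistics (mean latency, fast fraction, error rate per session and focal
#' polarity) are captured after the cutoff and warm-up removal but before the
#' error policy and tail recoding, which is the only ordering that keeps the
#' fast-response signal and the error information intact.
#'
#' @param trials A trial tibble.
#' @param config A [biat_config()].
#' @return A list with `trials` (scored-block trials ready for scoring),
#'   `respondents` (per session x polarity pre-treatment statistics), and
#'   `counts` (a tibble of per-stage trial accounting that reconciles:
#'   retained + all removals = input).
#' @export
preprocess_trials <- function(trials, config = biat_config()) {
  check_trial_frame(trials)
  n_input <- nrow(trials)

  practice <- trials[trials$block_index < 2, , drop = FALSE]
  scored <- trials[trials$block_index >= 2, , drop = FALSE]

  scored <- filter_slow_trials(scored, config$slow_hard_cutoff_ms)
  n_slow_removed <- attr(scored, "removed")

  n_warmup_removed <- 0L
  if (config$remove_warmup) {
    scored <- remove_warmup_trials(scored)
    n_warmup_removed <- attr(scored, "removed")
  }

  respondents <- scored |>
    dplyr::group_by(.data$session_id, .data$focal_polarity) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_latency_ms = mean(.data$latency_ms),
      fast_fraction = mean(.data$latency_ms < config$fast_definition_ms),
      error_rate = mean(.data$error),
      .groups = "drop"
    )

  scored <- handle_error_trials(scored, config$error_trials)
  n_error_removed <- attr(scored, "removed")

  n_fast_removed <- 0L
  n_fast_recoded <- 0L
  if (!is.null(config$fast_boundary_ms)) {
    scored <- apply_tail_treatment(scored, config$fast_boundary_ms,
                                   "fast", config$fast_mode)
    n_fast_removed <- attr(scored, "removed")
    n_fast_recoded <- attr(scored, "recoded")
  }
  n_slow_tail_removed <- 0L
  n_slow_recoded <- 0L
  if (!is.null(config$slow_boundary_ms)) {
    scored <- apply_tail_treatment(scored, config$slow_boundary_ms,
                                   "slow", config$slow_mode)
    n_slow_tail_removed <- attr(scored, "removed")
    n_slow_recoded <- attr(scored, "recoded")
  }

  counts <- tibble::tibble(
    stage = c("input", "practice_block_set_aside", "slow_cutoff_removed",
              "warmup_removed", "error_removed", "fast_tail_removed",
              "slow_tail_removed", "fast_tail_recoded", "slow_tail_recoded",
              "retained_for_scoring"),
    trials = c(n_input, nrow(practice), n_slow_removed, n_warmup_removed,
               n_error_removed, n_fast_removed, n_slow_tail_removed,
               n_fast_recoded, n_slow_recoded, nrow(scored))
  )

  list(trials = scored, respondents = respondents, counts = counts)
}
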