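#' D statistic for one pair of contrasted conditions
#'
#' The D score contrasts `n1` latencies from condition 1 with `n2` latencies
#' from condition 2: `D = (M2 - M1) / SD`, where `M1` and `M2` are the
#' condition means and `SD` is the standard deviation of all `N = n1 + n2`
#' pooled latencies (not the pooled within-condition SD). D is an individual
#' effect size akin to Cohen's d, but because the between-condition
#' separation contributes to the pooled SD it is bounded: with equal block
#' sizes `|D| < 2`, the bound being approached by two well-separated
#' constant blocks.
#'
#' `d_statistic()` returns the bare number; [d_score()] wraps it with the
#' intermediate quantities.
#'
#' @param lat1,lat2 Positive latency vectors for conditions 1 and 2, each of
#'   length at least 2.
#' @param sd_denominator `"n-1"` for the sample SD (default) or `"n"`.
#' @return `d_statistic()`: a single number. `d_score()`: a one-row tibble
#'   with `n1`, `n2`, `N`, `M1`, `M2`, `SD`, `score`.
#' @export
#' @examples
#' d_score(c(500, 600, 700), c(800, 900, 1000))
d_statistic <- function(lat1, lat2, sd_denominator = c("n-1", "n")) {
  sd_denominator <- rlang::arg_match(sd_denominator)
  check_block_pair(lat1, lat2)
  pooled <- c(lat1, lat2)
  s <- sd(pooled)
  if (sd_denominator == "n") {
    n <- length(pooled)
    s <- s * sqrt((n - 1) / n)
  }
  if (!is.finite(s) || s == 0) {
    abort("D is undefined: pooled latencies have zero standard deviation.")
  }
  (mean(lat2) - mean(lat1)) / s
}

#' @rdname d_statistic
#' @export
d_score <- function(lat1, lat2, sd_denominator = c("n-1", "n")) {
  sd_denominator <- rlang::arg_match(sd_denominator)
  score <- d_statistic(lat1, lat2, sd_denominator)
  pooled <- c(lat1, lat2)
  s <- sd(pooled)
  if (sd_denominator == "n") {
    s <- s * sqrt((length(pooled) - 1) / length(pooled))
  }
  tibble::tibble(
    n1 = length(lat1), n2 = length(lat2), N = length(pooled),
    M1 = mean(lat1), M2 = mean(lat2), SD = s, score = score
  )
}

check_block_pair <- function(lat1, lat2, call = rlang::caller_env()) {
  if (length(lat1) < 2 || length(lat2) < 2) {
    abort(sprintf(
      "insufficient data: need at least 2 latencies per condition (got %d and %d).",
      length(lat1), length(lat2)), call = call)
  }
  invisible(NULL)
}

#' Difference-score transformations of a block pair
#'
#' The conventional competitors to D. All three share D's sign convention:
#' slower responding in condition 2 gives a positive score.
#'
#' * `latency`: `mean(lat2) - mean(lat1)`, milliseconds.
#' * `log`: `mean(log(lat2)) - mean(log(lat1))`, log-ms units.
#' * `reciprocal`: `mean(1000/lat1) - mean(1000/lat2)`, responses per second.
#'   The subtraction is reversed because a reciprocal measures speed, not
#'   slowness.
#'
#' The `SD` column carries the pooled standard deviation of the transformed
#' values, for diagnostics only; it does not enter the score.
#'
#' @param lat1,lat2 Positive latency vectors, each of length at least 2.
#' @param kind `"latency"`, `"log"`, or `"reciprocal"`.
#' @return A one-row tibble with `n1`, `n2`, `N`, `M1`, `M2`, `SD`, `score`
#'   in the transformed units.
#' @export
#' @examples
#' transform_diff(c(500, 500), c(1000, 1000), "log")   # log 2
transform_diff <- function(lat1, lat2, kind = c("latency", "log", "reciprocal")) {
  kind <- rlang::arg_match(kind)
  check_block_pair(lat1, lat2)
  if (kind %in% c("log", "reciprocal") && any(c(lat1, lat2) <= 0)) {
    abort(sprintf("%s transformation requires strictly positive latencies.",
                  kind))
  }
  t1 <- switch(kind,
               latency = lat1,
               log = log(lat1),
               reciprocal = 1000 / lat1)
  t2 <- switch(kind,
               latency = lat2,
               log = log(lat2),
               reciprocal = 1000 / lat2)
  score <- if (kind == "reciprocal") mean(t1) - mean(t2) else mean(t2) - mean(t1)
  tibble::tibble(
    n1 = length(lat1), n2 = length(lat2), N = length(t1) + length(t2),
    M1 = mean(t1), M2 = mean(t2), SD = sd(c(t1, t2)), score = score
  )
}

pair_score <- function(lat1, lat2, transformation, sd_denominator) {
  switch(transformation,
         D = d_statistic(lat1, lat2, sd_denominator),
         latency_diff = transform_diff(lat1, lat2, "latency")$score,
         log_diff = transform_diff(lat1, lat2, "log")$score,
         reciprocal_diff = transform_diff(lat1, lat2, "reciprocal")$score)
}

block_pairs <- function(pairing) {
  if (pairing == "consecutive") list(c(2L, 3L), c(4L, 5L))
  else list(c(2L, 5L), c(3L, 4L))
}

#' Score every session in a trial table
#'
#' Runs the full treatment-and-scoring pipeline on a long trial table and
#' returns one score row per session and focal polarity. The stages, in
#' order: hard slow cutoff, warm-up removal, error-trial policy, fast and
#' slow tail treatment, per-pair scoring, respondent exclusion. The score is
#' computed separately for each pair of blocks sharing both conditions
#' (blocks 2+3 and 4+5 under the standard ABAB design) and the two pair
#' scores are averaged. Excluded sessions keep their pair diagnostics but
#' carry `score = NA` and the triggered exclusion rule.
#'
#' `mean_latency_ms` is each respondent's average latency over scored-block
#' trials after the hard cutoff and warm-up removal but before any tail
#' recoding, the quantity used by the speed-stability analyses.
#'
#' @param trials A trial tibble (see [read_trials()]).
#' @param config A [biat_config()].
#' @param transformation Optional override of `config$transformation`.
#' @return A score tibble (one row per session x focal polarity) with
#'   columns `session_id`, `focal_polarity`, `transformation`,
#'   `pair1_score`, `pair2_score`, `score`, `excluded`, `exclusion_reason`,
#'   `n_trials_used`, `mean_latency_ms`, plus pre-treatment `fast_fraction`
#'   and `error_rate`. The per-stage trial accounting is attached as
#'   attribute `"manifest"` (see [run_manifest()]).
#' @export
#' @examples
#' sim <- simulate_biat(biat_sim_params(n_subjects = 20), seed = 7)
#' scores <- score_sessions(sim$trials)
#' run_manifest(scores)
score_sessions <- function(trials, config = biat_config(),
                           transformation = NULL) {
  if (!is.null(transformation)) {
    config$transformation <- rlang::arg_match0(
      transformation, c("D", "latency_diff", "log_diff", "reciprocal_diff"))
  }
  prep <- preprocess_trials(trials, config)
  pairs <- block_pairs(config$pairing)
  pair_of_block <- integer(6)
  for (p in seq_along(pairs)) pair_of_block[pairs[[p]]] <- p

  scored <- prep$trials |>
    dplyr::mutate(pair = pair_of_block[.data$block_index])

  pair_rows <- scored |>
    dplyr::filter(.data$pair > 0) |>
    dplyr::group_by(.data$session_id, .data$focal_polarity, .data$pair) |>
    dplyr::summarise(
      value = {
        lat1 <- .data$latency_ms[.data$condition == "condition1"]
        lat2 <- .data$latency_ms[.data$condition == "condition2"]
        if (length(lat1) < 2 || length(lat2) < 2) NA_real_
        else tryCatch(
          pair_score(lat1, lat2, config$transformation, config$sd_denominator),
          error = function(e) NA_real_
        )
      },
      n_used = dplyr::n(),
      .groups = "drop"
    )

  wide <- pair_rows |>
    tidyr::pivot_wider(names_from = "pair",
                       values_from = c("value", "n_used"),
                       names_sep = "") |>
    dplyr::rename(pair1_score = "value1", pair2_score = "value2")
  if (!"pair2_score" %in% names(wide)) wide$pair2_score <- NA_real_
  if (!"n_used2" %in% names(wide)) wide$n_used2 <- NA_integer_

  out <- wide |>
    dplyr::mutate(
      transformation = config$transformation,
      score = (.data$pair1_score + .data$pair2_score) / 2,
      n_trials_used = dplyr::coalesce(.data$n_used1, 0L) +
        dplyr::coalesce(.data$n_used2, 0L)
    ) |>
    dplyr::left_join(prep$respondents,
                     by = c("session_id", "focal_polarity")) |>
    dplyr::mutate(
      excluded = exclusion_flag(.data$fast_fraction, .data$error_rate, config),
      exclusion_reason = exclusion_reason(.data$fast_fraction,
                                          .data$error_rate, config),
      # a pair left without >= 2 trials per condition (or with constant
      # latencies, so an undefined D) yields a flagged NA, not an abort
      exclusion_reason = dplyr::if_else(
        !.data$excluded & is.na(.data$score), "degenerate_pair",
        .data$exclusion_reason),
      score = dplyr::if_else(.data$excluded, NA_real_, .data$score)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "session_id", "focal_polarity", "transformation",
      "pair1_score", "pair2_score", "score", "excluded", "exclusion_reason",
      "n_trials_used", "mean_latency_ms", "fast_fraction", "error_rate"
    ))) |>
    dplyr::arrange(.data$session_id, .data$focal_polarity)

  attr(out, "manifest") <- list(
    config = config,
    counts = prep$counts,
    n_sessions = nrow(out),
    n_excluded = sum(out$excluded)
  )
  out
}

exclusion_flag <- function(fast_fraction, error_rate, config) {
  flag <- rep(FALSE, length(fast_fraction))
  if (!is.null(config$fast_exclusion_threshold)) {
    flag <- flag | fast_fraction > config$fast_exclusion_threshold
  }
  if (!is.null(config$error_exclusion_threshold)) {
    flag <- flag | error_rate > config$error_exclusion_threshold
  }
  flag
}

exclusion_reason <- function(fast_fraction, error_rate, config) {
  reason <- rep(NA_character_, length(fast_fraction))
  if (!is.null(config$error_exclusion_threshold)) {
    reason[error_rate > config$error_exclusion_threshold] <- "error"
  }
  if (!is.null(config$fast_exclusion_threshold)) {
    reason[fast_fraction > config$fast_exclusion_threshold] <- "fast"
  }
  reason
}

#' Per-stage trial accounting of a scoring run
#'
#' Every trial handed to [score_sessions()] is accounted for exactly once:
#' set aside with the practice block, removed at one of the pipeline stages,
#' or retained for scoring. Recodes are reported separately (they do not
#' change trial counts).
#'
#' @param scores A score tibble from [score_sessions()].
#' @return A list with `config`, `counts` (stage tibble), `n_sessions`,
#'   `n_excluded`.
#' @export
run_manifest <- function(scores) {
  manifest <- attr(scores, "manifest")
  if (is.null(manifest)) {
    abort("`scores` carries no manifest; was it produced by score_sessions()?")
  }
  manifest
}
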