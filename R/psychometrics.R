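#' Average correlations via Fisher's z transformation
#'
#' Correlations are averaged on the variance-stabilized scale:
#' `tanh(mean(atanh(r)))`. The result always lies between the smallest and
#' largest input and equals the plain mean to first order for small r.
#'
#' @param rs Correlations, each strictly inside (-1, 1); `NA`s dropped.
#' @return A single averaged correlation.
#' @export
#' @examples
#' fisher_z_average(c(0, 0.8))  # exactly 0.5
fisher_z_average <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) return(NA_real_)
  if (any(abs(rs) >= 1)) {
    abort("fisher_z_average requires |r| < 1 for every correlation.")
  }
  tanh(mean(atanh(rs)))
}

#' Split-half internal consistency from the two block pairs
#'
#' The BIAT yields two independent half-scores, one per pair of response
#' blocks. Internal consistency is the Pearson correlation between them;
#' Cronbach's alpha over the two halves and its Spearman-Brown counterpart
#' `2r / (1 + r)` are co-reported (the two coincide when the halves have
#' equal variance).
#'
#' @param scores A score tibble with the two half-scores, or any data frame.
#' @param half1,half2 Columns holding the half-scores (tidy-eval; default
#'   `pair1_score` and `pair2_score`).
#' @return A one-row tibble: `n`, `half_r`, `alpha`, `spearman_brown`.
#' @export
#' @examples
#' sim <- simulate_biat(biat_sim_params(n_subjects = 50), seed = 3)
#' score_sessions(sim$trials) |> split_half_consistency()
split_half_consistency <- function(scores, half1 = pair1_score,
                                   half2 = pair2_score) {
  h1 <- dplyr::pull(scores, {{ half1 }})
  h2 <- dplyr::pull(scores, {{ half2 }})
  ok <- stats::complete.cases(h1, h2)
  h1 <- h1[ok]
  h2 <- h2[ok]
  if (length(h1) < 3) {
    abort("split-half consistency needs at least 3 complete pairs.")
  }
  v1 <- var(h1)
  v2 <- var(h2)
  if (v1 == 0 || v2 == 0) {
    abort("split-half consistency is undefined: a half has zero variance.")
  }
  r <- cor(h1, h2)
  vt <- var(h1 + h2)
  tibble::tibble(
    n = length(h1),
    half_r = r,
    alpha = 2 * (1 - (v1 + v2) / vt),
    spearman_brown = 2 * r / (1 + r)
  )
}

#' Cohen's d of the mean score against zero
#'
#' The magnitude of the main effect: `mean(score) / sd(score)` over
#' non-missing scores.
#'
#' @param scores A score tibble (or data frame).
#' @param score Column holding the scores (tidy-eval, default `score`).
#' @return A single number.
#' @export
main_effect_d <- function(scores, score = score) {
  x <- dplyr::pull(scores, {{ score }})
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("main_effect_d needs at least 2 scores.")
  s <- sd(x)
  if (s == 0) abort("main_effect_d is undefined: scores have zero variance.")
  mean(x) / s
}

#' Correlations of scores with criterion covariates
#'
#' Pearson correlations between the session score and each covariate, with
#' listwise deletion per covariate. Covariates are assumed pre-coded so a
#' positive correlation is the predicted direction; dichotomous covariates
#' enter as 0/1 (point-biserial). Covariates with fewer than 3 complete
#' pairs are reported with a missing `r` rather than failing the batch. The
#' Fisher-z average over the reported correlations is attached as attribute
#' `"fisher_z_average"`.
#'
#' @param scores A score tibble with `session_id` and `score`.
#' @param covariates A data frame with `session_id` and one column per
#'   covariate.
#' @return A tibble with one row per covariate: `covariate`, `n`, `r`.
#' @export
criterion_correlations <- function(scores, covariates) {
  if (!"session_id" %in% names(covariates)) {
    abort("`covariates` must contain a session_id column.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(scores, "session_id", "score"),
    covariates, by = "session_id"
  )
  covariate_names <- setdiff(names(covariates), "session_id")
  rows <- purrr::map(covariate_names, function(nm) {
    x <- joined$score
    y <- joined[[nm]]
    if (is.factor(y) || is.character(y)) {
      y <- as.numeric(factor(y)) - 1
    }
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    r <- if (n >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      cor(x[ok], y[ok])
    } else NA_real_
    tibble::tibble(covariate = nm, n = n, r = r)
  })
  out <- purrr::list_rbind(rows)
  # perfect correlations have no finite z; they are left out of the average
  averageable <- out$r[!is.na(out$r) & abs(out$r) < 1]
  attr(out, "fisher_z_average") <- if (length(averageable) > 0) {
    fisher_z_average(averageable)
  } else NA_real_
  out
}

#' Correlations of scores with average response speed
#'
#' The extraneous-influence criterion: the correlation of the score with the
#' respondent's average latency, average log latency, and average
#' reciprocal latency. A transformation resistant to the speed confound
#' shows small absolute correlations; comparison across transformations
#' ranks by absolute value.
#'
#' @param scores A score tibble with `session_id` and `score`.
#' @param latency_summary Per-respondent latency summary from
#'   [respondent_latency_summary()], or `NULL` to use the `mean_latency_ms`
#'   column of `scores` (in which case only the raw-latency correlation is
#'   exact and the log/reciprocal columns are computed from it).
#' @return A tibble with one row per speed indicator: `indicator`, `n`, `r`.
#' @export
extraneous_influence <- function(scores, latency_summary = NULL) {
  if (is.null(latency_summary)) {
    if (!"mean_latency_ms" %in% names(scores)) {
      abort("`scores` needs mean_latency_ms or supply `latency_summary`.")
    }
    joined <- scores |>
      dplyr::transmute(
        .data$score,
        mean_latency = .data$mean_latency_ms,
        mean_log_latency = log(.data$mean_latency_ms),
        mean_reciprocal = 1000 / .data$mean_latency_ms
      )
  } else {
    by <- intersect(c("session_id", "focal_polarity"),
                    intersect(names(scores), names(latency_summary)))
    joined <- dplyr::inner_join(
      dplyr::select(scores, dplyr::all_of(c(by, "score"))),
      latency_summary, by = by
    )
  }
  indicators <- c("mean_latency", "mean_log_latency", "mean_reciprocal")
  purrr::list_rbind(purrr::map(indicators, function(nm) {
    ok <- stats::complete.cases(joined$score, joined[[nm]])
    r <- if (sum(ok) >= 3) cor(joined$score[ok], joined[[nm]][ok]) else NA_real_
    tibble::tibble(indicator = nm, n = sum(ok), r = r)
  }))
}

#' Per-respondent average-speed indicators
#'
#' Averages each respondent's scored-block latencies (after the hard slow
#' cutoff and warm-up removal, before any tail recoding) on the raw, log,
#' and reciprocal scales.
#'
#' @param trials A trial tibble.
#' @param config A [biat_config()] supplying the cutoff and warm-up rule.
#' @return A tibble: `session_id`, `focal_polarity`, `n_trials`,
#'   `mean_latency`, `mean_log_latency`, `mean_reciprocal`.
#' @export
respondent_latency_summary <- function(trials, config = biat_config()) {
  scored <- trials[trials$block_index >= 2, , drop = FALSE]
  scored <- filter_slow_trials(scored, config$slow_hard_cutoff_ms)
  if (config$remove_warmup) scored <- remove_warmup_trials(scored)
  scored |>
    dplyr::group_by(.data$session_id, .data$focal_polarity) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_latency = mean(.data$latency_ms),
      mean_log_latency = mean(log(.data$latency_ms)),
      mean_reciprocal = mean(1000 / .data$latency_ms),
      .groups = "drop"
    )
}

#' Latency operating characteristic
#'
#' Ranks respondents by average latency, cuts them into `n_deciles`
#' near-equal bins (fastest first), and standardizes each bin's mean score
#' by the full-sample score SD, giving a per-decile Cohen's d. A flat
#' profile indicates a score insensitive to overall response speed. Bin
#' sizes differ by at most one; when n is not divisible by the bin count the
#' larger bins sit at the fast end, and ties in latency are broken by
#' session id so the construction is deterministic.
#'
#' @param scores A score tibble with `score` and `mean_latency_ms` (or pass
#'   `latency` to name another column).
#' @param n_deciles Number of speed bins (default 10).
#' @param latency Column holding the average latency (tidy-eval).
#' @return A tibble of class `biat_loc`: `decile`, `n`, `mean_latency`,
#'   `mean_score`, `d` (bin mean over full-sample SD).
#' @export
#' @examples
#' sim <- simulate_biat(biat_sim_params(n_subjects = 80), seed = 11)
#' score_sessions(sim$trials) |> latency_operating_characteristic()
latency_operating_characteristic <- function(scores, n_deciles = 10,
                                             latency = mean_latency_ms) {
  lat <- dplyr::pull(scores, {{ latency }})
  sc <- scores$score
  id <- scores$session_id
  ok <- stats::complete.cases(lat, sc)
  lat <- lat[ok]; sc <- sc[ok]; id <- id[ok]
  n <- length(sc)
  if (n < n_deciles) {
    abort(sprintf("need at least %d respondents for %d bins (got %d).",
                  n_deciles, n_deciles, n))
  }
  overall_sd <- sd(sc)
  if (overall_sd == 0) {
    abort("latency operating characteristic is degenerate: constant scores.")
  }
  ord <- order(lat, id)
  sizes <- loc_bin_sizes(n, n_deciles)
  bin <- rep(seq_len(n_deciles), times = sizes)
  out <- tibble::tibble(
    decile = bin,
    latency = lat[ord],
    score = sc[ord]
  ) |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_latency = mean(.data$latency),
      mean_score = mean(.data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(d = .data$mean_score / overall_sd)
  class(out) <- c("biat_loc", class(out))
  attr(out, "overall_sd") <- overall_sd
  out
}

# Near-equal bin sizes summing to n; the remainder goes one-per-bin to the
# fastest bins. 23 into 10 -> 3,3,3,2,2,2,2,2,2,2.
loc_bin_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Stability of a score across the speed distribution
#'
#' Regresses the score on the linear, quadratic, cubic, and quartic trends
#' of each respondent's average latency (centered raw powers) and reports
#' the multiple R with the overall F-test p value. A small multiple R means
#' the score is stable across variations in overall response speed. The
#' statistic is invariant to affine rescaling of the latency predictor.
#'
#' @param scores A score tibble with `score` and `mean_latency_ms` (or name
#'   another column via `latency`).
#' @param latency Column holding the average latency (tidy-eval).
#' @return A one-row tibble: `n`, `multiple_R`, `p`.
#' @export
stability_regression <- function(scores, latency = mean_latency_ms) {
  lat <- dplyr::pull(scores, {{ latency }})
  sc <- scores$score
  ok <- stats::complete.cases(lat, sc)
  lat <- lat[ok]; sc <- sc[ok]
  if (length(sc) <= 5) {
    abort("stability regression needs more than 5 respondents.")
  }
  x <- lat - mean(lat)
  if (sd(x) == 0) abort("stability regression is degenerate: constant latency.")
  fit <- lm(sc ~ x + I(x^2) + I(x^3) + I(x^4))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else {
    pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]], lower.tail = FALSE)
  }
  tibble::tibble(
    n = length(sc),
    multiple_R = sqrt(max(sm$r.squared, 0)),
    p = p
  )
}
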