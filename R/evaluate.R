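#' Psychometric evaluation of one score set
#'
#' Runs the full evaluation battery on the output of [score_sessions()]:
#' main-effect Cohen's d, split-half internal consistency (half correlation
#' and two-half alpha), criterion correlations with Fisher-z average (when
#' covariates are supplied), the three extraneous-influence correlations
#' with average speed, the latency operating characteristic, and the
#' quartic stability regression. Sessions flagged for exclusion carry
#' missing scores and drop out of every statistic.
#'
#' @param scores A score tibble from [score_sessions()] (one transformation,
#'   one focal polarity; filter first if needed).
#' @param covariates Optional data frame with `session_id` plus covariate
#'   columns, pre-coded so positive correlations are the predicted
#'   direction.
#' @param n_deciles Bins for the latency operating characteristic.
#' @return An object of class `biat_evaluation`; see [tidy.biat_evaluation()]
#'   and [glance.biat_evaluation()] for tabular views.
#' @export
#' @examples
#' sim <- simulate_biat(biat_sim_params(n_subjects = 60), seed = 2)
#' scores <- score_sessions(sim$trials)
#' covars <- dplyr::select(sim$truth, session_id, group)
#' evaluate_scores(scores, covars)
evaluate_scores <- function(scores, covariates = NULL, n_deciles = 10) {
  usable <- scores |> dplyr::filter(!.data$excluded, !is.na(.data$score))
  result <- list(
    transformation = scores$transformation[1],
    n_scored = nrow(scores),
    n_retained = nrow(usable),
    n_excluded = sum(scores$excluded, na.rm = TRUE)
  )
  result$main_effect_d <- try_or_na(main_effect_d(usable))
  result$consistency <- try_or_null(split_half_consistency(usable))
  result$criterion <- if (!is.null(covariates)) {
    try_or_null(criterion_correlations(usable, covariates))
  }
  result$extraneous <- try_or_null(extraneous_influence(usable))
  result$loc <- try_or_null(
    latency_operating_characteristic(usable, n_deciles = n_deciles))
  result$stability <- try_or_null(stability_regression(usable))
  structure(result, class = "biat_evaluation")
}

try_or_na <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' @export
print.biat_evaluation <- function(x, ...) {
  cat(sprintf("<biat_evaluation> transformation %s, %d of %d sessions retained\n",
              x$transformation, x$n_retained, x$n_scored))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an evaluation into one row per criterion
#'
#' @param x A `biat_evaluation`.
#' @param ... Unused.
#' @return A tibble with `criterion`, `statistic`, `value`.
#' @exportS3Method generics::tidy
tidy.biat_evaluation <- function(x, ...) {
  rows <- list(
    tibble::tibble(criterion = "main_effect", statistic = "cohens_d",
                   value = x$main_effect_d)
  )
  if (!is.null(x$consistency)) {
    rows <- c(rows, list(tibble::tibble(
      criterion = "internal_consistency",
      statistic = c("half_r", "alpha"),
      value = c(x$consistency$half_r, x$consistency$alpha)
    )))
  }
  if (!is.null(x$criterion)) {
    rows <- c(rows, list(
      tibble::tibble(criterion = "criterion_correlation",
                     statistic = x$criterion$covariate,
                     value = x$criterion$r),
      tibble::tibble(criterion = "criterion_correlation",
                     statistic = "fisher_z_average",
                     value = attr(x$criterion, "fisher_z_average"))
    ))
  }
  if (!is.null(x$extraneous)) {
    rows <- c(rows, list(tibble::tibble(
      criterion = "extraneous_influence",
      statistic = x$extraneous$indicator,
      value = x$extraneous$r
    )))
  }
  if (!is.null(x$loc)) {
    rows <- c(rows, list(tibble::tibble(
      criterion = "loc", statistic = "decile_d_range",
      value = max(x$loc$d) - min(x$loc$d)
    )))
  }
  if (!is.null(x$stability)) {
    rows <- c(rows, list(tibble::tibble(
      criterion = "stability",
      statistic = c("multiple_R", "p"),
      value = c(x$stability$multiple_R, x$stability$p)
    )))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of an evaluation
#'
#' @param x A `biat_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with the headline statistic per criterion.
#' @exportS3Method generics::glance
glance.biat_evaluation <- function(x, ...) {
  tibble::tibble(
    transformation = x$transformation,
    n_retained = x$n_retained,
    n_excluded = x$n_excluded,
    main_effect_d = x$main_effect_d,
    half_r = if (!is.null(x$consistency)) x$consistency$half_r else NA_real_,
    alpha = if (!is.null(x$consistency)) x$consistency$alpha else NA_real_,
    criterion_r = if (!is.null(x$criterion)) {
      attr(x$criterion, "fisher_z_average")
    } else NA_real_,
    extraneous_abs_r = if (!is.null(x$extraneous)) {
      fisher_z_average(abs(x$extraneous$r))
    } else NA_real_,
    loc_d_range = if (!is.null(x$loc)) max(x$loc$d) - min(x$loc$d) else NA_real_,
    stability_R = if (!is.null(x$stability)) x$stability$multiple_R else NA_real_
  )
}

#' Evaluate a grid of treatment configurations
#'
#' The comparison harness: scores the same trial table under every supplied
#' configuration (optionally crossed with transformations and split by
#' focal polarity) and evaluates each cell, returning one summary row per
#' cell. Per-cell failures (for instance a degenerate cell after aggressive
#' deletion) are flagged in the `error` column rather than aborting the
#' grid. Deterministic for a given trial table.
#'
#' @param trials A trial tibble.
#' @param configs A named list of [biat_config()] objects (names label the
#'   rows); a single config is accepted.
#' @param transformations Transformations to cross with each config;
#'   `NULL` uses each config's own.
#' @param covariates Optional covariate data frame (see
#'   [criterion_correlations()]).
#' @param by_polarity Evaluate each focal polarity separately (default).
#' @return A tibble with one row per config x transformation x polarity:
#'   the glance columns plus `config`, `focal_polarity`, `error`.
#' @export
compare_configurations <- function(trials, configs,
                                   transformations = NULL,
                                   covariates = NULL,
                                   by_polarity = TRUE) {
  if (inherits(configs, "biat_config")) configs <- list(default = configs)
  if (length(configs) == 0) abort("`configs` must contain at least one config.")
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  polarities <- if (by_polarity) unique(trials$focal_polarity) else "all"

  grid <- tidyr::expand_grid(
    config = names(configs),
    transformation = transformations %||% NA_character_,
    focal_polarity = polarities
  )

  rows <- purrr::pmap(grid, function(config, transformation, focal_polarity) {
    cfg <- configs[[config]]
    trans <- if (is.na(transformation)) NULL else transformation
    cell_trials <- if (identical(focal_polarity, "all")) trials else {
      trials[trials$focal_polarity == focal_polarity, , drop = FALSE]
    }
    res <- tryCatch({
      scores <- score_sessions(cell_trials, cfg, transformation = trans)
      ev <- evaluate_scores(scores, covariates)
      dplyr::mutate(glance(ev), error = NA_character_)
    }, error = function(e) {
      tibble::tibble(transformation = transformation %||% cfg$transformation,
                     error = conditionMessage(e))
    })
    dplyr::mutate(res, config = config, focal_polarity = focal_polarity,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Rank transformations or treatments per evaluation criterion
#'
#' Orders the rows of a [compare_configurations()] table within each
#' criterion so that better performance comes first: larger values for
#' effect-size, consistency, and criterion-correlation columns; smaller
#' absolute values for the extraneous-influence, LOC-range, and stability
#' columns.
#'
#' @param comparison Output of [compare_configurations()].
#' @return A long tibble: `criterion`, `config`, `transformation`,
#'   `focal_polarity`, `value`, `rank` (1 = best).
#' @export
rank_configurations <- function(comparison) {
  higher_better <- c("main_effect_d", "half_r", "alpha", "criterion_r")
  lower_abs_better <- c("extraneous_abs_r", "loc_d_range", "stability_R")
  long <- comparison |>
    dplyr::filter(is.na(.data$error)) |>
    tidyr::pivot_longer(
      dplyr::any_of(c(higher_better, lower_abs_better)),
      names_to = "criterion", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  long |>
    dplyr::group_by(.data$criterion) |>
    dplyr::mutate(
      rank = dplyr::min_rank(dplyr::if_else(
        .data$criterion %in% higher_better, -.data$value, abs(.data$value)))
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$criterion, .data$rank) |>
    dplyr::select(dplyr::any_of(c("criterion", "config", "transformation",
                                  "focal_polarity", "value", "rank")))
}
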