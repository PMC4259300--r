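#' Data-treatment configuration for BIAT scoring
#'
#' Bundles every data-treatment choice the scoring pipeline makes. The
#' defaults implement the recommended practice: remove trials slower than
#' 10 s, drop the 4 warm-up trials of each response block, retain error
#' trials as-is, recode latencies below 400 ms to 400 and above 2000 ms to
#' 2000, score with the D transformation pair-by-pair, and exclude tasks with
#' more than 10% of responses faster than 300 ms. Every alternative treatment
#' studied for the BIAT (tail deletion at other boundaries, error-trial
#' removal, error-rate exclusions, the competitor transformations) is
#' reachable by overriding fields.
#'
#' All boundary and threshold comparisons are strict: a latency exactly at a
#' recode boundary is untouched, a fast fraction exactly at the threshold is
#' kept.
#'
#' @param remove_warmup Drop trials with `trial_index < 4` in scored blocks.
#' @param slow_hard_cutoff_ms Trials strictly above this latency are always
#'   removed (inattention); default 10000 ms.
#' @param fast_boundary_ms,fast_mode Fast-tail treatment: trials strictly
#'   below the boundary are deleted or recoded to it. `NULL` boundary
#'   disables the treatment.
#' @param slow_boundary_ms,slow_mode Slow-tail treatment, analogous.
#' @param error_trials `"retain"` keeps error trials (latency already runs to
#'   the correct response); `"remove"` drops them.
#' @param fast_exclusion_threshold Exclude a task when its fraction of trials
#'   faster than `fast_definition_ms` strictly exceeds this; `NULL` disables.
#' @param fast_definition_ms Latency defining a "fast" response (default 300).
#' @param error_exclusion_threshold Exclude a task when its error rate
#'   strictly exceeds this (e.g. 0.30 or 0.40); `NULL` (default) disables.
#' @param transformation Scoring transformation: `"D"`, `"latency_diff"`,
#'   `"log_diff"`, or `"reciprocal_diff"`.
#' @param sd_denominator Denominator of the pooled standard deviation in D:
#'   `"n-1"` (sample SD, default) or `"n"`.
#' @param pairing `"consecutive"` pairs blocks (2,3) and (4,5), matching the
#'   standard alternating (ABAB) administration; `"outer"` pairs (2,5) and
#'   (3,4), for administrations where consecutive blocks share a category
#'   pairing (AABB), so each pair still spans both conditions.
#' @return An object of class `biat_config` (a named list).
#' @export
#' @examples
#' biat_config()
#' biat_config(error_trials = "remove", slow_boundary_ms = 3000,
#'             slow_mode = "delete")
biat_config <- function(remove_warmup = TRUE,
                        slow_hard_cutoff_ms = 10000,
                        fast_boundary_ms = 400,
                        fast_mode = c("recode", "delete"),
                        slow_boundary_ms = 2000,
                        slow_mode = c("recode", "delete"),
                        error_trials = c("retain", "remove"),
                        fast_exclusion_threshold = 0.10,
                        fast_definition_ms = 300,
                        error_exclusion_threshold = NULL,
                        transformation = c("D", "latency_diff", "log_diff",
                                           "reciprocal_diff"),
                        sd_denominator = c("n-1", "n"),
                        pairing = c("consecutive", "outer")) {
  config <- list(
    remove_warmup = isTRUE(remove_warmup),
    slow_hard_cutoff_ms = slow_hard_cutoff_ms,
    fast_boundary_ms = fast_boundary_ms,
    fast_mode = rlang::arg_match(fast_mode),
    slow_boundary_ms = slow_boundary_ms,
    slow_mode = rlang::arg_match(slow_mode),
    error_trials = rlang::arg_match(error_trials),
    fast_exclusion_threshold = fast_exclusion_threshold,
    fast_definition_ms = fast_definition_ms,
    error_exclusion_threshold = error_exclusion_threshold,
    transformation = rlang::arg_match(transformation),
    sd_denominator = rlang::arg_match(sd_denominator),
    pairing = rlang::arg_match(pairing)
  )
  validate_biat_config(config)
  structure(config, class = "biat_config")
}

validate_biat_config <- function(config) {
  if (!is.null(config$slow_hard_cutoff_ms) && config$slow_hard_cutoff_ms <= 0) {
    abort("`slow_hard_cutoff_ms` must be positive.")
  }
  if (!is.null(config$fast_boundary_ms) && config$fast_boundary_ms <= 0) {
    abort("`fast_boundary_ms` must be positive.")
  }
  if (!is.null(config$slow_boundary_ms) && config$slow_boundary_ms <= 0) {
    abort("`slow_boundary_ms` must be positive.")
  }
  if (!is.null(config$fast_boundary_ms) && !is.null(config$slow_boundary_ms) &&
      config$fast_boundary_ms >= config$slow_boundary_ms) {
    abort("`fast_boundary_ms` must be below `slow_boundary_ms`.")
  }
  for (field in c("fast_exclusion_threshold", "error_exclusion_threshold")) {
    thr <- config[[field]]
    if (!is.null(thr) && (thr <= 0 || thr > 1)) {
      abort(sprintf("`%s` must lie in (0, 1].", field))
    }
  }
  invisible(config)
}

#' @export
print.biat_config <- function(x, ...) {
  cat("<biat_config>\n")
  fmt <- function(v) if (is.null(v)) "none" else as.character(v)
  cat(sprintf("  transformation:      %s (SD denominator %s)\n",
              x$transformation, x$sd_denominator))
  cat(sprintf("  hard slow cutoff:    > %s ms removed\n",
              fmt(x$slow_hard_cutoff_ms)))
  cat(sprintf("  warm-up trials:      %s\n",
              if (x$remove_warmup) "removed (first 4 per block)" else "retained"))
  cat(sprintf("  error trials:        %s\n", x$error_trials))
  cat(sprintf("  fast tail:           %s at %s ms\n", x$fast_mode,
              fmt(x$fast_boundary_ms)))
  cat(sprintf("  slow tail:           %s at %s ms\n", x$slow_mode,
              fmt(x$slow_boundary_ms)))
  cat(sprintf("  fast exclusion:      > %s of trials < %s ms\n",
              fmt(x$fast_exclusion_threshold), fmt(x$fast_definition_ms)))
  cat(sprintf("  error exclusion:     %s\n",
              if (is.null(x$error_exclusion_threshold)) "none"
              else sprintf("> %s error rate", x$error_exclusion_threshold)))
  cat(sprintf("  block pairing:       %s\n", x$pairing))
  invisible(x)
}

#' Read or write a scoring configuration as YAML
#'
#' A `biat_config` serializes to a flat YAML mapping so that a run's
#' effective configuration can be stored alongside its outputs and replayed.
#' Unset (`NULL`) fields are written as YAML nulls.
#'
#' @param path File path.
#' @param config A `biat_config`.
#' @return `read_biat_config()` returns a `biat_config`;
#'   `write_biat_config()` returns `path` invisibly.
#' @export
read_biat_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file does not exist: %s", path))
  }
  values <- yaml::read_yaml(path)
  known <- names(formals(biat_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(biat_config, values)
}

#' @rdname read_biat_config
#' @export
write_biat_config <- function(config, path) {
  stopifnot(inherits(config, "biat_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
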