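#' Plot a latency operating characteristic
#'
#' Lines of standardized decile means across the response-speed
#' distribution. A flat line indicates a score resistant to the speed
#' confound.
#'
#' @param object A `biat_loc` from [latency_operating_characteristic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.biat_loc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$decile, y = .data$d)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$decile) +
    ggplot2::labs(
      x = "Average-latency decile (fastest to slowest)",
      y = "Standardized mean score (Cohen's d)",
      title = "Latency operating characteristic"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overlay latency operating characteristics of several transformations
#'
#' Computes and plots the LOC of each transformation on the same trial
#' table, the standard visual comparison of speed stability.
#'
#' @param trials A trial tibble.
#' @param transformations Character vector of transformations to compare.
#' @param config Base [biat_config()]; its transformation field is
#'   overridden per curve.
#' @param n_deciles Number of speed bins.
#' @return A ggplot object; the underlying tibble is in `$data`.
#' @export
plot_loc_comparison <- function(trials,
                                transformations = c("D", "latency_diff",
                                                    "log_diff",
                                                    "reciprocal_diff"),
                                config = biat_config(),
                                n_deciles = 10) {
  curves <- purrr::map(transformations, function(trans) {
    scores <- score_sessions(trials, config, transformation = trans)
    usable <- scores |> dplyr::filter(!.data$excluded, !is.na(.data$score))
    loc <- latency_operating_characteristic(usable, n_deciles = n_deciles)
    dplyr::mutate(tibble::as_tibble(loc), transformation = trans)
  })
  data <- purrr::list_rbind(curves)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$decile, y = .data$d,
                                     colour = .data$transformation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(data$decile)) +
    ggplot2::labs(
      x = "Average-latency decile (fastest to slowest)",
      y = "Standardized mean score (Cohen's d)",
      colour = "Transformation",
      title = "Latency operating characteristics by transformation"
    ) +
    ggplot2::theme_minimal()
}
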