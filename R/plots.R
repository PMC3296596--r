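# autoplot() methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot screening flags by improvement topic
#'
#' @param object A `dqip_flags` tibble from [screen_cohort()].
#' @param ... Unused.
#' @return A ggplot: assessable flag counts per topic, filled by domain.
#' @export
autoplot.dqip_flags <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$assessable) |>
    count(.data$domain, .data$topic_id)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$topic_id, .data$n), y = .data$n,
    fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "improvement topic", y = "flags",
                  title = "Screening flags by topic") +
    ggplot2::theme_minimal()
}

#' Plot RAM classification outcomes
#'
#' @param object A `dqip_ram` tibble from [ram_classify()].
#' @param ... Unused.
#' @return A ggplot: item counts per acceptance label and domain.
#' @export
autoplot.dqip_ram <- function(object, ...) {
  df <- as_tibble(object) |> count(.data$domain, .data$accepted_as)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accepted_as, y = .data$n,
                                   fill = .data$domain)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "acceptance label", y = "items",
                  title = "Panel classification of candidate criteria") +
    ggplot2::theme_minimal()
}

#' Plot Delphi topic medians and tiers
#'
#' @param object A `dqip_delphi` tibble from [delphi_classify()].
#' @param ... Unused.
#' @return A ggplot: per-topic median ratings coloured by priority tier.
#' @export
autoplot.dqip_delphi <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$topic_id, .data$median), y = .data$median,
    colour = .data$priority)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(7, 8), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "topic", y = "second-round median",
                  title = "Delphi priority ratings") +
    ggplot2::theme_minimal()
}
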