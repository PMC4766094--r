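# ggplot2 visualisations of the result objects.

#' Plot state occupancy over cycles
#'
#' Stacked-area chart of cohort occupancy by state, summed over strata.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  dat <- object$occupancy |>
    group_by(.data$cycle, .data$state) |>
    summarise(occupancy = sum(.data$occupancy), .groups = "drop") |>
    mutate(state = factor(.data$state, levels = rev(.states)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                    fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "cycle (years)", y = "persons",
                  title = paste("Cohort occupancy:", object$strategy$name),
                  fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot the PSA ICER distribution
#'
#' Histogram of iteration ICERs with the cumulative frequency curve
#' overlaid on a secondary axis.
#'
#' @param object A `psa_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, bins = 30, ...) {
  v <- object$iterations |> filter(!is.na(.data$icer))
  rng <- max(v$icer) - min(v$icer)
  scale_f <- nrow(v) / max(1, bins) * 3
  ggplot2::ggplot(v, ggplot2::aes(x = .data$icer)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "white") +
    ggplot2::geom_step(data = object$curve,
                       ggplot2::aes(x = .data$icer, y = .data$cum_freq * scale_f),
                       colour = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "iterations",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "cumulative frequency")) +
    ggplot2::labs(x = "ICER (EUR per life-year gained)",
                  title = "Probabilistic sensitivity analysis of the ICER") +
    ggplot2::theme_minimal()
}

#' Plot budget-impact offset distributions
#'
#' Boxplots of the sampled cost offsets per disease and horizon, in
#' millions of euros.
#'
#' @param object A `bia_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bia_result <- function(object, ...) {
  dat <- object$iterations |>
    select(dplyr::starts_with("offset_")) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "quantity",
                        values_to = "offset") |>
    tidyr::extract("quantity", c("disease", "horizon"),
                   "offset_(.*)_(\\d+)y", convert = TRUE)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$horizon),
                                    y = .data$offset / 1e6,
                                    fill = .data$disease)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "horizon (years)", y = "cost offset (EUR million)",
                  title = "Chronic-disease cost offsets", fill = "disease") +
    ggplot2::theme_minimal()
}
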