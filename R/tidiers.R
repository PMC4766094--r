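# broom-style tidiers for the result objects.

#' Tidy a cost-effectiveness result
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return One row per arm: `arm`, `cost`, `life_years`.
#' @export
tidy.cea_result <- function(x, ...) x$arms

#' One-row summary of a cost-effectiveness result
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return Tibble with `delta_cost`, `delta_ly`, `icer`, `label`.
#' @export
glance.cea_result <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_ly = x$delta_ly,
         icer = x$icer, label = x$label)
}

#' Tidy PSA iterations
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return The per-iteration tibble (parameter draws and outputs).
#' @export
tidy.psa_result <- function(x, ...) x$iterations

#' One-row PSA summary
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return The summary tibble (recomputable from the iterations).
#' @export
glance.psa_result <- function(x, ...) x$summary

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return The tidy occupancy tibble (`stratum`, `cycle`, `state`,
#'   `occupancy`).
#' @export
tidy.cohort_trace <- function(x, ...) x$occupancy

#' One-row trace summary
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble with cohort size, recorded cycles, undiscounted
#'   life-years and total deaths by cause.
#' @export
glance.cohort_trace <- function(x, ...) {
  d <- colSums(apply(x$arrays$deaths, c(1, 2), sum))
  tibble(size = x$cohort$size, cycles = x$n_cycles,
         life_years = life_years(x, discount_spec(rate = 0)),
         deaths_lung_cancer = d[["lung_cancer"]], deaths_copd = d[["copd"]],
         deaths_cvd = d[["cvd"]], deaths_other = d[["other"]])
}

#' Tidy budget-impact iterations
#'
#' @param x A `bia_result`.
#' @param ... Unused.
#' @return The per-iteration tibble.
#' @export
tidy.bia_result <- function(x, ...) x$iterations

#' Budget-impact summary
#'
#' @param x A `bia_result`.
#' @param ... Unused.
#' @return The summary tibble (one row per budget quantity).
#' @export
glance.bia_result <- function(x, ...) x$summary
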