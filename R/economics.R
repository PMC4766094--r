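# Costing of traces and incremental cost-effectiveness ratios.

#' Inflate a 2009 cost
#'
#' @param base Cost in base-year euros.
#' @param rate Annual inflation rate (may be negative).
#' @param years Whole or fractional years elapsed (>= 0).
#' @return `base * (1 + rate)^years`.
#' @export
inflate_cost <- function(base, rate, years) {
  if (any(years < 0)) abort("years must be non-negative")
  base * (1 + rate)^years
}

#' Discount factor at a cycle
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (>= 0), vectorised.
#' @return `(1 + rate)^(-cycle)`.
#' @export
discount_factor <- function(rate, cycle) {
  if (any(cycle < 0)) abort("cycle must be non-negative")
  (1 + rate)^(-cycle)
}

#' Discounted payer cost of a strategy's trace
#'
#' Sums, over cycles, the intervention cost (covered attempts priced at the
#' strategy's consultation and drug cost, each inflated by its own price
#' index from the 2009 base year) and the chronic-illness cost (disease-state
#' person-years times the per-disease annual cost, inflated by the
#' chronic-disease index), discounted to cycle 0 when `discount_costs` is
#' set.
#'
#' @param trace A `cohort_trace`.
#' @param costs A [cost_parameters()].
#' @param discount A [discount_spec()].
#' @param horizon Optional: only cycles `0 .. horizon - 1` accrue cost.
#' @return Total discounted cost (EUR).
#' @export
strategy_cost <- function(trace, costs, discount = discount_spec(), horizon = NULL) {
  strat <- trace$strategy
  n_rec <- trace$n_cycles + 1
  tt <- 0:(n_rec - 1)
  keep <- if (is.null(horizon)) rep(TRUE, n_rec) else tt < horizon
  rate <- if (discount$discount_costs) discount$rate else 0
  df <- discount_factor(rate, tt)

  att <- rowSums(trace$arrays$att)
  att_unit <- inflate_cost(strat$visit_cost, costs$inflation[["gp"]], tt) +
    inflate_cost(strat$drug_cost, costs$inflation[["drugs"]], tt)
  intervention <- sum((att * att_unit * df)[keep])

  chronic <- 0
  infl_chronic <- (1 + costs$inflation[["chronic"]])^tt
  for (d in seq_along(.diseases)) {
    units <- rowSums(trace$arrays$chronic_units[d, , , drop = FALSE], dims = 2)[1, ]
    chronic <- chronic +
      sum((units * costs$chronic[[.diseases[d]]] * infl_chronic * df)[keep])
  }
  intervention + chronic
}

# per-disease undiscounted, inflation-adjusted chronic-cost stream by cycle
chronic_cost_stream <- function(trace, costs) {
  n_rec <- trace$n_cycles + 1
  tt <- 0:(n_rec - 1)
  infl <- (1 + costs$inflation[["chronic"]])^tt
  out <- matrix(0, n_rec, 3, dimnames = list(NULL, .diseases))
  for (d in seq_along(.diseases)) {
    units <- rowSums(trace$arrays$chronic_units[d, , , drop = FALSE], dims = 2)[1, ]
    out[, d] <- units * costs$chronic[[.diseases[d]]] * infl
  }
  out
}

#' Incremental cost-effectiveness ratio of two costed arms
#'
#' @param cost_a,ly_a Discounted cost and life-years of the intervention.
#' @param cost_b,ly_b Discounted cost and life-years of the comparator.
#' @param arm_names Labels for reporting.
#' @return A `cea_result`: per-arm costs/effects, increments, the ICER in
#'   euros per life-year gained when the incremental effect is positive,
#'   and a dominance label: `"icer"` (more costly, more effective),
#'   `"cost-saving"` (less costly, more effective; the negative ratio is
#'   retained), `"dominated"` (more costly, less effective) or
#'   `"indeterminate"` (no effect gain to divide by).
#' @export
compute_icer <- function(cost_a, cost_b, ly_a, ly_b,
                         arm_names = c("intervention", "comparator")) {
  stopifnot(is.finite(cost_a), is.finite(cost_b), is.finite(ly_a), is.finite(ly_b))
  d_cost <- cost_a - cost_b
  d_ly <- ly_a - ly_b
  if (d_ly > 0) {
    icer <- d_cost / d_ly
    label <- if (d_cost < 0) "cost-saving" else "icer"
  } else if (d_ly < 0 && d_cost > 0) {
    icer <- NA_real_
    label <- "dominated"
  } else {
    icer <- NA_real_
    label <- "indeterminate"
  }
  structure(list(
    arms = tibble(arm = arm_names, cost = c(cost_a, cost_b), life_years = c(ly_a, ly_b)),
    delta_cost = d_cost, delta_ly = d_ly, icer = icer, label = label),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  for (i in seq_len(nrow(x$arms))) {
    cat(sprintf("  %-14s cost EUR %12.2f  life-years %12.3f\n",
                x$arms$arm[i], x$arms$cost[i], x$arms$life_years[i]))
  }
  cat(sprintf("  delta cost EUR %.2f, delta LY %.4f\n", x$delta_cost, x$delta_ly))
  if (x$label %in% c("icer", "cost-saving")) {
    cat(sprintf("  ICER: EUR %.0f per LYG (%s)\n", x$icer, x$label))
  } else {
    cat(sprintf("  %s\n", x$label))
  }
  invisible(x)
}

#' Compare two coverage strategies end to end
#'
#' Runs the cohort model for both arms on the same cohort and tables,
#' costs the traces and returns the incremental cost-effectiveness result
#' with both traces attached.
#'
#' @param cohort A [cohort_spec()].
#' @param tables A [mortality_tables()] object.
#' @param intervention,comparator [strategy_spec()] objects.
#' @param costs A [cost_parameters()].
#' @param discount A [discount_spec()].
#' @param survival A [disease_survival_spec()].
#' @return A `cea_result` with a `traces` element.
#' @export
compare_strategies <- function(cohort, tables,
                               intervention = full_coverage_strategy(),
                               comparator = fifty_euro_strategy(),
                               costs = cost_parameters(),
                               discount = discount_spec(),
                               survival = disease_survival_spec()) {
  prep <- prepare_cohort_model(cohort, tables, survival)
  tr_a <- run_cohort(cohort, intervention, tables, survival, prep = prep)
  tr_b <- run_cohort(cohort, comparator, tables, survival, prep = prep)
  res <- compute_icer(strategy_cost(tr_a, costs, discount),
                      strategy_cost(tr_b, costs, discount),
                      life_years(tr_a, discount),
                      life_years(tr_b, discount),
                      arm_names = c(intervention$name, comparator$name))
  res$traces <- list(intervention = tr_a, comparator = tr_b)
  res
}

#' ICER stratified by age band and gender
#'
#' Runs the two-arm comparison separately within each cohort stratum and
#' reports the within-stratum ICER, mirroring the base-case age/gender
#' breakdown.
#'
#' @inheritParams compare_strategies
#' @return Tibble `gender`, `entry_age`, `icer`, `label`, `delta_cost`,
#'   `delta_ly`.
#' @export
icer_by_stratum <- function(cohort, tables,
                            intervention = full_coverage_strategy(),
                            comparator = fifty_euro_strategy(),
                            costs = cost_parameters(),
                            discount = discount_spec(),
                            survival = disease_survival_spec()) {
  strata <- cohort$strata
  purrr::map_dfr(seq_len(nrow(strata)), function(s) {
    sub <- cohort_spec(strata[s, c("gender", "entry_age", "weight")])
    res <- compare_strategies(sub, tables, intervention, comparator,
                              costs, discount, survival)
    tibble(gender = strata$gender[s], entry_age = strata$entry_age[s],
           icer = res$icer, label = res$label,
           delta_cost = res$delta_cost, delta_ly = res$delta_ly)
  })
}
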