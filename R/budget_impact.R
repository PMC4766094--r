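# Budget impact: national first-year implementation cost and chronic-cost
# offsets over 5/10/20-year horizons. Streams are undiscounted and
# inflation-adjusted only, the usual budget-impact convention; the cohort
# results are scaled to the national smoker population.

#' National population scaling
#'
#' @param national_count Number of smokers aged 15-75 in the target
#'   population (> 0). This is a required input: it comes from external
#'   survey data, not from the model.
#' @param cohort_size Modelled cohort size (default 1,000).
#' @return An object of class `population_scale` with the scaling factor.
#' @export
population_scale <- function(national_count, cohort_size = 1000) {
  if (national_count <= 0) abort("national smoker count must be positive")
  structure(list(national_count = national_count, cohort_size = cohort_size,
                 factor = national_count / cohort_size),
            class = "population_scale")
}

#' First-year national intervention cost
#'
#' Cycle-0 covered-attempt spending of the trace's strategy (consultations
#' plus drugs, undiscounted, base-year prices) scaled to the national
#' smoker population.
#'
#' @param trace A `cohort_trace` of the arm being budgeted.
#' @param costs A [cost_parameters()] (present for interface symmetry; the
#'   attempt unit costs come from the trace's strategy).
#' @param scale A [population_scale()].
#' @return First-year cost in euros.
#' @export
first_year_budget <- function(trace, costs, scale) {
  strat <- trace$strategy
  att0 <- sum(trace$arrays$att[1, ])
  att0 * (strat$visit_cost + strat$drug_cost) * scale$factor
}

#' Chronic-disease cost offsets at a horizon
#'
#' For each disease, the comparator arm's chronic-cost stream minus the
#' intervention arm's, summed over cycles before the horizon
#' (inflation-adjusted, undiscounted) and scaled nationally. A positive
#' offset is money the payer avoids spending under the intervention.
#'
#' @param trace_intervention,trace_comparator `cohort_trace` objects from
#'   the same cohort.
#' @param costs A [cost_parameters()].
#' @param scale A [population_scale()].
#' @param horizon Cycles to accumulate (5, 10 or 20 in the base analysis).
#' @return Tibble `disease`, `offset` (EUR), with a `"combined"` row equal
#'   to the sum of the three.
#' @export
horizon_cost_offsets <- function(trace_intervention, trace_comparator, costs,
                                 scale, horizon) {
  n_a <- trace_intervention$n_cycles + 1
  n_b <- trace_comparator$n_cycles + 1
  if (horizon > n_a || horizon > n_b) {
    abort("horizon exceeds the recorded trace length")
  }
  sa <- chronic_cost_stream(trace_intervention, costs)[seq_len(horizon), , drop = FALSE]
  sb <- chronic_cost_stream(trace_comparator, costs)[seq_len(horizon), , drop = FALSE]
  per_disease <- unname(colSums(sb) - colSums(sa)) * scale$factor
  tibble(disease = c(.diseases, "combined"),
         offset = c(per_disease, sum(per_disease)))
}

#' Probabilistic budget impact analysis
#'
#' Reuses the PSA sampling machinery: for each drawn parameter set, the
#' intervention arm is re-run and the first-year national cost and the
#' per-disease cost offsets at each horizon are recorded, then summarised
#' (mean and central 95% interval of the sampled distribution, plus a 95%
#' confidence interval for the mean).
#'
#' @inheritParams run_psa
#' @param scale A [population_scale()].
#' @param horizons Offset horizons in cycles.
#' @return A `bia_result`: `iterations` tibble and `summary` tibble.
#' @export
probabilistic_budget_impact <- function(cohort, tables,
                                        intervention = full_coverage_strategy(),
                                        comparator = fifty_euro_strategy(),
                                        costs = cost_parameters(),
                                        survival = disease_survival_spec(),
                                        dists = parameter_distributions(),
                                        scale = population_scale(13.5e6),
                                        n = 1000, seed = 1L,
                                        horizons = c(5, 10, 20)) {
  if (n < 1) abort("n must be >= 1")
  prep <- prepare_cohort_model(cohort, tables, survival)
  tr_b <- run_cohort(cohort, comparator, tables, survival, prep = prep)

  draws <- withr::with_seed(seed, sample_parameter_set(dists, n))
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    strat_i <- strategy_spec(
      name = intervention$name,
      participation = draws$participation[i],
      cessation_prob = draws$cessation[i],
      natural_cessation = intervention$natural_cessation,
      attempts = round(draws$attempts[i]),
      frequency = round(draws$frequency[i]),
      visit_cost = intervention$visit_cost,
      drug_cost = draws$drug_cost[i])
    costs_i <- cost_parameters(
      chronic = costs$chronic,
      inflation = c(gp = draws$inflation_gp[i],
                    drugs = draws$inflation_drugs[i],
                    chronic = draws$inflation_chronic[i]))
    tr_a <- run_cohort(cohort, strat_i, tables, survival, prep = prep)
    out <- tibble(iteration = i,
                  first_year_cost = first_year_budget(tr_a, costs_i, scale))
    for (h in horizons) {
      off <- horizon_cost_offsets(tr_a, tr_b, costs_i, scale, h)
      for (k in seq_len(nrow(off))) {
        out[[paste0("offset_", off$disease[k], "_", h, "y")]] <- off$offset[k]
      }
    }
    out
  })
  iterations <- dplyr::bind_cols(draws, rows)
  num_cols <- setdiff(names(rows), "iteration")
  summary <- purrr::map_dfr(num_cols, function(col) {
    v <- iterations[[col]]
    tibble(quantity = col, mean = mean(v),
           lo95 = unname(quantile(v, 0.025)), hi95 = unname(quantile(v, 0.975)),
           mean_lo95 = mean(v) - qnorm(0.975) * sd(v) / sqrt(length(v)),
           mean_hi95 = mean(v) + qnorm(0.975) * sd(v) / sqrt(length(v)))
  })
  structure(list(iterations = iterations, summary = summary,
                 scale = scale, horizons = horizons, n = n, seed = seed),
            class = "bia_result")
}

#' Deterministic budget impact at base-case parameters
#'
#' @inheritParams probabilistic_budget_impact
#' @return List with `first_year_cost` and the `offsets` tibble by horizon.
#' @export
deterministic_budget_impact <- function(cohort, tables,
                                        intervention = full_coverage_strategy(),
                                        comparator = fifty_euro_strategy(),
                                        costs = cost_parameters(),
                                        survival = disease_survival_spec(),
                                        scale = population_scale(13.5e6),
                                        horizons = c(5, 10, 20)) {
  prep <- prepare_cohort_model(cohort, tables, survival)
  tr_a <- run_cohort(cohort, intervention, tables, survival, prep = prep)
  tr_b <- run_cohort(cohort, comparator, tables, survival, prep = prep)
  offsets <- purrr::map_dfr(horizons, function(h) {
    horizon_cost_offsets(tr_a, tr_b, costs, scale, h) |> mutate(horizon = h)
  })
  list(first_year_cost = first_year_budget(tr_a, costs, scale),
       offsets = offsets)
}

#' @export
print.bia_result <- function(x, ...) {
  cat(sprintf("<bia_result> %d iterations, national count %.0f\n",
              x$n, x$scale$national_count))
  fy <- x$summary[x$summary$quantity == "first_year_cost", ]
  cat(sprintf("  first-year cost: mean EUR %.1fM [95%% sample interval %.1fM-%.1fM]\n",
              fy$mean / 1e6, fy$lo95 / 1e6, fy$hi95 / 1e6))
  invisible(x)
}
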