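# Probabilistic sensitivity analysis (Monte Carlo over parameter
# distributions) and the deterministic attempts-covered sweep.

#' Fit a log-normal distribution from a point estimate and 95% CI
#'
#' Anchors the point estimate at the median (`mu = log(point)`) and takes
#' the log-scale spread from the CI width:
#' `sigma = log(ci_high / ci_low) / (2 * 1.959964)`. Because a printed CI
#' need not be exactly symmetric about the point on the log scale, the
#' fitted quantiles can deviate slightly from the printed bounds.
#'
#' @param point Point estimate (> 0), treated as the median.
#' @param ci_low,ci_high 95% interval bounds, `0 < ci_low < point < ci_high`.
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
fit_lognormal_from_ci <- function(point, ci_low, ci_high) {
  if (!(ci_low > 0 && ci_low < point && point < ci_high)) {
    abort("need 0 < ci_low < point < ci_high (a degenerate CI gives sigma = 0)")
  }
  c(meanlog = log(point),
    sdlog = log(ci_high / ci_low) / (2 * qnorm(0.975)))
}

#' Sample from a triangular distribution by inverse CDF
#'
#' @param min,mode,max Distribution parameters, `min <= mode <= max`.
#' @param u Uniform(0, 1) variates (vectorised).
#' @return Samples; `u = 0` maps to `min`, `u = 1` to `max`.
#' @export
sample_triangular <- function(min, mode, max, u) {
  if (!(min <= mode && mode <= max)) abort("need min <= mode <= max")
  if (any(u < 0 | u > 1)) abort("u must lie in [0, 1]")
  if (min == max) return(rep(min, length(u)))
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Parameter distributions for the probabilistic analyses
#'
#' Defaults follow the base-case uncertainty specification: the program
#' cessation probability is log-normal matched to point 7.04% with 95% CI
#' \[5.64%, 9.47%\]; participation is triangular(5%, 7.3%, 73%); the
#' per-attempt drug cost is triangular(EUR 120, 201, 220); the number of
#' covered attempts is discrete over \{2, 4, 6\}, their frequency over
#' \{1, 2, 4\} years, the discount rate over \{0%, 3%, 6%\}; and each
#' inflation stream is discrete over its base and alternate value, sampled
#' independently per stream. Discrete supports are sampled uniformly. The
#' comparator's natural cessation rate is fixed. A distribution may be
#' replaced by `fixed_dist(value)` to degenerate it.
#'
#' @param cessation,participation,drug_cost,attempts,frequency,discount
#'   Distribution specifications (lists with a `dist` field).
#' @param inflation_gp,inflation_drugs,inflation_chronic Discrete supports
#'   for the three inflation streams.
#' @return An object of class `parameter_distributions`.
#' @export
parameter_distributions <- function(
    cessation = lognormal_dist(0.0704, 0.0564, 0.0947),
    participation = triangular_dist(0.05, 0.073, 0.73),
    drug_cost = triangular_dist(120, 201, 220),
    attempts = discrete_dist(c(2, 4, 6)),
    frequency = discrete_dist(c(1, 2, 4)),
    discount = discrete_dist(c(0, 0.03, 0.06)),
    inflation_gp = discrete_dist(c(0.0023, 0.0132)),
    inflation_drugs = discrete_dist(c(0.0219, -0.0538)),
    inflation_chronic = discrete_dist(c(-0.015, 0.015))) {
  structure(list(cessation = cessation, participation = participation,
                 drug_cost = drug_cost, attempts = attempts,
                 frequency = frequency, discount = discount,
                 inflation_gp = inflation_gp,
                 inflation_drugs = inflation_drugs,
                 inflation_chronic = inflation_chronic),
            class = "parameter_distributions")
}

#' @rdname parameter_distributions
#' @param point,ci_low,ci_high Log-normal anchor and CI (see
#'   [fit_lognormal_from_ci()]).
#' @export
lognormal_dist <- function(point, ci_low, ci_high) {
  pars <- fit_lognormal_from_ci(point, ci_low, ci_high)
  list(dist = "lognormal", point = point,
       meanlog = pars[["meanlog"]], sdlog = pars[["sdlog"]])
}

#' @rdname parameter_distributions
#' @param min,mode,max Triangular parameters.
#' @export
triangular_dist <- function(min, mode, max) {
  if (!(min <= mode && mode <= max)) abort("need min <= mode <= max")
  list(dist = "triangular", min = min, mode = mode, max = max)
}

#' @rdname parameter_distributions
#' @param values Non-empty support sampled uniformly.
#' @export
discrete_dist <- function(values) {
  if (length(values) == 0) abort("discrete support must be non-empty")
  list(dist = "discrete", values = values)
}

#' @rdname parameter_distributions
#' @param value Fixed value (degenerate distribution).
#' @export
fixed_dist <- function(value) list(dist = "fixed", value = value)

#' Degenerate all distributions at the base case
#'
#' Convenience set under which the probabilistic machinery must reproduce
#' the deterministic base case exactly.
#'
#' @param strategy The full-coverage [strategy_spec()] providing base values.
#' @param costs A [cost_parameters()].
#' @param discount A [discount_spec()].
#' @return A `parameter_distributions` object of fixed values.
#' @export
degenerate_distributions <- function(strategy = full_coverage_strategy(),
                                     costs = cost_parameters(),
                                     discount = discount_spec()) {
  parameter_distributions(
    cessation = fixed_dist(strategy$cessation_prob),
    participation = fixed_dist(strategy$participation),
    drug_cost = fixed_dist(strategy$drug_cost),
    attempts = fixed_dist(strategy$attempts),
    frequency = fixed_dist(strategy$frequency),
    discount = fixed_dist(discount$rate),
    inflation_gp = fixed_dist(costs$inflation[["gp"]]),
    inflation_drugs = fixed_dist(costs$inflation[["drugs"]]),
    inflation_chronic = fixed_dist(costs$inflation[["chronic"]]))
}

sample_one <- function(d, n) {
  switch(d$dist,
         fixed = rep(d$value, n),
         lognormal = rlnorm(n, d$meanlog, d$sdlog),
         triangular = sample_triangular(d$min, d$mode, d$max, runif(n)),
         discrete = d$values[sample.int(length(d$values), n, replace = TRUE)],
         abort(paste0("unknown distribution kind: ", d$dist)))
}

#' Draw parameter sets
#'
#' One independent draw per parameter per row; reproducible under the
#' caller's RNG state (set a seed before calling, or use [run_psa()] which
#' seeds for you).
#'
#' @param dists A [parameter_distributions()] object.
#' @param n Number of parameter sets.
#' @return Tibble with one column per parameter and `n` rows.
#' @export
sample_parameter_set <- function(dists, n = 1) {
  stopifnot(inherits(dists, "parameter_distributions"))
  as_tibble(purrr::map(unclass(dists), sample_one, n = n))
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets, re-evaluates the full model for each (common
#' random numbers: the comparator arm of an iteration shares the drawn
#' discount and inflation values with the intervention arm; the comparator's
#' own effectiveness is fixed) and summarises the resulting ICER
#' distribution. The comparator trace does not depend on any sampled
#' parameter and is computed once.
#'
#' @param cohort A [cohort_spec()].
#' @param tables A [mortality_tables()] object.
#' @param intervention,comparator [strategy_spec()] objects; sampled fields
#'   of the intervention (cessation, participation, drug cost, attempts,
#'   frequency) are overridden per iteration.
#' @param costs A [cost_parameters()].
#' @param survival A [disease_survival_spec()].
#' @param dists A [parameter_distributions()].
#' @param n Number of iterations (base case 1,000).
#' @param seed Integer seed; identical seed and configuration give an
#'   identical result object.
#' @return A `psa_result`: `iterations` tibble (draws and outputs),
#'   `summary` tibble, and the cumulative-frequency curve of the ICER.
#' @export
run_psa <- function(cohort, tables,
                    intervention = full_coverage_strategy(),
                    comparator = fifty_euro_strategy(),
                    costs = cost_parameters(),
                    survival = disease_survival_spec(),
                    dists = parameter_distributions(),
                    n = 1000, seed = 1L) {
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
    disc_i <- discount_spec(rate = draws$discount[i])
    tr_a <- run_cohort(cohort, strat_i, tables, survival, prep = prep)
    res <- compute_icer(strategy_cost(tr_a, costs_i, disc_i),
                        strategy_cost(tr_b, costs_i, disc_i),
                        life_years(tr_a, disc_i), life_years(tr_b, disc_i))
    tibble(iteration = i,
           cost_intervention = res$arms$cost[1], cost_comparator = res$arms$cost[2],
           ly_intervention = res$arms$life_years[1], ly_comparator = res$arms$life_years[2],
           delta_cost = res$delta_cost, delta_ly = res$delta_ly,
           icer = if (res$label %in% c("icer", "cost-saving")) res$icer else NA_real_,
           label = res$label)
  })
  iterations <- dplyr::bind_cols(draws, rows)
  structure(list(iterations = iterations,
                 summary = psa_summary(iterations),
                 curve = icer_cumulative_curve(iterations),
                 n = n, seed = seed),
            class = "psa_result")
}

#' Summarise PSA iterations
#'
#' Recomputable from the stored iterations: moments, quartiles, upper
#' percentiles and the fraction of cost-saving iterations, over iterations
#' with a defined ratio (positive incremental effect).
#'
#' @param iterations The `iterations` tibble of a `psa_result`.
#' @return One-row tibble of summaries.
#' @export
psa_summary <- function(iterations) {
  v <- iterations$icer[!is.na(iterations$icer)]
  tibble(n = nrow(iterations), n_ratio = length(v),
         mean = mean(v), sd = sd(v), min = min(v), max = max(v),
         median = median(v),
         q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)),
         p95 = unname(quantile(v, 0.95)), p99 = unname(quantile(v, 0.99)),
         frac_cost_saving = mean(iterations$label == "cost-saving"))
}

icer_cumulative_curve <- function(iterations) {
  v <- sort(iterations$icer[!is.na(iterations$icer)])
  tibble(icer = v, cum_freq = seq_along(v) / length(v))
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n, x$seed))
  cat(sprintf("  ICER: mean EUR %.0f (sd %.0f), median %.0f, IQR [%.0f, %.0f]\n",
              s$mean, s$sd, s$median, s$q25, s$q75))
  cat(sprintf("  95th pct %.0f, 99th pct %.0f, cost-saving in %.1f%% of iterations\n",
              s$p95, s$p99, 100 * s$frac_cost_saving))
  invisible(x)
}

#' Deterministic sweep over the number of covered attempts
#'
#' Re-runs the base-case comparison at each number of covered attempts and
#' reports the ICER together with the incremental life-years per cohort
#' with no discounting of benefits (costs stay discounted).
#'
#' @inheritParams run_psa
#' @param attempts Values to sweep (base \{2, 4, 6\}).
#' @param discount A [discount_spec()] for the costed results.
#' @return Tibble `attempts`, `icer`, `label`, `delta_cost`, `delta_ly`,
#'   `ly_gain_undiscounted`.
#' @export
attempts_sweep <- function(cohort, tables,
                           intervention = full_coverage_strategy(),
                           comparator = fifty_euro_strategy(),
                           costs = cost_parameters(),
                           discount = discount_spec(),
                           survival = disease_survival_spec(),
                           attempts = c(2, 4, 6)) {
  prep <- prepare_cohort_model(cohort, tables, survival)
  tr_b <- run_cohort(cohort, comparator, tables, survival, prep = prep)
  no_disc_benefit <- discount_spec(rate = discount$rate,
                                   discount_costs = discount$discount_costs,
                                   discount_benefits = FALSE)
  purrr::map_dfr(attempts, function(a) {
    strat <- intervention
    strat$attempts <- as.integer(a)
    tr_a <- run_cohort(cohort, strat, tables, survival, prep = prep)
    res <- compute_icer(strategy_cost(tr_a, costs, discount),
                        strategy_cost(tr_b, costs, discount),
                        life_years(tr_a, discount), life_years(tr_b, discount))
    tibble(attempts = a, icer = res$icer, label = res$label,
           delta_cost = res$delta_cost, delta_ly = res$delta_ly,
           ly_gain_undiscounted =
             life_years(tr_a, no_disc_benefit) - life_years(tr_b, no_disc_benefit))
  })
}
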