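# Constructors for the model's parameter objects: coverage strategies,
# cohort composition, post-diagnosis survival, costs and discounting.

#' Build a definitive cessation probability from a natural rate and odds ratios
#'
#' The base-case program cessation probability is constructed from the
#' natural (unaided) annual cessation probability and the odds ratios of the
#' pharmacological and counselling components. Two conventions are offered:
#' `"multiplier"` (default) applies the odds ratios as direct multipliers on
#' the probability, reproducing the conventional printed base-case value
#' (0.026 x 1.95 x 1.39 = 7.05%, printed as 7.04%); `"odds"` performs a
#' strict odds-scale conversion (about 6.75% for the same inputs).
#'
#' @param natural Natural annual cessation probability.
#' @param odds_ratios Numeric vector of odds ratios to apply.
#' @param method `"multiplier"` or `"odds"`.
#' @return A probability.
#' @export
cessation_rate_from_or <- function(natural = 0.026, odds_ratios = c(1.95, 1.39),
                                   method = c("multiplier", "odds")) {
  method <- match.arg(method)
  if (natural <= 0 || natural >= 1) abort("natural cessation rate must lie in (0, 1)")
  if (any(odds_ratios <= 0)) abort("odds ratios must be positive")
  if (method == "multiplier") {
    p <- natural * prod(odds_ratios)
  } else {
    o <- natural / (1 - natural) * prod(odds_ratios)
    p <- o / (1 + o)
  }
  if (p >= 1) abort("derived cessation probability reaches 1; check inputs")
  p
}

#' Participation rate from desire-to-quit and motivation fractions
#'
#' @param want_to_quit Fraction of smokers who report wanting to quit.
#' @param motivated Fraction of those who are genuinely motivated to enter a
#'   supported program.
#' @return The participation probability (product of the two).
#' @export
participation_rate <- function(want_to_quit = 0.73, motivated = 0.10) {
  stopifnot(want_to_quit >= 0, want_to_quit <= 1, motivated >= 0, motivated <= 1)
  want_to_quit * motivated
}

#' Definitive cessation rate from a one-year quit rate and relapse
#'
#' Folds long-run relapse into a one-year cessation rate: the definitive
#' rate is the one-year rate times the fraction of one-year quitters who
#' never relapse.
#'
#' @param one_year_rate One-year observed cessation rate.
#' @param never_relapse Fraction of one-year quitters who never relapse.
#' @return A probability.
#' @export
definitive_cessation_rate <- function(one_year_rate, never_relapse) {
  stopifnot(one_year_rate >= 0, one_year_rate <= 1,
            never_relapse >= 0, never_relapse <= 1)
  one_year_rate * never_relapse
}

#' Specify a coverage strategy
#'
#' One arm of the comparison: who enters the program (participation), how
#' effective each covered attempt is, how many attempts are covered and how
#' often, and what one attempt costs the payer (consultations and drugs,
#' 2009 euros). Participants face the program cessation probability at the
#' covered attempt cycles while still smoking and the natural rate in all
#' other cycles; non-participants always face the natural rate. Relapse is
#' folded into the definitive cessation probability, so there is no
#' former-to-smoker transition.
#'
#' @param name Label for reporting.
#' @param participation Fraction of the cohort entering the program.
#' @param cessation_prob Per-attempt definitive cessation probability.
#' @param natural_cessation Annual cessation probability outside covered
#'   attempts (default 2.6%).
#' @param attempts Number of covered attempts (>= 0).
#' @param frequency Years between consecutive covered attempts (>= 1).
#' @param visit_cost,drug_cost Per-attempt consultation and drug cost, EUR 2009.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, participation, cessation_prob,
                          natural_cessation = 0.026,
                          attempts = 4L, frequency = 2L,
                          visit_cost = 0, drug_cost = 0) {
  probs <- c(participation, cessation_prob, natural_cessation)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (attempts < 0) abort("attempts must be >= 0")
  if (attempts > 0 && frequency < 1) abort("frequency must be >= 1 year")
  if (visit_cost < 0 || drug_cost < 0) abort("costs must be non-negative")
  structure(list(name = name, participation = participation,
                 cessation_prob = cessation_prob,
                 natural_cessation = natural_cessation,
                 attempts = as.integer(attempts),
                 frequency = as.integer(frequency),
                 visit_cost = visit_cost, drug_cost = drug_cost),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy_spec> %s\n", x$name))
  cat(sprintf("  participation %.2f%%, cessation/attempt %.2f%%, natural %.2f%%\n",
              100 * x$participation, 100 * x$cessation_prob, 100 * x$natural_cessation))
  cat(sprintf("  %d attempt(s) every %d year(s); EUR %.1f visits + EUR %.1f drugs per attempt\n",
              x$attempts, x$frequency, x$visit_cost, x$drug_cost))
  invisible(x)
}

#' Full-coverage strategy (base case)
#'
#' Full payer coverage of a medically managed cessation program: 7.3%
#' participation (73% want to quit, 10% of them truly motivated), four
#' covered attempts every two years, definitive cessation probability 7.05%
#' per covered attempt (2.6% natural rate scaled by odds ratios 1.95 and
#' 1.39), EUR 132 of consultations plus EUR 201 of drugs per attempt.
#'
#' @param ... Overrides passed to [strategy_spec()].
#' @return A `strategy_spec`.
#' @export
full_coverage_strategy <- function(...) {
  defaults <- list(name = "full coverage",
                   participation = participation_rate(),
                   cessation_prob = cessation_rate_from_or(),
                   attempts = 4L, frequency = 2L,
                   visit_cost = 132, drug_cost = 201)
  do.call(strategy_spec, utils::modifyList(defaults, list(...)))
}

#' Lump-sum EUR 50 coverage strategy (comparator)
#'
#' The existing lump-sum subsidy: 3.75% of the cohort claims it once (a
#' single covered "attempt" at entry costing EUR 14.4 for the prescribing
#' visit plus EUR 50 of drugs), with no effect on cessation beyond the
#' natural rate — participation is cost-only, so the per-attempt cessation
#' probability equals the natural rate.
#'
#' @param ... Overrides passed to [strategy_spec()].
#' @return A `strategy_spec`.
#' @export
fifty_euro_strategy <- function(...) {
  defaults <- list(name = "EUR 50 coverage",
                   participation = 0.0375,
                   cessation_prob = 0.026,
                   attempts = 1L, frequency = 1L,
                   visit_cost = 14.4, drug_cost = 50)
  do.call(strategy_spec, utils::modifyList(defaults, list(...)))
}

#' No-coverage strategy
#'
#' Natural cessation only, no payer spending; used for the sensitivity
#' comparison of full coverage against no coverage at all.
#'
#' @param ... Overrides passed to [strategy_spec()].
#' @return A `strategy_spec`.
#' @export
no_coverage_strategy <- function(...) {
  defaults <- list(name = "no coverage", participation = 0,
                   cessation_prob = 0.026, attempts = 0L, frequency = 1L,
                   visit_cost = 0, drug_cost = 0)
  do.call(strategy_spec, utils::modifyList(defaults, list(...)))
}

#' Specify the simulated cohort
#'
#' @param strata Tibble with columns `gender` (`"male"`/`"female"`),
#'   `entry_age` (whole years, within \[15, 75\]) and `weight` (persons;
#'   non-negative, summing to the cohort size).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(strata) {
  strata <- as_tibble(strata)
  stopifnot(all(c("gender", "entry_age", "weight") %in% names(strata)))
  if (any(strata$weight < 0)) abort("stratum weights must be non-negative")
  if (any(strata$entry_age < 15 | strata$entry_age > 75)) {
    abort("entry ages must lie in [15, 75]")
  }
  strata$stratum <- paste0(strata$gender, "_", strata$entry_age)
  structure(list(strata = strata, size = sum(strata$weight)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d strata, %.0f persons, ages %d-%d\n",
              nrow(x$strata), x$size, min(x$strata$entry_age),
              max(x$strata$entry_age)))
  invisible(x)
}

#' Default cohort of 1,000 smokers aged 15-75
#'
#' Twelve strata (six ten-year age bands per gender, represented by their
#' mid-band single year of age) with weights reflecting the age and gender
#' profile of the smoking population: smoking is most prevalent in early
#' and mid adulthood and somewhat more common among men (55% male).
#'
#' @param size Cohort size in persons (default 1,000).
#' @return A `cohort_spec`.
#' @export
default_cohort <- function(size = 1000) {
  entry <- c(20L, 30L, 40L, 50L, 60L, 70L)
  share <- c(0.17, 0.20, 0.20, 0.19, 0.15, 0.09)
  male_frac <- 0.55
  strata <- bind_rows(
    tibble(gender = "male", entry_age = entry, weight = size * share * male_frac),
    tibble(gender = "female", entry_age = entry, weight = size * share * (1 - male_frac))
  )
  cohort_spec(strata)
}

#' Life expectancy after diagnosis, by disease, age band and smoking status
#'
#' Default values: lung cancer 2 years at all ages and statuses; COPD for
#' smokers 18 / 10 / 3 years (ages <70 / 70-79 / >=80), former smokers
#' 20 / 15 / 5, never smokers 20 / 5 (ages <80 / >=80); CVD 15 / 6 / 3 / 1
#' years (ages <65 / 65-74 / 75-84 / >=85) regardless of smoking status.
#' Age bands are closed-open. The conversion from life expectancy to a
#' constant annual death probability is `1/LE` (geometric survival with the
#' stated mean) by default; `"exponential"` uses `1 - exp(-1/LE)`.
#'
#' @param table Optional replacement tibble with columns `disease`,
#'   `status`, `age_lo`, `age_hi`, `le`.
#' @param conversion `"inverse"` (default) or `"exponential"`.
#' @return An object of class `survival_spec`.
#' @export
disease_survival_spec <- function(table = NULL,
                                  conversion = c("inverse", "exponential")) {
  conversion <- match.arg(conversion)
  if (is.null(table)) {
    table <- bind_rows(
      tibble(disease = "lung_cancer",
             status = rep(c("current", "former", "never"), each = 1),
             age_lo = 0, age_hi = Inf, le = 2),
      tibble(disease = "copd", status = "current",
             age_lo = c(0, 70, 80), age_hi = c(70, 80, Inf), le = c(18, 10, 3)),
      tibble(disease = "copd", status = "former",
             age_lo = c(0, 70, 80), age_hi = c(70, 80, Inf), le = c(20, 15, 5)),
      tibble(disease = "copd", status = "never",
             age_lo = c(0, 80), age_hi = c(80, Inf), le = c(20, 5)),
      purrr::map_dfr(c("current", "former", "never"), function(st)
        tibble(disease = "cvd", status = st,
               age_lo = c(0, 65, 75, 85), age_hi = c(65, 75, 85, Inf),
               le = c(15, 6, 3, 1)))
    )
  }
  table <- as_tibble(table)
  if (any(table$le < 1)) abort("life expectancy after diagnosis must be >= 1 year")
  structure(list(table = table, conversion = conversion), class = "survival_spec")
}

#' Annual death probability from a post-diagnosis life expectancy
#'
#' Converts a mean survival of `le` years into a constant annual death
#' probability. The default `"inverse"` convention returns `1/le`, the
#' geometric-lifetime parameter whose mean equals `le`; `"exponential"`
#' returns `1 - exp(-1/le)`, the discretisation of a constant hazard.
#'
#' @param le Life expectancy after diagnosis, years (>= 1).
#' @param conversion Conversion convention.
#' @return A probability.
#' @export
annual_death_probability_from_life_expectancy <- function(le, conversion = c("inverse", "exponential")) {
  conversion <- match.arg(conversion)
  if (any(le < 1)) abort("life expectancy must be at least 1 year")
  if (conversion == "inverse") 1 / le else 1 - exp(-1 / le)
}

# Vectorised LE lookup for one disease: status and age vectors -> LE years.
lookup_le <- function(survival, disease, status, age) {
  sub <- survival$table[survival$table$disease == disease, ]
  out <- rep(NA_real_, length(age))
  for (i in seq_len(nrow(sub))) {
    hit <- sub$status[i] == status & age >= sub$age_lo[i] & age < sub$age_hi[i]
    out[hit] <- sub$le[i]
  }
  if (anyNA(out)) abort(paste0("no survival entry for disease ", disease,
                               " at some (status, age)"))
  out
}

#' Chronic-disease cost and inflation parameters (EUR 2009)
#'
#' Annual per-person long-term illness costs charged for every cycle spent
#' in a disease state (including the diagnosis cycle), and annual inflation
#' rates applied from the 2009 base year by cycle index: one rate for GP
#' visits, one for drugs, one for chronic-disease costs (which may be
#' negative).
#'
#' @param chronic Named annual costs per disease.
#' @param inflation Named annual inflation rates (`gp`, `drugs`, `chronic`).
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(chronic = c(lung_cancer = 13872, copd = 6562, cvd = 7976),
                            inflation = c(gp = 0.0023, drugs = 0.0219, chronic = -0.015)) {
  if (any(chronic < 0)) abort("chronic-illness costs must be non-negative")
  stopifnot(all(.diseases %in% names(chronic)),
            all(c("gp", "drugs", "chronic") %in% names(inflation)))
  structure(list(chronic = chronic[.diseases], inflation = inflation),
            class = "cost_parameters")
}

#' Discounting specification
#'
#' @param rate Annual discount rate (base case 3%; alternatives 0% and 6%).
#' @param discount_costs,discount_benefits Whether to discount each stream;
#'   turning benefit discounting off reproduces the "0% on benefits"
#'   sensitivity while keeping costs discounted.
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(rate = 0.03, discount_costs = TRUE, discount_benefits = TRUE) {
  if (rate < 0) abort("discount rate must be non-negative")
  structure(list(rate = rate, discount_costs = discount_costs,
                 discount_benefits = discount_benefits),
            class = "discount_spec")
}
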