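test_that("model life expectancy matches closed-form benchmarks", {
  # zero mortality with an 80-cycle cap yields exactly 80 years
  expect_equal(model_life_expectancy(zero_tables(), "male", "smoker",
                                     horizon = 80), 80)
  # constant all-cause mortality 0.05: expected years ~ 1/p counting the
  # entry year (discrete geometric lifetime), truncated at age 110
  const <- flat_tables(p_nev = c(lung_cancer = 0, copd = 0, cvd = 0),
                       mult = 1, p_all = 0.05)
  le <- model_life_expectancy(const, "male", "non-smoker", entry_age = 20)
  q <- rep(0.05, 91)
  oracle <- 1 + sum(cumprod(1 - q)[-91])
  expect_equal(le, oracle, tolerance = 1e-9)
  expect_equal(le, 20, tolerance = 0.4)   # near the 1/p mean
})

test_that("life expectancy responds correctly to mortality shifts and status", {
  tab <- shared_synthetic_tables()
  # uniform upward shift of all-cause mortality lowers life expectancy
  worse <- tab
  worse$all_cause$p_allcause <- pmin(worse$all_cause$p_allcause + 0.01, 1)
  worse <- mortality_tables(worse$disease, worse$all_cause, worse$rr)
  expect_lt(model_life_expectancy(worse, "male", "non-smoker"),
            model_life_expectancy(tab, "male", "non-smoker"))
  # smokers never outlive non-smokers when current rates dominate never rates
  for (g in c("male", "female")) {
    expect_lt(model_life_expectancy(tab, g, "smoker"),
              model_life_expectancy(tab, g, "non-smoker"))
  }
})

test_that("onset-time shares form a distribution with the expected structure", {
  tab <- shared_synthetic_tables()
  tr <- run_cohort(default_cohort(), fifty_euro_strategy(), tab)
  shares <- onset_time_distribution(tr, horizon = 20)
  for (d in unique(shares$disease)) {
    expect_equal(sum(shares$share[shares$disease == d]), 1, tolerance = 1e-9)
  }
  # lung cancer (2-year survival) is concentrated at recent onsets; the
  # longer-survival diseases spread across the bins
  lung <- shares[shares$disease == "lung_cancer", ]
  copd <- shares[shares$disease == "copd", ]
  expect_gt(lung$share[lung$bin == "<1"], copd$share[copd$bin == "<1"])
  expect_gt(copd$share[copd$bin == ">15"], lung$share[lung$bin == ">15"])

  # all diagnoses in the final cycle fall in the under-one-year bin:
  # a two-cycle horizon with incidence only possible in the last cycle
  one <- cohort_spec(tibble::tibble(gender = "male", entry_age = 40, weight = 100))
  tr2 <- run_cohort(one, no_coverage_strategy(), shared_synthetic_tables(),
                    horizon = 1)
  s2 <- onset_time_distribution(tr2, horizon = 1)
  expect_equal(s2$share[s2$bin == "<1"], rep(1, 3))

  # an empty disease state is flagged, not divided
  tr0 <- run_cohort(one, no_coverage_strategy(), zero_tables(), horizon = 5)
  w <- testthat::capture_warnings(s0 <- onset_time_distribution(tr0, horizon = 5))
  expect_length(w, 3)                         # one flag per empty disease
  expect_true(all(grepl("no survivors", w)))
  expect_true(all(is.na(s0$share)))
})

test_that("external scenario replication behaves consistently", {
  tab <- shared_synthetic_tables()
  co <- tiny_cohort()
  # a zero-effect coverage scenario gains nothing and saves nothing
  null_sc <- list(mode = "coverage", participation = 0, cessation_prob = 0.026,
                  attempts = 4, frequency = 2, horizon = 10)
  out0 <- replicate_external_scenario(tab, null_sc, cohort = co)
  expect_equal(out0$ly_gained, 0, tolerance = 1e-9)
  expect_equal(out0$cost_savings, 0, tolerance = 1e-9)

  # 1,000 definitive quitters gain life-years and avoid disease costs over
  # a 10-year horizon
  quit_sc <- list(mode = "quitters", horizon = 10)
  out <- replicate_external_scenario(tab, quit_sc, cohort = co)
  expect_gt(out$ly_gained, 0)
  expect_gt(out$cost_savings, 0)

  # more effective coverage gains more
  lo <- replicate_external_scenario(tab, list(mode = "coverage",
                                              participation = 0.07,
                                              cessation_prob = 0.05,
                                              horizon = 10), cohort = co)
  hi <- replicate_external_scenario(tab, list(mode = "coverage",
                                              participation = 0.07,
                                              cessation_prob = 0.15,
                                              horizon = 10), cohort = co)
  expect_gt(hi$ly_gained, lo$ly_gained)
})

test_that("the validation report assembles both tables", {
  tab <- shared_synthetic_tables()
  rep <- validation_report(tab, cohort = tiny_cohort())
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$life_expectancy), 2)
  expect_true(all(rep$life_expectancy$gap > 0))
  expect_equal(nrow(rep$onset_times), 18)
})
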