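test_that("life expectancy converts to a constant annual death probability", {
  expect_equal(annual_death_probability_from_life_expectancy(1), 1)
  expect_equal(annual_death_probability_from_life_expectancy(2), 0.5)
  expect_equal(annual_death_probability_from_life_expectancy(20), 0.05)
  expect_error(annual_death_probability_from_life_expectancy(0.5), "at least 1")
  # exponential-hazard alternative
  expect_equal(annual_death_probability_from_life_expectancy(2, "exponential"),
               1 - exp(-0.5))
  # Monte Carlo check: geometric lifetimes with p = 0.05 have mean ~ 20
  withr::with_seed(99, {
    lifetimes <- rgeom(200000, 0.05) + 1   # cycles survived into, >= 1
    expect_equal(mean(lifetimes), 20, tolerance = 0.02)
  })
})

test_that("transition rows are proper and match an independent assembly", {
  tab <- flat_tables()
  strat <- full_coverage_strategy()

  # dead origin is absorbing
  row_d <- build_transition_row("D", "male", 50, 0, strat, tab)
  expect_equal(row_d$prob[row_d$state == "D"], 1)
  expect_equal(sum(row_d$prob), 1)

  # with zero mortality and zero cessation the smoker row is the identity
  strat0 <- no_coverage_strategy(natural_cessation = 0)
  row_s <- build_transition_row("S", "male", 50, 0, strat0, zero_tables())
  expect_equal(row_s$prob[row_s$state == "S"], 1)

  # oracle equivalence across random tables, origins and keys
  for (seed in 1:10) {
    tabr <- random_tables(seed)
    withr::with_seed(100 + seed, {
      g <- sample(c("male", "female"), 1)
      age <- sample(15:105, 1)
      d <- sample(1:20, 1)
    })
    dis <- tabr$disease
    ac <- tabr$all_cause$p_allcause[tabr$all_cause$gender == g &
                                      tabr$all_cause$age == age]
    nev <- dis[dis$gender == g & dis$age == age & dis$status == "never", ]
    res_nev <- ac - (nev$p_lung + nev$p_copd + nev$p_cvd)

    cur <- dis[dis$gender == g & dis$age == age & dis$status == "current", ]
    row <- build_transition_row("S", g, age, 0, strat, tabr, participant = TRUE)
    cess <- min(strat$cessation_prob,
                1 - cur$p_lung - cur$p_copd - cur$p_cvd - res_nev)
    expect_equal(row$prob[row$state == "C"], cur$p_lung)
    expect_equal(row$prob[row$state == "O"], cur$p_copd)
    expect_equal(row$prob[row$state == "V"], cur$p_cvd)
    expect_equal(row$prob[row$state == "D"], res_nev)
    expect_equal(row$prob[row$state == "F"], cess)
    expect_equal(sum(row$prob), 1, tolerance = 1e-15)

    band <- max(findInterval(max(d, 1), c(1, 3, 6, 11, 16)), 1)
    frm <- dis[dis$gender == g & dis$age == age & dis$status == "former" &
                 !is.na(dis$band_lo) &
                 dis$band_lo == c(1, 3, 6, 11, 16)[band], ]
    row_f <- build_transition_row("F", g, age, 3, strat, tabr,
                                  years_since_quit = d)
    expect_equal(row_f$prob[row_f$state == "C"], frm$p_lung)
    expect_equal(row_f$prob[row_f$state == "D"], res_nev, tolerance = 1e-12)
    expect_equal(sum(row_f$prob), 1, tolerance = 1e-15)
  }

  # disease origin: death probability is 1/LE at the diagnosis band
  row_c <- build_transition_row("C", "male", 60, 5, strat, tab)
  expect_equal(row_c$prob[row_c$state == "D"], 0.5)     # lung cancer LE 2
  row_o <- build_transition_row("O", "male", 60, 5, strat, tab,
                                dx_age = 75, dx_status = "former")
  expect_equal(row_o$prob[row_o$state == "D"], 1 / 15)  # COPD former 70-79
})

test_that("the cohort conserves mass, keeps death monotone, and starts in S", {
  tab <- flat_tables()
  co <- tiny_cohort()
  tr <- run_cohort(co, full_coverage_strategy(), tab)
  occ_tot <- apply(tr$arrays$occ, 1, sum)
  expect_equal(occ_tot, rep(co$size, length(occ_tot)), tolerance = 1e-9)
  expect_equal(sum(tr$arrays$occ[1, "S", ]), co$size)   # cycle 0 all smokers
  dead <- rowSums(tr$arrays$occ[, "D", ])
  expect_true(all(diff(dead) >= -1e-12))
  # extinction at the end of a lifetime run
  expect_equal(dead[length(dead)], co$size, tolerance = 1e-9)

  # zero mortality: occupancy stays at cohort size with no deaths over 10 cycles
  tr0 <- run_cohort(co, full_coverage_strategy(), zero_tables(), horizon = 10)
  alive <- rowSums(tr0$arrays$occ[, 1:5, ], dims = 1)
  expect_equal(alive, rep(co$size, 11))
  expect_equal(sum(tr0$arrays$deaths), 0)
})

test_that("a program no better than natural cessation changes nothing", {
  tab <- flat_tables()
  co <- tiny_cohort()
  prep <- cessmod:::prepare_cohort_model(co, tab)
  same <- strategy_spec("same", participation = 0.5, cessation_prob = 0.026,
                        attempts = 4L, frequency = 2L)
  none <- no_coverage_strategy()
  tr_a <- run_cohort(co, same, tab, prep = prep)
  tr_b <- run_cohort(co, none, tab, prep = prep)
  expect_equal(tr_a$arrays$occ, tr_b$arrays$occ, tolerance = 1e-12)
  expect_equal(life_years(tr_a) - life_years(tr_b), 0, tolerance = 1e-9)
})

test_that("higher per-attempt cessation increases former occupancy and life-years", {
  tab <- shared_synthetic_tables()
  co <- tiny_cohort()
  prep <- cessmod:::prepare_cohort_model(co, tab)
  lys <- c()
  fly <- c()
  for (p in c(0.026, 0.0704, 0.2)) {
    tr <- run_cohort(co, full_coverage_strategy(cessation_prob = p), tab, prep = prep)
    lys <- c(lys, life_years(tr))
    fly <- c(fly, sum(tr$arrays$occ[, "F", ]))
  }
  expect_true(all(diff(lys) > 0))
  expect_true(all(diff(fly) > 0))
})

test_that("life-years follow the discounted alive count", {
  tab <- flat_tables()
  co <- tiny_cohort()
  # everyone alive for exactly 2 cycles at rate 0 gives 2 * size life-years
  sudden <- flat_tables(p_nev = c(lung_cancer = 0, copd = 0, cvd = 0),
                        mult = 1, p_all = 1)
  tr2 <- run_cohort(co, no_coverage_strategy(), sudden, horizon = 5)
  expect_equal(life_years(tr2, discount_spec(rate = 0)), co$size)
  # with zero mortality, LY = size * horizon at rate 0 (discounting identity)
  tr0 <- run_cohort(co, no_coverage_strategy(), zero_tables(), horizon = 7)
  expect_equal(life_years(tr0, discount_spec(rate = 0), horizon = 7), co$size * 7)
  # discounting strictly reduces LY
  tr <- run_cohort(co, no_coverage_strategy(), tab)
  expect_lt(life_years(tr, discount_spec(rate = 0.03)),
            life_years(tr, discount_spec(rate = 0)))
  # discounted sum oracle
  alive <- rowSums(tr$arrays$occ[, 1:5, ], dims = 1)
  expect_equal(life_years(tr, discount_spec(rate = 0.03)),
               sum(alive / 1.03^(seq_along(alive) - 1)))
})

test_that("deaths avoided equal the independent subtraction oracle", {
  tab <- shared_synthetic_tables()
  co <- tiny_cohort()
  prep <- cessmod:::prepare_cohort_model(co, tab)
  tr_a <- run_cohort(co, full_coverage_strategy(cessation_prob = 0.3), tab, prep = prep)
  tr_b <- run_cohort(co, fifty_euro_strategy(), tab, prep = prep)
  avoided <- cause_specific_deaths(tr_a, tr_b)
  for (i in seq_along(cessmod:::.causes)) {
    oracle <- (sum(tr_b$arrays$deaths[, i, ]) - sum(tr_a$arrays$deaths[, i, ])) *
      1000 / co$size
    expect_equal(avoided$avoided[i], oracle)
  }
  # identical traces avoid nothing
  same <- cause_specific_deaths(tr_b, tr_b)
  expect_equal(same$avoided, rep(0, 4))
  # mismatched cohorts error
  other <- cohort_spec(tibble::tibble(gender = "male", entry_age = 30, weight = 500))
  tr_c <- run_cohort(other, fifty_euro_strategy(), tab)
  expect_error(cause_specific_deaths(tr_a, tr_c), "different cohorts")
})

test_that("doubling stratum weights doubles life-years and costs", {
  tab <- shared_synthetic_tables()
  co1 <- tiny_cohort(1000)
  co2 <- tiny_cohort(2000)
  strat <- full_coverage_strategy()
  tr1 <- run_cohort(co1, strat, tab)
  tr2 <- run_cohort(co2, strat, tab)
  expect_equal(life_years(tr2), 2 * life_years(tr1), tolerance = 1e-12)
  expect_equal(strategy_cost(tr2, cost_parameters()),
               2 * strategy_cost(tr1, cost_parameters()), tolerance = 1e-12)
})
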