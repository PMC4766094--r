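test_that("cost inflation and discount factors follow the closed forms", {
  expect_equal(inflate_cost(100, 0.05, 0), 100)
  expect_equal(inflate_cost(100, -0.015, 1), 98.5)
  # loop oracle for repeated annual inflation
  v <- 201
  for (i in 1:5) v <- v * 1.0219
  expect_equal(inflate_cost(201, 0.0219, 5), v)

  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.03, 2), 1 / 1.0609)
  expect_error(discount_factor(0.03, -1), "non-negative")
})

test_that("strategy cost sums attempts and chronic person-years", {
  co <- tiny_cohort()
  costs <- cost_parameters()

  # everyone dead within the first cycle: no attempts after 0, chronic 0
  sudden <- flat_tables(p_nev = c(lung_cancer = 0, copd = 0, cvd = 0),
                        mult = 1, p_all = 1)
  # natural cessation competes with certain death, so only the cycle-0
  # attempt is priced
  tr <- run_cohort(co, fifty_euro_strategy(), sudden, horizon = 3)
  expect_equal(strategy_cost(tr, costs),
               0.0375 * co$size * (14.4 + 50))

  # one full-coverage attempt of weight 1 at cycle 0 costs 132 + 201 = 333
  one <- cohort_spec(tibble::tibble(gender = "male", entry_age = 40, weight = 1))
  tr1 <- run_cohort(one, full_coverage_strategy(participation = 1, attempts = 1),
                    zero_tables(), horizon = 1)
  expect_equal(strategy_cost(tr1, costs), 333)

  # cycle-by-cycle summation oracle on a real trace
  tab <- shared_synthetic_tables()
  trs <- run_cohort(co, full_coverage_strategy(), tab)
  disc <- discount_spec(rate = 0.03)
  got <- strategy_cost(trs, costs, disc)
  oracle <- 0
  strat <- trs$strategy
  for (t in 0:trs$n_cycles) {
    df <- 1 / 1.03^t
    att <- sum(trs$arrays$att[t + 1, ])
    oracle <- oracle + att * (132 * 1.0023^t + 201 * 1.0219^t) * df
    for (d in 1:3) {
      units <- sum(trs$arrays$chronic_units[d, t + 1, ])
      oracle <- oracle + units * costs$chronic[[d]] * 0.985^t * df
    }
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # with zero chronic costs the incremental cost is pure intervention cost
  costs0 <- cost_parameters(chronic = c(lung_cancer = 0, copd = 0, cvd = 0))
  prep <- cessmod:::prepare_cohort_model(co, tab)
  tr_b <- run_cohort(co, fifty_euro_strategy(), tab, prep = prep)
  d_cost <- strategy_cost(trs, costs0, disc) - strategy_cost(tr_b, costs0, disc)
  att_only <- function(tr) {
    s <- tr$strategy
    tt <- 0:tr$n_cycles
    sum(rowSums(tr$arrays$att) *
          (s$visit_cost * 1.0023^tt + s$drug_cost * 1.0219^tt) / 1.03^tt)
  }
  expect_equal(d_cost, att_only(trs) - att_only(tr_b), tolerance = 1e-12)
})

test_that("raising the discount rate lowers both discounted streams", {
  tab <- shared_synthetic_tables()
  co <- tiny_cohort()
  tr <- run_cohort(co, full_coverage_strategy(), tab)
  costs <- cost_parameters()
  ly <- sapply(c(0, 0.03, 0.06), function(r) life_years(tr, discount_spec(rate = r)))
  expect_true(all(diff(ly) < 0))
  cost <- sapply(c(0, 0.03, 0.06), function(r)
    strategy_cost(tr, costs, discount_spec(rate = r)))
  expect_true(all(diff(cost) < 0))
  # per-stream flags reproduce the benefits-at-0% sensitivity
  mixed <- discount_spec(rate = 0.03, discount_benefits = FALSE)
  expect_equal(life_years(tr, mixed), life_years(tr, discount_spec(rate = 0)))
  expect_equal(strategy_cost(tr, costs, mixed),
               strategy_cost(tr, costs, discount_spec(rate = 0.03)))
})

test_that("the ICER quadrant logic labels dominance correctly", {
  r <- compute_icer(100, 0, 50, 0)
  expect_equal(r$icer, 2)
  expect_equal(r$label, "icer")

  saving <- compute_icer(-50, 0, 10, 0)
  expect_equal(saving$label, "cost-saving")
  expect_equal(saving$icer, -5)       # negative ratio retained

  dominated <- compute_icer(10, 0, -1, 0)
  expect_equal(dominated$label, "dominated")
  expect_true(is.na(dominated$icer))

  tie <- compute_icer(10, 0, 0, 0)
  expect_equal(tie$label, "indeterminate")
  expect_true(is.na(tie$icer))

  expect_error(compute_icer(Inf, 0, 1, 0))
})

test_that("the two-arm comparison yields a scale-invariant positive ICER", {
  tab <- shared_synthetic_tables()
  res <- compare_strategies(tiny_cohort(), tab)
  expect_s3_class(res, "cea_result")
  expect_gt(res$delta_ly, 0)
  expect_equal(res$label, "icer")
  g <- glance(res)
  expect_named(g, c("delta_cost", "delta_ly", "icer", "label"))
  t <- tidy(res)
  expect_equal(nrow(t), 2)
  res2 <- compare_strategies(tiny_cohort(2000), tab)
  expect_equal(res2$icer, res$icer, tolerance = 1e-9)
})

test_that("the stratified ICER table covers every stratum", {
  tab <- shared_synthetic_tables()
  co <- cohort_spec(tibble::tibble(gender = c("male", "male", "female"),
                                   entry_age = c(30L, 60L, 45L),
                                   weight = c(400, 300, 300)))
  out <- icer_by_stratum(co, tab)
  expect_equal(nrow(out), 3)
  expect_true(all(is.finite(out$icer)))
  expect_true(all(out$delta_ly > 0))
})
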