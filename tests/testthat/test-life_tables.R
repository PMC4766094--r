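test_that("adjustment ratios multiply entries and compose", {
  tab <- flat_tables()
  # identity ratios leave the schedule unchanged
  r1 <- adjustment_ratios()
  expect_equal(apply_adjustment_ratios(tab$disease, r1), tab$disease)

  # direct multiplication example: 0.002 * 1.2 * 0.9 = 0.00216
  one <- tibble::tibble(gender = "male", age = 40L, status = "current",
                        band_lo = NA_integer_, p_lung = 0.002, p_copd = 0,
                        p_cvd = 0)
  r2 <- adjustment_ratios(spatial = c(lung_cancer = 1.2, copd = 1, cvd = 1),
                          temporal = c(lung_cancer = 0.9, copd = 1, cvd = 1))
  expect_equal(apply_adjustment_ratios(one, r2)$p_lung, 0.00216)

  # element-wise oracle on a random table, and spatial-then-temporal equals
  # the one-pass product
  tabr <- random_tables(11)$disease[1:10, ]
  sp <- c(lung_cancer = 1.3, copd = 0.7, cvd = 1.1)
  tm <- c(lung_cancer = 0.9, copd = 1.2, cvd = 0.8)
  out <- apply_adjustment_ratios(tabr, adjustment_ratios(spatial = sp, temporal = tm))
  oracle <- tabr
  for (i in seq_len(nrow(oracle))) {
    oracle$p_lung[i] <- min(oracle$p_lung[i] * sp[["lung_cancer"]] * tm[["lung_cancer"]], 1)
    oracle$p_copd[i] <- min(oracle$p_copd[i] * sp[["copd"]] * tm[["copd"]], 1)
    oracle$p_cvd[i] <- min(oracle$p_cvd[i] * sp[["cvd"]] * tm[["cvd"]], 1)
  }
  expect_equal(out, oracle)
  prod_once <- apply_adjustment_ratios(
    tabr, adjustment_ratios(spatial = sp * tm,
                            temporal = c(lung_cancer = 1, copd = 1, cvd = 1)))
  expect_equal(out, prod_once)

  # a missing disease ratio is a configuration error naming the disease
  expect_error(adjustment_ratios(spatial = c(lung_cancer = 1.2)), "copd")
})

test_that("former-smoker rates follow the relative-risk bands with a current cap", {
  never <- tibble::tibble(gender = "male", age = 50L, status = "never",
                          band_lo = NA_integer_, p_lung = 0.001, p_copd = 0.002,
                          p_cvd = 0.003)
  unit_rr <- fixture_rr(rep(1, 5))
  frm <- derive_former_smoker_rates(never, unit_rr)
  expect_equal(unique(frm$p_lung), 0.001)
  expect_equal(unique(frm$p_copd), 0.002)

  # never 0.001 with RR 2.5 in band [3,6) gives 0.0025
  rr <- fixture_rr(c(3, 2.5, 2, 1.5, 1))
  frm <- derive_former_smoker_rates(never, rr)
  expect_equal(frm$p_lung[frm$band_lo == 3], 0.0025)

  # cap at the current-smoker rate
  current <- never |> dplyr::mutate(status = "current", p_lung = 0.002)
  capped <- derive_former_smoker_rates(never, rr, current = current)
  expect_equal(capped$p_lung[capped$band_lo == 1], 0.002)  # 0.003 capped

  expect_error(derive_former_smoker_rates(never, rr[0, ]), "no bands")
})

test_that("former rates are non-increasing in duration for monotone RR schedules", {
  for (seed in 1:5) {
    tab <- random_tables(seed)
    frm <- tab$disease |> dplyr::filter(status == "former") |>
      dplyr::arrange(gender, age, band_lo)
    for (col in c("p_lung", "p_copd", "p_cvd")) {
      mono <- tapply(frm[[col]], paste(frm$gender, frm$age),
                     function(v) all(diff(v) <= 1e-15))
      expect_true(all(mono))
    }
  }
})

test_that("female rates derive from male rates by the configured ratios", {
  male <- flat_tables()$disease |> dplyr::filter(gender == "male")
  r1 <- adjustment_ratios()
  expect_equal(derive_female_rates(male, r1) |> dplyr::mutate(gender = "male"), male)

  one <- male[male$status == "current", ][1, ]
  one$p_lung <- 0.004
  r2 <- adjustment_ratios(female_male_lung_ratio = 0.5)
  expect_equal(derive_female_rates(one, r2)$p_lung, 0.002)

  # element-wise oracle on a full table with all three ratios
  r3 <- adjustment_ratios(female_male_lung_ratio = 0.4,
                          gender_ratios = c(copd = 0.8, cvd = 0.9))
  fem <- derive_female_rates(male, r3)
  expect_equal(fem$p_lung, pmin(male$p_lung * 0.4, 1))
  expect_equal(fem$p_copd, pmin(male$p_copd * 0.8, 1))
  expect_equal(fem$p_cvd, pmin(male$p_cvd * 0.9, 1))
  expect_true(all(fem$gender == "female"))

  expect_error(adjustment_ratios(female_male_lung_ratio = -1), "positive")
})

test_that("other-cause residual subtracts the status-specific disease sum", {
  tab <- flat_tables()
  # all-cause 0.02, never diseases 0.001+0.001+0.002
  res <- residual_other_cause_mortality(tab, "never")
  expect_equal(unique(res$p_other), 0.02 - 0.004)

  # zero diseases leave the full all-cause rate
  res0 <- residual_other_cause_mortality(zero_tables(), "current")
  expect_equal(unique(res0$p_other), 0)

  # conservation oracle on random tables: residual + disease sum = all-cause
  for (seed in 6:8) {
    tabr <- random_tables(seed)
    for (st in c("never", "current")) {
      res <- residual_other_cause_mortality(tabr, st)
      dis <- tabr$disease |> dplyr::filter(status == st)
      recon <- res$p_other + dis$p_lung + dis$p_copd + dis$p_cvd
      ac <- tabr$all_cause$p_allcause[match(paste(res$gender, res$age),
                                            paste(tabr$all_cause$gender,
                                                  tabr$all_cause$age))]
      expect_equal(recon, ac, tolerance = 1e-14)
    }
  }

  # an inconsistent table reports the offending key
  bad <- flat_tables()
  bad$all_cause$p_allcause <- 0.001
  expect_error(residual_other_cause_mortality(
    mortality_tables(bad$disease, bad$all_cause, bad$rr, validate = FALSE),
    "current"), "age=15")
})

test_that("synthetic tables are reproducible, invariant-satisfying, and round-trip", {
  p <- synthetic_table_params(seed = 42)
  t1 <- generate_synthetic_tables(p)
  t2 <- generate_synthetic_tables(p)
  expect_identical(t1, t2)

  # a different seed perturbs the disease schedule
  t3 <- generate_synthetic_tables(synthetic_table_params(seed = 43))
  expect_false(identical(t1$disease, t3$disease))

  # invariants are enforced by the constructor; run the validator explicitly
  expect_silent(cessmod:::validate_mortality_tables(t1))
  expect_setequal(unique(t1$disease$status), c("never", "current", "former"))
  expect_equal(range(t1$all_cause$age), c(15, 110))

  # zero disease shares degenerate to pure all-cause mortality
  tz <- generate_synthetic_tables(synthetic_table_params(
    disease_shares = c(lung_cancer = 0, copd = 0, cvd = 0),
    current_multipliers = c(lung_cancer = 1, copd = 1, cvd = 1)))
  expect_true(all(tz$disease[c("p_lung", "p_copd", "p_cvd")] == 0))
  res <- residual_other_cause_mortality(tz, "current")
  ac <- tz$all_cause$p_allcause[match(paste(res$gender, res$age),
                                      paste(tz$all_cause$gender, tz$all_cause$age))]
  expect_equal(res$p_other, ac)

  # share constraints are rejected
  expect_error(synthetic_table_params(
    disease_shares = c(lung_cancer = 0.5, copd = 0.3, cvd = 0.3)), "below 1")

  # CSV round-trip preserves values
  dir <- withr::local_tempdir()
  paths <- write_life_tables(t1, dir)
  back <- read_life_tables(paths[1], paths[2], paths[3])
  expect_equal(back$disease, t1$disease)
  expect_equal(back$all_cause, t1$all_cause)
  expect_equal(back$rr, t1$rr)
})

test_that("life expectancy calibration hits the configured targets", {
  tab <- shared_synthetic_tables()
  for (g in c("male", "female")) {
    target <- synthetic_table_params()$le20_target[[g]]
    q <- tab$all_cause$p_allcause[tab$all_cause$gender == g & tab$all_cause$age >= 20]
    le <- cessmod:::le_from_schedule(q)
    expect_equal(le, target, tolerance = 1e-6)
  }
})
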