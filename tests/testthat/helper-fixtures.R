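# Fixtures built in code: small consistent life tables and cohorts.

fixture_rr <- function(vals = c(1.8, 1.5, 1.3, 1.15, 1.05)) {
  purrr::map_dfr(c("lung_cancer", "copd", "cvd"), function(d)
    tibble::tibble(disease = d, band_lo = c(1L, 3L, 6L, 11L, 16L),
                   band_hi = c(3, 6, 11, 16, Inf), rr = vals))
}

# Age-constant tables: never rates p_nev per disease, current = mult * never,
# former from the rr schedule, all-cause constant p_all.
flat_tables <- function(p_nev = c(lung_cancer = 0.001, copd = 0.001, cvd = 0.002),
                        mult = 2, p_all = 0.02,
                        rr = fixture_rr()) {
  ages <- 15:110
  never <- purrr::map_dfr(c("male", "female"), function(g)
    tibble::tibble(gender = g, age = ages, status = "never", band_lo = NA_integer_,
                   p_lung = p_nev[["lung_cancer"]], p_copd = p_nev[["copd"]],
                   p_cvd = p_nev[["cvd"]]))
  current <- never |> dplyr::mutate(status = "current",
                                    p_lung = p_lung * mult,
                                    p_copd = p_copd * mult,
                                    p_cvd = p_cvd * mult)
  former <- derive_former_smoker_rates(never, rr, current = current)
  all_cause <- purrr::map_dfr(c("male", "female"), function(g)
    tibble::tibble(gender = g, age = ages, p_allcause = p_all))
  mortality_tables(dplyr::bind_rows(never, current, former), all_cause, rr)
}

zero_tables <- function() {
  flat_tables(p_nev = c(lung_cancer = 0, copd = 0, cvd = 0), mult = 1, p_all = 0)
}

# Random but invariant-consistent tables (age-varying rates).
random_tables <- function(seed) {
  withr::with_seed(seed, {
    ages <- 15:110
    n <- length(ages)
    rr_vals <- sort(runif(5, 1, 2.5), decreasing = TRUE)
    rr <- fixture_rr(rr_vals)
    parts <- purrr::map(c("male", "female"), function(g) {
      nev <- tibble::tibble(gender = g, age = ages, status = "never",
                            band_lo = NA_integer_,
                            p_lung = runif(n, 0, 0.004),
                            p_copd = runif(n, 0, 0.004),
                            p_cvd = runif(n, 0, 0.008))
      mult <- runif(3, 1, 4)
      cur <- nev |> dplyr::mutate(status = "current",
                                  p_lung = p_lung * mult[1],
                                  p_copd = p_copd * mult[2],
                                  p_cvd = p_cvd * mult[3])
      frm <- derive_former_smoker_rates(nev, rr, current = cur)
      cur_sum <- cur$p_lung + cur$p_copd + cur$p_cvd
      all_cause <- tibble::tibble(gender = g, age = ages,
                                  p_allcause = pmin(cur_sum * runif(n, 1.2, 3) +
                                                      runif(n, 0.001, 0.02), 0.95))
      list(disease = dplyr::bind_rows(nev, cur, frm), all_cause = all_cause)
    })
    mortality_tables(dplyr::bind_rows(purrr::map(parts, "disease")),
                     dplyr::bind_rows(purrr::map(parts, "all_cause")), rr)
  })
}

tiny_cohort <- function(size = 1000) {
  cohort_spec(tibble::tibble(gender = c("male", "female"),
                             entry_age = c(40L, 50L),
                             weight = c(0.6, 0.4) * size))
}

# shared synthetic tables for the heavier tests (built once per test run)
shared_synthetic_tables <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- generate_synthetic_tables()
    tab
  }
})
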