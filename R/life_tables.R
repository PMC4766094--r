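# Mortality life tables stratified by gender, single year of age and smoking
# status, for the three major smoking-related diseases (lung cancer, COPD,
# cardiovascular disease) plus an all-cause schedule from which the
# other-cause residual is derived.
#
# Disease schedules are tibbles with columns
#   gender, age, status, band_lo, p_lung, p_copd, p_cvd
# where status is one of "never", "current", "former"; band_lo is the lower
# edge (completed years since cessation) of the relative-risk band for
# former-smoker rows and NA otherwise. Rates are annual death probabilities.

.genders <- c("male", "female")
.age_grid <- 15:110

#' Relative-risk bands by duration of cessation
#'
#' Default half-open duration bands (completed years since quitting) over
#' which the former-smoker relative risk versus never smokers is piecewise
#' constant. The last band is unbounded and acts as the asymptotic floor.
#'
#' @return Integer vector of band lower edges.
#' @keywords internal
default_rr_bands <- function() {
  tibble(band_lo = c(1L, 3L, 6L, 11L, 16L),
         band_hi = c(3, 6, 11, 16, Inf))
}

#' Construct a mortality-tables object
#'
#' Bundles the disease-specific schedule, the all-cause schedule and the
#' former-smoker relative-risk schedule, and checks the epidemiological
#' invariants they must satisfy before the cohort engine will accept them.
#'
#' @param disease Tibble with columns `gender`, `age`, `status`, `band_lo`,
#'   `p_lung`, `p_copd`, `p_cvd`; one row per (gender, age) for `never` and
#'   `current` status and one per relative-risk band for `former`.
#' @param all_cause Tibble with columns `gender`, `age`, `p_allcause`.
#' @param rr Tibble with columns `disease`, `band_lo`, `band_hi`, `rr`.
#' @param validate Run the invariant checks (default `TRUE`).
#'
#' @details Invariants enforced: all probabilities in \[0, 1\]; the three
#' disease probabilities sum to at most 1 at every key; at fixed
#' (gender, age, disease) the current-smoker probability is at least the
#' former-smoker probability in every band, which is at least the
#' never-smoker probability; former-smoker probabilities are non-increasing
#' in time since cessation; and the all-cause probability is at least the
#' disease sum for every status, so the other-cause residual is non-negative.
#'
#' @return An object of class `mortality_tables`.
#' @export
mortality_tables <- function(disease, all_cause, rr, validate = TRUE) {
  disease <- as_tibble(disease)
  all_cause <- as_tibble(all_cause)
  rr <- as_tibble(rr)
  out <- structure(list(disease = disease, all_cause = all_cause, rr = rr),
                   class = "mortality_tables")
  if (validate) validate_mortality_tables(out)
  out
}

#' @export
print.mortality_tables <- function(x, ...) {
  ages <- range(x$all_cause$age)
  cat("<mortality_tables>\n")
  cat("  ages", ages[1], "-", ages[2], "; genders:",
      paste(unique(x$all_cause$gender), collapse = ", "), "\n")
  cat("  former-smoker RR bands:", nrow(dplyr::distinct(x$rr, .data$band_lo)),
      "per disease\n")
  invisible(x)
}

validate_mortality_tables <- function(tables) {
  dis <- tables$disease
  ac <- tables$all_cause
  rr <- tables$rr
  pcols <- unname(.disease_cols)

  pm <- as.matrix(dis[pcols])
  if (any(pm < 0 | pm > 1)) {
    abort("disease probabilities must lie in [0, 1]")
  }
  if (any(rowSums(pm) > 1 + 1e-12)) {
    abort("disease probabilities must sum to at most 1 at every key")
  }
  if (any(ac$p_allcause < 0 | ac$p_allcause > 1)) {
    abort("all-cause probabilities must lie in [0, 1]")
  }

  # ordering: current >= former(band) >= never, former non-increasing in band
  nev <- dis |> filter(.data$status == "never") |> arrange(.data$gender, .data$age)
  cur <- dis |> filter(.data$status == "current") |> arrange(.data$gender, .data$age)
  if (nrow(nev) != nrow(cur)) abort("never and current rows must cover the same keys")
  for (col in pcols) {
    if (any(cur[[col]] < nev[[col]] - 1e-12)) {
      abort(paste0("current-smoker probability below never-smoker for ", col))
    }
  }
  frm <- dis |> filter(.data$status == "former") |> arrange(.data$gender, .data$age, .data$band_lo)
  if (nrow(frm) > 0) {
    key <- paste(frm$gender, frm$age)
    for (col in pcols) {
      v <- frm[[col]]
      nv <- nev[[col]][match(paste(frm$gender, frm$age), paste(nev$gender, nev$age))]
      cv <- cur[[col]][match(paste(frm$gender, frm$age), paste(cur$gender, cur$age))]
      if (any(v > cv + 1e-12) || any(v < nv - 1e-12)) {
        abort(paste0("former-smoker probability outside [never, current] for ", col))
      }
      # non-increasing within key as band_lo grows
      mono <- tapply(v, key, function(z) all(diff(z) <= 1e-12))
      if (!all(mono)) {
        abort(paste0("former-smoker probability must be non-increasing in years since quitting for ", col))
      }
    }
  }

  if (any(rr$rr < 1 - 1e-12)) abort("relative risks must be >= 1 in every band")
  bad <- rr |> group_by(.data$disease) |>
    summarise(ok = all(diff(.data$rr) <= 1e-12), .groups = "drop")
  if (!all(bad$ok)) abort("relative risks must be non-increasing across bands")

  # residual feasibility for every status present
  for (st in unique(dis$status)) {
    sub <- dis |> filter(.data$status == st)
    s <- rowSums(as.matrix(sub[pcols]))
    acm <- ac$p_allcause[match(paste(sub$gender, sub$age), paste(ac$gender, ac$age))]
    neg <- which(s > acm + 1e-12)
    if (length(neg) > 0) {
      k <- neg[1]
      abort(sprintf(
        "all-cause mortality below disease sum at gender=%s age=%d status=%s",
        sub$gender[k], sub$age[k], st))
    }
  }
  invisible(tables)
}

#' Spatial/temporal and gender adjustment ratios
#'
#' Per-disease multiplicative adjustments used to transport an external
#' cohort's mortality rates to the target setting: a spatial ratio
#' (target country / source country at a common year) and a temporal ratio
#' (target country recent year / earlier year), plus the male-to-female
#' lung-cancer death ratio used to derive female rates from male rates.
#'
#' @param spatial,temporal Named numeric vectors with one positive entry per
#'   disease (`lung_cancer`, `copd`, `cvd`).
#' @param female_male_lung_ratio Positive scalar: female/male lung-cancer
#'   death ratio.
#' @param gender_ratios Named positive scalars for `copd` and `cvd` female
#'   scaling (default 1: only the lung-cancer differential is applied).
#' @return An object of class `adjustment_ratios`.
#' @export
adjustment_ratios <- function(spatial = c(lung_cancer = 1, copd = 1, cvd = 1),
                              temporal = c(lung_cancer = 1, copd = 1, cvd = 1),
                              female_male_lung_ratio = 1,
                              gender_ratios = c(copd = 1, cvd = 1)) {
  for (d in .diseases) {
    if (is.na(spatial[d])) abort(paste0("missing spatial ratio for disease ", d))
    if (is.na(temporal[d])) abort(paste0("missing temporal ratio for disease ", d))
  }
  if (any(c(spatial, temporal) <= 0)) abort("adjustment ratios must be positive")
  if (female_male_lung_ratio <= 0) abort("female_male_lung_ratio must be positive")
  if (any(gender_ratios <= 0)) abort("gender ratios must be positive")
  structure(list(spatial = spatial[.diseases], temporal = temporal[.diseases],
                 female_male_lung_ratio = female_male_lung_ratio,
                 gender_ratios = gender_ratios),
            class = "adjustment_ratios")
}

#' Apply spatial and temporal adjustment ratios to a disease schedule
#'
#' Multiplies every disease-specific probability by that disease's spatial
#' ratio and then its temporal ratio. Probabilities pushed above 1 are
#' clipped with a warning. Applying both ratios is equivalent to applying
#' their product in a single pass.
#'
#' @param disease A disease schedule tibble (or a `mortality_tables` object,
#'   whose disease component is adjusted in place).
#' @param ratios An [adjustment_ratios()] object.
#' @return Same type as `disease`, with adjusted probabilities.
#' @export
apply_adjustment_ratios <- function(disease, ratios) {
  if (inherits(disease, "mortality_tables")) {
    disease$disease <- apply_adjustment_ratios(disease$disease, ratios)
    return(disease)
  }
  stopifnot(inherits(ratios, "adjustment_ratios"))
  out <- as_tibble(disease)
  clipped <- FALSE
  for (d in .diseases) {
    col <- .disease_cols[[d]]
    v <- out[[col]] * ratios$spatial[[d]] * ratios$temporal[[d]]
    if (any(v > 1)) clipped <- TRUE
    out[[col]] <- pmin(v, 1)
  }
  if (clipped) warn("adjusted probabilities exceeded 1 and were clipped")
  out
}

#' Derive former-smoker rates from never-smoker rates and relative risks
#'
#' For each relative-risk band, the former-smoker probability is the
#' never-smoker probability times the band's relative risk, capped at the
#' current-smoker probability at the same (gender, age) key. Durations below
#' one completed year fall in the first band; durations beyond the last band
#' use the last band's floor.
#'
#' @param never Disease schedule rows with `status == "never"`.
#' @param rr Relative-risk tibble (`disease`, `band_lo`, `band_hi`, `rr`).
#' @param current Optional `status == "current"` rows used as the cap; if
#'   omitted no cap is applied.
#' @return Former-smoker rows of a disease schedule, one per band.
#' @export
derive_former_smoker_rates <- function(never, rr, current = NULL) {
  if (nrow(rr) == 0) abort("relative-risk schedule has no bands")
  never <- as_tibble(never)
  bands <- rr |> distinct(.data$band_lo) |> arrange(.data$band_lo) |> pull(.data$band_lo)
  out <- purrr::map(bands, function(b) {
    res <- never
    res$status <- "former"
    res$band_lo <- b
    for (d in .diseases) {
      col <- .disease_cols[[d]]
      r <- rr$rr[rr$disease == d & rr$band_lo == b]
      if (length(r) != 1) abort(paste0("missing relative risk for disease ", d, " band ", b))
      res[[col]] <- pmin(never[[col]] * r, 1)
    }
    res
  }) |> bind_rows()
  if (!is.null(current)) {
    current <- as_tibble(current)
    idx <- match(paste(out$gender, out$age), paste(current$gender, current$age))
    for (col in unname(.disease_cols)) {
      out[[col]] <- pmin(out[[col]], current[[col]][idx])
    }
  }
  out
}

#' Derive female rates from male rates
#'
#' Scales male lung-cancer probabilities by the female/male lung-cancer
#' death ratio; COPD and CVD are scaled by their configured gender ratios
#' (default 1, i.e. unchanged).
#'
#' @param male Disease schedule rows with `gender == "male"`.
#' @param ratios An [adjustment_ratios()] object.
#' @return The corresponding `gender == "female"` rows.
#' @export
derive_female_rates <- function(male, ratios) {
  stopifnot(inherits(ratios, "adjustment_ratios"))
  out <- as_tibble(male)
  out$gender <- "female"
  out$p_lung <- pmin(out$p_lung * ratios$female_male_lung_ratio, 1)
  out$p_copd <- pmin(out$p_copd * ratios$gender_ratios[["copd"]], 1)
  out$p_cvd <- pmin(out$p_cvd * ratios$gender_ratios[["cvd"]], 1)
  out
}

#' Other-cause residual mortality
#'
#' Subtracts the three disease-specific probabilities for the given smoking
#' status from the all-cause probability, giving the annual probability of
#' death from any other cause. Errors if the residual would be negative,
#' naming the offending key.
#'
#' @param tables A `mortality_tables` object.
#' @param status `"never"`, `"current"` or `"former"`; for former smokers
#'   one residual per relative-risk band is returned.
#' @return Tibble `gender`, `age`, (`band_lo`,) `p_other`.
#' @export
residual_other_cause_mortality <- function(tables, status = c("current", "never", "former")) {
  status <- match.arg(status)
  dis <- tables$disease |> filter(.data$status == !!status)
  ac <- tables$all_cause
  idx <- match(paste(dis$gender, dis$age), paste(ac$gender, ac$age))
  res <- ac$p_allcause[idx] - rowSums(as.matrix(dis[unname(.disease_cols)]))
  neg <- which(res < -1e-12)
  if (length(neg) > 0) {
    k <- neg[1]
    abort(sprintf("negative other-cause residual at gender=%s age=%d status=%s",
                  dis$gender[k], dis$age[k], status))
  }
  out <- dis |> select("gender", "age", dplyr::any_of("band_lo"))
  out$p_other <- pmax(res, 0)
  if (status != "former") out$band_lo <- NULL
  out
}

#' Parameters of the synthetic life-table generator
#'
#' The generator emulates the stratified mortality schedules the model
#' needs when transcribed national tables are not supplied: a Gompertz
#' (log-linear in age) all-cause baseline per gender calibrated so that
#' life expectancy at age 20 matches the stated targets; disease-specific
#' never-smoker mortality as a fixed share of all-cause mortality, with
#' small seeded multiplicative jitter; current-smoker excess risk as a
#' per-disease multiplier; and former-smoker relative risks decaying
#' exponentially with time since cessation toward an asymptotic floor.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param le20_target Named target remaining life expectancy at age 20
#'   (years, general population) used to calibrate the Gompertz intercept.
#' @param gompertz_slope Named per-gender Gompertz slope (per year of age).
#' @param disease_shares Share of all-cause mortality attributable to each
#'   disease among never smokers; must sum to below 1.
#' @param current_multipliers Current-vs-never risk multipliers per disease
#'   (all at least 1).
#' @param rr_decay_years E-folding time (years) of the former-smoker excess
#'   risk decay.
#' @param rr_floor Asymptotic relative risk in the last duration band.
#' @param jitter Half-width of the uniform multiplicative jitter applied to
#'   never-smoker disease rates (0 disables it).
#' @return An object of class `synthetic_table_params`.
#' @export
synthetic_table_params <- function(seed = 20090L,
                                   le20_target = c(male = 56, female = 63.4),
                                   gompertz_slope = c(male = 0.074, female = 0.080),
                                   disease_shares = c(lung_cancer = 0.022, copd = 0.004, cvd = 0.025),
                                   current_multipliers = c(lung_cancer = 38, copd = 10, cvd = 3),
                                   rr_decay_years = 7,
                                   rr_floor = 1.05,
                                   jitter = 0.02) {
  if (sum(disease_shares) >= 1) abort("disease shares must sum to below 1")
  if (any(current_multipliers < 1)) abort("current-smoker multipliers must be >= 1")
  if (sum(disease_shares * current_multipliers) * (1 + jitter) >= 1) {
    abort("disease shares times multipliers too large: current-smoker disease sum would exceed all-cause mortality")
  }
  if (rr_floor < 1) abort("rr_floor must be >= 1")
  if (rr_decay_years <= 0) abort("rr_decay_years must be positive")
  if (jitter < 0 || jitter >= 0.5) abort("jitter must lie in [0, 0.5)")
  structure(list(seed = as.integer(seed), le20_target = le20_target,
                 gompertz_slope = gompertz_slope, disease_shares = disease_shares,
                 current_multipliers = current_multipliers,
                 rr_decay_years = rr_decay_years, rr_floor = rr_floor,
                 jitter = jitter),
            class = "synthetic_table_params")
}

# Remaining life expectancy implied by a vector of annual death
# probabilities, crediting one year per cycle survived into (the same
# convention the cohort engine uses for life-years).
le_from_schedule <- function(q) {
  surv <- cumprod(1 - q)
  1 + sum(head(surv, -1))
}

# Calibrate the Gompertz intercept so remaining LE at age 20 hits target.
calibrate_gompertz_intercept <- function(target, slope, ages = 20:110) {
  f <- function(log_a) {
    q <- pmin(exp(log_a) * exp(slope * ages), 0.97)
    le_from_schedule(q) - target
  }
  uniroot(f, lower = log(1e-9), upper = log(1e-2), tol = 1e-12)$root |> exp()
}

#' Generate synthetic stratified life tables
#'
#' Builds the disease-specific schedule, the all-cause schedule and the
#' former-smoker relative-risk schedule over ages 15 to 110 for both
#' genders, satisfying every schedule invariant, deterministically for a
#' given seed. See [synthetic_table_params()] for the generating model.
#'
#' @param params A [synthetic_table_params()] object.
#' @return A [mortality_tables()] object.
#' @export
generate_synthetic_tables <- function(params = synthetic_table_params()) {
  stopifnot(inherits(params, "synthetic_table_params"))
  bands <- default_rr_bands()
  mids <- ifelse(is.finite(bands$band_hi), (bands$band_lo + bands$band_hi) / 2,
                 bands$band_lo + 2)
  rr <- purrr::map(.diseases, function(d) {
    m <- params$current_multipliers[[d]]
    r <- 1 + (m - 1) * exp(-mids / params$rr_decay_years)
    r <- pmax(pmin(r, m), params$rr_floor)
    r <- rev(cummax(rev(r)))  # enforce non-increasing across bands
    tibble(disease = d, band_lo = bands$band_lo, band_hi = bands$band_hi, rr = r)
  }) |> bind_rows()

  withr::with_seed(params$seed, {
    parts <- purrr::map(.genders, function(g) {
      slope <- params$gompertz_slope[[g]]
      a <- calibrate_gompertz_intercept(params$le20_target[[g]], slope)
      q_all <- pmin(a * exp(slope * .age_grid), 0.97)
      jit <- matrix(runif(length(.age_grid) * 3,
                          1 - params$jitter, 1 + params$jitter),
                    ncol = 3)
      nev <- tibble(gender = g, age = .age_grid, status = "never",
                    band_lo = NA_integer_)
      for (i in seq_along(.diseases)) {
        col <- .disease_cols[[.diseases[i]]]
        nev[[col]] <- params$disease_shares[[.diseases[i]]] * q_all * jit[, i]
      }
      cur <- nev
      cur$status <- "current"
      for (d in .diseases) {
        col <- .disease_cols[[d]]
        cur[[col]] <- nev[[col]] * params$current_multipliers[[d]]
      }
      frm <- derive_former_smoker_rates(nev, rr, current = cur)
      list(disease = bind_rows(nev, cur, frm),
           all_cause = tibble(gender = g, age = .age_grid, p_allcause = q_all))
    })
  })
  mortality_tables(disease = bind_rows(purrr::map(parts, "disease")),
                   all_cause = bind_rows(purrr::map(parts, "all_cause")),
                   rr = rr)
}

# ---- CSV round-trip -------------------------------------------------------

band_label <- function(band_lo) {
  bands <- default_rr_bands()
  hi <- bands$band_hi[match(band_lo, bands$band_lo)]
  ifelse(is.na(band_lo), NA_character_,
         paste0("[", band_lo, ",", ifelse(is.finite(hi), hi, "Inf"), ")"))
}

parse_band_label <- function(x) {
  as.integer(sub("^\\[(\\d+),.*$", "\\1", x))
}

#' Write life tables to CSV files
#'
#' Writes three UTF-8 CSV files: `life_table_disease.csv` with columns
#' `gender, age, status, years_since_quit_band, p_lung, p_copd, p_cvd`;
#' `life_table_allcause.csv` with `gender, age, p_allcause`; and
#' `life_table_rr.csv` with `disease, band_lo, band_hi, rr`.
#'
#' @param tables A `mortality_tables` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_life_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("life_table_disease.csv", "life_table_allcause.csv",
                            "life_table_rr.csv"))
  dis <- tables$disease |>
    mutate(years_since_quit_band = band_label(.data$band_lo)) |>
    select("gender", "age", "status", "years_since_quit_band",
           "p_lung", "p_copd", "p_cvd")
  readr::write_csv(dis, paths[1])
  readr::write_csv(tables$all_cause, paths[2])
  readr::write_csv(tables$rr, paths[3])
  invisible(paths)
}

#' Read life tables from CSV files
#'
#' Inverse of [write_life_tables()]; values round-trip to full stored
#' precision.
#'
#' @param disease_csv,all_cause_csv,rr_csv File paths as written by
#'   [write_life_tables()].
#' @param validate Check invariants on the assembled object.
#' @return A `mortality_tables` object.
#' @export
read_life_tables <- function(disease_csv, all_cause_csv, rr_csv, validate = TRUE) {
  dis <- readr::read_csv(disease_csv, show_col_types = FALSE) |>
    mutate(band_lo = parse_band_label(.data$years_since_quit_band)) |>
    select("gender", "age", "status", "band_lo", "p_lung", "p_copd", "p_cvd")
  ac <- readr::read_csv(all_cause_csv, show_col_types = FALSE)
  rr <- readr::read_csv(rr_csv, show_col_types = FALSE)
  mortality_tables(dis, ac, rr, validate = validate)
}
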