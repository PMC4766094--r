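# Six-state cohort engine: smoker (S), former smoker (F, tunnel sub-states
# by completed years since cessation), lung cancer (C), COPD (O), CVD (V)
# and dead (D, absorbing). One-year cycles; ages advance one year per cycle;
# the cohort starts entirely in S. Disease states are terminal-track: the
# annual death probability is fixed by the age band and smoking status at
# diagnosis, converted from the post-diagnosis life expectancy.

.states <- c("S", "F", "C", "O", "V", "D")
.causes <- c(.diseases, "other")
.max_age <- 110L

# ---- compiled table representation ---------------------------------------

# Turn the tidy tables into per-gender matrices indexed by age for fast
# cycle-loop lookups.
compile_tables <- function(tables) {
  bands <- tables$rr |> distinct(.data$band_lo) |> arrange(.data$band_lo) |> pull(.data$band_lo)
  nb <- length(bands)
  ages <- sort(unique(tables$all_cause$age))
  n_age <- length(ages)
  out <- list(bands = bands, ages = ages)
  for (g in unique(tables$all_cause$gender)) {
    ac <- tables$all_cause |> filter(.data$gender == g) |> arrange(.data$age)
    dis <- tables$disease |> filter(.data$gender == g)
    getm <- function(st) {
      sub <- dis |> filter(.data$status == st) |> arrange(.data$age)
      t(as.matrix(sub[unname(.disease_cols)]))  # 3 x n_age
    }
    nev <- getm("never")
    cur <- getm("current")
    frm <- array(0, c(3, nb, n_age))
    for (b in seq_len(nb)) {
      sub <- dis |> filter(.data$status == "former", .data$band_lo == bands[b]) |>
        arrange(.data$age)
      frm[, b, ] <- t(as.matrix(sub[unname(.disease_cols)]))
    }
    all_q <- ac$p_allcause
    res_cur <- all_q - colSums(cur)
    res_nev <- all_q - colSums(nev)
    res_frm <- matrix(0, nb, n_age)
    for (b in seq_len(nb)) res_frm[b, ] <- all_q - colSums(frm[, b, ])
    if (min(res_cur, res_nev, res_frm) < -1e-12) {
      abort("all-cause mortality below disease sum; tables are inconsistent")
    }
    out[[g]] <- list(nev = nev, cur = cur, frm = frm, all = all_q,
                     res_cur = pmax(res_cur, 0), res_nev = pmax(res_nev, 0),
                     res_frm = pmax(res_frm, 0))
  }
  out
}

# Map completed years since cessation to a band index (d < 1 uses band 1;
# beyond the last band, the last band).
band_of_duration <- function(d, bands) {
  pmax(findInterval(d, bands), 1L)
}

# ---- model preparation ----------------------------------------------------

# Pre-compute, for every stratum and cycle, the disease/other-cause
# probabilities and the disease compartment (distinct disease x LE pair)
# that an incident diagnosis enters. Everything here is independent of the
# strategy, so PSA iterations can reuse one prepared object.
prepare_cohort_model <- function(cohort, tables, survival = disease_survival_spec(),
                                 status_override = NULL, horizon = "lifetime") {
  stopifnot(inherits(cohort, "cohort_spec"))
  ct <- compile_tables(tables)
  strata <- cohort$strata
  S <- nrow(strata)
  entry <- strata$entry_age
  if (identical(horizon, "lifetime")) {
    Tmax <- .max_age - min(entry) + 1L
  } else {
    Tmax <- as.integer(horizon)
    if (Tmax < 1) abort("horizon must be >= 1 cycle or \"lifetime\"")
  }
  bands <- ct$bands
  nb <- length(bands)
  n_F <- max(bands)                 # tunnel advances up to the last band's edge
  band_of <- band_of_duration(seq_len(n_F), bands)

  comps <- survival$table |> distinct(.data$disease, .data$le) |>
    arrange(.data$disease, .data$le)
  comps$p_death <- annual_death_probability_from_life_expectancy(comps$le, survival$conversion)
  nC <- nrow(comps)
  comp_id <- function(dis, le) {
    match(paste(dis, le), paste(comps$disease, comps$le))
  }

  smoker_status <- status_override %||% "current"
  PC <- array(0, c(3, Tmax, S))      # disease probs in the smoking state
  RESC <- matrix(0, Tmax, S)
  PF <- array(0, c(3, nb, Tmax, S))
  RESF <- array(0, c(nb, Tmax, S))
  CIS <- array(NA_integer_, c(3, Tmax, S))
  CIF <- array(NA_integer_, c(3, Tmax, S))
  age_mat <- matrix(0L, Tmax, S)
  for (s in seq_len(S)) {
    g <- strata$gender[s]
    gt <- ct[[g]]
    if (is.null(gt)) abort(paste0("tables do not cover gender ", g))
    ages_t <- entry[s] + 0:(Tmax - 1)
    age_mat[, s] <- ages_t
    valid <- ages_t <= .max_age
    ai <- match(pmin(ages_t, .max_age), ct$ages)
    if (anyNA(ai[valid])) abort(paste0("tables do not cover ages reached by stratum ",
                                       strata$stratum[s]))
    # other-cause mortality is smoking-independent: the never-smoker
    # residual applies to every living state, so current/former excess
    # disease mortality adds on top of it (capped so rows stay proper)
    src <- if (smoker_status == "never") gt$nev else gt$cur
    PC[, , s] <- src[, ai]
    RESC[, s] <- pmin(gt$res_nev[ai], pmax(1 - colSums(src[, ai, drop = FALSE]), 0))
    for (b in seq_len(nb)) {
      PF[, b, , s] <- gt$frm[, b, ai]
      RESF[b, , s] <- pmin(gt$res_nev[ai],
                           pmax(1 - colSums(gt$frm[, b, ai, drop = FALSE]), 0))
    }
    for (d in seq_along(.diseases)) {
      le_s <- lookup_le(survival, .diseases[d], rep(smoker_status, Tmax), pmin(ages_t, .max_age))
      CIS[d, , s] <- comp_id(.diseases[d], le_s)
      le_f <- lookup_le(survival, .diseases[d], rep("former", Tmax), pmin(ages_t, .max_age))
      CIF[d, , s] <- comp_id(.diseases[d], le_f)
    }
  }
  list(cohort = cohort, survival = survival, status_override = status_override,
       Tmax = Tmax, lifetime = identical(horizon, "lifetime"),
       S = S, nb = nb, n_F = n_F, band_of = band_of, comps = comps, nC = nC,
       PC = PC, RESC = RESC, PF = PF, RESF = RESF, CIS = CIS, CIF = CIF,
       age_mat = age_mat)
}

# ---- transition rows (desk-scale interface) -------------------------------

#' Build one transition row of the cohort model
#'
#' Assembles the one-cycle transition probabilities out of a given origin
#' state for a given gender, age and cycle, exactly as the cohort engine
#' applies them. Rows sum to 1 to machine precision; a negative remainder
#' (over-allocated probabilities) raises an error naming the key.
#'
#' @param origin One of `"S"`, `"F"`, `"C"`, `"O"`, `"V"`, `"D"`.
#' @param gender,age Stratum key.
#' @param cycle Cycle index (0-based), used for attempt scheduling.
#' @param strategy A [strategy_spec()]; governs the cessation probability a
#'   smoker faces this cycle.
#' @param tables A [mortality_tables()] object.
#' @param survival A [disease_survival_spec()].
#' @param participant Does the smoker belong to the covered program?
#' @param years_since_quit Completed years since cessation (former smokers).
#' @param dx_age,dx_status Age and smoking status at diagnosis (disease
#'   origins); default to `age` and `"current"`.
#' @return Tibble with columns `state` and `prob` over the six destinations.
#' @export
build_transition_row <- function(origin, gender, age, cycle, strategy, tables,
                                 survival = disease_survival_spec(),
                                 participant = FALSE, years_since_quit = 1,
                                 dx_age = NULL, dx_status = NULL) {
  origin <- match.arg(origin, .states)
  p <- setNames(numeric(6), .states)
  if (origin == "D") {
    p["D"] <- 1
    return(tibble(state = .states, prob = unname(p)))
  }
  ct <- compile_tables(tables)
  gt <- ct[[gender]]
  if (is.null(gt)) abort(paste0("tables do not cover gender ", gender))
  ai <- match(age, ct$ages)
  if (is.na(ai)) abort(paste0("tables do not cover age ", age))

  if (origin %in% c("C", "O", "V")) {
    dis <- c(C = "lung_cancer", O = "copd", V = "cvd")[[origin]]
    le <- lookup_le(survival, dis, dx_status %||% "current", dx_age %||% age)
    pd <- annual_death_probability_from_life_expectancy(le, survival$conversion)
    p["D"] <- pd
    p[origin] <- 1 - pd
    return(tibble(state = .states, prob = unname(p)))
  }

  if (origin == "S") {
    att_cycles <- attempt_cycles(strategy)
    cess <- if (participant && cycle %in% att_cycles) strategy$cessation_prob
            else strategy$natural_cessation
    pdis <- gt$cur[, ai]
    poth <- min(gt$res_nev[ai], max(1 - sum(pdis), 0))
    if (sum(pdis) + poth > 1 + 1e-12) {
      abort(sprintf("transition probabilities over-allocated at gender=%s age=%d origin=S",
                    gender, age))
    }
    # cessation competes with death: only survivors can quit
    cess <- min(cess, max(1 - sum(pdis) - poth, 0))
    rest <- 1 - cess - sum(pdis) - poth
    p[c("C", "O", "V")] <- pdis
    p["D"] <- poth
    p["F"] <- cess
    p["S"] <- max(rest, 0)
  } else {                                   # former smoker
    b <- band_of_duration(max(years_since_quit, 1), ct$bands)
    pdis <- gt$frm[, b, ai]
    poth <- min(gt$res_nev[ai], max(1 - sum(pdis), 0))
    rest <- 1 - sum(pdis) - poth
    if (rest < -1e-12) {
      abort(sprintf("transition probabilities over-allocated at gender=%s age=%d origin=F",
                    gender, age))
    }
    p[c("C", "O", "V")] <- pdis
    p["D"] <- poth
    p["F"] <- max(rest, 0)                   # relapse folded into cessation rate
  }
  tibble(state = .states, prob = unname(p))
}

attempt_cycles <- function(strategy) {
  if (strategy$attempts == 0) integer(0)
  else strategy$frequency * (seq_len(strategy$attempts) - 1L)
}

# ---- the cohort run -------------------------------------------------------

#' Run the cohort model for one strategy
#'
#' Deterministic expected-value simulation: everyone starts as a smoker;
#' participants (the participation fraction of each stratum) face the
#' program cessation probability at the covered-attempt cycles while still
#' smoking and the natural rate otherwise; former smokers advance through
#' duration tunnel states; incident diagnoses enter terminal-track disease
#' states whose death probability is fixed at diagnosis; death is
#' absorbing. The run stops when the cohort is extinct (lifetime horizon,
#' capped at age 110) or after `horizon` cycles.
#'
#' @param cohort A [cohort_spec()].
#' @param strategy A [strategy_spec()].
#' @param tables A [mortality_tables()] object.
#' @param survival A [disease_survival_spec()].
#' @param horizon `"lifetime"` or a positive number of cycles.
#' @param status_override Force a lifelong smoking status: `"never"` runs
#'   the cohort on never-smoker rates (validation use); `"current"` keeps
#'   smoker rates; both force the cessation probability to zero.
#' @param prep Optional pre-computed model object from an internal
#'   preparation step, reused across PSA iterations.
#' @return A `cohort_trace` object: tidy `occupancy`, `deaths`, `incidence`
#'   and `attempts` tibbles plus internal arrays used by the costing
#'   functions.
#' @export
run_cohort <- function(cohort, strategy, tables, survival = disease_survival_spec(),
                       horizon = "lifetime", status_override = NULL, prep = NULL) {
  if (is.null(prep)) {
    prep <- prepare_cohort_model(cohort, tables, survival, status_override, horizon)
  }
  strata <- prep$cohort$strata
  S <- prep$S
  Tmax <- prep$Tmax
  n_F <- prep$n_F
  nC <- prep$nC
  p_death_comp <- prep$comps$p_death
  band_of <- prep$band_of
  cess_off <- !is.null(prep$status_override)

  att_cycles <- attempt_cycles(strategy)
  natural <- if (cess_off) 0 else strategy$natural_cessation
  cess_at <- if (cess_off) 0 else strategy$cessation_prob

  Sp <- strategy$participation * strata$weight
  Sn <- (1 - strategy$participation) * strata$weight
  Fm <- matrix(0, n_F, S)
  Cm <- matrix(0, nC, S)
  Dv <- numeric(S)

  occ <- array(0, c(Tmax + 1, 6, S), dimnames = list(NULL, .states, NULL))
  deaths <- array(0, c(Tmax + 1, 4, S), dimnames = list(NULL, .causes, NULL))
  inc <- array(0, c(nC, Tmax + 1, S))
  att <- matrix(0, Tmax + 1, S)
  dis_of_comp <- match(prep$comps$disease, .diseases)

  record_occ <- function(t1) {
    occ[t1, 1, ] <<- Sp + Sn
    occ[t1, 2, ] <<- colSums(Fm)
    for (d in 1:3) occ[t1, 2 + d, ] <<- colSums(Cm[dis_of_comp == d, , drop = FALSE])
    occ[t1, 6, ] <<- Dv
  }

  t_end <- Tmax
  for (t in 0:(Tmax - 1)) {
    t1 <- t + 1
    record_occ(t1)
    alive <- sum(occ[t1, 1:5, ])
    if (prep$lifetime && alive < 1e-9) { t_end <- t; break }

    age <- prep$age_mat[t1, ]
    kill <- age >= .max_age            # everyone alive at age 110 dies this cycle

    cess_p <- if (t %in% att_cycles) cess_at else natural
    cess_n <- natural
    if (t %in% att_cycles && !cess_off) att[t1, ] <- Sp

    # smokers
    pdis <- prep$PC[, t1, , drop = FALSE]
    dim(pdis) <- c(3, S)
    poth <- prep$RESC[t1, ]
    cp <- rep(cess_p, S); cn <- rep(cess_n, S)
    if (any(kill)) {
      pdis[, kill] <- 0; poth[kill] <- 1; cp[kill] <- 0; cn[kill] <- 0
    }
    Stot <- Sp + Sn
    mort_s <- colSums(pdis) + poth
    if (min(1 - mort_s) < -1e-12) abort("smoker transition probabilities over-allocated")
    # cessation competes with death: where annual mortality approaches 1,
    # only survivors can quit
    cp <- pmin(cp, pmax(1 - mort_s, 0))
    cn <- pmin(cn, pmax(1 - mort_s, 0))
    inc_s <- pdis * rep(Stot, each = 3)
    d_oth <- Stot * poth
    newF1 <- Sp * cp + Sn * cn
    Sp <- Sp * pmax(1 - cp - mort_s, 0)
    Sn <- Sn * pmax(1 - cn - mort_s, 0)

    # former smokers (process in descending d so advancement is clean)
    inc_f <- matrix(0, 3, S)
    newF <- matrix(0, n_F, S)
    for (d in n_F:1) {
      occd <- Fm[d, ]
      if (all(occd == 0)) next
      b <- band_of[d]
      pd <- prep$PF[, b, t1, , drop = FALSE]
      dim(pd) <- c(3, S)
      po <- prep$RESF[b, t1, ]
      if (any(kill)) { pd[, kill] <- 0; po[kill] <- 1 }
      rem <- 1 - colSums(pd) - po
      if (min(rem) < -1e-12) abort("former-smoker transition probabilities over-allocated")
      inc_f <- inc_f + pd * rep(occd, each = 3)
      d_oth <- d_oth + occd * po
      tgt <- min(d + 1L, n_F)
      newF[tgt, ] <- newF[tgt, ] + occd * pmax(rem, 0)
    }
    newF[1, ] <- newF[1, ] + newF1
    Fm <- newF

    # disease states: deaths, then incident inflow
    pdc <- matrix(p_death_comp, nC, S)
    if (any(kill)) pdc[, kill] <- 1
    d_dis <- Cm * pdc
    Cm <- Cm - d_dis
    for (d in 1:3) {
      ci_s <- prep$CIS[d, t1, ]
      Cm[cbind(ci_s, seq_len(S))] <- Cm[cbind(ci_s, seq_len(S))] + inc_s[d, ]
      inc[cbind(ci_s, t1, seq_len(S))] <- inc[cbind(ci_s, t1, seq_len(S))] + inc_s[d, ]
      ci_f <- prep$CIF[d, t1, ]
      Cm[cbind(ci_f, seq_len(S))] <- Cm[cbind(ci_f, seq_len(S))] + inc_f[d, ]
      inc[cbind(ci_f, t1, seq_len(S))] <- inc[cbind(ci_f, t1, seq_len(S))] + inc_f[d, ]
    }

    # tally deaths
    for (d in 1:3) {
      deaths[t1, d, ] <- colSums(d_dis[dis_of_comp == d, , drop = FALSE])
    }
    deaths[t1, 4, ] <- d_oth
    Dv <- Dv + colSums(d_dis) + d_oth
  }
  if (t_end == Tmax) record_occ(Tmax + 1)
  n_rec <- min(t_end, Tmax) + 1          # occupancy rows 0..n_rec-1

  occ <- occ[seq_len(n_rec), , , drop = FALSE]
  deaths <- deaths[seq_len(n_rec), , , drop = FALSE]
  inc <- inc[, seq_len(n_rec), , drop = FALSE]
  att <- att[seq_len(n_rec), , drop = FALSE]

  # chronic-cost person-years: occupants at cycle start plus incident
  # diagnoses of the cycle (the diagnosis cycle is charged)
  chronic_units <- array(0, c(3, n_rec, S))
  for (d in 1:3) {
    chronic_units[d, , ] <- occ[, 2 + d, ] +
      apply(inc[dis_of_comp == d, , , drop = FALSE], c(2, 3), sum)
  }

  arrays <- list(occ = occ, deaths = deaths, inc = inc, att = att,
                 chronic_units = chronic_units, comps = prep$comps,
                 dis_of_comp = dis_of_comp)
  new_cohort_trace(arrays, prep, strategy, n_rec)
}

new_cohort_trace <- function(arrays, prep, strategy, n_rec) {
  strata <- prep$cohort$strata
  S <- nrow(strata)
  cyc <- rep(0:(n_rec - 1), times = 6)
  occupancy <- purrr::map_dfr(seq_len(S), function(s) {
    tibble(stratum = strata$stratum[s], gender = strata$gender[s],
           entry_age = strata$entry_age[s],
           cycle = cyc, state = rep(.states, each = n_rec),
           occupancy = as.vector(arrays$occ[, , s]))
  })
  deaths <- purrr::map_dfr(seq_len(S), function(s) {
    tibble(stratum = strata$stratum[s], cycle = rep(0:(n_rec - 1), times = 4),
           cause = rep(.causes, each = n_rec),
           deaths = as.vector(arrays$deaths[, , s]))
  })
  comps <- arrays$comps
  incidence <- purrr::map_dfr(seq_len(S), function(s) {
    m <- arrays$inc[, , s, drop = FALSE]
    tibble(stratum = strata$stratum[s],
           cycle = rep(0:(n_rec - 1), each = nrow(comps)),
           disease = rep(comps$disease, times = n_rec),
           le = rep(comps$le, times = n_rec),
           count = as.vector(m))
  }) |> filter(.data$count > 0)
  attempts <- purrr::map_dfr(seq_len(S), function(s) {
    tibble(stratum = strata$stratum[s], cycle = 0:(n_rec - 1),
           attempts = arrays$att[, s])
  }) |> filter(.data$attempts > 0)
  structure(list(occupancy = occupancy, deaths = deaths, incidence = incidence,
                 attempts = attempts, arrays = arrays,
                 cohort = prep$cohort, strategy = strategy,
                 status_override = prep$status_override,
                 n_cycles = n_rec - 1L),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %s: %d strata, %.0f persons, %d cycles\n",
              x$strategy$name, nrow(x$cohort$strata), x$cohort$size, x$n_cycles))
  dead <- sum(x$arrays$occ[x$n_cycles + 1, 6, ])
  cat(sprintf("  dead at final recorded cycle: %.2f\n", dead))
  invisible(x)
}

# persons alive (any non-dead state) at the start of each cycle
alive_by_cycle <- function(trace) {
  rowSums(trace$arrays$occ[, 1:5, , drop = FALSE], dims = 1)
}

#' Discounted life-years of a trace
#'
#' One full life-year is credited per person alive at the start of each
#' cycle (no half-cycle correction), discounted to cycle 0.
#'
#' @param trace A `cohort_trace`.
#' @param discount A [discount_spec()]; the rate applies only if
#'   `discount_benefits` is `TRUE`.
#' @param horizon Optional: count only cycles `0 .. horizon - 1`.
#' @return Discounted life-years (scalar).
#' @export
life_years <- function(trace, discount = discount_spec(), horizon = NULL) {
  alive <- alive_by_cycle(trace)
  tt <- seq_along(alive) - 1
  if (!is.null(horizon)) {
    keep <- tt < horizon
    alive <- alive[keep]; tt <- tt[keep]
  }
  rate <- if (discount$discount_benefits) discount$rate else 0
  sum(alive * discount_factor(rate, tt))
}

#' Deaths avoided per cause between two traces
#'
#' Cumulative cause-specific deaths in the comparator trace minus those in
#' the intervention trace, normalised per `per` population.
#'
#' @param trace_a Intervention trace.
#' @param trace_b Comparator trace.
#' @param per Normalisation population (default 1,000).
#' @return Tibble `cause`, `avoided` (per `per` persons).
#' @export
cause_specific_deaths <- function(trace_a, trace_b, per = 1000) {
  ca <- trace_a$cohort; cb <- trace_b$cohort
  if (abs(ca$size - cb$size) > 1e-9 ||
      !identical(ca$strata[c("gender", "entry_age")], cb$strata[c("gender", "entry_age")])) {
    abort("traces come from different cohorts")
  }
  tot <- function(tr) colSums(apply(tr$arrays$deaths, c(1, 2), sum))
  avoided <- (tot(trace_b) - tot(trace_a)) * per / ca$size
  tibble(cause = .causes, avoided = unname(avoided))
}
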