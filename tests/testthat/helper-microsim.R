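# Independent individual-level microsimulation oracle for the cohort
# engine. Probabilities are assembled directly from the tidy tables with
# plain arithmetic (never-smoker residual as the common other-cause hazard,
# same convention as the engine), and walkers are simulated one by one,
# so expected state occupancies should match the deterministic cohort
# trace within Monte Carlo error.

microsim_occupancy <- function(cohort, strategy, tables, survival, horizon,
                               walkers_per_stratum, seed) {
  states <- c("S", "F", "C", "O", "V", "D")
  strata <- cohort$strata
  att_cycles <- if (strategy$attempts == 0) integer(0)
  else strategy$frequency * (seq_len(strategy$attempts) - 1L)
  bands <- sort(unique(tables$rr$band_lo))

  lookup_rates <- function(g, age, status, band = NULL) {
    dis <- tables$disease
    if (is.null(band)) {
      row <- dis[dis$gender == g & dis$age == age & dis$status == status, ]
    } else {
      row <- dis[dis$gender == g & dis$age == age & dis$status == status &
                   !is.na(dis$band_lo) & dis$band_lo == band, ]
    }
    c(row$p_lung, row$p_copd, row$p_cvd)
  }
  res_nev <- function(g, age) {
    all_q <- tables$all_cause$p_allcause[tables$all_cause$gender == g &
                                           tables$all_cause$age == age]
    max(all_q - sum(lookup_rates(g, age, "never")), 0)
  }

  occ <- array(0, c(horizon + 1, 6, nrow(strata)),
               dimnames = list(NULL, states, NULL))
  withr::with_seed(seed, {
    for (s in seq_len(nrow(strata))) {
      g <- strata$gender[s]
      n <- walkers_per_stratum
      state <- rep(1L, n)                      # everyone starts as a smoker
      part <- seq_len(n) <= round(strategy$participation * n)
      ysq <- rep(0L, n)
      pdth <- rep(NA_real_, n)
      for (t in 0:(horizon - 1)) {
        for (k in 1:6) occ[t + 1, k, s] <- occ[t + 1, k, s] + sum(state == k)
        age <- strata$entry_age[s] + t
        rn <- res_nev(g, age)
        u <- runif(n)
        new_state <- state
        new_pdth <- pdth
        # smokers
        idx <- which(state == 1L)
        if (length(idx) > 0) {
          pc <- lookup_rates(g, age, "current")
          for (grp in list(idx[part[idx]], idx[!part[idx]])) {
            if (length(grp) == 0) next
            is_part <- part[grp[1]]
            cess <- if (is_part && t %in% att_cycles) strategy$cessation_prob
            else strategy$natural_cessation
            cess <- min(cess, max(1 - sum(pc) - rn, 0))
            cuts <- cumsum(c(pc, rn, cess))     # C, O, V, D, F, stay S
            dest <- findInterval(u[grp], cuts) + 1L  # 1..4 events, 5 quit, 6 stay
            new_state[grp] <- c(3L, 4L, 5L, 6L, 2L, 1L)[dest]
            for (d in 1:3) {
              who <- grp[dest == d]
              if (length(who) > 0) {
                le <- lookup_le(survival, c("lung_cancer", "copd", "cvd")[d],
                                "current", age)
                new_pdth[who] <- 1 / le
              }
            }
            new_state[grp][dest == 4] <- 6L
            ysq[grp[dest == 5]] <- 0L
          }
        }
        # former smokers
        idx <- which(state == 2L)
        if (length(idx) > 0) {
          for (dval in unique(ysq[idx])) {
            grp <- idx[ysq[idx] == dval]
            band <- bands[max(findInterval(max(dval, 1), bands), 1)]
            pf <- lookup_rates(g, age, "former", band = band)
            po <- min(rn, max(1 - sum(pf), 0))
            cuts <- cumsum(c(pf, po))
            dest <- findInterval(u[grp], cuts) + 1L  # 1..3 disease, 4 die, 5 stay
            new_state[grp] <- c(3L, 4L, 5L, 6L, 2L)[dest]
            for (d in 1:3) {
              who <- grp[dest == d]
              if (length(who) > 0) {
                le <- lookup_le(survival, c("lung_cancer", "copd", "cvd")[d],
                                "former", age)
                new_pdth[who] <- 1 / le
              }
            }
          }
        }
        # diseased walkers die with their fixed probability
        idx <- which(state %in% c(3L, 4L, 5L))
        if (length(idx) > 0) {
          dies <- u[idx] < pdth[idx]
          new_state[idx[dies]] <- 6L
        }
        state <- new_state
        pdth <- new_pdth
        adv <- state == 2L
        ysq[adv] <- pmin(ysq[adv] + 1L, max(bands))
      }
      for (k in 1:6) occ[horizon + 1, k, s] <- occ[horizon + 1, k, s] + sum(state == k)
    }
  })
  occ / walkers_per_stratum
}
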