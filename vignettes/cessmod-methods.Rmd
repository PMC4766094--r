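---
title: "Methods: the cohort model behind cessmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cohort model behind cessmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cessmod)
```

`cessmod` estimates the cost-effectiveness, for the statutory health
insurer, of fully covering medically managed smoking cessation versus the
existing lump-sum €50 drug subsidy, crediting the intervention with the
avoided treatment costs of lung cancer, COPD and cardiovascular disease.
This vignette documents the model itself: its structure, assumptions, the
parameters that matter, the synthetic life-table generator, and the
numerical and design choices that were genuinely open.

## The state-transition model

The model is a deterministic Markov cohort simulation over one-year
cycles with six mutually exclusive states: smoker (S), former smoker (F),
lung cancer (C), COPD (O), CVD (V) and death (D, absorbing). A cohort of
1,000 smokers aged 15–75 (twelve gender × age strata) starts entirely in
S; each stratum ages one year per cycle and the run continues until the
cohort is extinct, with a hard cap at age 110 (survivors are moved to
death at that age).

**Cessation.** The participation fraction of each stratum enters the
covered program. Participants face the program's *definitive* cessation
probability at the covered-attempt cycles — cycles `0, f, 2f, …` for `n`
covered attempts at frequency `f` years (base case: four biennial
attempts, so cycles 0, 2, 4, 6) — while they are still smokers, and the
natural annual rate of 2.6% in every other cycle; non-participants always
face the natural rate. The calendar of attempts is not pinned down by the
base-case description beyond `n` and `f`; anchoring the first attempt at
entry and spacing the rest by `f` is the simplest consistent reading and
is what the engine implements. Relapse is folded into the definitive
cessation probability (7.05% = 2.6% × 1.95 × 1.39), so the relapse arrow
F→S exists in the state space but carries probability zero.

The odds ratios are applied as direct multipliers on the probability
because that reproduces the conventional base-case value of 7.04%; a
strict odds-scale conversion (≈6.75%) is available via
`cessation_rate_from_or(..., method = "odds")`.

**Former-smoker tunnel.** F is expanded into tunnel sub-states F(1)…F(16)
counting completed years since cessation. Disease risks for F(d) follow a
banded relative-risk schedule versus never smokers — default bands
[1,3), [3,6), [6,11), [11,16), [16,∞) — with risks capped at the
current-smoker level. Durations below one completed year use the first
band; beyond the last band the floor applies (the tunnel stops advancing
at d = 16).

**Disease states are terminal-track.** An incident diagnosis fixes the
annual death probability for the rest of that person's life as `1/LE`,
where `LE` is the life expectancy after diagnosis at the age band and
smoking status at diagnosis (lung cancer: 2 years at all ages; COPD and
CVD: banded by age, COPD also by status). `1/LE` is the geometric-lifetime
parameter whose mean survival equals `LE` in discrete annual cycles; the
constant-hazard discretisation `1 − exp(−1/LE)` is available behind the
`conversion` flag of `disease_survival_spec()`. There are no transitions
between disease states and no recovery, and disease-state occupants face
only their fixed death probability.

**Incidence from mortality.** Disease-specific annual incidence for S and
F states is proxied by disease-specific *mortality* rates, a deliberately
conservative convention (incidence is at least mortality for these
diseases). A consequence worth stating plainly: a diagnosis converts an
imminent life-table death into a survival of mean `LE` years, so the proxy
systematically defers disease deaths relative to the raw life table. This
is visible in the validation output, where modelled never-smoker life
expectancy sits slightly above the all-cause schedule's own value.

**Other-cause mortality.** The package provides
`residual_other_cause_mortality()`, which subtracts the status-specific
disease sum from the all-cause schedule, and the engine's design choice is
that the *never-smoker* residual is the other-cause hazard for every
living state. The two would coincide only if all-cause mortality were
itself status-specific. With a single shared all-cause schedule,
subtracting each status's own disease sum would force every status's total
hazard to the same value — smokers' extra diagnoses would then only defer
already-scheduled deaths, and lifelong smokers could never have lower life
expectancy than never smokers, which contradicts both observed smoking
epidemiology and the model's own validation targets. Treating other-cause
mortality as smoking-independent lets current- and former-smoker excess
disease mortality act additively, which is what the underlying
status-stratified cohort data describe.

**No half-cycle correction.** One full life-year is credited per person
alive at the start of a cycle. Life-years and costs are discounted at 3%
(alternatives 0% and 6%), with independent flags per stream so the
"benefits at 0%" sensitivity is expressible.

### Numerical conventions

- Transition rows must sum to 1 within 1e−12; mass is conserved to 1e−9
  over a lifetime run (enforced in tests).
- Annual probabilities saturate rather than overflow: where total
  mortality approaches 1 (extreme ages), the cessation probability and the
  other-cause residual are truncated so rows stay proper. Adjustment
  ratios that push a probability above 1 clip it with a warning.
- Age bands are closed-open ([70, 80) for "70–79"); the age grid is single
  years 15–110, with banded inputs expanded piecewise-constant.
- A cohort run stops when alive mass falls below 1e−9 of a person.
- Degenerate inputs fail loudly: inconsistent tables (all-cause below a
  disease sum) name the offending gender/age/status; empty disease states
  at a validation horizon yield `NA` shares with a warning, never a
  division by zero.

## Costs

Per covered attempt the payer spends the strategy's consultation cost plus
drug cost (€132 + €201 full coverage; €14.4 + €50 for the single
comparator claim — the €14.4 figure is used rather than the rounded €14
that appears in some summaries, and is configurable). The comparator's
participation (3.75%) is *cost-only*: its claimants face the same natural
cessation rate as everyone else. Chronic-illness costs (€13,872 lung
cancer, €6,562 COPD, €7,976 CVD per person-year, €2009) accrue for every
cycle spent in a disease state *including the diagnosis cycle*. Each cost
stream is inflated from the 2009 base year by its own index (GP visits
+0.23%/y, drugs +2.19%/y, chronic care −1.50%/y) before discounting.
Setting all chronic costs to zero reduces the incremental cost to pure
intervention spending, an identity used in the tests.

The ICER is reported only when the incremental effect is positive;
otherwise the result is labelled dominated or indeterminate, and a
negative ratio with positive effect is labelled cost-saving with the
ratio retained.

## Uncertainty analysis

The PSA draws, independently per iteration: the program cessation
probability from a log-normal anchored at the 7.04% point (treated as the
median) with σ from the 95% CI [5.64%, 9.47%] via
`σ = log(hi/lo)/(2·1.959964)`; participation from triangular(5%, 7.3%,
73%); the per-attempt drug cost from triangular(€120, €201, €220); the
number of covered attempts from {2, 4, 6}; their frequency from {1, 2, 4}
years; the discount rate from {0%, 3%, 6%}; and each inflation stream from
its base/alternate pair — discrete supports sampled uniformly. The printed
CI is not exactly log-symmetric about the point, so the fitted tail masses
are ≈4.7% below and ≈1.2% above rather than 2.5% each; anchoring the
median at the base-case value was preferred over matching either bound.
The comparator's natural cessation rate is not sampled. Within an
iteration the comparator shares the drawn discount and inflation values
(common random numbers); since no sampled parameter affects the
comparator's state dynamics, its trace is computed once and re-costed.

A degenerate distribution set (`degenerate_distributions()`) must — and
in the tests does — reproduce the deterministic base case exactly, and a
fixed seed reproduces the full iteration table bit for bit.

The budget impact analysis follows the standard payer convention:
undiscounted, inflation-adjusted streams, scaled by a *required* national
smoker count (the shipped example configuration uses 13.5 million smokers
aged 15–75, a round figure of the right order for France; with 7.3%
participation at €333 per attempt this puts the deterministic first-year
cost at ≈€330M). The probabilistic budget impact reuses the PSA
distribution set unchanged — including the wide triangular participation,
which dominates the spread of the first-year cost. Both the sample 95%
interval and the 95% CI of the mean are reported, since either reading of
a published interval is defensible.

## The synthetic life-table generator

The stratified schedules the engine needs (never/current/former(d) ×
gender × single year of age, for three diseases plus all-cause) come from
national and cohort sources that cannot be redistributed, so
`generate_synthetic_tables()` emulates them:

- **All-cause baseline**: Gompertz, `q(a) = α·exp(β·a)` capped at 0.97,
  with β = 0.074/y (men) and 0.080/y (women) and α calibrated by root
  finding (tolerance 1e−12) so remaining life expectancy at age 20 equals
  56 years (men) and 63.4 years (women) — the general-population anchors.
- **Never-smoker disease rates**: fixed shares of all-cause mortality
  (lung cancer 2.2%, COPD 0.4%, CVD 2.5%), with ±2% uniform multiplicative
  jitter per (gender, age, disease), seeded and reproducible.
- **Current smokers**: per-disease multipliers (lung cancer 38, COPD 10,
  CVD 3). The lung-cancer multiplier sits at the top of the observed
  range deliberately: under a shared all-cause schedule the smoker excess
  must flow through the disease states, and concentrating it in the
  rapidly fatal disease (2-year survival) is what reproduces a realistic
  overall smoker/never-smoker life-expectancy differential; spreading the
  same excess over the long-survival diseases would understate it.
- **Former smokers**: relative risks `1 + (m−1)·exp(−t/τ)` at band
  midpoints with decay time τ = 7 years, floored at 1.05 in the last band,
  capped at the current-smoker rate — a monotone decay toward (near)
  never-smoker risk over ≈15 years of abstinence.

The defaults were calibrated once so that the lifelong smoker/non-smoker
life-expectancy gap at age 20 falls in the 6–10-year range reported by
status-stratified cohort studies (the acceptance run prints ≈7.0 years for
men, ≈6.7 for women), and were not adjusted thereafter. What the generator
does **not** emulate: cohort effects and period trends in smoking-related
mortality, dose–response by cigarettes per day, age-varying disease
shares (the share profile is flat in age), and any correlation structure
between diseases. Tests passing on these tables therefore validate the
*pipeline* — arithmetic, conservation, ordering, reproducibility — and the
broad magnitudes, not the specific published point estimates, which
require the transcribed national tables (loadable via
`read_life_tables()`).

## Validation computations

`model_life_expectancy()` runs a single-stratum cohort that never changes
smoking status (cessation forced to zero; the never-smoker variant runs on
never rates throughout). `onset_time_distribution()` reconstructs, from
recorded incident diagnoses and the fixed per-compartment death
probabilities, the distribution of completed years since diagnosis among
disease-state survivors at a 20-year horizon, binned `<1, 1–2, 3–5, 5–9,
10–15, >15` years. The printed labels of the two middle bins overlap at 5;
they are resolved as [3,5) and [5,10) so the bins partition the line.
With 2-year lung-cancer survival the geometric survivor mass beyond two
completed years is at most (1 − 1/2)³ = 12.5% (exactly that under
constant incidence; less when incidence rises over the window), so the
lung row concentrates in the first two bins — the acceptance run prints
≈87% there — while COPD and CVD spread across all six. Exact confinement
to the first two bins would require deterministic (fixed-term) survival
after diagnosis rather than the geometric `1/LE` convention.

`replicate_external_scenario()` supports two designs: `"coverage"`
(arbitrary participation/cessation/attempt settings against a no-coverage
comparator, horizon-limited, undiscounted) and `"quitters"` (a cohort of
definitive quitters versus the same cohort continuing to smoke, natural
cessation suppressed, normalised per 1,000 quitters) — the latter matching
quitter-based external models.

## Problem sizes used in the tests

The shipped suite runs the full lifetime engine on 2–12-stratum cohorts,
cross-checks the cohort engine against a 200,000-walker individual-level
microsimulation over 30 cycles (≈900 simultaneous occupancy comparisons;
with that multiplicity a rare chance excursion past 3 standard errors is
expected, so the criterion is <0.5% of comparisons beyond 3 SE and none
beyond 4.5), validates transition rows across 1,000 randomized table
draws, and exercises the samplers at 10⁵–10⁶ draws. The acceptance script
uses the base-case 1,000-iteration PSA and budget impact. These sizes keep
a full run in the low minutes on a single core while leaving Monte Carlo
error well inside the asserted bands.

## Known limitations

- Mortality-as-incidence underestimates COPD and CVD case counts (and
  hence cost offsets), and defers disease deaths by construction.
- Participation in the comparator arm is cost-only; if the €50 subsidy has
  any real effect on cessation the incremental benefit of full coverage is
  overstated by that margin, and conversely.
- No QALY weighting: the effect unit is the life-year.
- Disease states are exclusive and terminal; comorbidity among the three
  diseases is not represented.
- The synthetic tables are a calibrated stand-in, not transcriptions;
  absolute euro values on them should be read as orders of magnitude.
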