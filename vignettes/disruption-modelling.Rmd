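---
title: "Modelling screening, diagnosis and treatment disruptions for colorectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling screening, diagnosis and treatment disruptions for colorectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcdisrupt)
```

# The problem

A temporary disruption to cancer control — a pandemic, a strike, a funding
gap — hits three distinct services at once: population screening,
diagnostic workup, and treatment. Each channel harms differently and on a
different time scale. Missed screening rounds mean precancerous lesions
that would have been removed instead progress to cancer, raising incidence
years later, and preclinical cancers that would have been found early are
instead diagnosed symptomatically at a worse stage. Reduced diagnostic and
treatment throughput creates *backlogs*: patients whose diagnosis or
treatment would already have happened queue for it, and weeks spent on a
backlog translate into measurably higher cancer mortality. This package
implements that causal chain as a composable, fully tested pipeline, with
counterfactual (no-disruption) comparison built into its core.

# Pipeline and assumptions

## Synthetic natural history

The national estimates this design follows were produced with proprietary,
registry-calibrated microsimulation platforms. Those cannot be rebuilt at
desk scale, and this package deliberately does not try: instead
`generate_case_stream()` simulates the *simplest* per-person process with
the needed qualitative response surface — a three-compartment chain
(precursor lesion → preclinical cancer → clinical presentation) with
exponential dwell times, heterogeneous by age, under biennial stool-test
screening between ages 50 and 74.

Assumptions worth stating plainly:

* **Closed cohort.** Persons aged 20–99 in January 2018, no births or
  migration. Comparator incidence therefore *declines* over the 33-year
  horizon as the cohort ages and depletes; all results are paired
  differences, so this drift cancels to first order.
* **Single episode.** At most one precursor/cancer per person.
* **Prevalent pool.** Onset clocks run from age 20 in person-time, so
  older cohort members can carry prevalent precursors or preclinical
  cancers into 2018; cancers that would have presented clinically before
  2018 are excluded. Screening before 2018 is not modelled, which slightly
  inflates early screen-detections — immaterial for paired contrasts.
* **Stage progression.** Stage at preclinical onset is drawn from a
  simplex; while undiagnosed, stage advances as a unit-jump Poisson
  process with annual hazard `-log(1 - annual_upstage_rate)`. Clinical
  presentation is modelled as *accompanying one further stage advance*:
  symptoms are taken to arise from progression. This last choice needs
  justification: with exponential sojourns, screening preferentially
  intercepts long-sojourn cancers, and the resulting length-biased
  selection makes the undiagnosed-duration distributions of screen-detected
  and symptomatic cancers nearly identical — duration-driven upstaging
  alone then produces nearly identical stage mixes, contrary to universal
  registry experience. Tying symptomatic presentation to a progression
  event restores the expected ordering mechanistically rather than by
  fiat.
* **Paired seeds.** Every latent draw (ages, onset clocks, dwell times,
  per-round attendance and test uniforms, the stage-advance quantile) is
  made up-front, independent of the participation series. Two runs
  differing only in participation share one latent population, so their
  difference is pure detection effect; the attendance coupling is monotone
  (lower participation can only flip attendances off), which makes
  sign-level contrasts near-deterministic per seed and desk-scale Monte
  Carlo feasible.

## Key parameters

All defaults live in `population_params()` and are this package's own —
explicitly *not* calibrated to any registry or to either national
microsimulation platform.

| parameter | default | units | why |
|---|---|---|---|
| `cohort_size` | 200,000 | persons | desk-scale; tests use 20–50k |
| `precursor_incidence_rate` | 0.003 | /person-year at 50–54 | with the age curve, gives a plausible adult lifetime precursor risk |
| `age_multipliers` | `(mid/52.5)^2.5` | — | steep age gradient of adenoma incidence |
| `precursor_to_preclinical_rate` | 0.02 | /precursor-year | most precursors never progress |
| `preclinical_sojourn_mean` | 5 | years | screen-detectable window of a few biennial rounds |
| `annual_upstage_rate` | 0.25 | /year | undiagnosed cancers advance roughly one stage in 3–4 years |
| `stage_distribution_at_onset` | .50/.30/.15/.05 | — | early-stage-heavy at onset |
| `screening_sensitivity_preclinical` | 0.85 | /attended screen | stool-test sensitivity for invasive cancer |
| `screening_sensitivity_precursor` | 0.30 | /attended screen | much lower for precursors |
| `participation_baseline` | 0.55 | /invitation round | organised-program attendance |

The screening triple (participation, sensitivity, sojourn) was set — once,
before any acceptance measurement — to meet the module's stated
calibration target that roughly 60% of comparator diagnoses in
screening-eligible ages be screen-detected; the packaged defaults measure
0.61 at cohort 100,000. Missed rounds simply resume at the next scheduled
round: catch-up screening is excluded by design, because a fresh biennial
round reaches the missed population within two years anyway.

## Capacity timelines

`build_capacity_series()` converts observed relative volume changes into
per-timestep capacity multipliers: `1 + Δ` during the disruption window,
`1 + mitigation` from the mitigation start (January 2022 at the earliest),
1 elsewhere. Yearly records expand uniformly over their 12 months (no
seasonality — the monthly interface exists for users who have real monthly
data); monthly records override yearly ones; genuinely contradictory
overlaps are rejected by name. Where only diagnostic-*procedure*
(colonoscopy) volumes are observed, the implied change in actual diagnoses
is `0.504 × Δ`, the ratio observed in the one region with both series.
Mitigation applies to diagnostic and treatment capacity only, never
screening.

**Calendar convention.** Months are 0-indexed from January 2018 and
treated as exactly 4 weeks long (a 48-week year), so monthly volumes
divide evenly into two 2-week or four 1-week steps. All week↔month
conversions use the same convention, so identities checked by the tests
are unaffected by it.

## Backlog engines

Two engines, deliberately kept as independent implementations so each can
oracle-check the other:

* `simulate_aggregate_queue()` — the deterministic recursion
  `served = min(waiting + arrivals, capacity)`, expected additional wait
  `waiting_{after}/capacity` steps, attributed to every patient arriving
  that step. Zero capacity against a positive queue yields an `Inf`
  sentinel, never a silent division.
* `simulate_agent_queue()` — each waiting patient is served independently
  with probability `min(1, capacity/waiting)` per step (random service
  discipline, matching the equal-treatment assumption; FIFO is available
  for sensitivity). Patients still queued at the horizon are served in a
  drain phase at final capacity and *flagged*, avoiding censoring bias
  while keeping them excludable.

Their expected queue lengths coincide, and in steady state their mean
waits coincide exactly; transients differ slightly because the aggregate
method assigns the backlog-average wait to immediately-served arrivals
too. The acceptance suite bounds the disagreement at 5% on a standard
shock profile.

`run_scenario()` drives the queues at *monthly* steps by default: the
baseline capacity equals the counterfactual arrival series (the
undisrupted queue is exactly in balance, as intended by defining expected
capacity from pre-disruption incidence), and monthly stepping keeps that
balance exact for integer arrivals, which is what makes the zero-shock
scenario reproduce the comparator byte-for-byte. Finer steps (2-week
agent, 1-week aggregate) are available but break the exact identity
whenever a month's arrivals do not divide evenly across its steps.

## Delay impact

A delay of `d` weeks multiplies the mortality hazard by `1.06^(d/4)`
(continuous compounding; a whole-block mode exists for sensitivity, since
a per-4-week rate is ambiguous between the two). Under proportional
hazards survival transforms as `S(t)^m`. Diagnostic delay also upstages
with probability `1 - (1 - r)^(d/52)` — one stage at most per episode, as
observed delays are well under a year; stage IV absorbs.

**Double-counting guard.** Diagnostic delays of screen-detected cancers
feed *neither* channel. The published rationale concerns the hazard ratio
(their diagnostic-delay harm is already captured inside the screening
model); this package extends the guard to the upstaging channel as well,
because the two channels are combined in one pipeline here and a
screen-detected case with a purely diagnostic delay must contribute zero
excess — otherwise the same harm would be counted twice by construction.

Default stage-specific survival is exponential with monthly hazards set so
5-year survival is 0.95/0.85/0.70/0.15 for stages I–IV — placeholders in a
plausible range, override with `survival_model()` or a CSV via
`read_survival_model()`.

A case assigned several treatment modalities waits for all of them; its
treatment delay is the maximum of its modality waits (the combination rule
is not specified in the source design; the maximum reflects that treatment
is incomplete until its slowest component happens).

## Scenarios, decomposition, reporting

`run_scenario()` composes the chain per seed and averages outcome arrays
(month × age × stage diagnoses and expected deaths) over seeds. Excess is
always a paired-seed difference against the no-pandemic comparator over
half-open calendar windows. `decompose_excess()` mirrors the two-model
chaining of the source design: screening-related = screening-only run −
comparator; diagnosis/treatment-related = full run − screening-only run;
the parts sum to the total exactly in floats. The decomposition is
order-dependent (screening first); the reverse ordering can be computed by
swapping arguments as a diagnostic.

Rates are age-standardised with the 18-band Segi world standard; model
bands 85–99 aggregate into "85+", and weights renormalise over the bands
present. ASRs are *annual* (the standard epidemiological convention;
monthly ASRs would mostly amplify noise). Person-years come from the
cohort's age structure aged forward deterministically, ignoring deaths — a
reporting simplification that cancels in relative comparisons.

# What a green test establishes — and what it does not

The synthetic generator emulates: the screening dip and its delayed
stage-shifted compensation, the long-term incidence excess from unremoved
precursors, backlog formation and clearance, and the delay→mortality
machinery. It does *not* emulate: real registry incidence levels, national
demography (births, migration), dual-pathway biology
(adenoma–carcinoma *and* serrated), family-history colonoscopy streams,
provincial test-threshold variation, or behavioural responses to delayed
care. Green tests therefore establish internal correctness and the
qualitative response surface — signs, orderings, conservation laws, exact
arithmetic identities — not reproduction of published absolute national
counts, which depend on proprietary calibrations. Where published
arithmetic *is* self-contained (the mitigation percentages, the
decomposition identity, deaths averted), the acceptance suite reproduces
it exactly.

# Numerical choices

* 4-week months / 48-week year (exact step division; see above).
* Diagnosis months shift by `round(diagnostic wait in weeks / 4)` months.
* Queue capacities are real-valued rates; no integer rounding of capacity
  (the FIFO discipline draws a Bernoulli for the fractional slot).
* The stage-advance count is the Poisson quantile of one shared uniform
  per person — monotone in undiagnosed duration, so coupling survives
  scenario changes.
* Upstaging inside `run_scenario()` is *sampled* (seeded) so that counts
  and deaths agree on one realised stage; `excess_deaths()` uses the
  analytic mixture.
* Drain-phase behaviour at the data horizon is a genuine unknown in the
  source design; drained patients are flagged so either convention can be
  reported.

# Known limitations

* The closed cohort makes late-horizon (2040s) arrival rates small, so
  no-mitigation waits in the 2020–2050 window are less stable than
  mid-horizon ones; mitigation comparisons are unaffected in sign.
* Treatment arrivals queue at the counterfactual diagnosis month, not the
  backlog-shifted one; diagnostic and treatment backlogs are independent
  queues, slightly overstating simultaneity of the two delays.
* One stage advance per delay episode caps the upstaging harm for very
  long delays.
* Monte-Carlo standard errors at test scale (cohorts of tens of
  thousands, ≤ a dozen seeds) are adequate for sign and ordering checks
  only; scale `cohort_size` and `seeds` up for production estimates.
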