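#' Scenario specification
#'
#' One analysed scenario: a screening-participation series, a set of
#' procedure-volume change records, and an optional capacity-mitigation
#' uplift applied to diagnostic and treatment capacity (never screening)
#' from 2022 onward. The comparator `no_pandemic` scenario must have unit
#' participation, no volume records and no mitigation.
#'
#' @param name `"no_pandemic"`, `"pandemic_no_mitigation"` or
#'   `"pandemic_mitigation"`.
#' @param participation a [participation_series()].
#' @param volume_records a `volume_change_records` table or `NULL`.
#' @param mitigation_factor relative diagnostic/treatment capacity uplift
#'   (0, 0.05 or 0.15 in the published scenarios).
#' @param mitigation_start "YYYY-MM"; at or after January 2022.
#' @param seeds integer replicate seeds (paired across scenarios).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("no_pandemic", "pandemic_no_mitigation",
                                   "pandemic_mitigation"),
                          participation = participation_series(),
                          volume_records = NULL,
                          mitigation_factor = 0,
                          mitigation_start = "2022-01",
                          seeds = 1:10) {
  name <- match.arg(name)
  stopifnot(inherits(participation, "participation_series"),
            mitigation_factor >= 0, length(seeds) >= 1L)
  if (month_index(mitigation_start) < month_index("2022-01"))
    stop("mitigation_start must be at or after January 2022")
  if (name == "no_pandemic") {
    if (any(participation$values != 1) ||
        (!is.null(volume_records) && nrow(volume_records) > 0L) ||
        mitigation_factor != 0)
      stop("no_pandemic requires unit participation, no volume records ",
           "and zero mitigation")
  }
  if (name != "pandemic_mitigation" && mitigation_factor != 0)
    stop("only pandemic_mitigation scenarios may carry mitigation")
  structure(list(name = name, participation = participation,
                 volume_records = volume_records,
                 mitigation_factor = mitigation_factor,
                 mitigation_start = mitigation_start,
                 seeds = as.integer(seeds)),
            class = "scenario_spec")
}

default_windows <- function() {
  list("2020-2021" = c("2020-01", "2022-01"),
       "2020-2025" = c("2020-01", "2026-01"),
       "2020-2030" = c("2020-01", "2031-01"),
       "2020-2050" = c("2020-01", "2051-01"))
}

# expected person-years by calendar year x age band, from the age-at-2018
# distribution aged forward deterministically (other-cause deaths ignored;
# a reporting simplification documented in the vignette)
person_years_expected <- function(params, n_years) {
  bands <- age_bands()
  grid <- seq(20.05, 99.95, by = 0.1)
  dens <- params$age_distribution[pmin(length(bands),
                                       (floor(grid) - 20L) %/% 5L + 1L)] / 50
  py <- matrix(0, n_years, length(bands),
               dimnames = list(2018L + seq_len(n_years) - 1L, bands))
  for (y in seq_len(n_years)) {
    age <- grid + (y - 1) + 0.5
    keep <- age < 100
    b <- (floor(age[keep]) - 20L) %/% 5L + 1L
    py[y, ] <- params$cohort_size * vapply(
      seq_along(bands), function(bb) sum(dens[keep][b == bb]), numeric(1))
  }
  py
}

# allocate each case to a queue timestep within its counterfactual
# diagnosis month (round-robin), run the chosen engine, and return the
# per-case additional waits in weeks
queue_case_delays <- function(case_months, capacity, engine, seed) {
  spm <- capacity$steps_per_month
  n_steps <- length(capacity$capacity)
  within <- stats::ave(seq_along(case_months), case_months,
                       FUN = seq_along)
  step <- case_months * spm + (within - 1L) %% spm
  arrivals <- tabulate(step + 1L, nbins = n_steps)
  dd <- if (engine == "agent")
    simulate_agent_queue(arrivals, capacity, seed = seed)
  else simulate_aggregate_queue(arrivals, capacity)
  # dd rows are in arrival order (step, then within-step); map back
  ord <- order(step, within)
  dd_ord <- dd[order(dd$arrival_step, dd$patient_id), ]
  waits <- numeric(length(case_months))
  waits[ord] <- dd_ord$additional_wait_weeks
  waits
}

# monthly x age x stage death array implied by a set of cases, via the
# stage-specific cumulative-incidence kernels (deaths allocated to months
# after each case's actual diagnosis month)
deaths_array <- function(cases, survival, mult, out_months) {
  bands <- age_bands()
  S <- unclass(survival)
  grid <- ncol(S) - 1L
  D <- array(0, c(out_months, length(bands), 4L),
             dimnames = list(NULL, bands, stage_levels()))
  plain <- mult == 1
  # undelayed cases: one kernel per stage, applied by shifting a
  # month x age count matrix down the calendar axis
  if (any(plain)) {
    cp <- cases[plain, ]
    tab <- table(factor(cp$diagnosis_month, levels = 0:(out_months - 1L)),
                 factor(match(cp$age_group, bands),
                        levels = seq_along(bands)),
                 factor(match(cp$stage_at_diagnosis, stage_levels()),
                        levels = 1:4))
    C <- array(as.numeric(tab), dim(D))
    for (si in 1:4) {
      f <- diff(1 - S[si, ])
      Cs <- C[, , si]
      for (t in seq_len(grid)) {
        if (t >= out_months) break
        rows <- seq_len(out_months - t)
        D[rows + t, , si] <- D[rows + t, , si] + Cs[rows, ] * f[t]
      }
    }
  }
  # delayed cases (few): scatter per unique (stage, multiplier) kernel
  if (any(!plain)) {
    dt <- data.table::data.table(
      s = cases$stage_at_diagnosis[!plain],
      mult = mult[!plain], m = cases$diagnosis_month[!plain],
      a = match(cases$age_group[!plain], bands))
    key <- dt[, list(n = .N), by = c("s", "mult", "m", "a")]
    for (i in seq_len(nrow(key))) {
      f <- diff(1 - S[key$s[i], ]^key$mult[i])
      at <- key$m[i] + seq_len(grid)
      ok <- at >= 0L & at < out_months
      si <- match(key$s[i], stage_levels())
      D[cbind(at[ok] + 1L, key$a[i], si)] <-
        D[cbind(at[ok] + 1L, key$a[i], si)] + key$n[i] * f[ok]
    }
  }
  D
}

#' Run one scenario end-to-end
#'
#' Pipeline per replicate seed: generate the synthetic case stream under
#' the scenario's participation series; form counterfactual procedure
#' arrivals; build capacity series from the volume records (with the
#' diagnostic-procedure scaling and any mitigation uplift); run the backlog
#' engine per procedure to obtain per-case additional diagnostic and
#' treatment waits (the treatment wait of a case needing several
#' modalities is the largest of its modality waits); shift diagnosis months
#' by the diagnostic wait, upstage sampled stages from diagnostic waits,
#' and apply the per-4-week mortality hazard ratio to the effective delay
#' (treatment wait plus diagnostic wait for symptomatic cases only).
#' Results are averaged over seeds. With paired seeds a zero-shock pandemic
#' scenario reproduces the comparator exactly.
#'
#' @param spec a [scenario_spec()].
#' @param params a [population_params()].
#' @param horizon_months simulation horizon (>= 396).
#' @param engine backlog engine: `"aggregate"` (deterministic, default) or
#'   `"agent"` (stochastic).
#' @param timestep_weeks queue timestep. The default 4 (monthly steps)
#'   keeps the undisrupted queue exactly in balance, so a zero-magnitude
#'   shock reproduces the comparator to the byte; finer steps (2 for the
#'   agent pathway, 1 for the weekly aggregate pathway) are available but
#'   introduce sub-monthly imbalance whenever a month's integer arrivals do
#'   not divide evenly across its steps.
#' @param treatment_mix modality-need probabilities (see
#'   [split_counterfactual_arrivals()]).
#' @param survival a [survival_model()].
#' @param impact a [delay_impact_params()].
#' @return an `outcome_table`: list with `diagnoses` and `deaths`
#'   (month x age x stage arrays, seed-averaged; the death axis extends
#'   past the diagnosis horizon by the survival grid), `person_years`
#'   (year x age), and metadata.
#' @export
run_scenario <- function(spec, params,
                         horizon_months = 396L,
                         engine = c("aggregate", "agent"),
                         timestep_weeks = 4L,
                         treatment_mix = c(surgery = 0.7, chemotherapy = 0.4,
                                           radiotherapy = 0.2),
                         survival = survival_model_exponential(),
                         impact = delay_impact_params()) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(params, "population_params"))
  horizon_months <- as.integer(horizon_months)
  out_months <- horizon_months + ncol(survival) + 12L
  bands <- age_bands()
  Dx <- array(0, c(out_months, length(bands), 4L),
              dimnames = list(NULL, bands, stage_levels()))
  De <- Dx
  has_shock <- (!is.null(spec$volume_records) &&
                  nrow(spec$volume_records) > 0L) ||
    spec$mitigation_factor != 0

  for (seed in spec$seeds) {
    stream <- generate_case_stream(params, spec$participation,
                                   horizon_months, seed = seed)
    arr <- split_counterfactual_arrivals(stream, horizon_months,
                                         treatment_mix, seed = seed)
    d_diag <- numeric(nrow(stream))
    d_treat <- numeric(nrow(stream))
    if (has_shock) {
      baselines <- list(diagnosis = arr$arrivals[, "diagnosis"],
                        surgery = arr$arrivals[, "surgery"],
                        chemotherapy = arr$arrivals[, "chemotherapy"],
                        radiotherapy = arr$arrivals[, "radiotherapy"])
      caps <- build_capacity_set(spec$volume_records, baselines,
                                 horizon_months, timestep_weeks,
                                 spec$mitigation_factor,
                                 spec$mitigation_start)
      d_diag <- queue_case_delays(stream$diagnosis_month,
                                  caps$diagnosis, engine, seed)
      for (mod in c("surgery", "chemotherapy", "radiotherapy")) {
        sel <- arr$assignments[[mod]]
        if (!any(sel)) next
        w <- queue_case_delays(stream$diagnosis_month[sel], caps[[mod]],
                               engine, seed + 1L)
        d_treat[sel] <- pmax(d_treat[sel], w)
      }
    }
    stream$diagnostic_delay_weeks <- d_diag
    stream$treatment_delay_weeks <- d_treat

    m_actual <- stream$diagnosis_month +
      as.integer(round(d_diag / WEEKS_PER_MONTH))
    # double-counting guard: screen-detected diagnostic delays feed neither
    # the hazard ratio nor the upstaging channel
    d_diag_guarded <- d_diag *
      (stream$detection_mode == "symptomatic" |
         impact$apply_diagnostic_hr_to_screen_detected)
    stage_final <- apply_upstaging(stream$stage_at_diagnosis,
                                   d_diag_guarded, impact, mode = "sample",
                                   seed = seed + 104729L)
    mult <- delay_hazard_multiplier(d_treat + d_diag_guarded, impact)

    a_idx <- match(stream$age_group, bands)
    s_idx <- match(stage_final, stage_levels())
    ok <- m_actual >= 0L & m_actual < out_months
    tab <- table(factor(m_actual[ok], levels = 0:(out_months - 1L)),
                 factor(a_idx[ok], levels = seq_along(bands)),
                 factor(s_idx[ok], levels = 1:4))
    Dx <- Dx + as.numeric(tab)
    case_view <- data.table::data.table(
      stage_at_diagnosis = stage_final[ok],
      diagnosis_month = m_actual[ok],
      age_group = stream$age_group[ok])
    De <- De + deaths_array(case_view, survival, mult[ok], out_months)
  }
  ns <- length(spec$seeds)
  structure(list(diagnoses = Dx / ns,
                 deaths = De / ns,
                 person_years = person_years_expected(
                   params, ceiling(out_months / 12)),
                 horizon_months = horizon_months,
                 out_months = out_months,
                 name = spec$name,
                 seeds = spec$seeds,
                 engine = engine),
            class = "outcome_table")
}

# total events of an outcome table inside a half-open month window
window_total <- function(tab, what, window) {
  m <- month_index(window)
  rows <- seq.int(m[1] + 1L, min(m[2], tab$out_months))
  sum(tab[[what]][rows, , ])
}

#' Cumulative excess over reporting windows
#'
#' Differences two seed-paired outcome tables over half-open calendar
#' windows.
#'
#' @param scenario,comparator `outcome_table`s sharing seeds and horizon.
#' @param windows named list of `c(start, end)` "YYYY-MM" labels.
#' @return data.table (window, excess_cases, excess_deaths,
#'   relative_cases, relative_deaths).
#' @export
cumulative_excess <- function(scenario, comparator,
                              windows = default_windows()) {
  check_paired(scenario, comparator)
  do.call(rbind, lapply(names(windows), function(w) {
    ec <- window_total(scenario, "diagnoses", windows[[w]]) -
      window_total(comparator, "diagnoses", windows[[w]])
    cd <- window_total(comparator, "deaths", windows[[w]])
    cc <- window_total(comparator, "diagnoses", windows[[w]])
    ed <- window_total(scenario, "deaths", windows[[w]]) - cd
    data.table::data.table(window = w, excess_cases = ec,
                           excess_deaths = ed,
                           relative_cases = if (cc > 0) ec / cc else NA_real_,
                           relative_deaths = if (cd > 0) ed / cd else NA_real_)
  }))
}

check_paired <- function(a, b) {
  if (!identical(a$seeds, b$seeds))
    stop("outcome tables do not share replicate seeds")
  if (a$out_months != b$out_months)
    stop("outcome tables do not share a horizon")
  invisible(TRUE)
}

#' Decompose excess outcomes into screening and diagnosis/treatment parts
#'
#' Mirrors the two-model chaining of the published analysis: the
#' screening-related component is the screening-only run minus the
#' comparator; the diagnosis/treatment-related component is the full run
#' minus the screening-only run; their sum equals the total excess exactly
#' in unrounded floats.
#'
#' @param run_all full scenario `outcome_table` (screening + capacity
#'   shocks).
#' @param run_screening_only same participation shock, no capacity shocks.
#' @param comparator the no-pandemic `outcome_table`.
#' @param windows reporting windows as in [cumulative_excess()].
#' @return an `excess_table` data.table with per-window excess cases and
#'   the decomposed excess deaths.
#' @export
decompose_excess <- function(run_all, run_screening_only, comparator,
                             windows = default_windows()) {
  check_paired(run_all, comparator)
  check_paired(run_screening_only, comparator)
  full <- cumulative_excess(run_all, comparator, windows)
  scr <- cumulative_excess(run_screening_only, comparator, windows)
  out <- data.table::data.table(
    window = full$window,
    excess_cases = full$excess_cases,
    excess_deaths_screening = scr$excess_deaths,
    excess_deaths_diagnosis_treatment =
      full$excess_deaths - scr$excess_deaths,
    excess_deaths_total = full$excess_deaths,
    relative_cases = full$relative_cases,
    relative_deaths = full$relative_deaths)
  data.table::setattr(out, "class", c("excess_table", class(out)))
  out
}

#' Relative reduction in excess achieved by mitigation
#'
#' @param no_mitigation_excess cumulative excess deaths without mitigation
#'   (must be > 0).
#' @param mitigation_excess cumulative excess deaths under mitigation.
#' @return fraction `(no_mitigation - mitigation) / no_mitigation`.
#' @examples
#' mitigation_reduction(1186, 842) # 0.29, the Australian 2020-2030 figure
#' @export
mitigation_reduction <- function(no_mitigation_excess, mitigation_excess) {
  if (!is.finite(no_mitigation_excess) || no_mitigation_excess <= 0)
    stop("no-mitigation excess must be positive")
  (no_mitigation_excess - mitigation_excess) / no_mitigation_excess
}

#' Deaths averted by mitigation
#'
#' @inheritParams mitigation_reduction
#' @return difference of cumulative excess deaths over the window.
#' @examples
#' deaths_averted(1820, 1031) # 789, the Canadian 2020-2030 figure
#' @export
deaths_averted <- function(no_mitigation_excess, mitigation_excess) {
  stopifnot(is.finite(no_mitigation_excess), is.finite(mitigation_excess))
  no_mitigation_excess - mitigation_excess
}
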