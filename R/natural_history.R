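#' Generate a synthetic CRC case stream
#'
#' Simulates a cohort through a three-compartment natural history
#' (precursor lesion -> preclinical cancer -> clinical presentation, all
#' exponential dwell times) under biennial organised FIT screening, and
#' returns the diagnosed cancers as one row per case. Screening attendance
#' at each invitation round is `participation_baseline` multiplied by the
#' participation series value at the invitation month; a precursor found at
#' an attended screen is removed (the person never develops that cancer), a
#' preclinical cancer found is a screen-detected diagnosis, and cancers
#' that reach clinical presentation undetected are symptomatic diagnoses.
#'
#' All latent randomness (onset clocks, dwell times, attendance and test
#' uniforms) is drawn up-front from `seed`, independent of the
#' participation series, so two calls differing only in participation share
#' one latent population: differences between the streams are pure
#' detection effects (paired-seed counterfactual design). With
#' participation identically 1.0 the stream is the no-pandemic comparator.
#'
#' Stage at diagnosis starts from the onset stage and may advance one stage
#' with probability `1 - (1 - annual_upstage_rate)^years_undiagnosed`, so
#' symptomatic cancers (longer undiagnosed) present with a worse stage mix
#' than screen-detected ones. A participation dip therefore produces fewer
#' screen-detected diagnoses during the dip, a later compensating excess of
#' symptomatic diagnoses with worse stages, and a small long-term
#' incidence excess from precursors that were not removed.
#'
#' @param params a [population_params()] bundle.
#' @param participation a [participation_series()]; padded with 1.0 to the
#'   horizon. Must not be longer than the horizon.
#' @param horizon_months simulation horizon in months from January 2018;
#'   must cover at least 2018-2050 (396 months).
#' @param seed integer RNG seed; defaults to `params$random_seed`.
#' @return a `data.table` of case records with columns `case_id`,
#'   `age_group`, `stage_at_diagnosis`, `detection_mode`
#'   (`"screen_detected"` or `"symptomatic"`), `onset_month` (preclinical
#'   onset, may be negative for pre-2018 onsets), `diagnosis_month`,
#'   `diagnostic_delay_weeks`, `treatment_delay_weeks` (both 0 here; filled
#'   by the backlog engines) and `death_month` (NA here).
#' @seealso [split_counterfactual_arrivals()]
#' @export
generate_case_stream <- function(params, participation,
                                 horizon_months = 396L,
                                 seed = params$random_seed) {
  stopifnot(inherits(params, "population_params"),
            inherits(participation, "participation_series"))
  horizon_months <- as.integer(horizon_months)
  if (horizon_months < 396L)
    stop("horizon must cover at least 2018-2050 (396 months)")
  pmult <- participation_values(participation, horizon_months)

  n <- params$cohort_size
  nb <- length(age_bands())
  set.seed(as.integer(seed))

  ## latent population -------------------------------------------------
  band <- sample.int(nb, n, replace = TRUE, prob = params$age_distribution)
  age0 <- (15 + 5 * band) + stats::runif(n, 0, 5)     # age at Jan 2018
  rate_prec <- params$precursor_incidence_rate * params$age_multipliers[band]
  # precursor onset clock runs from age 20 in person-time; persons older
  # than 20 at 2018 may carry prevalent precursors/cancers into the window
  t_prec <- (20 - age0) + stats::rexp(n, rate_prec)   # years from Jan 2018
  t_cancer <- t_prec + stats::rexp(n, params$precursor_to_preclinical_rate)
  t_clin <- t_cancer + stats::rexp(n, 1 / params$preclinical_sojourn_mean)
  t_death <- stats::rexp(n, params$other_cause_mortality[band])
  stage_onset <- sample.int(4L, n, replace = TRUE,
                            prob = params$stage_distribution_at_onset)
  u_upstage <- stats::runif(n)

  ## screening schedule -------------------------------------------------
  elig_start <- pmax(0, params$screening_start_age - age0)        # years
  elig_end <- (params$screening_end_age + 1) - age0
  offset <- sample.int(params$screening_interval_months, n,
                       replace = TRUE) - 1L                       # months
  first_round <- ceiling(elig_start * 12) + offset
  k_max <- ceiling((params$screening_end_age - params$screening_start_age)
                   * 12 / params$screening_interval_months) + 1L
  u_attend <- matrix(stats::runif(n * k_max), n, k_max)
  u_test <- matrix(stats::runif(n * k_max), n, k_max)

  diagnosed <- rep(FALSE, n)
  removed <- rep(FALSE, n)
  diag_time <- rep(NA_real_, n)                                   # years
  screen_det <- rep(FALSE, n)

  for (k in seq_len(k_max)) {
    m <- first_round + (k - 1L) * params$screening_interval_months
    ty <- m / 12                                                  # years
    active <- !diagnosed & !removed & m >= 0L & m < horizon_months &
      ty < elig_end & ty < t_death & ty < t_clin
    if (!any(active)) next
    pm <- numeric(n)
    pm[active] <- pmult[m[active] + 1L]
    attend <- active & u_attend[, k] < params$participation_baseline * pm
    has_cancer <- attend & t_cancer <= ty
    has_prec <- attend & !has_cancer & t_prec <= ty
    det <- has_cancer &
      u_test[, k] < params$screening_sensitivity_preclinical
    rem <- has_prec & u_test[, k] < params$screening_sensitivity_precursor
    diagnosed[det] <- TRUE
    screen_det[det] <- TRUE
    diag_time[det] <- ty[det]
    removed[rem] <- TRUE
  }

  ## symptomatic presentation -------------------------------------------
  sympt <- !diagnosed & !removed & t_clin >= 0 & t_clin < t_death &
    t_clin < horizon_months / 12
  diagnosed[sympt] <- TRUE
  diag_time[sympt] <- t_clin[sympt]

  idx <- which(diagnosed)
  undx_years <- pmax(0, diag_time[idx] - t_cancer[idx])
  # stage advances as a unit-jump process at the annual upstage hazard;
  # the shared uniform couples advancement across participation scenarios
  # (longer undiagnosed => stochastically more advances, same latent draw)
  adv_rate <- -log(1 - params$annual_upstage_rate)
  n_adv <- stats::qpois(u_upstage[idx], adv_rate * undx_years)
  # clinical presentation is itself a progression event: symptoms are
  # taken to accompany one further stage advance, which is what makes the
  # symptomatic stage mix worse than the screen-detected one
  n_adv <- n_adv + as.integer(!screen_det[idx])
  stage <- pmin(stage_onset[idx] + n_adv, 4L)
  band_at_dx <- pmin(nb, pmax(1L, (floor(age0[idx] + diag_time[idx]) - 20L)
                              %/% 5L + 1L))
  out <- data.table::data.table(
    case_id = idx,
    age_group = age_bands()[band_at_dx],
    stage_at_diagnosis = stage_levels()[stage],
    detection_mode = ifelse(screen_det[idx], "screen_detected", "symptomatic"),
    onset_month = as.integer(floor(12 * t_cancer[idx])),
    diagnosis_month = as.integer(floor(12 * diag_time[idx])),
    diagnostic_delay_weeks = 0,
    treatment_delay_weeks = 0,
    death_month = NA_integer_
  )
  data.table::setorderv(out, c("diagnosis_month", "case_id"))
  data.table::setattr(out, "horizon_months", horizon_months)
  out[]
}

#' Counterfactual monthly procedure arrivals from a case stream
#'
#' Every diagnosed case contributes one diagnostic arrival at its
#' counterfactual diagnosis month, and one treatment arrival per assigned
#' treatment modality (Bernoulli assignment by the configured mix, so a
#' case can need several modalities). These series are what the backlog
#' engines consume as queue arrivals; the diagnostic series also defines
#' pre-pandemic expected capacity.
#'
#' @param cases a case stream from [generate_case_stream()]; must be
#'   non-empty.
#' @param horizon_months number of months in the output series.
#' @param treatment_mix named probabilities of needing each modality.
#' @param seed seed for modality assignment.
#' @return list with `arrivals` (horizon x 4 matrix, columns `diagnosis`,
#'   `surgery`, `chemotherapy`, `radiotherapy`) and `assignments` (logical
#'   case x modality `data.table` aligned with `cases`).
#' @export
split_counterfactual_arrivals <- function(cases,
                                          horizon_months =
                                            attr(cases, "horizon_months"),
                                          treatment_mix = c(surgery = 0.7,
                                                            chemotherapy = 0.4,
                                                            radiotherapy = 0.2),
                                          seed = 1L) {
  if (nrow(cases) == 0L) stop("case stream is empty")
  stopifnot(!is.null(horizon_months),
            all(names(treatment_mix) %in% c("surgery", "chemotherapy",
                                            "radiotherapy")))
  horizon_months <- as.integer(horizon_months)
  n <- nrow(cases)
  set.seed(as.integer(seed))
  assign <- data.table::as.data.table(
    lapply(treatment_mix, function(p) stats::runif(n) < p))
  arr <- matrix(0L, horizon_months, 4L,
                dimnames = list(NULL, c("diagnosis", "surgery",
                                        "chemotherapy", "radiotherapy")))
  m <- cases$diagnosis_month + 1L      # 1-based for tabulate
  arr[, "diagnosis"] <- tabulate(m, nbins = horizon_months)
  for (mod in names(treatment_mix))
    arr[, mod] <- tabulate(m[assign[[mod]]], nbins = horizon_months)
  list(arrivals = arr, assignments = assign)
}
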