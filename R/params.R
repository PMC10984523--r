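#' Age bands used by the synthetic cohort
#'
#' Sixteen 5-year bands spanning ages 20-99, the age range the cohort
#' simulates.
#'
#' @return character vector of band labels ("20-24", ..., "95-99").
#' @export
age_bands <- function() {
  lo <- seq(20L, 95L, by = 5L)
  sprintf("%d-%d", lo, lo + 4L)
}

# midpoints of the model age bands
age_band_mid <- function() seq(22.5, 97.5, by = 5)

#' Natural-history parameters for the synthetic cohort
#'
#' Bundles every rate the case-stream generator needs. The generator is a
#' deliberately simple three-compartment surrogate (precancerous precursor
#' -> preclinical cancer -> clinical presentation, exponential dwell times)
#' for the full microsimulation natural-history models used in national
#' CRC-screening evaluations; its defaults are this package's own and are
#' not calibrated to any registry. They are chosen so that roughly 60% of
#' comparator diagnoses in screening-eligible ages are screen-detected and
#' the stage mix at symptomatic presentation is later than at screen
#' detection (see the methods vignette).
#'
#' @param cohort_size number of simulated persons.
#' @param age_distribution weights over the 16 bands of [age_bands()];
#'   normalised internally.
#' @param precursor_incidence_rate precursor onsets per person-year in the
#'   reference band (50-54); scaled by `age_multipliers`.
#' @param age_multipliers relative precursor-incidence multiplier per band.
#' @param precursor_to_preclinical_rate transitions per precursor-year.
#' @param preclinical_sojourn_mean mean preclinical dwell, years.
#' @param annual_upstage_rate probability per year that a yet-undiagnosed
#'   cancer advances one stage.
#' @param stage_distribution_at_onset simplex over stages I-IV at
#'   preclinical onset; must sum to 1 within 1e-12.
#' @param screening_sensitivity_preclinical per-attended-screen probability
#'   of detecting a preclinical cancer.
#' @param screening_sensitivity_precursor per-attended-screen probability
#'   of detecting (and removing) a precursor lesion.
#' @param participation_baseline per-invitation-round attendance probability
#'   at status quo.
#' @param other_cause_mortality deaths per person-year by age band.
#' @param screening_start_age,screening_end_age inclusive eligibility ages
#'   for the biennial organised-screening program.
#' @param screening_interval_months months between invitation rounds.
#' @param random_seed default seed used when none is passed to
#'   [generate_case_stream()].
#' @return an object of class `population_params`.
#' @export
population_params <- function(cohort_size = 200000L,
                              age_distribution = NULL,
                              precursor_incidence_rate = 0.003,
                              age_multipliers = NULL,
                              precursor_to_preclinical_rate = 0.02,
                              preclinical_sojourn_mean = 5,
                              annual_upstage_rate = 0.25,
                              stage_distribution_at_onset =
                                c(I = 0.50, II = 0.30, III = 0.15, IV = 0.05),
                              screening_sensitivity_preclinical = 0.85,
                              screening_sensitivity_precursor = 0.30,
                              participation_baseline = 0.55,
                              other_cause_mortality = NULL,
                              screening_start_age = 50L,
                              screening_end_age = 74L,
                              screening_interval_months = 24L,
                              random_seed = 1L) {
  bands <- age_bands()
  mid <- age_band_mid()
  if (is.null(age_distribution)) {
    # plausible adult pyramid: broad plateau 20-60, tapering thereafter
    age_distribution <- c(8.5, 8.5, 8.8, 9.0, 8.8, 8.5, 8.0, 7.5,
                          6.8, 6.0, 5.2, 4.2, 3.2, 2.2, 1.3, 0.5)
  }
  if (is.null(age_multipliers)) {
    # precursor incidence rises steeply with age; reference band 50-54
    age_multipliers <- (mid / 52.5)^2.5
  }
  if (is.null(other_cause_mortality)) {
    # Gompertz-like all-cause (non-CRC) mortality
    other_cause_mortality <- 0.0008 * exp(0.085 * (mid - 30))
  }
  p <- list(
    cohort_size = as.integer(cohort_size),
    age_distribution = stats::setNames(
      age_distribution / sum(age_distribution), bands),
    precursor_incidence_rate = precursor_incidence_rate,
    age_multipliers = stats::setNames(age_multipliers, bands),
    precursor_to_preclinical_rate = precursor_to_preclinical_rate,
    preclinical_sojourn_mean = preclinical_sojourn_mean,
    annual_upstage_rate = annual_upstage_rate,
    stage_distribution_at_onset = stage_distribution_at_onset,
    screening_sensitivity_preclinical = screening_sensitivity_preclinical,
    screening_sensitivity_precursor = screening_sensitivity_precursor,
    participation_baseline = participation_baseline,
    other_cause_mortality = stats::setNames(other_cause_mortality, bands),
    screening_start_age = as.integer(screening_start_age),
    screening_end_age = as.integer(screening_end_age),
    screening_interval_months = as.integer(screening_interval_months),
    random_seed = as.integer(random_seed)
  )
  validate_population_params(p)
  structure(p, class = "population_params")
}

validate_population_params <- function(p) {
  num <- unlist(p[c("precursor_incidence_rate", "precursor_to_preclinical_rate",
                    "preclinical_sojourn_mean", "annual_upstage_rate",
                    "stage_distribution_at_onset",
                    "screening_sensitivity_preclinical",
                    "screening_sensitivity_precursor",
                    "participation_baseline", "other_cause_mortality",
                    "age_distribution", "age_multipliers")])
  if (any(!is.finite(num))) stop("non-finite natural-history parameter")
  if (p$cohort_size < 1L) stop("cohort_size must be positive")
  probs <- c(p$annual_upstage_rate, p$screening_sensitivity_preclinical,
             p$screening_sensitivity_precursor, p$participation_baseline,
             p$stage_distribution_at_onset)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rates <- c(p$precursor_incidence_rate, p$precursor_to_preclinical_rate,
             p$preclinical_sojourn_mean, p$other_cause_mortality)
  if (any(rates <= 0)) stop("rates must be strictly positive")
  if (length(p$stage_distribution_at_onset) != 4L ||
      abs(sum(p$stage_distribution_at_onset) - 1) > 1e-12)
    stop("stage_distribution_at_onset must be a length-4 simplex (tol 1e-12)")
  invisible(p)
}

#' Monthly screening-participation multiplier series
#'
#' A relative participation multiplier per calendar month (1.0 = status
#' quo), e.g. 0.6 throughout 2020 to encode a 40% screening drop. Series
#' shorter than a simulation horizon are padded with 1.0.
#'
#' @param values numeric multipliers, one per month from January 2018.
#' @param country_label free-text provenance label.
#' @return an object of class `participation_series`.
#' @examples
#' # the Canadian pattern: -40% screening throughout 2020, status quo else
#' p <- participation_series(c(rep(1, 24), rep(0.6, 12)), "Canada")
#' @export
participation_series <- function(values = numeric(0), country_label = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("participation multipliers must be finite and >= 0")
  structure(list(values = values, country_label = country_label),
            class = "participation_series")
}

# multiplier vector padded with 1.0 to `horizon_months`
participation_values <- function(participation, horizon_months) {
  v <- participation$values
  if (length(v) > horizon_months)
    stop("horizon shorter than participation series")
  c(v, rep(1, horizon_months - length(v)))
}

stage_levels <- function() c("I", "II", "III", "IV")
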