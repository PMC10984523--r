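#' Stage-specific baseline survival curves
#'
#' Survival since diagnosis on a monthly grid, one curve per stage I-IV.
#' `survival_model()` validates an arbitrary set of curves;
#' `survival_model_exponential()` builds the package default — exponential
#' survival with the monthly hazard for each stage chosen so that 5-year
#' survival matches `five_year` (placeholder values, config-overridable;
#' national stage-specific survival tables can be substituted via CSV).
#'
#' @param curves numeric matrix, rows named "I".."IV", columns months
#'   0..`months`; each row must start at 1, be non-increasing and lie in
#'   [0, 1].
#' @param form free-text label for the parametric form.
#' @return an object of class `survival_model` (the validated matrix, with
#'   a `form` attribute).
#' @export
survival_model <- function(curves, form = "custom") {
  curves <- as.matrix(curves)
  if (!identical(rownames(curves), stage_levels()))
    stop("curves must have rows I, II, III, IV")
  if (any(abs(curves[, 1] - 1) > 1e-12)) stop("S(0) must equal 1")
  if (any(curves < 0 | curves > 1)) stop("survival must lie in [0, 1]")
  if (any(apply(curves, 1, function(s) any(diff(s) > 1e-12))))
    stop("survival curves must be non-increasing")
  structure(curves, class = "survival_model", form = form)
}

#' @rdname survival_model
#' @param five_year named 5-year survival probabilities by stage.
#' @param months follow-up grid length in months since diagnosis.
#' @export
survival_model_exponential <- function(five_year = c(I = 0.95, II = 0.85,
                                                     III = 0.70, IV = 0.15),
                                       months = 120L) {
  stopifnot(identical(names(five_year), stage_levels()),
            all(five_year > 0 & five_year <= 1))
  lambda <- -log(five_year) / 60           # monthly hazards
  tgrid <- 0:months
  curves <- exp(-outer(lambda, tgrid))
  dimnames(curves) <- list(stage_levels(), tgrid)
  survival_model(curves, form = "exponential")
}

#' Read/write survival curves as CSV (stage, month, survival)
#' @param path CSV file path.
#' @rdname survival_model
#' @export
read_survival_model <- function(path) {
  x <- data.table::fread(path)
  wide <- data.table::dcast(x, stage ~ month, value.var = "survival")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$stage
  survival_model(m[stage_levels(), , drop = FALSE])
}

#' Delay-to-outcome parameters
#'
#' The mortality hazard ratio per 4-week delay (default 1.06, from a
#' meta-analysis of treatment-delay studies) and the annual upstage rates
#' of undiagnosed cancer by stage. `apply_diagnostic_hr_to_screen_detected`
#' defaults to `FALSE`: the hazard ratio is never applied to diagnostic
#' delays of screen-detected cancers, because their diagnostic-delay harm
#' is already captured by the screening model (double-counting guard).
#'
#' @param hr_per_4_weeks hazard ratio per 4 weeks of delay, > 0.
#' @param annual_upstage_rate named per-year one-stage advance
#'   probabilities for stages I-III (IV is absorbing).
#' @param apply_diagnostic_hr_to_screen_detected keep `FALSE` unless
#'   deliberately exploring the double-counting bias.
#' @param hr_mode `"continuous"` compounds the HR as `hr^(weeks/4)`;
#'   `"blocks"` compounds per whole 4-week block (sensitivity mode).
#' @return object of class `delay_impact_params`.
#' @export
delay_impact_params <- function(hr_per_4_weeks = 1.06,
                                annual_upstage_rate =
                                  c(I = 0.35, II = 0.30, III = 0.25, IV = 0),
                                apply_diagnostic_hr_to_screen_detected = FALSE,
                                hr_mode = c("continuous", "blocks")) {
  hr_mode <- match.arg(hr_mode)
  stopifnot(hr_per_4_weeks > 0,
            identical(names(annual_upstage_rate), stage_levels()),
            all(annual_upstage_rate >= 0 & annual_upstage_rate <= 1),
            annual_upstage_rate[["IV"]] == 0)
  structure(list(hr_per_4_weeks = hr_per_4_weeks,
                 annual_upstage_rate = annual_upstage_rate,
                 apply_diagnostic_hr_to_screen_detected =
                   apply_diagnostic_hr_to_screen_detected,
                 hr_mode = hr_mode),
            class = "delay_impact_params")
}

#' Hazard multiplier implied by a delay
#'
#' `hr^(delay_weeks / 4)` under continuous compounding (default), or
#' `hr^floor(delay_weeks / 4)` in whole-block mode.
#'
#' @param delay_weeks non-negative delay(s), weeks.
#' @param params a [delay_impact_params()] bundle.
#' @return hazard multiplier(s) >= 0.
#' @examples
#' delay_hazard_multiplier(4, delay_impact_params())  # 1.06
#' delay_hazard_multiplier(8, delay_impact_params())  # 1.06^2
#' @export
delay_hazard_multiplier <- function(delay_weeks, params =
                                      delay_impact_params()) {
  if (any(!is.finite(delay_weeks)) || any(delay_weeks < 0))
    stop("delay_weeks must be finite and non-negative")
  ex <- if (params$hr_mode == "blocks") floor(delay_weeks / 4)
  else delay_weeks / 4
  params$hr_per_4_weeks^ex
}

#' Transform survival under a proportional-hazards multiplier
#'
#' Under proportional hazards, multiplying the hazard by `m` raises
#' survival to the power `m`: `S_delayed(t) = S(t)^m`.
#'
#' @param survival a [survival_model()].
#' @param multiplier hazard multiplier > 0.
#' @return a `survival_model` with transformed curves.
#' @export
apply_hazard_to_survival <- function(survival, multiplier) {
  stopifnot(inherits(survival, "survival_model"))
  if (length(multiplier) != 1L || !is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be a single positive number")
  if (multiplier == 1) return(survival)
  survival_model(unclass(survival)^multiplier,
                 form = paste0(attr(survival, "form"), "^", multiplier))
}

#' Stage shift caused by a diagnostic delay
#'
#' A yet-undiagnosed cancer of stage s advances one stage during a delay of
#' `d` weeks with probability `1 - (1 - annual_upstage_rate[s])^(d / 52)`;
#' stage IV absorbs. Analytic mode returns the resulting distribution over
#' stages; sampling mode draws one stage per case.
#'
#' @param stage stage label(s) "I".."IV".
#' @param diagnostic_delay_weeks non-negative delay(s).
#' @param params a [delay_impact_params()] bundle.
#' @param mode `"analytic"` or `"sample"`.
#' @param seed RNG seed for sampling mode.
#' @return analytic: matrix (cases x stages) of probabilities summing to 1
#'   per row; sample: character vector of stages.
#' @examples
#' apply_upstaging("II", 26,
#'   delay_impact_params(annual_upstage_rate =
#'     c(I = 0.3, II = 0.3, III = 0.3, IV = 0)))  # P(III) = 1 - 0.7^0.5
#' @export
apply_upstaging <- function(stage, diagnostic_delay_weeks,
                            params = delay_impact_params(),
                            mode = c("analytic", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  if (!all(stage %in% stage_levels()))
    stop("unknown stage label: ",
         paste(setdiff(stage, stage_levels()), collapse = ", "))
  if (any(diagnostic_delay_weeks < 0)) stop("delay must be non-negative")
  n <- max(length(stage), length(diagnostic_delay_weeks))
  stage <- rep_len(stage, n)
  d <- rep_len(diagnostic_delay_weeks, n)
  rate <- params$annual_upstage_rate[stage]
  p_up <- 1 - (1 - rate)^(d / 52)
  p_up[stage == "IV"] <- 0                 # absorbing
  if (mode == "sample") {
    set.seed(as.integer(seed))
    s_idx <- match(stage, stage_levels()) +
      as.integer(stats::runif(n) < p_up)
    return(stage_levels()[pmin(s_idx, 4L)])
  }
  out <- matrix(0, n, 4L, dimnames = list(NULL, stage_levels()))
  s_idx <- match(stage, stage_levels())
  out[cbind(seq_len(n), s_idx)] <- 1 - p_up
  up_idx <- pmin(s_idx + 1L, 4L)
  out[cbind(seq_len(n), up_idx)] <- out[cbind(seq_len(n), up_idx)] + p_up
  out
}

#' Monthly excess-death series attributable to delays
#'
#' For each case the effective delay entering the hazard ratio is the
#' treatment delay plus, for symptomatic cases only, the diagnostic delay
#' (the double-counting guard exempts screen-detected diagnostic delays).
#' The diagnostic delay also upstages the case analytically via
#' [apply_upstaging()]. The case's excess-death contribution at month `t`
#' after diagnosis is the difference of cumulative-incidence curves
#' `F = 1 - S` between the delayed (possibly upstaged, hazard-multiplied)
#' and baseline states, and contributions are aggregated onto the calendar
#' grid at the case's diagnosis month.
#'
#' @param cases case records carrying `stage_at_diagnosis`,
#'   `detection_mode`, `diagnosis_month`, `diagnostic_delay_weeks` and
#'   `treatment_delay_weeks`.
#' @param survival a [survival_model()].
#' @param params a [delay_impact_params()] bundle.
#' @param horizon_months calendar length of the output series; must cover
#'   the last diagnosis month plus the survival grid (else rejected).
#' @return numeric vector of monthly excess deaths (length
#'   `horizon_months`), with the grand total in `attr(, "total")`.
#' @export
excess_deaths <- function(cases, survival, params = delay_impact_params(),
                          horizon_months) {
  stopifnot(inherits(survival, "survival_model"))
  need <- c("stage_at_diagnosis", "detection_mode", "diagnosis_month",
            "diagnostic_delay_weeks", "treatment_delay_weeks")
  if (!all(need %in% names(cases))) stop("cases lack delay columns")
  grid_months <- ncol(survival) - 1L
  if (horizon_months < max(cases$diagnosis_month) + grid_months + 1L)
    stop("horizon shorter than maximum follow-up")

  d_diag <- cases$diagnostic_delay_weeks *
    (cases$detection_mode == "symptomatic" |
       params$apply_diagnostic_hr_to_screen_detected)  # double-count guard
  d_treat <- cases$treatment_delay_weeks
  eff <- d_treat + d_diag
  mult <- delay_hazard_multiplier(eff, params)
  up <- apply_upstaging(cases$stage_at_diagnosis, d_diag, params,
                        mode = "analytic")

  S <- unclass(survival)
  out <- numeric(horizon_months)
  grp <- data.table::data.table(stage = cases$stage_at_diagnosis,
                                mult = mult,
                                p_up = up[cbind(seq_len(nrow(up)),
                                                pmin(match(
                                                  cases$stage_at_diagnosis,
                                                  stage_levels()) + 1L, 4L))],
                                m0 = cases$diagnosis_month)
  grp$p_up[grp$stage == "IV"] <- 0
  key <- grp[, list(n = .N), by = c("stage", "mult", "p_up", "m0")]
  for (i in seq_len(nrow(key))) {
    s <- key$stage[i]
    s_up <- stage_levels()[min(match(s, stage_levels()) + 1L, 4L)]
    Fd <- key$p_up[i] * (1 - S[s_up, ]^key$mult[i]) +
      (1 - key$p_up[i]) * (1 - S[s, ]^key$mult[i])
    Fb <- 1 - S[s, ]
    inc <- diff(Fd) - diff(Fb)
    at <- key$m0[i] + seq_len(grid_months)
    ok <- at >= 0 & at < horizon_months
    out[at[ok] + 1L] <- out[at[ok] + 1L] + key$n[i] * inc[ok]
  }
  attr(out, "total") <- sum(out)
  out
}
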