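#' Observed procedure-volume change records
#'
#' One record per (procedure type, period): the signed relative change in
#' procedure volume versus pre-pandemic expectation, e.g. -0.40 for the
#' Canadian 2020 screening drop. Periods are whole calendar years or single
#' months; yearly records are expanded to 12 equal monthly multipliers when
#' a capacity series is built, and monthly records take precedence over
#' yearly ones for the same month.
#'
#' @param procedure_type one of `screening`, `diagnosis`,
#'   `diagnostic_procedure`, `surgery`, `chemotherapy`, `radiotherapy`,
#'   `treatment` (the last applies to all three treatment modalities).
#' @param period_start "YYYY" or "YYYY-MM" (or 0-based month index).
#' @param period_kind `"year"` or `"month"`.
#' @param relative_change signed fraction, must be >= -1.
#' @return a `data.table` of class `volume_change_records`.
#' @seealso [read_volume_changes()], [build_capacity_series()]
#' @export
volume_change_records <- function(procedure_type, period_start, period_kind,
                                  relative_change) {
  types <- c("screening", "diagnosis", "diagnostic_procedure", "surgery",
             "chemotherapy", "radiotherapy", "treatment")
  if (!all(procedure_type %in% types))
    stop("unknown procedure_type: ",
         paste(setdiff(procedure_type, types), collapse = ", "))
  if (!all(period_kind %in% c("year", "month")))
    stop("period_kind must be 'year' or 'month'")
  relative_change <- as.numeric(relative_change)
  if (any(!is.finite(relative_change)) || any(relative_change < -1))
    stop("relative_change must be finite and >= -1")
  rec <- data.table::data.table(
    procedure_type = as.character(procedure_type),
    period_start = as.character(period_start),
    period_kind = as.character(period_kind),
    relative_change = relative_change)
  data.table::setattr(rec, "class",
                      c("volume_change_records", class(rec)))
  rec
}

#' Read volume-change records from CSV
#'
#' Expected columns: `procedure_type`, `period_start`, `period_kind`,
#' `relative_change`. The packaged files
#' `system.file("extdata", "volume_changes_canada.csv", package =
#' "crcdisrupt")` and `..._australia.csv` hold the observed national yearly
#' changes for 2020-2021.
#'
#' @param path CSV file path.
#' @return a `volume_change_records` table.
#' @export
read_volume_changes <- function(path) {
  x <- data.table::fread(path, colClasses = list(character = "period_start"))
  volume_change_records(x$procedure_type, x$period_start, x$period_kind,
                        x$relative_change)
}

# months covered by one record (0-based indices)
record_months <- function(period_start, period_kind) {
  if (period_kind == "year") {
    y <- as.integer(period_start)
    (y - 2018L) * 12L + 0:11
  } else {
    month_index(period_start)
  }
}

#' Scale a diagnostic-procedure change to a diagnoses change
#'
#' Where only diagnostic-procedure (colonoscopy) volumes are observed, the
#' implied change in actual cancer diagnoses is taken as a fixed fraction
#' of the procedure change's magnitude, sign preserved. The default 0.504
#' is the observed ratio of the relative decrease in CRC diagnoses to the
#' relative decrease in colonoscopy procedures in the one region where both
#' were recorded (Victoria, 2020).
#'
#' @param procedure_change signed fraction, >= -1.
#' @param scaling fraction in [0, 1].
#' @return signed fraction `scaling * procedure_change`.
#' @examples
#' procedures_to_diagnoses(-0.117) # -0.0590
#' @export
procedures_to_diagnoses <- function(procedure_change, scaling = 0.504) {
  if (any(!is.finite(procedure_change)) || any(procedure_change < -1))
    stop("procedure_change must be finite and >= -1")
  if (length(scaling) != 1L || !is.finite(scaling) ||
      scaling < 0 || scaling > 1)
    stop("scaling must lie in [0, 1]")
  scaling * procedure_change
}

#' Build a per-timestep capacity series from volume-change records
#'
#' Converts observed relative volume changes into the capacity series a
#' queue engine consumes: monthly multipliers equal to `1 + relative
#' change` during the disruption window, `1 + mitigation_factor` from the
#' mitigation start onward, and 1 elsewhere; monthly volume is divided
#' equally across the timesteps within the month (4-week months, so 2
#' two-week steps or 4 weekly steps).
#'
#' @param records a `volume_change_records` table, all rows sharing one
#'   procedure type (or `NULL` for no disruption).
#' @param baseline_monthly expected procedures per month; either a scalar
#'   or a vector of length `horizon_months` (e.g. the counterfactual
#'   arrival series).
#' @param horizon_months series length in months.
#' @param timestep_weeks 1, 2 or 4.
#' @param mitigation_factor relative capacity uplift from
#'   `mitigation_start`; 0 disables mitigation.
#' @param mitigation_start "YYYY-MM" or month index; must not overlap any
#'   record.
#' @return an object of class `capacity_series`: list with
#'   `procedure_type`, `timestep_weeks`, `steps_per_month`, `multipliers`
#'   (monthly) and `capacity` (per timestep).
#' @examples
#' rec <- volume_change_records("screening", "2020", "year", -0.40)
#' cs <- build_capacity_series(rec, baseline_monthly = 100,
#'                             horizon_months = 48)
#' cs$multipliers[25]       # 0.6 throughout 2020
#' @export
build_capacity_series <- function(records, baseline_monthly, horizon_months,
                                  timestep_weeks = 2L,
                                  mitigation_factor = 0,
                                  mitigation_start = "2022-01") {
  horizon_months <- as.integer(horizon_months)
  timestep_weeks <- as.integer(timestep_weeks)
  if (!timestep_weeks %in% c(1L, 2L, 4L))
    stop("timestep_weeks must be 1, 2 or 4")
  spm <- WEEKS_PER_MONTH %/% timestep_weeks
  if (length(baseline_monthly) == 1L)
    baseline_monthly <- rep(baseline_monthly, horizon_months)
  if (length(baseline_monthly) != horizon_months)
    stop("baseline must be scalar or one value per month")
  if (any(baseline_monthly < 0)) stop("negative baseline volume")

  mult <- rep(1, horizon_months)
  source_kind <- rep(NA_character_, horizon_months)
  ptype <- "none"
  if (!is.null(records) && nrow(records) > 0L) {
    if (length(unique(records$procedure_type)) != 1L)
      stop("records must share one procedure_type; use build_capacity_set()")
    ptype <- records$procedure_type[1L]
    for (kind in c("year", "month")) {       # monthly overrides yearly
      rk <- records[records$period_kind == kind, ]
      for (i in seq_len(nrow(rk))) {
        mo <- record_months(rk$period_start[i], kind)
        mo <- mo[mo >= 0L & mo < horizon_months]
        clash <- mo[!is.na(source_kind[mo + 1L]) & source_kind[mo + 1L] == kind]
        if (length(clash) > 0L)
          stop("overlapping contradictory records for ", ptype, " at ",
               paste(month_label(clash), collapse = ", "))
        mult[mo + 1L] <- 1 + rk$relative_change[i]
        source_kind[mo + 1L] <- kind
      }
    }
  }
  if (mitigation_factor != 0) {
    ms <- month_index(mitigation_start)
    if (ms < month_index("2022-01"))
      stop("mitigation cannot start before January 2022")
    post <- seq.int(ms, horizon_months - 1L)
    clash <- post[!is.na(source_kind[post + 1L])]
    if (length(clash) > 0L)
      stop("volume records overlap the mitigation window at ",
           paste(month_label(clash), collapse = ", "))
    mult[post + 1L] <- 1 + mitigation_factor
  }
  if (any(mult < 0)) stop("negative implied capacity")

  capacity <- rep(baseline_monthly * mult / spm, each = spm)
  structure(list(procedure_type = ptype,
                 timestep_weeks = timestep_weeks,
                 steps_per_month = spm,
                 baseline_volume = baseline_monthly,
                 multipliers = mult,
                 capacity = capacity),
            class = "capacity_series")
}

#' Capacity series for every procedure type at once
#'
#' Splits a mixed record table by procedure type, routes
#' `diagnostic_procedure` records through [procedures_to_diagnoses()] into
#' the `diagnosis` series, expands `treatment` records to each modality,
#' and applies mitigation to diagnostic and treatment series only (never
#' to screening, which has no mitigation by design).
#'
#' @inheritParams build_capacity_series
#' @param baselines named list/matrix of monthly baselines per series
#'   (`diagnosis`, `surgery`, `chemotherapy`, `radiotherapy`).
#' @param diagnoses_scaling magnitude scaling for diagnostic-procedure
#'   records (see [procedures_to_diagnoses()]).
#' @return named list of `capacity_series`.
#' @export
build_capacity_set <- function(records, baselines, horizon_months,
                               timestep_weeks = 2L, mitigation_factor = 0,
                               mitigation_start = "2022-01",
                               diagnoses_scaling = 0.504) {
  want <- c("diagnosis", "surgery", "chemotherapy", "radiotherapy")
  rec_for <- function(type) {
    if (is.null(records) || nrow(records) == 0L) return(NULL)
    r <- records[records$procedure_type == type, ]
    if (type == "diagnosis") {
      dp <- records[records$procedure_type == "diagnostic_procedure", ]
      if (nrow(dp) > 0L) {
        dp$relative_change <- procedures_to_diagnoses(dp$relative_change,
                                                      diagnoses_scaling)
        dp$procedure_type <- "diagnosis"
        r <- rbind(r, dp)
      }
    } else {
      tr <- records[records$procedure_type == "treatment", ]
      if (nrow(tr) > 0L) {
        tr$procedure_type <- type
        r <- rbind(r, tr)
      }
    }
    if (nrow(r) == 0L) NULL else r
  }
  out <- lapply(want, function(type) {
    build_capacity_series(rec_for(type),
                          baseline_monthly = baselines[[type]],
                          horizon_months = horizon_months,
                          timestep_weeks = timestep_weeks,
                          mitigation_factor = mitigation_factor,
                          mitigation_start = mitigation_start)
  })
  stats::setNames(out, want)
}

#' Net yearly relative change implied by a monthly multiplier series
#'
#' The volume-weighted mean of the monthly multipliers minus one, per
#' calendar year — the quantity a yearly total "including both increases
#' and decreases on a month-by-month basis" reports.
#'
#' @param series a `capacity_series`.
#' @return named numeric vector, one value per calendar year covered.
#' @export
net_yearly_change <- function(series) {
  stopifnot(inherits(series, "capacity_series"))
  m <- seq_along(series$multipliers) - 1L
  vol <- series$baseline_volume
  w <- if (all(vol == 0)) rep(1, length(vol)) else vol
  agg <- tapply(series$multipliers * w, month_year(m), sum) /
    tapply(w, month_year(m), sum)
  agg - 1
}
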