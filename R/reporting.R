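#' Segi world standard population
#'
#' The 18-band (0-4 ... 85+) Segi world standard weights used for age
#' standardisation, normalised to sum to 1.
#'
#' @return data.table (`age_group`, `weight`).
#' @export
segi_standard <- function() {
  w <- c(12000, 10000, 9000, 9000, 8000, 8000, 6000, 6000, 6000,
         6000, 5000, 4000, 4000, 3000, 2000, 1000, 500, 500)
  lab <- c(sprintf("%d-%d", seq(0L, 80L, 5L), seq(4L, 84L, 5L)), "85+")
  data.table::data.table(age_group = lab, weight = w / sum(w))
}

#' Map model age bands onto standard-population bands
#'
#' The cohort's 20-99 bands are mapped onto the Segi bands, with ages 85-99
#' aggregated into "85+".
#'
#' @param events named numeric vector over [age_bands()].
#' @return named numeric vector over the Segi band labels present.
#' @export
map_to_standard_bands <- function(events) {
  stopifnot(identical(names(events), age_bands()))
  lo <- seq(20L, 95L, by = 5L)
  target <- ifelse(lo >= 85L, "85+", sprintf("%d-%d", lo, lo + 4L))
  out <- tapply(events, target, sum)
  out[unique(target)]
}

#' Age-standardised rate per 100,000
#'
#' `ASR = sum_a w_a * (events_a / person_years_a) * 100000` with weights
#' normalised over the bands supplied. Bands with zero person-years must
#' have zero events (their rate is taken as 0); events and person-years
#' must share band names with the standard.
#'
#' @param events named event counts by age band.
#' @param person_years named person-years by the same bands.
#' @param standard a standard population table as from [segi_standard()];
#'   only bands present in `events` are used (weights renormalised).
#' @return rate per 100,000.
#' @examples
#' st <- data.frame(age_group = c("a", "b"), weight = c(0.25, 0.75))
#' age_standardised_rate(c(a = 1, b = 3),
#'                       c(a = 1000, b = 1000), st) # 250
#' @export
age_standardised_rate <- function(events, person_years,
                                  standard = segi_standard()) {
  if (!identical(names(events), names(person_years)))
    stop("age bands of events and person-years misaligned: ",
         paste(union(setdiff(names(events), names(person_years)),
                     setdiff(names(person_years), names(events))),
               collapse = ", "))
  missing_bands <- setdiff(names(events), standard$age_group)
  if (length(missing_bands) > 0L)
    stop("bands absent from the standard population: ",
         paste(missing_bands, collapse = ", "))
  w <- standard$weight[match(names(events), standard$age_group)]
  w <- w / sum(w)
  bad <- person_years <= 0 & events > 0
  if (any(bad))
    stop("events without person-years in band ",
         paste(names(events)[bad], collapse = ", "))
  rate <- ifelse(person_years > 0, events / person_years, 0)
  sum(w * rate) * 1e5
}

#' Annual age-standardised rates of an outcome table
#'
#' @param tab an `outcome_table` from [run_scenario()].
#' @param what `"diagnoses"` (ASIR) or `"deaths"` (ASMR).
#' @param years calendar years to report.
#' @return named numeric vector of ASRs per 100,000.
#' @export
annual_asr <- function(tab, what = c("diagnoses", "deaths"),
                       years = 2018:2050) {
  what <- match.arg(what)
  arr <- tab[[what]]
  vapply(years, function(y) {
    rows <- (y - 2018L) * 12L + 1:12
    rows <- rows[rows <= dim(arr)[1]]
    ev <- stats::setNames(apply(arr[rows, , , drop = FALSE], 2, sum),
                          age_bands())
    py <- stats::setNames(tab$person_years[as.character(y), ], age_bands())
    age_standardised_rate(map_to_standard_bands(ev),
                          map_to_standard_bands(py))
  }, numeric(1)) |> stats::setNames(years)
}

#' Relative change in annual ASRs versus a comparator
#'
#' `(ASR_scenario - ASR_comparator) / ASR_comparator` per calendar year,
#' for incidence and mortality. Years with zero comparator ASR are flagged
#' `NA` (never a silent division).
#'
#' @param scenario,comparator `outcome_table`s on the same horizon.
#' @param years calendar years to report.
#' @return data.table (year, asir_scenario, asir_comparator, asir_change,
#'   asmr_scenario, asmr_comparator, asmr_change).
#' @export
relative_change_series <- function(scenario, comparator,
                                   years = 2018:2050) {
  check_paired(scenario, comparator)
  rel <- function(s, c) ifelse(c > 0, (s - c) / c, NA_real_)
  ai_s <- annual_asr(scenario, "diagnoses", years)
  ai_c <- annual_asr(comparator, "diagnoses", years)
  am_s <- annual_asr(scenario, "deaths", years)
  am_c <- annual_asr(comparator, "deaths", years)
  data.table::data.table(year = years,
                         asir_scenario = ai_s, asir_comparator = ai_c,
                         asir_change = rel(ai_s, ai_c),
                         asmr_scenario = am_s, asmr_comparator = am_c,
                         asmr_change = rel(am_s, am_c))
}

#' Write and read case streams as CSV
#'
#' @param cases a case-stream `data.table`.
#' @param path CSV file path.
#' @export
write_case_stream <- function(cases, path) {
  data.table::fwrite(cases, path)
  invisible(path)
}

#' @rdname write_case_stream
#' @export
read_case_stream <- function(path) {
  x <- data.table::fread(path, colClasses = list(
    integer = c("case_id", "onset_month", "diagnosis_month", "death_month"),
    character = c("age_group", "stage_at_diagnosis", "detection_mode"),
    numeric = c("diagnostic_delay_weeks", "treatment_delay_weeks")))
  data.table::setorderv(x, c("diagnosis_month", "case_id"))
  x[]
}

#' Write the standard outputs of a run
#'
#' Emits, under `out_dir`: per-scenario monthly outcome CSVs (diagnoses and
#' deaths by month, age band and stage), the excess table as CSV and JSON
#' (windows x components layout), and a JSON run manifest recording the
#' configuration snapshot, every seed used and the wall time.
#'
#' @param tables named list of `outcome_table`s.
#' @param excess an `excess_table` from [decompose_excess()] (or `NULL`).
#' @param config a list snapshot of the run configuration.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(tables, excess, config, out_dir) {
  t0 <- proc.time()[["elapsed"]]
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    long <- data.table::as.data.table(tab$diagnoses)
    data.table::setnames(long, c("month", "age_group", "stage", "diagnoses"))
    long$month <- as.integer(long$month) - 1L
    long$deaths <- as.numeric(tab$deaths)
    p <- file.path(out_dir, paste0("outcomes_", nm, ".csv"))
    data.table::fwrite(long, p)
    paths <- c(paths, p)
  }
  if (!is.null(excess)) {
    p <- file.path(out_dir, "excess_table.csv")
    data.table::fwrite(excess, p)
    jsonlite::write_json(
      lapply(split(excess, excess$window), as.list),
      file.path(out_dir, "excess_table.json"),
      auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p, file.path(out_dir, "excess_table.json"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crcdisrupt")),
    config = config,
    seeds = lapply(tables, function(t) t$seeds),
    scenarios = names(tables),
    wall_time_seconds = proc.time()[["elapsed"]] - t0,
    written_at = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(out_dir, "manifest.json")))
}
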