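#' Published scenario sets
#'
#' Convenience constructors for the scenario triplets analysed in the
#' source data: the no-pandemic comparator, the pandemic run without
#' mitigation, and the pandemic run with a 5% (or 15%, supplementary)
#' capacity uplift from January 2022. Volume records come from the
#' packaged national yearly change tables
#' (`inst/extdata/volume_changes_<country>.csv`); the participation series
#' is derived from the same tables' screening rows (e.g. a flat -40%
#' throughout 2020 for Canada).
#'
#' @param country `"canada"` or `"australia"`.
#' @param seeds replicate seeds shared across the three scenarios (paired
#'   seeds).
#' @param mitigation_factor capacity uplift for the mitigation member
#'   (0.05 published, 0.15 supplementary).
#' @return named list of [scenario_spec()]s: `no_pandemic`,
#'   `no_mitigation`, `mitigation`.
#' @export
published_scenarios <- function(country = c("canada", "australia"),
                                seeds = 1:10, mitigation_factor = 0.05) {
  country <- match.arg(country)
  rec <- read_volume_changes(system.file(
    "extdata", paste0("volume_changes_", country, ".csv"),
    package = "crcdisrupt", mustWork = TRUE))
  part <- screening_participation_from_records(rec, country)
  cap_rec <- rec[rec$procedure_type != "screening", ]
  list(
    no_pandemic = scenario_spec("no_pandemic",
                                participation_series(numeric(0), country),
                                seeds = seeds),
    no_mitigation = scenario_spec("pandemic_no_mitigation", part,
                                  volume_records = cap_rec, seeds = seeds),
    mitigation = scenario_spec("pandemic_mitigation", part,
                               volume_records = cap_rec,
                               mitigation_factor = mitigation_factor,
                               mitigation_start = "2022-01", seeds = seeds))
}

#' Participation series implied by screening volume records
#'
#' Expands yearly/monthly screening change records into a monthly
#' multiplier series (1 + relative change during each record's period, 1
#' elsewhere), ending at the last record.
#'
#' @param records a `volume_change_records` table (screening rows used).
#' @param country_label provenance label.
#' @return a [participation_series()].
#' @export
screening_participation_from_records <- function(records,
                                                 country_label = "") {
  scr <- records[records$procedure_type == "screening", ]
  if (nrow(scr) == 0L) return(participation_series(numeric(0), country_label))
  months <- unlist(lapply(seq_len(nrow(scr)), function(i)
    record_months(scr$period_start[i], scr$period_kind[i])))
  v <- rep(1, max(months) + 1L)
  for (i in seq_len(nrow(scr)))
    v[record_months(scr$period_start[i], scr$period_kind[i]) + 1L] <-
      1 + scr$relative_change[i]
  participation_series(v, country_label)
}
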