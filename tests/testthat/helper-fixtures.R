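# shared fixtures: a small cohort for fast stream generation, the Canadian
# participation dip, and a minimal hand-built outcome table

small_params <- function(cohort = 20000L, ...) {
  population_params(cohort_size = cohort, ...)
}

canada_dip <- function(depth = 0.4) {
  participation_series(c(rep(1, 24), rep(1 - depth, 12)), "canada")
}

flat_participation <- function() participation_series(numeric(0))

# an outcome_table whose monthly totals are set by hand: `diagnoses` and
# `deaths` are scalars-per-month vectors recycled over months, spread over
# one age band / stage so window sums are exact
fake_outcome <- function(diagnoses_monthly, deaths_monthly,
                         out_months = 420L, seeds = 1L) {
  dx <- array(0, c(out_months, 16L, 4L),
              dimnames = list(NULL, age_bands(), c("I", "II", "III", "IV")))
  de <- dx
  dx[, 7L, 2L] <- rep_len(diagnoses_monthly, out_months)
  de[, 7L, 2L] <- rep_len(deaths_monthly, out_months)
  py <- matrix(1e5, ceiling(out_months / 12), 16L,
               dimnames = list(2018L + seq_len(ceiling(out_months / 12)) - 1L,
                               age_bands()))
  structure(list(diagnoses = dx, deaths = de, person_years = py,
                 horizon_months = out_months, out_months = out_months,
                 name = "fake", seeds = seeds, engine = "none"),
            class = "outcome_table")
}
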