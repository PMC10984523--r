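test_that("a yearly -40% screening record scales 2020 capacity to 60%", {
  rec <- volume_change_records("screening", "2020", "year", -0.40)
  cs <- build_capacity_series(rec, baseline_monthly = 100,
                              horizon_months = 48, timestep_weeks = 4)
  expect_equal(cs$capacity[25:36], rep(60, 12))
  expect_equal(cs$capacity[37:48], rep(100, 12))
  expect_equal(cs$multipliers[1:24], rep(1, 24))
})

test_that("no records and no mitigation give unit multipliers", {
  cs <- build_capacity_series(NULL, 100, 24)
  expect_equal(cs$multipliers, rep(1, 24))
  expect_equal(cs$capacity, rep(50, 48))    # 2-week steps split the month
})

test_that("mitigation lifts capacity by its factor from its start month", {
  cs <- build_capacity_series(NULL, 100, 60, timestep_weeks = 4,
                              mitigation_factor = 0.05,
                              mitigation_start = "2022-01")
  expect_equal(cs$capacity[49:60], rep(105, 12))
  expect_equal(cs$capacity[1:48], rep(100, 48))  # never before its start
  expect_error(build_capacity_series(NULL, 100, 60,
                                     mitigation_factor = 0.05,
                                     mitigation_start = "2021-06"),
               "2022")
})

test_that("timestep resampling conserves monthly volume", {
  rec <- volume_change_records("surgery", "2020", "year", -0.25)
  for (tw in c(1L, 2L, 4L)) {
    cs <- build_capacity_series(rec, 80, 36, timestep_weeks = tw)
    monthly <- colSums(matrix(cs$capacity, nrow = cs$steps_per_month))
    expect_equal(monthly, 80 * cs$multipliers)
  }
})

test_that("monthly records override yearly; contradictions are rejected", {
  rec <- volume_change_records(c("diagnosis", "diagnosis"),
                               c("2020", "2020-04"),
                               c("year", "month"),
                               c(-0.10, -0.50))
  cs <- build_capacity_series(rec, 100, 36, timestep_weeks = 4)
  expect_equal(cs$capacity[28], 50)     # April 2020 from the monthly record
  expect_equal(cs$capacity[27], 90)     # March 2020 from the yearly record
  clash <- volume_change_records(c("diagnosis", "diagnosis"),
                                 c("2020", "2020"), c("year", "year"),
                                 c(-0.1, -0.2))
  expect_error(build_capacity_series(clash, 100, 36), "2020-01")
  mixed <- volume_change_records(c("surgery", "diagnosis"),
                                 c("2020", "2020"), c("year", "year"),
                                 c(-0.1, -0.2))
  expect_error(build_capacity_series(mixed, 100, 36), "one procedure_type")
})

test_that("yearly expansion round-trips through net_yearly_change", {
  rec <- volume_change_records("chemotherapy", "2021", "year", -0.137)
  cs <- build_capacity_series(rec, 100, 60, timestep_weeks = 4)
  nyc <- net_yearly_change(cs)
  expect_equal(unname(nyc[["2021"]]), -0.137, tolerance = 1e-12)
  expect_equal(unname(nyc[["2020"]]), 0, tolerance = 1e-12)
  # a mixed monthly series: net change is the volume-weighted mean - 1
  rec2 <- volume_change_records(rep("surgery", 2),
                                c("2020-01", "2020-02"),
                                rep("month", 2), c(-0.4, 0.2))
  cs2 <- build_capacity_series(rec2, 100, 36, timestep_weeks = 4)
  expect_equal(unname(net_yearly_change(cs2)[["2020"]]),
               (0.6 + 1.2 + 10) / 12 - 1, tolerance = 1e-12)
})

test_that("procedures-to-diagnoses scaling is sign-preserving", {
  expect_equal(procedures_to_diagnoses(-0.117), -0.058968)
  expect_equal(procedures_to_diagnoses(0), 0)
  expect_equal(procedures_to_diagnoses(-1), -0.504)
  expect_error(procedures_to_diagnoses(-1.2), ">= -1")
  expect_error(procedures_to_diagnoses(-0.1, scaling = 1.5), "\\[0, 1\\]")
})

test_that("record constructor and CSV reader validate and round-trip", {
  expect_error(volume_change_records("biopsy", "2020", "year", -0.1),
               "unknown procedure_type")
  expect_error(volume_change_records("surgery", "2020", "year", -1.2))
  can <- read_volume_changes(system.file("extdata",
                                         "volume_changes_canada.csv",
                                         package = "crcdisrupt"))
  expect_s3_class(can, "volume_change_records")
  expect_equal(can$relative_change[can$procedure_type == "screening"], -0.40)
  tmp <- tempfile(fileext = ".csv")
  data.table::fwrite(can, tmp)
  expect_equal(read_volume_changes(tmp)$relative_change,
               can$relative_change)
})

test_that("build_capacity_set wires scaling, treatment and mitigation", {
  aus <- read_volume_changes(system.file("extdata",
                                         "volume_changes_australia.csv",
                                         package = "crcdisrupt"))
  caps <- build_capacity_set(aus[aus$procedure_type != "screening", ],
                             baselines = list(diagnosis = 100, surgery = 50,
                                              chemotherapy = 30,
                                              radiotherapy = 20),
                             horizon_months = 60, timestep_weeks = 4,
                             mitigation_factor = 0.05)
  # diagnostic_procedure -11.7% scaled by 0.504 onto the diagnosis series
  expect_equal(caps$diagnosis$multipliers[25], 1 - 0.058968)
  # "treatment" records fan out to every modality
  expect_equal(caps$surgery$multipliers[37], 1 - 0.072)
  expect_equal(caps$radiotherapy$multipliers[37], 1 - 0.072)
  # mitigation applies to all four series from 2022
  for (nm in names(caps))
    expect_equal(caps[[nm]]$multipliers[49], 1.05)
})
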