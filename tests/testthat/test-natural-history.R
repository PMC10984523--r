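test_that("case stream is deterministic and paired across participation", {
  p <- small_params()
  s1 <- generate_case_stream(p, flat_participation(), 396, seed = 11)
  s2 <- generate_case_stream(p, flat_participation(), 396, seed = 11)
  expect_identical(s1, s2)
  # an explicit all-1.0 series is the comparator stream (padding identity)
  s3 <- generate_case_stream(p, participation_series(rep(1, 300)), 396,
                             seed = 11)
  expect_identical(s1, s3)
  # a different seed gives a different stream
  s4 <- generate_case_stream(p, flat_participation(), 396, seed = 12)
  expect_false(identical(s1$diagnosis_month, s4$diagnosis_month))
})

test_that("zero participation yields no screen-detected cases", {
  p <- small_params()
  s <- generate_case_stream(p, participation_series(rep(0, 396)), 396,
                            seed = 3)
  expect_true(all(s$detection_mode == "symptomatic"))
})

test_that("case records satisfy their invariants", {
  s <- generate_case_stream(small_params(), canada_dip(), 396, seed = 5)
  expect_true(all(s$detection_mode %in% c("screen_detected", "symptomatic")))
  expect_true(all(s$diagnosis_month >= s$onset_month))
  expect_true(all(s$diagnosis_month >= 0 & s$diagnosis_month < 396))
  expect_true(all(s$diagnostic_delay_weeks >= 0))
  expect_true(all(s$stage_at_diagnosis %in% c("I", "II", "III", "IV")))
  expect_false(any(duplicated(s$case_id)))   # one diagnosis per person
  expect_true(all(s$age_group %in% age_bands()))
})

test_that("invalid inputs are rejected", {
  p <- small_params()
  expect_error(generate_case_stream(p, participation_series(rep(1, 500)),
                                    396),
               "horizon shorter")
  expect_error(generate_case_stream(p, flat_participation(), 200),
               "at least 2018-2050")
  expect_error(population_params(preclinical_sojourn_mean = -1))
  expect_error(population_params(participation_baseline = 1.4))
  expect_error(population_params(stage_distribution_at_onset =
                                   c(0.5, 0.3, 0.1, 0.05)),
               "simplex")
  expect_error(participation_series(c(1, NA)))
})

test_that("a participation dip lowers screen-detection and shifts stages", {
  p <- small_params(30000L)
  seeds <- 1:12   # paired seeds make the comparison near-deterministic
  res <- vapply(seeds, function(sd) {
    s1 <- generate_case_stream(p, canada_dip(), 396, seed = sd)
    s0 <- generate_case_stream(p, flat_participation(), 396, seed = sd)
    in2020 <- function(s) s$diagnosis_month %/% 12L == 2L
    c(sd_dip = sum(s1$detection_mode == "screen_detected" & in2020(s1)),
      sd_cmp = sum(s0$detection_mode == "screen_detected" & in2020(s0)),
      cum_dip = sum(s1$diagnosis_month >= 24 & s1$diagnosis_month < 156),
      cum_cmp = sum(s0$diagnosis_month >= 24 & s0$diagnosis_month < 156))
  }, numeric(4))
  expect_lt(mean(res["sd_dip", ]), mean(res["sd_cmp", ]))
  # missed precursor removals raise cumulative 2020-2030 diagnoses
  expect_gt(mean(res["cum_dip", ]), mean(res["cum_cmp", ]))
})

test_that("deeper dips remove more screen detections (monotone coupling)", {
  p <- small_params()
  counts <- vapply(c(0.2, 0.4, 0.6), function(depth) {
    s <- generate_case_stream(p, canada_dip(depth), 396, seed = 21)
    sum(s$detection_mode == "screen_detected" &
          s$diagnosis_month %/% 12L == 2L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("symptomatic stage mix is later than screen-detected", {
  s <- generate_case_stream(small_params(50000L), flat_participation(),
                            396, seed = 2)
  late <- function(mode)
    mean(s$stage_at_diagnosis[s$detection_mode == mode] %in% c("III", "IV"))
  expect_gt(late("symptomatic"), late("screen_detected"))
})

test_that("counterfactual arrivals conserve cases", {
  s <- generate_case_stream(small_params(), flat_participation(), 396,
                            seed = 9)
  arr <- split_counterfactual_arrivals(s, 396, seed = 1)
  expect_equal(sum(arr$arrivals[, "diagnosis"]), nrow(s))
  # arrivals land exactly at the counterfactual diagnosis month
  expect_equal(as.integer(arr$arrivals[, "diagnosis"]),
               tabulate(s$diagnosis_month + 1L, 396))
  expect_error(split_counterfactual_arrivals(s[0, ], 396), "empty")
})

test_that("treatment-mix assignment matches its expectation", {
  # law-of-large-numbers check of the multinomial-style assignment
  s <- generate_case_stream(small_params(), flat_participation(), 396,
                            seed = 9)
  s <- s[seq_len(100L), ]
  mix <- c(surgery = 0.7, chemotherapy = 0.4, radiotherapy = 0.2)
  tot <- Reduce(`+`, lapply(1:200, function(sd) {
    colSums(split_counterfactual_arrivals(s, 396, mix, seed = sd)$arrivals)
  }))
  got <- tot[c("surgery", "chemotherapy", "radiotherapy")] / 200
  # SE of a mean of 200 Binomial(100, p) draws is < 0.33; allow 4 SE
  expect_true(all(abs(got - c(70, 40, 20)) < 1.4))
})
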