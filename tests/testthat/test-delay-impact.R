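test_that("the hazard multiplier compounds per 4-week delay", {
  p <- delay_impact_params()
  expect_equal(delay_hazard_multiplier(0, p), 1)
  expect_equal(delay_hazard_multiplier(4, p), 1.06)
  expect_equal(delay_hazard_multiplier(8, p), 1.1236)
  expect_equal(delay_hazard_multiplier(2, p), sqrt(1.06))
  # whole-block sensitivity mode
  pb <- delay_impact_params(hr_mode = "blocks")
  expect_equal(delay_hazard_multiplier(7, pb), 1.06)
  expect_error(delay_hazard_multiplier(-1, p), "non-negative")
})

test_that("proportional hazards transforms survival as S^m", {
  sm <- survival_model_exponential()
  expect_equal(unclass(apply_hazard_to_survival(sm, 1)), unclass(sm))
  # exponential closed form: exp(-lambda t) -> exp(-m lambda t)
  m <- 1.37
  tr <- apply_hazard_to_survival(sm, m)
  lam <- -log(0.85) / 60
  expect_equal(tr["II", "60"], exp(-m * lam * 60), tolerance = 1e-12)
  # direct power evaluation of a custom curve point
  cur <- matrix(rep(seq(1, 0.70, length.out = 61), each = 4), nrow = 4,
                dimnames = list(c("I", "II", "III", "IV"), 0:60))
  tr2 <- apply_hazard_to_survival(survival_model(cur), 1.06)
  expect_equal(unname(tr2["I", "60"]), 0.70^1.06)
  # malformed curves are rejected
  bad <- cur; bad[1, 10] <- 1.2
  expect_error(survival_model(bad))
  bad2 <- cur; bad2[2, 30] <- 0.95   # local bump breaks monotonicity
  expect_error(survival_model(bad2), "non-increasing")
  expect_error(apply_hazard_to_survival(sm, 0), "positive")
})

test_that("upstaging follows fractional-year compounding and absorbs at IV", {
  p <- delay_impact_params(annual_upstage_rate =
                             c(I = 0.3, II = 0.3, III = 0.3, IV = 0))
  d0 <- apply_upstaging("II", 0, p)
  expect_equal(unname(d0[1, ]), c(0, 1, 0, 0))
  d26 <- apply_upstaging("II", 26, p)
  expect_equal(unname(d26[1, "III"]), 1 - 0.7^0.5, tolerance = 1e-12)
  expect_equal(rowSums(d26), 1)
  dIV <- apply_upstaging("IV", 520, p)
  expect_equal(unname(dIV[1, ]), c(0, 0, 0, 1))
  expect_identical(apply_upstaging("IV", 52, p, mode = "sample"), "IV")
  expect_error(apply_upstaging("V", 1, p), "unknown stage")
  expect_error(apply_upstaging("II", -1, p), "non-negative")
})

test_that("excess deaths vanish with no delays and match the closed form", {
  sm <- survival_model_exponential()
  cases <- data.table::data.table(
    stage_at_diagnosis = c("I", "III"),
    detection_mode = c("symptomatic", "screen_detected"),
    diagnosis_month = c(24L, 30L),
    diagnostic_delay_weeks = 0, treatment_delay_weeks = 0)
  ex <- excess_deaths(cases, sm, horizon_months = 200)
  expect_equal(max(abs(ex)), 0)

  # single symptomatic case, exponential survival lambda = 0.01/month,
  # 4-week treatment delay, no upstaging: the closed-form oracle is
  # (1 - exp(-1.06 * 1.2)) - (1 - exp(-1.2))
  lam <- 0.01
  curves <- matrix(rep(exp(-lam * 0:120), each = 4), nrow = 4,
                   dimnames = list(c("I", "II", "III", "IV"), 0:120))
  smx <- survival_model(curves)
  one <- data.table::data.table(
    stage_at_diagnosis = "II", detection_mode = "symptomatic",
    diagnosis_month = 0L, diagnostic_delay_weeks = 0,
    treatment_delay_weeks = 4)
  ex1 <- excess_deaths(one, smx, horizon_months = 130)
  oracle <- (1 - exp(-1.06 * lam * 120)) - (1 - exp(-lam * 120))
  expect_equal(attr(ex1, "total"), oracle, tolerance = 1e-10)
})

test_that("screen-detected diagnostic delays are never double-counted", {
  sm <- survival_model_exponential()
  guard <- data.table::data.table(
    stage_at_diagnosis = "II", detection_mode = "screen_detected",
    diagnosis_month = 10L, diagnostic_delay_weeks = 26,
    treatment_delay_weeks = 0)
  ex <- excess_deaths(guard, sm, horizon_months = 200)
  expect_equal(attr(ex, "total"), 0)
  # the same delay on a symptomatic case does cause excess
  guard$detection_mode <- "symptomatic"
  expect_gt(attr(excess_deaths(guard, sm, horizon_months = 200), "total"), 0)
})

test_that("excess deaths are monotone in delay and zero when HR = 1", {
  sm <- survival_model_exponential()
  p1 <- delay_impact_params(hr_per_4_weeks = 1,
                            annual_upstage_rate =
                              c(I = 0, II = 0, III = 0, IV = 0))
  case <- function(d) data.table::data.table(
    stage_at_diagnosis = "III", detection_mode = "symptomatic",
    diagnosis_month = 0L, diagnostic_delay_weeks = d,
    treatment_delay_weeks = d)
  expect_equal(attr(excess_deaths(case(40), sm, p1, 200), "total"), 0)
  totals <- vapply(c(0, 2, 6, 12, 30), function(d)
    attr(excess_deaths(case(d), sm, horizon_months = 200), "total"),
    numeric(1))
  expect_true(all(diff(totals) > 0))
  expect_true(all(totals >= 0))
})

test_that("upstaging raises expected mortality when later stages fare worse", {
  sm <- survival_model_exponential()
  case <- data.table::data.table(
    stage_at_diagnosis = "II", detection_mode = "symptomatic",
    diagnosis_month = 0L, diagnostic_delay_weeks = 26,
    treatment_delay_weeks = 0)
  totals <- vapply(c(0, 0.2, 0.5), function(r) {
    p <- delay_impact_params(annual_upstage_rate =
                               c(I = r, II = r, III = r, IV = 0))
    attr(excess_deaths(case, sm, p, 200), "total")
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("survival models round-trip through CSV and reject short horizons", {
  sm <- survival_model_exponential(months = 24L)
  tmp <- tempfile(fileext = ".csv")
  long <- data.table::data.table(
    stage = rep(rownames(sm), each = ncol(sm)),
    month = rep(0:24, times = 4),
    survival = as.numeric(t(unclass(sm))))
  data.table::fwrite(long, tmp)
  back <- read_survival_model(tmp)
  expect_equal(unclass(back), unclass(sm), tolerance = 1e-12,
               ignore_attr = TRUE)
  case <- data.table::data.table(
    stage_at_diagnosis = "I", detection_mode = "symptomatic",
    diagnosis_month = 100L, diagnostic_delay_weeks = 0,
    treatment_delay_weeks = 0)
  expect_error(excess_deaths(case, sm, horizon_months = 110),
               "horizon shorter")
})
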