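test_that("the same master seed reproduces the cohort exactly", {
  cfg <- generator_config(seed = 99, frequencies = 1.5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truths, b$truths)
  c2 <- simulate_cohort(generator_config(seed = 100, frequencies = 1.5))
  expect_false(identical(a$measurements$vo2, c2$measurements$vo2))
})

test_that("zero population SDs give identical subjects at the means", {
  cfg <- generator_config(
    n_subjects = 4, n_female = 0, seed = 5,
    intercept_sd = 0, slope_sd = 0, vo2max_sd = 0, resting_sd = 0,
    loadless_k_sd = 0, lt_fraction_sd = 0
  )
  truths <- sample_subjects(cfg)
  expect_equal(unique(truths$intercept_true), 0.50)
  expect_equal(unique(truths$slope_true), 8.8)
  expect_equal(unique(truths$vo2max), 2.9)
  expect_equal(unique(truths$resting_vo2), 0.26)
})

test_that("population draws concentrate at the configured means", {
  cfg <- generator_config(n_subjects = 1000, n_female = 250, seed = 42)
  truths <- sample_subjects(cfg)
  se <- 0.6 / sqrt(1000)
  expect_lt(abs(mean(truths$vo2max) - 2.9), 3 * se)
  expect_lt(abs(mean(truths$intercept_true) - 0.50), 3 * 0.05 / sqrt(1000))
  expect_true(all(truths$lt_power <
    (truths$vo2max - truths$intercept_true) / truths$slope_true * 1000))
  expect_true(all(truths$drift_above > truths$drift_below))
})

test_that("infeasible truncation bounds are a config error", {
  cfg <- generator_config(n_subjects = 3, seed = 1, intercept_sd = 0,
    intercept_mean = 0.1) # below the 0.2 physiological floor
  expect_error(sample_subjects(cfg), class = "o2deficit_config_error")
})

test_that("expected VO2 anchors: linear regime, loadless cubic, drift ratio", {
  cfg <- generator_config()
  truth <- tibble::tibble(
    subject_id = "T", sex = "M", body_mass = 80, vo2max = 2.9,
    intercept_true = 0.50, slope_true = 8.8, resting_vo2 = 0.26,
    loadless_k = 0.1185, loadless_excess_e0 = 0.26 + 0.1185 * 1.5^3 - 0.50,
    lt_power = 200, drift_below = 0.018, drift_above = 0.049, noise_sd = 0
  )
  # at or above the non-linearity threshold the steady value is exactly linear
  p <- c(75, 120, 200, 256)
  expect_equal(
    expected_vo2(truth, p, 1.5, "bout10", "steady", cfg),
    0.50 + 8.8 * p / 1000
  )
  # loadless pedaling at 1.5 Hz: 0.26 + 0.1185 * 1.5^3 = 0.66 mmol/s (2 dp)
  ll_15 <- 0.26 + 0.1185 * 1.5^3
  expect_equal(expected_vo2(truth, 0, 1.5, "loadless", "steady", cfg), ll_15)
  expect_equal(round(ll_15, 2), 0.66)
  expect_equal(expected_vo2(truth, 0, 0.5, "loadless", "steady", cfg),
    0.26 + 0.1185 * 0.5^3)
  # the loaded curve is continuous with the loadless value at P = 0
  expect_equal(expected_vo2(truth, 0, 1.5, "bout10", "steady", cfg), ll_15)
  # early/steady ratio is exactly 1/(1+drift), switching at the threshold
  below <- expected_vo2(truth, 120, 1.5, "bout10", "early", cfg) /
    expected_vo2(truth, 120, 1.5, "bout10", "steady", cfg)
  above <- expected_vo2(truth, 240, 1.5, "bout10", "early", cfg) /
    expected_vo2(truth, 240, 1.5, "bout10", "steady", cfg)
  expect_equal(below, 1 / 1.018)
  expect_equal(above, 1 / 1.049)
  # the stepwise protocol offset applies at 1.5 Hz, not at 0.75 Hz
  expect_equal(
    expected_vo2(truth, 120, 1.5, "step4", "early", cfg) -
      expected_vo2(truth, 120, 1.5, "bout10", "early", cfg),
    0.015
  )
  expect_equal(
    expected_vo2(truth, 120, 0.75, "step4", "early", cfg) -
      expected_vo2(truth, 120, 0.75, "bout10", "early", cfg),
    0
  )
  # the low-power excess decays to zero exactly at the threshold power
  e75 <- expected_vo2(truth, 75, 1.5, "bout10", "steady", cfg) -
    (0.50 + 8.8 * 75 / 1000)
  e40 <- expected_vo2(truth, 40, 1.5, "bout10", "steady", cfg) -
    (0.50 + 8.8 * 40 / 1000)
  expect_equal(e75, 0)
  expect_equal(e40, (ll_15 - 0.50) * (1 - 40 / 75)^2)
})

test_that("a noiseless, drift-free, excess-free cohort is identified exactly", {
  cfg <- generator_config(
    n_subjects = 3, n_female = 1, seed = 8, frequencies = 1.5,
    noise_sd = 0, drift_below = 0, drift_above = 1e-9,
    low_power_excess = FALSE
  )
  co <- simulate_cohort(cfg)
  rel <- fit_demand_relations(co$measurements, methods = c("M0", "M4"))
  joined <- dplyr::left_join(rel, co$truths, by = "subject_id")
  expect_equal(joined$intercept, joined$intercept_true, tolerance = 1e-6)
  expect_equal(joined$slope, joined$slope_true, tolerance = 1e-6)
})

test_that("simulated lactate crosses the criterion near the true threshold power", {
  co <- simulate_cohort(generator_config(seed = 21, frequencies = 1.5))
  est <- co$measurements |>
    dplyr::filter(protocol == "bout10", !is.na(lactate)) |>
    dplyr::group_by(subject_id) |>
    dplyr::group_map(~ lactate_threshold_power(.x))
  est <- unlist(est)
  err <- abs(est - co$truths$lt_power)
  # logistic scale 20 W plus 0.2 mmol/L assay noise: well within one bout step
  expect_lt(stats::median(err, na.rm = TRUE), 22)
})

test_that("the simulated cohort validates and spans the documented protocols", {
  co <- simulate_cohort(generator_config(seed = 2))
  expect_s3_class(co$measurements, "tbl_df")
  expect_setequal(
    unique(co$measurements$protocol),
    c("bout10", "step4", "loadless", "rest")
  )
  # both windows recorded for the 10-min bouts
  phases <- co$measurements |>
    dplyr::filter(protocol == "bout10") |>
    dplyr::mutate(phase = window_phase(window_start, window_end))
  expect_setequal(unique(phases$phase), c("early", "steady"))
  # bout powers step by at most the configured increment
  steps <- phases |>
    dplyr::filter(phase == "steady", frequency == 1.5) |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(max_step = max(diff(sort(power))))
  expect_true(all(steps$max_step <= 22 + 1)) # +1 for rounding to whole watts
})
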