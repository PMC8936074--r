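test_that("fixed-intercept methods run a line through the high-power anchor", {
  m <- dplyr::bind_rows(
    mk_measurements(c(150, 200, 250), c(1.85, 2.3, 2.7)),
    mk_measurements(0, 0.66, protocol = "loadless"),
    mk_measurements(0, 0.26, protocol = "rest", frequency = 0)
  )
  m6 <- fit_method_relation(m, "M6")
  expect_equal(m6$intercept, 0)
  expect_equal(m6$slope, 2.7 / 250 * 1000) # 10.8 umol/J

  m5 <- fit_method_relation(
    dplyr::mutate(m, vo2 = replace(vo2, power == 250, 2.9),
      power = replace(power, power == 250, 274)),
    "M5", common_intercept = 0.48
  )
  expect_equal(m5$slope, (2.9 - 0.48) / 274 * 1000) # 8.83 umol/J

  m7 <- fit_method_relation(m, "M7")
  expect_equal(m7$intercept, 0.26)
  expect_equal(m7$slope, (2.7 - 0.26) / 250 * 1000)

  m8 <- fit_method_relation(m, "M8")
  expect_equal(m8$intercept, 0.66)
  expect_equal(m8$slope, (2.7 - 0.66) / 250 * 1000)
})

test_that("the anchor can average several top points, ties averaged first", {
  m <- dplyr::bind_rows(
    mk_measurements(c(150, 200, 250), c(1.85, 2.3, 2.7)),
    mk_measurements(250, 2.9) # replicate bout at the top power
  )
  one <- fit_method_relation(m, "M6")
  expect_equal(one$slope, mean(c(2.7, 2.9)) / 250 * 1000)
  two <- fit_method_relation(m, "M6", config = fit_config(n_high_points = 2))
  expect_equal(two$slope, mean(c(2.3, 2.8)) / mean(c(200, 250)) * 1000)
})

test_that("methods needing absent protocols raise missing-protocol errors", {
  m <- mk_measurements(c(150, 200, 250), c(1.85, 2.3, 2.7))
  expect_error(fit_method_relation(m, "M7"),
    class = "o2deficit_missing_protocol")
  expect_error(fit_method_relation(m, "M8"),
    class = "o2deficit_missing_protocol")
  expect_error(fit_method_relation(m, "M2"),
    class = "o2deficit_config_error")
  expect_error(fit_method_relation(m, "M5"),
    class = "o2deficit_config_error")
})

test_that("M2 with the free-fit intercept reproduces the M1 slope", {
  toy <- mk_toy_cohort()
  m <- dplyr::filter(toy$measurements, subject_id == "A")
  m1 <- fit_method_relation(m, "M1")
  m2 <- fit_method_relation(m, "M2", common_intercept = m1$intercept)
  expect_equal(m2$slope, m1$slope, tolerance = 1e-9)
})

test_that("mean_common_intercept averages the requested method's intercepts", {
  rel <- tibble::tibble(
    method_id = c("M1", "M1", "M0"),
    intercept = c(0.4, 0.6, 0.9)
  )
  expect_equal(mean_common_intercept(rel, "M1"), 0.5)
  expect_equal(mean_common_intercept(rel[2, ], "M1"), 0.6)
  expect_error(mean_common_intercept(rel, "M3"),
    class = "o2deficit_domain_error")
})

test_that("a noiseless cohort on exact lines is identified exactly by M0/M1/M3", {
  toy <- mk_toy_cohort()
  rel <- fit_demand_relations(toy$measurements)
  expect_equal(sort(unique(rel$method_id)), method_ids())
  expect_equal(nrow(rel), 2 * 9)
  for (sid in c("A", "B")) {
    truth <- toy$lines[[sid]]
    m0 <- dplyr::filter(rel, method_id == "M0", subject_id == sid)
    expect_equal(m0$intercept, unname(truth["a"]), tolerance = 1e-9)
    expect_equal(m0$slope, unname(truth["b"]), tolerance = 1e-9)
    # the toy's 4-min values are steady/1.03: slope shrinks by exactly 1.03
    m1 <- dplyr::filter(rel, method_id == "M1", subject_id == sid)
    expect_equal(m1$slope, unname(truth["b"]) / 1.03, tolerance = 1e-9)
  }
})

test_that("M4 on data with low-power excess raises the intercept, lowers the slope", {
  toy <- mk_toy_cohort()
  rel <- fit_demand_relations(toy$measurements)
  for (sid in c("A", "B")) {
    m0 <- dplyr::filter(rel, method_id == "M0", subject_id == sid)
    m4 <- dplyr::filter(rel, method_id == "M4", subject_id == sid)
    expect_gt(m4$intercept, m0$intercept)
    expect_lt(m4$slope, m0$slope)
  }
})

test_that("slope ordering M6 > M0 > M8 holds when loadless VO2 exceeds the intercept", {
  toy <- mk_toy_cohort()
  rel <- fit_demand_relations(toy$measurements)
  for (sid in c("A", "B")) {
    s <- function(mid) dplyr::filter(rel, method_id == mid, subject_id == sid)$slope
    expect_gt(s("M6"), s("M0"))
    expect_gt(s("M0"), s("M8"))
  }
})

test_that("cohorts missing a protocol degrade with a warning, not an error", {
  toy <- mk_toy_cohort()
  no_rest <- dplyr::filter(toy$measurements, protocol != "rest")
  expect_warning(
    rel <- fit_demand_relations(no_rest),
    regexp = "M7"
  )
  expect_false("M7" %in% rel$method_id)
  expect_true(all(setdiff(method_ids(), "M7") %in% rel$method_id))
})

test_that("cohort-mean rows average per-subject coefficients", {
  toy <- mk_toy_cohort()
  rel <- fit_demand_relations(toy$measurements, methods = c("M0", "M1"))
  cm <- cohort_mean_relations(rel)
  m0 <- dplyr::filter(cm, method_id == "M0")
  expect_equal(m0$subject_id, "cohort-mean")
  expect_equal(m0$intercept, mean(c(0.5, 0.4)), tolerance = 1e-9)
  expect_equal(m0$slope, mean(c(9, 10)), tolerance = 1e-9)
  expect_equal(m0$n_points, 2L)
})
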