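ref_mass <- (3 * 74 + 10 * 82) / 13

test_that("reference worked example: deficits from the canonical inputs", {
  tab <- aod_table(
    reference_method_coefficients(), reference_exercise_models(),
    body_mass = ref_mass
  )
  m0 <- dplyr::filter(tab, method_id == "M0")
  # 200% model, 30 s: demand 5.8*30 = 174 mmol, uptake 52.2 -> 1.52 mmol/kg
  expect_equal(m0$aod_30s_200, (174 - 52.2) / ref_mass)
  expect_equal(round(m0$aod_30s_200, 2), 1.52)
  # 250% model, 10 s for the gross-efficiency relation (0, 10.80) at 768 W
  m6 <- dplyr::filter(tab, method_id == "M6")
  expect_equal(round(m6$aod_10s_250, 2), 0.94)
})

test_that("deficit is exactly demand minus uptake in every result", {
  long <- accumulated_o2_deficit(
    reference_method_coefficients(), reference_exercise_models(),
    body_mass = ref_mass
  )
  expect_equal(long$deficit, long$accumulated_demand - long$accumulated_uptake)
  expect_equal(long$deficit_per_kg, long$deficit / ref_mass)
  expect_true(all(long$accumulated_uptake >= 0))
})

test_that("uptake is anchored to the reference demand for every method", {
  long <- accumulated_o2_deficit(
    reference_method_coefficients(), reference_exercise_models(),
    body_mass = ref_mass
  )
  per_model <- long |>
    dplyr::group_by(time_to_exhaustion) |>
    dplyr::summarise(n_uptakes = dplyr::n_distinct(accumulated_uptake))
  expect_true(all(per_model$n_uptakes == 1))
  expect_equal(
    sort(unique(long$accumulated_uptake)),
    sort(reference_exercise_models()$aerobic_fraction *
      reference_exercise_models()$demand_ref *
      reference_exercise_models()$time_to_exhaustion)
  )
})

test_that("doubling time to exhaustion doubles demand, uptake and deficit", {
  rel <- demand_relation(0.5, 9, method_id = "M3")
  base <- exercise_models(2.9, rel,
    intensity_fraction = 1.5, time_to_exhaustion = 60, aerobic_fraction = 0.47)
  doubled <- dplyr::mutate(base, time_to_exhaustion = 120)
  a <- accumulated_o2_deficit(rel, base, body_mass = 80)
  b <- accumulated_o2_deficit(rel, doubled, body_mass = 80)
  expect_equal(b$accumulated_demand, 2 * a$accumulated_demand)
  expect_equal(b$accumulated_uptake, 2 * a$accumulated_uptake)
  expect_equal(b$deficit, 2 * a$deficit)
})

test_that("both reference-demand paths agree exactly on an unrounded relation", {
  ref <- demand_relation(0.513, 8.914, method_id = "M0")
  mdl <- exercise_models(2.87, ref)
  via_model <- accumulated_o2_deficit(ref, mdl, body_mass = 80,
    reference_demand_source = "model")
  via_rel <- accumulated_o2_deficit(ref, mdl, body_mass = 80,
    reference_demand_source = "relation")
  expect_equal(via_model$deficit, via_rel$deficit, tolerance = 1e-12)
  # on printed (rounded) inputs the two paths differ only by rounding of
  # the coefficients and of the printed demands (4.4 stands for 4.35):
  # under 2% on the demand rate; on the deficit the subtracted uptake
  # amplifies that to at most ~3.5%
  printed_ref <- dplyr::filter(reference_method_coefficients(), method_id == "M0")
  a <- accumulated_o2_deficit(printed_ref, reference_exercise_models(),
    body_mass = ref_mass, reference_demand_source = "model")
  b <- accumulated_o2_deficit(printed_ref, reference_exercise_models(),
    body_mass = ref_mass, reference_demand_source = "relation")
  rate_a <- a$accumulated_demand / a$time_to_exhaustion
  rate_b <- b$accumulated_demand / b$time_to_exhaustion
  expect_true(all(abs(rate_a - rate_b) / rate_a < 0.02))
  expect_true(all(abs(a$deficit - b$deficit) / a$deficit < 0.035))
})

test_that("fully aerobic exercise at the reference relation has zero deficit", {
  ref <- demand_relation(0.5, 9, method_id = "M0")
  mdl <- exercise_models(2.9, ref,
    intensity_fraction = 1, time_to_exhaustion = 217, aerobic_fraction = 1)
  out <- accumulated_o2_deficit(ref, mdl, body_mass = 80)
  expect_equal(out$deficit, 0, tolerance = 1e-12)
})

test_that("a negative deficit is flagged with a warning, not an error", {
  low <- demand_relation(0.1, 5, method_id = "M6")
  mdl <- reference_exercise_models()
  expect_warning(
    out <- accumulated_o2_deficit(low, mdl, body_mass = 80),
    regexp = "negative deficit"
  )
  expect_true(any(out$negative_deficit))
  expect_equal(out$deficit, out$accumulated_demand - out$accumulated_uptake)
})

test_that("measured-uptake mode with a constant series equals the modelled mode", {
  rel <- demand_relation(0.5, 9, method_id = "M0")
  mdl <- exercise_models(2.9, rel,
    intensity_fraction = 2, time_to_exhaustion = 30, aerobic_fraction = 0.3)
  series <- tibble::tibble(
    time = seq(0, 40, by = 1),
    vo2 = mdl$aerobic_fraction * mdl$demand_ref
  )
  measured <- accumulated_o2_deficit(rel, mdl, body_mass = 80,
    mode = "measured_uptake", uptake_series = series)
  modelled <- accumulated_o2_deficit(rel, mdl, body_mass = 80)
  expect_equal(measured$deficit, modelled$deficit, tolerance = 1e-10)
  expect_error(
    accumulated_o2_deficit(rel, mdl, body_mass = 80, mode = "measured_uptake"),
    class = "o2deficit_config_error"
  )
})

test_that("paired t matches its closed form and the textbook implementation", {
  withr::local_seed(3)
  d <- rnorm(20, 0.05, 0.1)
  out <- paired_t(d)
  expect_equal(out$t, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  oracle <- stats::t.test(d)
  expect_equal(out$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(out$p, oracle$p.value, tolerance = 1e-12)
  sym <- paired_t(c(-1, 0, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_warning(deg <- paired_t(c(1, 1, 1)),
    class = "o2deficit_degenerate_sample")
  expect_true(is.na(deg$t))
  expect_error(paired_t(1), class = "o2deficit_domain_error")
})

test_that("compare_methods: residuals, between-subject SD and self-comparison", {
  # two-subject toy with hand-set relations
  rel <- dplyr::bind_rows(
    tibble::tibble(method_id = "M0", subject_id = c("A", "B"),
      intercept = c(0.5, 0.4), slope = c(9, 10)),
    tibble::tibble(method_id = "M6", subject_id = c("A", "B"),
      intercept = 0, slope = c(10.5, 11.2))
  )
  mdl <- reference_exercise_models()[5, ] # 10 s model
  long <- accumulated_o2_deficit(
    rel, mdl,
    body_mass = tibble::tibble(subject_id = c("A", "B"), body_mass = c(70, 90)),
    reference_demand_source = "relation"
  )
  comp <- compare_methods(long)
  m6 <- dplyr::filter(comp, method_id == "M6")
  # hand-computed residuals per subject
  aodk <- function(a, b, mass) {
    ((a + b * 768 / 1000) * 10 - 0.10 * 7.3 * 10) / mass
  }
  res_a <- aodk(0, 10.5, 70) - aodk(0.5, 9, 70)
  res_b <- aodk(0, 11.2, 90) - aodk(0.4, 10, 90)
  expect_equal(m6$bias, mean(c(res_a, res_b)), tolerance = 1e-12)
  expect_equal(m6$sd, sd(c(res_a, res_b)), tolerance = 1e-12)
  # the reference against itself: all-zero residuals, flagged t
  m0 <- dplyr::filter(comp, method_id == "M0")
  expect_equal(m0$bias, 0)
  expect_equal(m0$sd, 0)
  expect_true(is.na(m0$t))
  expect_equal(m0$note, "zero variance")
})

test_that("compare_methods reports SD missing with fewer than 2 pairs", {
  rel <- tibble::tibble(
    method_id = c("M0", "M6"), subject_id = "A",
    intercept = c(0.5, 0), slope = c(9, 10.5)
  )
  long <- accumulated_o2_deficit(rel, reference_exercise_models()[5, ],
    body_mass = tibble::tibble(subject_id = "A", body_mass = 70),
    reference_demand_source = "relation")
  comp <- compare_methods(long)
  expect_true(all(is.na(dplyr::filter(comp, method_id == "M6")$sd)))
  expect_error(
    compare_methods(dplyr::filter(long, method_id == "M6")),
    class = "o2deficit_config_error"
  )
})

test_that("bonferroni adjustment scales p by the number of method contrasts", {
  rel <- dplyr::bind_rows(
    tibble::tibble(method_id = "M0", subject_id = c("A", "B", "C"),
      intercept = 0.5, slope = 9),
    tibble::tibble(method_id = "M6", subject_id = c("A", "B", "C"),
      intercept = 0, slope = c(10.4, 10.5, 10.7)),
    tibble::tibble(method_id = "M8", subject_id = c("A", "B", "C"),
      intercept = 0.66, slope = c(8.1, 8.0, 7.8))
  )
  long <- accumulated_o2_deficit(rel, reference_exercise_models()[5, ],
    body_mass = 80, reference_demand_source = "relation")
  comp <- compare_methods(long, adjust = "bonferroni")
  test_rows <- dplyr::filter(comp, method_id != "M0")
  expect_equal(test_rows$p_adj, pmin(1, test_rows$p * 2))
})

test_that("pooled drift is the n-weighted mean of subgroup increases", {
  expect_equal(
    pooled_drift(tibble::tibble(mean_increase = c(0.026, 0.113), n = c(126, 33))),
    (0.026 * 126 + 0.113 * 33) / 159
  )
  expect_equal(pooled_drift(mean_increase = 0.05, n = 40), 0.05)
  expect_equal(pooled_drift(mean_increase = c(0.04, 0.04), n = c(5, 500)), 0.04)
  expect_error(pooled_drift(mean_increase = numeric(0), n = numeric(0)),
    class = "o2deficit_domain_error")
})
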