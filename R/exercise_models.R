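#' Canonical supramaximal exercise models
#'
#' AOD computation needs a grid of hypothetical constant-intensity
#' exercises to exhaustion. The canonical grid used throughout this
#' package spans intensities of 100-250% of the power eliciting maximal
#' O2 uptake, with times to exhaustion and aerobic energy fractions taken
#' from pooled exercise-to-exhaustion data:
#'
#' | intensity | time to exhaustion | aerobic fraction |
#' |-----------|--------------------|------------------|
#' | 100%      | 217 s (3.6 min)    | 0.75             |
#' | 120%      | 120 s              | 0.63             |
#' | 150%      | 60 s               | 0.47             |
#' | 200%      | 30 s               | 0.30             |
#' | 250%      | 10 s               | 0.10             |
#'
#' `reference_exercise_models()` returns this grid evaluated for the
#' reference cohort of the original cycle-ergometry comparison study
#' (mean VO2max 2.9 mmol s^-1; reference relation a = 0.48 mmol s^-1,
#' b = 8.77 umol J^-1), with the demand and power columns exactly as
#' reported there (demands 2.9-7.3 mmol s^-1, powers 274-768 W).
#' `exercise_models()` recomputes demand and power for any cohort from
#' its mean VO2max and a fitted reference relation.
#'
#' @param vo2max Cohort mean maximal O2 uptake, mmol s^-1.
#' @param reference A [demand_relation()] used to convert demands into
#'   powers.
#' @param intensity_fraction,time_to_exhaustion,aerobic_fraction The grid
#'   itself; defaults are the canonical five rows.
#' @return A tibble with columns `intensity_fraction`,
#'   `time_to_exhaustion` (s), `aerobic_fraction`, `demand_ref`
#'   (mmol s^-1) and `power` (W).
#' @examples
#' exercise_models(2.9, demand_relation(0.48, 8.77))
#' @export
exercise_models <- function(vo2max, reference,
                            intensity_fraction = c(1.0, 1.2, 1.5, 2.0, 2.5),
                            time_to_exhaustion = c(217, 120, 60, 30, 10),
                            aerobic_fraction = c(0.75, 0.63, 0.47, 0.30, 0.10)) {
  stopifnot(
    inherits(reference, "demand_relation"),
    is.numeric(vo2max), vo2max > 0,
    length(intensity_fraction) == length(time_to_exhaustion),
    length(intensity_fraction) == length(aerobic_fraction),
    all(aerobic_fraction >= 0 & aerobic_fraction <= 1)
  )
  if (is.unsorted(rev(time_to_exhaustion)) &&
      is.unsorted(time_to_exhaustion)) {
    abort("`time_to_exhaustion` must be monotone in intensity.",
      class = "o2deficit_config_error"
    )
  }
  demand_ref <- intensity_fraction * vo2max
  if (any(demand_ref <= reference$intercept)) {
    abort("Model demand at or below the relation intercept gives no power.",
      class = "o2deficit_domain_error"
    )
  }
  tibble(
    intensity_fraction = intensity_fraction,
    time_to_exhaustion = time_to_exhaustion,
    aerobic_fraction = aerobic_fraction,
    demand_ref = demand_ref,
    power = invert_relation(reference, demand_ref)
  )
}

#' @rdname exercise_models
#' @export
reference_exercise_models <- function() {
  tibble(
    intensity_fraction = c(1.0, 1.2, 1.5, 2.0, 2.5),
    time_to_exhaustion = c(217, 120, 60, 30, 10),
    aerobic_fraction = c(0.75, 0.63, 0.47, 0.30, 0.10),
    demand_ref = c(2.9, 3.5, 4.4, 5.8, 7.3),
    power = c(274, 343, 438, 603, 768)
  )
}

#' Reference per-method coefficients
#'
#' The cohort-mean intercepts (mmol s^-1) and slopes (umol J^-1) of the
#' nine methods as reported for the original 13-subject cycle-ergometry
#' comparison at 1.5 Hz. Useful as a worked example and for reproducing
#' the published AOD grid with [aod_table()].
#'
#' @return A tibble with `method_id`, `label`, `intercept`, `slope`.
#' @export
reference_method_coefficients <- function() {
  left_join(
    tibble(
      method_id = method_ids(),
      intercept = c(0.48, 0.50, 0.50, 0.45, 0.60, 0.48, 0, 0.26, 0.66),
      slope = c(8.77, 8.38, 8.51, 9.00, 8.24, 8.71, 10.80, 9.66, 7.95)
    ),
    method_labels(),
    by = "method_id"
  ) %>%
    select(all_of(c("method_id", "label", "intercept", "slope")))
}

#' Aerobic energy fraction at an arbitrary time to exhaustion
#'
#' Interpolates the canonical aerobic fractions piecewise-linearly in
#' log(time) between the five canonical rows; times outside 10-217 s are
#' clamped to the nearest endpoint.
#'
#' @param time_to_exhaustion Time to exhaustion, s (vectorised).
#' @return Aerobic fraction of total energy release, in \[0, 1\].
#' @export
aerobic_fraction_at <- function(time_to_exhaustion) {
  stopifnot(is.numeric(time_to_exhaustion), all(time_to_exhaustion > 0))
  grid <- reference_exercise_models()
  stats::approx(
    x = log(grid$time_to_exhaustion),
    y = grid$aerobic_fraction,
    xout = log(time_to_exhaustion),
    rule = 2
  )$y
}
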