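#' Synthetic-cohort generator configuration
#'
#' The generator emulates the measurement structure of a graded
#' cycle-ergometry AOD study: per-subject linear VO2-power relations,
#' slow-component drift between the 3-4-min and 8-10-min windows (larger
#' at or above the lactate threshold), a non-linear VO2 excess at low
#' powers that vanishes at the frequency-dependent threshold power, a
#' cubic dependence of loadless-pedaling VO2 on pedaling frequency, a
#' small offset of the stepwise protocol relative to rested 4-min bouts,
#' and independent Gaussian measurement noise per window.
#'
#' Population defaults (mean +/- SD, truncated at physiological bounds):
#' intercept 0.50 +/- 0.05 mmol s^-1, slope 8.8 +/- 0.8 umol J^-1,
#' VO2max 2.9 +/- 0.6 mmol s^-1, resting VO2 0.26 +/- 0.03 mmol s^-1,
#' loadless cubic coefficient 0.1185 +/- 0.012 mmol s^-1 Hz^-3 (so mean
#' loadless VO2 at 1.5 Hz is 0.26 + 0.1185 * 1.5^3 = 0.66 mmol s^-1),
#' fractional 4-to-10-min drift 1.8% below / 4.9% at-or-above the
#' lactate threshold, lactate threshold at 75 +/- 6% of the power
#' eliciting VO2max, measurement noise SD 0.03 mmol s^-1 (which puts the
#' standard error of a pooled drift estimate at n around 150 on the
#' order of +/- 0.005 mmol s^-1). Body masses: women 74 +/- 7 kg, men
#' 82 +/- 7 kg; 3 women among 13 subjects.
#'
#' @param n_subjects Number of subjects.
#' @param n_female Number of women (drawn first).
#' @param frequencies Exercise pedaling frequencies, Hz.
#' @param seed Master seed; every draw derives from it.
#' @param intercept_mean,intercept_sd,slope_mean,slope_sd,vo2max_mean,vo2max_sd
#'   Population parameters of the linear relation and VO2max.
#' @param resting_mean,resting_sd Resting VO2 population parameters.
#' @param loadless_k_mean,loadless_k_sd Cubic coefficient of loadless VO2
#'   vs frequency, mmol s^-1 Hz^-3.
#' @param drift_below,drift_above Fractional VO2 rise from the 3-4-min to
#'   the 8-10-min window, below / at-or-above the lactate threshold.
#' @param step_offset_1.5,step_offset_0.75 Additive offset (mmol s^-1) of
#'   the stepwise protocol relative to rested 4-min values, per frequency.
#' @param lt_fraction_mean,lt_fraction_sd Lactate-threshold power as a
#'   fraction of the power eliciting VO2max.
#' @param lactate_scale Logistic scale (W) of the lactate-vs-power curve.
#' @param noise_sd Gaussian measurement noise SD, mmol s^-1.
#' @param p_nl Named vector of low-power non-linearity thresholds (W) by
#'   frequency (Hz as names).
#' @param power_step Largest power increment between bouts, W.
#' @param low_power_excess Enable the low-power non-linear excess.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 13,
                             n_female = 3,
                             frequencies = c(1.5, 0.75),
                             seed = 1L,
                             intercept_mean = 0.50, intercept_sd = 0.05,
                             slope_mean = 8.8, slope_sd = 0.8,
                             vo2max_mean = 2.9, vo2max_sd = 0.6,
                             resting_mean = 0.26, resting_sd = 0.03,
                             loadless_k_mean = 0.1185, loadless_k_sd = 0.012,
                             drift_below = 0.018, drift_above = 0.049,
                             step_offset_1.5 = 0.015, step_offset_0.75 = 0,
                             lt_fraction_mean = 0.75, lt_fraction_sd = 0.06,
                             lactate_scale = 20,
                             noise_sd = 0.03,
                             p_nl = c("0.75" = 30, "1.5" = 75),
                             power_step = 22,
                             low_power_excess = TRUE) {
  if (n_subjects < 1) {
    abort("`n_subjects` must be at least 1.", class = "o2deficit_config_error")
  }
  stopifnot(
    n_female >= 0, n_female <= n_subjects,
    all(frequencies > 0 & frequencies <= 3),
    intercept_sd >= 0, slope_sd >= 0, vo2max_sd >= 0, resting_sd >= 0,
    loadless_k_sd >= 0, lt_fraction_sd >= 0, noise_sd >= 0,
    drift_above > drift_below, drift_below >= 0,
    all(p_nl >= 0), !is.null(names(p_nl)), power_step > 0
  )
  structure(
    as.list(environment()),
    class = "generator_config"
  )
}

# Truncated-normal draw by resampling; aborts if the support is
# practically empty.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (any(mean < lower | mean > upper)) {
      abort("Degenerate draw outside the truncation bounds.",
        class = "o2deficit_config_error"
      )
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (tries in 1:100) {
    x <- rnorm(n * 2, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    if (length(out) >= n) {
      return(out[seq_len(n)])
    }
  }
  abort("Truncation bounds leave (almost) no support.",
    class = "o2deficit_config_error"
  )
}

#' Draw the ground-truth parameters of a synthetic cohort
#'
#' Draws one `SubjectTruth` row per subject from the population
#' distributions in the [generator_config()]. The lactate-threshold
#' power is placed at a drawn fraction (capped below 0.95) of the power
#' eliciting VO2max, so it always lies below it.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per subject: identifiers, sex,
#'   `body_mass`, `vo2max`, `intercept_true`, `slope_true`,
#'   `resting_vo2`, `loadless_k`, `loadless_excess_e0` (loadless VO2 at
#'   1.5 Hz minus the intercept), `lt_power`, `drift_below`,
#'   `drift_above`, `noise_sd`.
#' @export
sample_subjects <- function(config = generator_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_subjects
    sex <- c(rep("F", cfg$n_female), rep("M", n - cfg$n_female))
    body_mass <- ifelse(
      sex == "F",
      rnorm_trunc(n, 74, 7, lower = 40),
      rnorm_trunc(n, 82, 7, lower = 45)
    )
    intercept <- rnorm_trunc(n, cfg$intercept_mean, cfg$intercept_sd, lower = 0.2)
    slope <- rnorm_trunc(n, cfg$slope_mean, cfg$slope_sd, lower = 5)
    vo2max <- rnorm_trunc(n, cfg$vo2max_mean, cfg$vo2max_sd, lower = 1.2)
    resting <- rnorm_trunc(n, cfg$resting_mean, cfg$resting_sd, lower = 0.1)
    k <- rnorm_trunc(n, cfg$loadless_k_mean, cfg$loadless_k_sd, lower = 0.02)
    lt_frac <- rnorm_trunc(
      n, cfg$lt_fraction_mean, cfg$lt_fraction_sd,
      lower = 0.4, upper = 0.95
    )
    max_power <- (vo2max - intercept) / slope * 1000
    tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      sex = sex,
      body_mass = body_mass,
      vo2max = vo2max,
      intercept_true = intercept,
      slope_true = slope,
      resting_vo2 = resting,
      loadless_k = k,
      loadless_excess_e0 = resting + k * 1.5^3 - intercept,
      lt_power = lt_frac * max_power,
      drift_below = cfg$drift_below,
      drift_above = cfg$drift_above,
      noise_sd = cfg$noise_sd
    )
  })
}

# Threshold power of the low-power non-linearity at a frequency.
p_nl_for <- function(config, frequency) {
  freqs <- as.numeric(names(config$p_nl))
  vapply(frequency, function(f) {
    unname(config$p_nl[which.min(abs(freqs - f))])
  }, numeric(1))
}

#' Noise-free expected VO2 of a synthetic subject
#'
#' The generative model. Loadless-pedaling VO2 follows a cubic law of
#' pedaling frequency, `resting_vo2 + k f^3`. Loaded steady-state VO2 at
#' 8-10 min is the subject's linear relation plus a low-power excess
#' that decays quadratically to zero at the non-linearity threshold
#' `P_nl(f)` (smoothest sign-definite shape vanishing with zero slope at
#' the threshold) and is anchored so the curve is continuous with the
#' loadless value at P = 0:
#'
#'   steady(P) = a + b P + (resting + k f^3 - a) * max(0, 1 - P/P_nl)^2.
#'
#' The 3-4-min window value is `steady / (1 + drift)`, with the drift
#' fraction chosen by whether the bout power is below the subject's
#' lactate-threshold power. The stepwise protocol's 4-min value carries
#' a small additive protocol offset (at 1.5 Hz only, by default).
#'
#' @param truth One row of [sample_subjects()] (data frame or list).
#' @param power Power, W (vectorised).
#' @param frequency Pedaling frequency, Hz (scalar).
#' @param protocol One of [measurement_protocols()] (scalar).
#' @param window `"early"` (3-4 min) or `"steady"` (8-10 min).
#' @param config A [generator_config()] (for thresholds and offsets).
#' @return Expected VO2, mmol s^-1.
#' @export
expected_vo2 <- function(truth, power, frequency, protocol,
                         window = c("steady", "early"),
                         config = generator_config()) {
  window <- match.arg(window)
  truth <- as.list(as_tibble(truth)[1, ])
  stopifnot(
    is.numeric(power), all(power >= 0),
    protocol %in% measurement_protocols()
  )
  if (protocol == "rest") {
    return(rep(truth$resting_vo2, length(power)))
  }
  # disabling the low-power excess removes the whole non-linearity,
  # collapsing loadless pedaling onto the linear relation
  loadless_vo2 <- if (isTRUE(config$low_power_excess)) {
    truth$resting_vo2 + truth$loadless_k * frequency^3
  } else {
    truth$intercept_true
  }
  if (protocol == "loadless") {
    return(rep(loadless_vo2, length(power)))
  }

  linear <- truth$intercept_true + truth$slope_true * power / 1000
  p_nl <- p_nl_for(config, frequency)
  e_f <- loadless_vo2 - truth$intercept_true
  steady <- linear + e_f * pmax(0, 1 - power / p_nl)^2

  if (window == "steady") {
    return(steady)
  }
  drift <- ifelse(power < truth$lt_power, truth$drift_below, truth$drift_above)
  early <- steady / (1 + drift)
  if (protocol == "step4") {
    offset <- if (abs(frequency - 1.5) < abs(frequency - 0.75)) {
      config$step_offset_1.5
    } else {
      config$step_offset_0.75
    }
    early <- early + offset
  }
  early
}

# Logistic lactate-vs-power curve crossing the 4.0 mmol/L criterion
# exactly at the subject's threshold power: 1 + 6 / (1 + exp(-(P -
# lt_power)/scale)). Only the crossing matters downstream.
expected_lactate <- function(truth, power, config) {
  1 + 6 / (1 + exp(-(power - truth$lt_power) / config$lactate_scale))
}

#' Simulate a synthetic cohort of measurements
#'
#' Emits, per subject and exercise frequency: 10-min constant-power
#' bouts spanning roughly 30-95% of VO2max in steps no larger than
#' `power_step` (both the 3-4-min and 8-10-min windows recorded, with
#' blood lactate on the steady window), a 4-min stepwise incremental
#' series (22 W steps for men, 11 W for women, from 40 W), a
#' loadless-pedaling measurement, and (per subject) loadless pedaling at
#' 0.5 Hz plus a seated-rest measurement. Gaussian noise of SD
#' `noise_sd` is added independently to every window; the whole cohort
#' is a deterministic function of the config (including its seed).
#'
#' @param config A [generator_config()].
#' @return A list of class `aod_cohort` with elements `subjects`
#'   (subject table), `measurements` (measurement table) and `truths`
#'   (the [sample_subjects()] ground truth).
#' @export
simulate_cohort <- function(config = generator_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  truths <- sample_subjects(cfg)

  measurements <- withr::with_seed(cfg$seed + 1L, {
    purrr::map(seq_len(nrow(truths)), function(i) {
      truth <- truths[i, ]
      noisy <- function(x) x + rnorm(length(x), 0, truth$noise_sd)
      max_power <- (truth$vo2max - truth$intercept_true) /
        truth$slope_true * 1000

      per_freq <- purrr::map(cfg$frequencies, function(f) {
        # 10-min bouts: powers at 30-95% of VO2max in <= power_step steps
        lo <- max(0, invert_truth(truth, 0.30 * truth$vo2max))
        hi <- invert_truth(truth, 0.95 * truth$vo2max)
        n_steps <- max(1, ceiling((hi - lo) / cfg$power_step))
        powers <- round(seq(lo, hi, length.out = n_steps + 1))
        bout_steady <- tibble(
          subject_id = truth$subject_id, protocol = "bout10", frequency = f,
          power = powers, window_start = 480, window_end = 600,
          vo2 = noisy(expected_vo2(truth, powers, f, "bout10", "steady", cfg)),
          hr = round(60 + 110 * powers / max_power),
          lactate = round(
            expected_lactate(truth, powers, cfg) + rnorm(length(powers), 0, 0.2),
            1
          )
        )
        bout_early <- bout_steady %>%
          mutate(
            window_start = 180, window_end = 240,
            vo2 = noisy(expected_vo2(truth, powers, f, "bout10", "early", cfg)),
            lactate = NA_real_
          )
        step_inc <- if (truth$sex == "F") cfg$power_step / 2 else cfg$power_step
        step_powers <- seq(40, max(41, 0.95 * max_power), by = step_inc)
        steps <- tibble(
          subject_id = truth$subject_id, protocol = "step4", frequency = f,
          power = round(step_powers), window_start = 180, window_end = 240,
          vo2 = noisy(
            expected_vo2(truth, step_powers, f, "step4", "early", cfg)
          ),
          hr = round(60 + 110 * step_powers / max_power),
          lactate = round(
            expected_lactate(truth, step_powers, cfg) +
              rnorm(length(step_powers), 0, 0.2),
            1
          )
        )
        loadless <- tibble(
          subject_id = truth$subject_id, protocol = "loadless", frequency = f,
          power = 0, window_start = 480, window_end = 600,
          vo2 = noisy(expected_vo2(truth, 0, f, "loadless", "steady", cfg)),
          hr = 70, lactate = NA_real_
        )
        bind_rows(bout_steady, bout_early, steps, loadless)
      })

      extras <- bind_rows(
        tibble(
          subject_id = truth$subject_id, protocol = "loadless", frequency = 0.5,
          power = 0, window_start = 480, window_end = 600,
          vo2 = noisy(expected_vo2(truth, 0, 0.5, "loadless", "steady", cfg)),
          hr = 68, lactate = NA_real_
        ),
        tibble(
          subject_id = truth$subject_id, protocol = "rest", frequency = 0,
          power = 0, window_start = 0, window_end = 600,
          vo2 = noisy(truth$resting_vo2),
          hr = 60, lactate = NA_real_
        )
      )
      bind_rows(bind_rows(per_freq), extras)
    }) %>%
      bind_rows() %>%
      mutate(vo2 = pmax(.data$vo2, 0))
  })

  structure(
    list(
      subjects = truths %>%
        select(all_of(c("subject_id", "sex", "body_mass", "vo2max"))),
      measurements = validate_measurements(measurements),
      truths = truths
    ),
    class = "aod_cohort"
  )
}

# Power eliciting a target VO2 under the subject's true linear relation.
invert_truth <- function(truth, vo2) {
  (vo2 - truth$intercept_true) / truth$slope_true * 1000
}

#' @export
print.aod_cohort <- function(x, ...) {
  cat(sprintf(
    "<aod_cohort> %d subjects, %d measurements (%s)\n",
    nrow(x$subjects), nrow(x$measurements),
    paste(unique(x$measurements$protocol), collapse = ", ")
  ))
  invisible(x)
}

#' Write generator ground truth as JSON
#'
#' @param truths The `truths` table of [simulate_cohort()].
#' @param path Output path.
#' @export
write_truths_json <- function(truths, path) {
  jsonlite::write_json(as_tibble(truths), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
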