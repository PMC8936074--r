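#' Fitting configuration
#'
#' Collects the tunable rules shared by the nine demand-relation methods.
#'
#' @param low_power_threshold Named numeric vector mapping pedaling
#'   frequency (Hz, as names) to the minimum power (W) retained by the
#'   regression methods. Below these powers VO2 rises above the linear
#'   relation (leg accelerations, postural work), so such points are
#'   excluded — except by method M4, which deliberately keeps them. The
#'   defaults are 75 W at 1.5 Hz and 30 W at 0.75 Hz; an unlisted
#'   frequency uses the nearest listed one.
#' @param boundary Whether a power exactly at the threshold is `"keep"`ed
#'   (default) or `"drop"`ped.
#' @param common_intercept Optional forced intercept (mmol s^-1) for
#'   methods M2/M5 when fitting a single subject outside a cohort run;
#'   [fit_demand_relations()] computes it from the cohort itself.
#' @param n_high_points Number of highest-power steady-state points
#'   averaged into the anchor used by the fixed-intercept methods M5-M8.
#'   Default 1; 2-3 recommended as a safeguard against occasional poor
#'   measurements.
#' @param lactate_criterion Blood lactate criterion (mmol L^-1) defining
#'   the lactate threshold, default 4.0.
#' @param vo2max_bound Sanity multiplier: measurements above
#'   `vo2max_bound * vo2max` are rejected at validation.
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(low_power_threshold = c("0.75" = 30, "1.5" = 75),
                       boundary = c("keep", "drop"),
                       common_intercept = NULL,
                       n_high_points = 1,
                       lactate_criterion = 4.0,
                       vo2max_bound = 1.15) {
  boundary <- match.arg(boundary)
  stopifnot(
    is.numeric(low_power_threshold), all(low_power_threshold >= 0),
    !is.null(names(low_power_threshold)),
    n_high_points >= 1, lactate_criterion > 0
  )
  structure(
    list(
      low_power_threshold = low_power_threshold,
      boundary = boundary,
      common_intercept = common_intercept,
      n_high_points = as.integer(n_high_points),
      lactate_criterion = lactate_criterion,
      vo2max_bound = vo2max_bound
    ),
    class = "fit_config"
  )
}

#' @rdname fit_config
#' @param config A `fit_config`.
#' @param frequency Pedaling frequency, Hz.
#' @return `low_power_threshold_for()` returns the threshold (W) at the
#'   listed frequency nearest to `frequency`.
#' @export
low_power_threshold_for <- function(config, frequency) {
  stopifnot(inherits(config, "fit_config"), is.numeric(frequency))
  freqs <- as.numeric(names(config$low_power_threshold))
  vapply(frequency, function(f) {
    unname(config$low_power_threshold[which.min(abs(freqs - f))])
  }, numeric(1))
}

#' Classify the measurement window within a bout
#'
#' Long constant-power bouts are measured twice: once at 3-4 min ("early",
#' before the slow component has fully developed) and once at 8-10 min
#' ("steady"). A window whose start is at or beyond 6 min is classified
#' steady; anything earlier is early.
#'
#' @param window_start,window_end Window bounds, s.
#' @return Character vector, `"early"` or `"steady"`.
#' @export
window_phase <- function(window_start, window_end) {
  ifelse(window_start >= 360, "steady", "early")
}

#' Select the measurement points a method regresses on
#'
#' Applies, for one subject at one pedaling frequency, the protocol,
#' window and low-power rules of the requested method:
#'
#' * M0 and M4 use the 8-10-min window of 10-min bouts; M4 additionally
#'   keeps every power including loadless pedaling, while M0 drops powers
#'   below the low-power threshold.
#' * M1 and M2 use the 3-4-min window of rested bouts (`bout10` early
#'   window or `bout4_rest`), powers at or above threshold.
#' * M3 uses the stepwise protocol (`step4`), powers at or above threshold.
#' * M5-M8 use the 8-10-min steady points at or above threshold (the
#'   anchor-selection among them happens in [fit_method_relation()]).
#'
#' A power exactly at the threshold is kept under the default
#' `boundary = "keep"`.
#'
#' @param measurements Measurement rows for a single subject at a single
#'   frequency (plus that subject's `loadless` rows for M4).
#' @param method_id One of `"M0"` ... `"M8"`.
#' @param config A [fit_config()].
#' @return A tibble of points (`power`, `vo2`, plus passthrough columns)
#'   sorted by power.
#' @export
apply_inclusion_rules <- function(measurements, method_id, config = fit_config()) {
  m <- as_tibble(measurements)
  stopifnot(method_id %in% method_ids())
  exercise <- filter(m, !.data$protocol %in% c("rest"))
  freqs <- unique(exercise$frequency)
  if (length(freqs) > 1) {
    abort("Measurements span several pedaling frequencies; fit one at a time.",
      class = "o2deficit_domain_error"
    )
  }
  thr <- low_power_threshold_for(config, freqs[1])
  keep_power <- function(p) if (config$boundary == "keep") p >= thr else p > thr

  pts <- switch(
    method_id,
    M0 = ,
    M5 = ,
    M6 = ,
    M7 = ,
    M8 = filter(
      m, .data$protocol == "bout10",
      window_phase(.data$window_start, .data$window_end) == "steady",
      keep_power(.data$power)
    ),
    M1 = ,
    M2 = filter(
      m,
      (.data$protocol == "bout10" &
         window_phase(.data$window_start, .data$window_end) == "early") |
        .data$protocol == "bout4_rest",
      keep_power(.data$power)
    ),
    M3 = filter(m, .data$protocol == "step4", keep_power(.data$power)),
    M4 = filter(
      m,
      (.data$protocol == "bout10" &
         window_phase(.data$window_start, .data$window_end) == "steady") |
        .data$protocol == "loadless"
    )
  )
  pts <- arrange(pts, .data$power)
  regression <- method_id %in% c("M0", "M1", "M3", "M4")
  if (regression && dplyr::n_distinct(pts$power) < 2) {
    abort(
      sprintf(
        "Method %s: fewer than 2 distinct powers survive the %s rule (threshold %g W).",
        method_id,
        if (method_id == "M4") "protocol/window" else "low-power",
        thr
      ),
      class = "o2deficit_insufficient_data"
    )
  }
  if (!regression && nrow(pts) < 1) {
    abort(
      sprintf("Method %s: no steady-state points available for the anchor.", method_id),
      class = "o2deficit_insufficient_data"
    )
  }
  pts
}

#' Power at the lactate threshold
#'
#' Finds the power at which blood lactate first reaches the criterion
#' concentration (default 4.0 mmol L^-1), linearly interpolating between
#' the bracketing measurements; an exact hit returns that power. If the
#' lactate curve crosses the criterion more than once (non-monotone data)
#' the first upward crossing is used with a warning. If lactate never
#' reaches the criterion, `NA` is returned with a
#' `o2deficit_threshold_not_reached` warning — all of that subject's bouts
#' are then classified below threshold.
#'
#' @param data Data frame with columns `power` (W) and `lactate`
#'   (mmol L^-1), sorted by power (rows with missing lactate are dropped).
#' @param criterion Lactate criterion, mmol L^-1.
#' @return Threshold power, W (scalar; `NA` if not reached).
#' @examples
#' lactate_threshold_power(
#'   tibble::tibble(power = c(200, 250), lactate = c(3, 5))
#' ) # 225 W
#' @export
lactate_threshold_power <- function(data, criterion = 4.0) {
  d <- as_tibble(data)
  stopifnot(all(c("power", "lactate") %in% names(d)))
  d <- filter(d, !is.na(.data$lactate))
  d <- arrange(d, .data$power)
  if (nrow(d) == 0 || all(d$lactate < criterion)) {
    warn("Lactate never reaches the criterion; no threshold power.",
      class = "o2deficit_threshold_not_reached"
    )
    return(NA_real_)
  }
  hit <- which(d$lactate == criterion)
  cross <- which(d$lactate[-1] >= criterion & d$lactate[-nrow(d)] < criterion)
  n_cross <- length(cross) + length(hit)
  if (d$lactate[1] >= criterion) {
    return(d$power[1])
  }
  if (length(cross) > 1) {
    warn("Lactate crosses the criterion more than once; using the first crossing.")
  }
  i <- cross[1]
  if (length(hit) > 0 && hit[1] <= i + 1) {
    return(d$power[hit[1]])
  }
  lo <- d[i, ]
  hi <- d[i + 1, ]
  lo$power + (criterion - lo$lactate) / (hi$lactate - lo$lactate) *
    (hi$power - lo$power)
}

#' Polynomial fit of VO2 against pedaling frequency
#'
#' Loadless-pedaling VO2 (and the intercepts of power-demand relations)
#' rise steeply with pedaling frequency, consistent with a cubic — almost
#' equally a quadratic — function of frequency. This fits a raw
#' least-squares polynomial of the requested degree.
#'
#' @param data Data frame with columns `frequency` (Hz) and `vo2`
#'   (mmol s^-1).
#' @param degree Polynomial degree, 2 or 3.
#' @return An object of class `frequency_polyfit` with ascending
#'   `coefficients`, `degree`, `r.squared` and the fitted `domain` (Hz).
#' @export
fit_frequency_polynomial <- function(data, degree = 3) {
  d <- as_tibble(data)
  stopifnot(all(c("frequency", "vo2") %in% names(d)), degree %in% c(2, 3))
  if (dplyr::n_distinct(d$frequency) < degree + 1) {
    abort(
      sprintf("Need at least %d distinct frequencies for a degree-%d fit.",
        degree + 1, degree),
      class = "o2deficit_insufficient_data"
    )
  }
  f <- lm(vo2 ~ poly(frequency, degree, raw = TRUE), data = d)
  ss_res <- sum(stats::residuals(f)^2)
  ss_tot <- sum((d$vo2 - mean(d$vo2))^2)
  structure(
    list(
      coefficients = unname(coef(f)),
      degree = degree,
      # computed directly so saturated (exact) fits stay warning-free
      r.squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      domain = range(d$frequency),
      fit = f
    ),
    class = "frequency_polyfit"
  )
}

#' @export
predict.frequency_polyfit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), "frequency" %in% names(newdata))
  f <- newdata$frequency
  powers <- outer(f, seq(0, object$degree), `^`)
  drop(powers %*% object$coefficients)
}

#' @export
tidy.frequency_polyfit <- function(x, ...) {
  tibble(
    term = paste0("frequency^", seq(0, x$degree)),
    estimate = x$coefficients
  )
}

#' @export
glance.frequency_polyfit <- function(x, ...) {
  tibble(degree = x$degree, r.squared = x$r.squared,
    domain_lo = x$domain[1], domain_hi = x$domain[2])
}

#' @export
print.frequency_polyfit <- function(x, ...) {
  cat(sprintf(
    "<frequency_polyfit> degree %d, R^2 = %.4f\n  vo2 = %s\n",
    x$degree, x$r.squared,
    paste(sprintf("%.4g f^%d", x$coefficients, seq(0, x$degree)), collapse = " + ")
  ))
  invisible(x)
}
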