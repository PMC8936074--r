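# Small hand-built fixtures shared across the suite.

# A measurement row builder with sensible defaults.
mk_measurements <- function(power, vo2, subject_id = "S01", protocol = "bout10",
                            frequency = 1.5, window = c("steady", "early"),
                            lactate = NA_real_) {
  window <- match.arg(window)
  tibble::tibble(
    subject_id = subject_id,
    protocol = protocol,
    frequency = frequency,
    power = power,
    window_start = if (window == "steady") 480 else 180,
    window_end = if (window == "steady") 600 else 240,
    vo2 = vo2,
    hr = NA_real_,
    lactate = lactate
  )
}

# Two-subject toy cohort on exact lines (no noise): subject A on
# y = 0.5 + 9 P/1000, subject B on y = 0.4 + 10 P/1000, with rest and
# loadless rows so every method is fittable.
mk_toy_cohort <- function() {
  lines <- list(A = c(a = 0.5, b = 9), B = c(a = 0.4, b = 10))
  powers <- c(80, 120, 160, 200, 240)
  meas <- dplyr::bind_rows(lapply(names(lines), function(sid) {
    a <- lines[[sid]]["a"]
    b <- lines[[sid]]["b"]
    steady <- mk_measurements(powers, a + b * powers / 1000, subject_id = sid,
      lactate = c(1.5, 2.0, 3.0, 5.0, 7.0))
    early <- mk_measurements(powers, (a + b * powers / 1000) / 1.03,
      subject_id = sid, window = "early")
    steps <- mk_measurements(powers, (a + b * powers / 1000) / 1.03 + 0.015,
      subject_id = sid, protocol = "step4", window = "early")
    low <- mk_measurements(c(30, 50), a + b * c(30, 50) / 1000 +
      c(0.08, 0.04), subject_id = sid)
    loadless <- mk_measurements(0, a + 0.16, subject_id = sid,
      protocol = "loadless")
    rest <- mk_measurements(0, 0.26, subject_id = sid, protocol = "rest",
      frequency = 0)
    dplyr::bind_rows(steady, early, steps, low, loadless, rest)
  }))
  subjects <- tibble::tibble(
    subject_id = c("A", "B"), sex = c("F", "M"),
    body_mass = c(70, 90), vo2max = c(2.6, 3.2)
  )
  list(subjects = subjects, measurements = meas, lines = lines)
}

# Independent normal-equations solver: coefficients of y ~ 1 + x.
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# The 13-subject reference cohort mass table built from the published
# group means (3 women at 74 kg, 10 men at 82 kg).
reference_subjects <- function() {
  tibble::tibble(
    subject_id = sprintf("S%02d", 1:13),
    sex = c(rep("F", 3), rep("M", 10)),
    body_mass = c(rep(74, 3), rep(82, 10)),
    vo2max = rep(2.9, 13)
  )
}
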