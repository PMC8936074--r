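#' Linear power-to-demand relations
#'
#' The central object of the AOD framework is the linear relation between
#' mechanical power P (W) and total O2 demand Y (mmol s^-1),
#'
#'   Y = a + b P,
#'
#' with intercept `a` in mmol s^-1 and slope `b` in umol J^-1 (so that
#' numerically `Y = a + b * P / 1000`). A `demand_relation` carries the two
#' coefficients plus provenance: the method id that produced it, the
#' subject (or `"cohort-mean"`), the pedaling frequency and the number of
#' points used. Relations are never pooled across frequencies.
#'
#' @param intercept Intercept a, mmol s^-1.
#' @param slope Slope b, umol J^-1; must be positive.
#' @param method_id Method label, `"M0"` ... `"M8"` (or `NA`).
#' @param subject_id Subject label or `"cohort-mean"`.
#' @param frequency Pedaling frequency, Hz.
#' @param n_points Number of measurement points behind the fit.
#' @param fit Optional underlying `lm` fit (kept for `tidy()`/`glance()`).
#'
#' @return An object of class `demand_relation`.
#' @export
demand_relation <- function(intercept, slope, method_id = NA_character_,
                            subject_id = NA_character_, frequency = NA_real_,
                            n_points = NA_integer_, fit = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(slope), length(slope) == 1)
  if (!is.na(slope) && slope <= 0) {
    abort("Demand slope must be positive (umol J^-1).",
      class = "o2deficit_invariant_error"
    )
  }
  structure(
    list(
      intercept = as.numeric(intercept),
      slope = as.numeric(slope),
      method_id = method_id,
      subject_id = subject_id,
      frequency = as.numeric(frequency),
      n_points = as.integer(n_points),
      fit = fit
    ),
    class = "demand_relation"
  )
}

#' @export
print.demand_relation <- function(x, ...) {
  cat("<demand_relation>",
    if (!is.na(x$method_id)) x$method_id else "",
    if (!is.na(x$subject_id)) paste0("subject ", x$subject_id) else "",
    "\n"
  )
  cat(sprintf(
    "  Y = %.4f + %.4f P/1000  (a mmol/s, b umol/J; n = %s, f = %s Hz)\n",
    x$intercept, x$slope,
    ifelse(is.na(x$n_points), "?", x$n_points),
    ifelse(is.na(x$frequency), "?", format(x$frequency))
  ))
  invisible(x)
}

#' Fit a demand relation by ordinary least squares
#'
#' `fit_ols()` regresses steady-state VO2 on power with both coefficients
#' free; `fit_ols_fixed_intercept()` forces the intercept to `intercept`
#' (a constrained least-squares fit: the slope minimises
#' sum((vo2 - a0 - b P)^2), i.e. b = sum(P (vo2 - a0)) / sum(P^2)). The
#' slope is reported in umol J^-1.
#'
#' @param data Data frame with columns `power` (W) and `vo2` (mmol s^-1).
#' @param intercept Forced intercept a0, mmol s^-1.
#' @param ... Provenance fields passed on to [demand_relation()].
#' @return A [demand_relation()].
#' @examples
#' fit_ols(tibble::tibble(power = c(100, 200, 300), vo2 = c(1.5, 2.0, 2.5)))
#' fit_ols_fixed_intercept(
#'   tibble::tibble(power = 200, vo2 = 2.5),
#'   intercept = 0.5
#' )
#' @export
fit_ols <- function(data, ...) {
  d <- as_tibble(data)
  stopifnot(all(c("power", "vo2") %in% names(d)))
  if (dplyr::n_distinct(d$power) < 2) {
    abort("Need at least 2 distinct power values for a free OLS fit.",
      class = "o2deficit_singular_design"
    )
  }
  f <- lm(vo2 ~ power, data = d)
  demand_relation(
    intercept = unname(coef(f)[1]),
    slope = unname(coef(f)[2]) * 1000,
    n_points = nrow(d),
    fit = f,
    ...
  )
}

#' @rdname fit_ols
#' @export
fit_ols_fixed_intercept <- function(data, intercept, ...) {
  d <- as_tibble(data)
  stopifnot(all(c("power", "vo2") %in% names(d)), is.numeric(intercept))
  if (!any(d$power > 0)) {
    abort("Need at least one point with power > 0 for a fixed-intercept fit.",
      class = "o2deficit_singular_design"
    )
  }
  d$vo2_net <- d$vo2 - intercept
  f <- lm(vo2_net ~ 0 + power, data = d)
  demand_relation(
    intercept = intercept,
    slope = unname(coef(f)[1]) * 1000,
    n_points = nrow(d),
    fit = f,
    ...
  )
}

#' Evaluate and invert a demand relation
#'
#' `demand_at_power()` returns the O2 demand a + b P / 1000 (mmol s^-1) at
#' a power P (W); `invert_relation()` solves the relation for the power
#' eliciting a given demand, P = (Y - a) / b * 1000 (W). Demands below the
#' intercept have no non-negative power solution and abort.
#'
#' @param rel A [demand_relation()].
#' @param power Power, W (vectorised).
#' @param demand O2 demand, mmol s^-1 (vectorised).
#' @return Numeric vector (mmol s^-1 for `demand_at_power()`, W for
#'   `invert_relation()`).
#' @examples
#' rel <- demand_relation(0.48, 8.77)
#' demand_at_power(rel, 274)
#' invert_relation(rel, 2.9)
#' @export
demand_at_power <- function(rel, power) {
  stopifnot(inherits(rel, "demand_relation"), is.numeric(power))
  if (any(power < 0, na.rm = TRUE)) {
    abort("`power` must be non-negative.", class = "o2deficit_domain_error")
  }
  rel$intercept + rel$slope * power / 1000
}

#' @rdname demand_at_power
#' @export
invert_relation <- function(rel, demand) {
  stopifnot(inherits(rel, "demand_relation"), is.numeric(demand))
  if (rel$slope <= 0) {
    abort("Relation slope must be positive to invert.",
      class = "o2deficit_domain_error"
    )
  }
  if (any(demand < rel$intercept, na.rm = TRUE)) {
    abort(
      sprintf(
        "Demand below the intercept (%.3f mmol/s) has no non-negative power.",
        rel$intercept
      ),
      class = "o2deficit_domain_error"
    )
  }
  (demand - rel$intercept) / rel$slope * 1000
}

#' @export
predict.demand_relation <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), "power" %in% names(newdata))
  demand_at_power(object, newdata$power)
}

#' @export
tidy.demand_relation <- function(x, ...) {
  out <- tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    unit = c("mmol/s", "umol/J")
  )
  if (!is.null(x$fit)) {
    se <- summary(x$fit)$coefficients[, "Std. Error"]
    # fixed-intercept fits have a single coefficient (the slope, mmol/s/W)
    out$std.error <- if (length(se) == 2) {
      c(se[1], se[2] * 1000)
    } else {
      c(NA_real_, se[1] * 1000)
    }
  }
  out
}

#' @export
glance.demand_relation <- function(x, ...) {
  r2 <- sigma <- NA_real_
  if (!is.null(x$fit)) {
    s <- summary(x$fit)
    r2 <- s$r.squared
    sigma <- s$sigma
  }
  tibble(
    method_id = x$method_id,
    subject_id = x$subject_id,
    frequency = x$frequency,
    intercept = x$intercept,
    slope = x$slope,
    n_points = x$n_points,
    r.squared = r2,
    sigma = sigma
  )
}

#' Convert relations between objects and table rows
#'
#' `relation_row()` flattens a [demand_relation()] to a one-row tibble in
#' the `relations.csv` dialect (`method_id`, `subject_id`, `frequency`,
#' `intercept`, `slope`, `n_points`); `relation_from_row()` rebuilds the
#' object from such a row.
#'
#' @param rel A [demand_relation()].
#' @param row A one-row data frame with at least `intercept` and `slope`.
#' @return A tibble, or a [demand_relation()].
#' @export
relation_row <- function(rel) {
  stopifnot(inherits(rel, "demand_relation"))
  tibble(
    method_id = rel$method_id,
    subject_id = rel$subject_id,
    frequency = rel$frequency,
    intercept = rel$intercept,
    slope = rel$slope,
    n_points = rel$n_points
  )
}

#' @rdname relation_row
#' @export
relation_from_row <- function(row) {
  row <- as_tibble(row)
  stopifnot(nrow(row) == 1, all(c("intercept", "slope") %in% names(row)))
  demand_relation(
    intercept = row$intercept,
    slope = row$slope,
    method_id = if ("method_id" %in% names(row)) row$method_id else NA_character_,
    subject_id = if ("subject_id" %in% names(row)) row$subject_id else NA_character_,
    frequency = if ("frequency" %in% names(row)) row$frequency else NA_real_,
    n_points = if ("n_points" %in% names(row)) row$n_points else NA_integer_
  )
}
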