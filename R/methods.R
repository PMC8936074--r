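#' The nine demand-relation methods
#'
#' `method_ids()` lists the nine computational methods for establishing
#' the linear power-demand relation of a subject:
#'
#' * **M0** — reference: OLS on steady-state VO2 at 8-10 min of repeated
#'   10-min bouts, low powers excluded.
#' * **M1** — as M0 but using the 3-4-min window of rested bouts.
#' * **M2** — as M1 with the intercept forced to the cohort mean of the
#'   individual M1 intercepts.
#' * **M3** — OLS on the 4-min stepwise incremental protocol.
#' * **M4** — as M0 but keeping every measurement, including low powers
#'   and loadless pedaling.
#' * **M5** — intercept forced to the cohort mean of the individual M0
#'   intercepts; slope through the highest-power steady point(s).
#' * **M6** — gross efficiency: zero intercept, slope through the
#'   highest-power steady point(s).
#' * **M7** — net efficiency from resting VO2 as the intercept.
#' * **M8** — net efficiency from loadless-pedaling VO2 (at the session
#'   frequency) as the intercept.
#'
#' @return Character vector `c("M0", ..., "M8")`.
#' @export
method_ids <- function() paste0("M", 0:8)

#' @rdname method_ids
#' @return `method_labels()` returns a tibble mapping each id to a short
#'   descriptive label.
#' @export
method_labels <- function() {
  tibble(
    method_id = method_ids(),
    label = c(
      "10 min bouts (reference)",
      "4 min bouts with rest",
      "4 min bouts with rest, common y-intercept",
      "4 min stepwise increasing power",
      "10 min bouts, including low powers",
      "Fixed, measured intercept + 10 min bout(s) at high(est) power(s)",
      "Gross efficiency",
      "Net efficiency from resting O2 uptake",
      "Net efficiency from O2 uptake at loadless cycling"
    )
  )
}

# Mean of the n highest-power steady points; VO2 at tied powers is
# averaged first, then the anchor is the mean point over the top powers.
high_power_anchor <- function(points, n_high_points = 1) {
  by_power <- points %>%
    group_by(.data$power) %>%
    summarise(vo2 = mean(.data$vo2), .groups = "drop") %>%
    arrange(desc(.data$power))
  top <- head(by_power, n_high_points)
  list(power = mean(top$power), vo2 = mean(top$vo2), n = nrow(top))
}

#' Fit one method's demand relation for one subject
#'
#' Applies the method's inclusion rules (see [apply_inclusion_rules()])
#' and fits the relation: free OLS for M0/M1/M3/M4, constrained least
#' squares for M2, and a line from a fixed intercept through the mean of
#' the `n_high_points` highest-power steady points for M5-M8.
#'
#' @param measurements Measurement rows of a single subject at a single
#'   exercise frequency (the subject's `rest` and `loadless` rows may be
#'   included; M7 uses rest rows regardless of frequency, M8 uses
#'   loadless rows at the session frequency).
#' @param method_id One of [method_ids()].
#' @param config A [fit_config()].
#' @param common_intercept Forced intercept (mmol s^-1) for M2/M5;
#'   defaults to `config$common_intercept`. Cohort-level runs compute it
#'   via [fit_demand_relations()].
#' @return A [demand_relation()].
#' @export
fit_method_relation <- function(measurements, method_id, config = fit_config(),
                                common_intercept = NULL) {
  m <- as_tibble(measurements)
  stopifnot(method_id %in% method_ids())
  common_intercept <- common_intercept %||% config$common_intercept
  subject <- unique(m$subject_id)
  if (length(subject) != 1) {
    abort("`measurements` must belong to a single subject.",
      class = "o2deficit_domain_error"
    )
  }
  freq <- unique(m$frequency[!m$protocol %in% "rest"])
  if (length(freq) != 1) {
    abort("`measurements` must be at a single exercise frequency.",
      class = "o2deficit_domain_error"
    )
  }

  if (method_id %in% c("M2", "M5") && is.null(common_intercept)) {
    abort(
      sprintf("Method %s needs a cohort `common_intercept`.", method_id),
      class = "o2deficit_config_error"
    )
  }

  prov <- list(method_id = method_id, subject_id = subject, frequency = freq)

  if (method_id %in% c("M0", "M1", "M3", "M4")) {
    pts <- apply_inclusion_rules(m, method_id, config)
    return(do.call(fit_ols, c(list(data = pts), prov)))
  }
  if (method_id == "M2") {
    pts <- apply_inclusion_rules(m, "M2", config)
    return(do.call(
      fit_ols_fixed_intercept,
      c(list(data = pts, intercept = common_intercept), prov)
    ))
  }

  # M5-M8: fixed intercept, slope through the high-power anchor
  pts <- apply_inclusion_rules(m, method_id, config)
  anchor <- high_power_anchor(pts, config$n_high_points)
  a0 <- switch(
    method_id,
    M5 = common_intercept,
    M6 = 0,
    M7 = {
      rest <- filter(m, .data$protocol == "rest")
      if (nrow(rest) == 0) {
        abort("Method M7 needs at least one resting measurement.",
          class = "o2deficit_missing_protocol"
        )
      }
      mean(rest$vo2)
    },
    M8 = {
      ll <- filter(m, .data$protocol == "loadless", .data$frequency == freq)
      if (nrow(ll) == 0) {
        abort(
          "Method M8 needs a loadless-pedaling measurement at the session frequency.",
          class = "o2deficit_missing_protocol"
        )
      }
      mean(ll$vo2)
    }
  )
  demand_relation(
    intercept = a0,
    slope = (anchor$vo2 - a0) / anchor$power * 1000,
    method_id = method_id,
    subject_id = subject,
    frequency = freq,
    n_points = anchor$n
  )
}

#' Cohort mean of individual intercepts
#'
#' The forced common intercept of methods M2 and M5 is the unweighted
#' mean of the individually fitted intercepts (M1's for M2, M0's for M5).
#'
#' @param relations A relations table (as from [fit_demand_relations()])
#'   or any data frame with `method_id` and `intercept` columns.
#' @param method_id Which method's intercepts to average.
#' @return Mean intercept, mmol s^-1.
#' @export
mean_common_intercept <- function(relations, method_id = "M1") {
  r <- as_tibble(relations)
  r <- filter(r, .data$method_id == !!method_id)
  if (nrow(r) == 0) {
    abort(
      sprintf("No %s relations to average an intercept over.", method_id),
      class = "o2deficit_domain_error"
    )
  }
  mean(r$intercept)
}

#' Fit all demand relations for a cohort
#'
#' For every subject, exercise frequency and requested method, applies
#' that method's rules and fits the relation, returning one row per fit
#' in the `relations.csv` dialect. The common intercepts needed by M2
#' (mean of M1 intercepts) and M5 (mean of M0 intercepts) are computed
#' per frequency from the cohort itself. Subject/method combinations that
#' cannot be fitted (missing protocol, too few points) are skipped with a
#' single warning listing the reasons.
#'
#' @param measurements Cohort measurement table.
#' @param methods Methods to fit, default all nine.
#' @param config A [fit_config()].
#' @return A tibble with columns `method_id`, `subject_id`, `frequency`,
#'   `intercept`, `slope`, `n_points`.
#' @export
fit_demand_relations <- function(measurements, methods = method_ids(),
                                 config = fit_config()) {
  m <- validate_measurements(measurements)
  stopifnot(all(methods %in% method_ids()))
  ex <- filter(m, !.data$protocol %in% c("rest", "loadless"))
  combos <- distinct(ex, .data$subject_id, .data$frequency)
  if (nrow(combos) == 0) {
    abort("No exercise measurements to fit.", class = "o2deficit_domain_error")
  }

  skipped <- character(0)
  fit_one <- function(sid, f, method, common_intercept = NULL) {
    rows <- filter(
      m,
      .data$subject_id == sid,
      .data$protocol == "rest" | .data$frequency == f
    )
    tryCatch(
      relation_row(fit_method_relation(rows, method, config, common_intercept)),
      error = function(e) {
        skipped <<- c(skipped, paste0(sid, "/", f, " Hz/", method, ": ",
          conditionMessage(e)))
        NULL
      }
    )
  }

  fit_layer <- function(method, intercepts = NULL) {
    purrr::pmap(combos, function(subject_id, frequency) {
      ci <- if (!is.null(intercepts)) {
        intercepts$common_intercept[intercepts$frequency == frequency][1]
      }
      fit_one(subject_id, frequency, method, ci)
    }) %>%
      purrr::compact() %>%
      bind_rows()
  }

  out <- list()
  # Free-fit layers first: M1/M0 intercept means feed M2/M5.
  base_needed <- union(
    intersect(methods, c("M0", "M1", "M3", "M4")),
    c(if ("M2" %in% methods) "M1", if ("M5" %in% methods) "M0")
  )
  base <- purrr::map(setNames(base_needed, base_needed), fit_layer)

  for (method in intersect(methods, c("M0", "M1", "M3", "M4"))) {
    out[[method]] <- base[[method]]
  }
  common_of <- function(tbl) {
    tbl %>%
      group_by(.data$frequency) %>%
      summarise(common_intercept = mean(.data$intercept), .groups = "drop")
  }
  if ("M2" %in% methods && nrow(base[["M1"]] %||% tibble()) > 0) {
    out[["M2"]] <- fit_layer("M2", common_of(base[["M1"]]))
  }
  if ("M5" %in% methods && nrow(base[["M0"]] %||% tibble()) > 0) {
    out[["M5"]] <- fit_layer("M5", common_of(base[["M0"]]))
  }
  for (method in intersect(methods, c("M6", "M7", "M8"))) {
    out[[method]] <- fit_layer(method)
  }

  if (length(skipped) > 0) {
    warn(paste0(
      "Skipped ", length(skipped), " fit(s):\n",
      paste("-", head(skipped, 10), collapse = "\n"),
      if (length(skipped) > 10) "\n- ..." else ""
    ))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    abort("No method could be fitted for any subject.",
      class = "o2deficit_insufficient_data"
    )
  }
  res %>%
    mutate(method_id = factor(.data$method_id, levels = method_ids())) %>%
    arrange(.data$frequency, .data$subject_id, .data$method_id) %>%
    mutate(method_id = as.character(.data$method_id))
}

#' Cohort-mean relations
#'
#' Averages per-subject intercepts and slopes into one `"cohort-mean"`
#' relation per (method, frequency) — the coefficients a summary table
#' reports.
#'
#' @param relations Output of [fit_demand_relations()].
#' @return A tibble in the same dialect with `subject_id = "cohort-mean"`
#'   and `n_points` = number of subjects averaged.
#' @export
cohort_mean_relations <- function(relations) {
  as_tibble(relations) %>%
    group_by(.data$method_id, .data$frequency) %>%
    summarise(
      subject_id = "cohort-mean",
      intercept = mean(.data$intercept),
      slope = mean(.data$slope),
      n_points = dplyr::n(),
      .groups = "drop"
    ) %>%
    select(all_of(c(
      "method_id", "subject_id", "frequency", "intercept", "slope", "n_points"
    )))
}
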