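#' Accumulated O2 deficit for relations crossed with exercise models
#'
#' For each relation row and each exercise model, the accumulated O2
#' demand is the test relation's demand at the model power times the time
#' to exhaustion, and the accumulated O2 uptake is the aerobic fraction
#' of the *reference* accumulated demand (`aerobic_fraction * demand_ref
#' * time`). Anchoring the uptake to the reference total — the same
#' power, time to exhaustion and accumulated uptake for every method —
#' is what makes a cross-method comparison coherent: methods differ only
#' through their demand relation. The deficit is demand minus uptake,
#' also reported per kg body mass.
#'
#' Two demand paths exist for the reference method itself: evaluating its
#' relation at the model power, or taking the model's reference demand
#' `demand_ref` directly. With an unrounded relation (the one that
#' generated the powers) the two coincide exactly; with rounded
#' coefficients they differ by the rounding. `reference_demand_source`
#' selects the path used for the reference method's own rows.
#'
#' @param relations A relations table (`method_id`, `intercept`, `slope`,
#'   optionally `subject_id`, `frequency`) or a single
#'   [demand_relation()].
#' @param models Exercise-model grid from [exercise_models()] or
#'   [reference_exercise_models()].
#' @param body_mass Body mass, kg: a scalar (used for every row — e.g.
#'   the cohort mean for cohort-mean relations), or a subject table with
#'   `subject_id` and `body_mass` for per-subject results.
#' @param reference_id Method id whose rows may use the model demand
#'   directly, default `"M0"`.
#' @param reference_demand_source `"model"` (default: reference rows use
#'   `demand_ref`) or `"relation"` (all rows evaluate their relation).
#' @param mode `"modelled_fraction"` (default) takes the accumulated
#'   uptake as `aerobic_fraction * demand_ref * time`;
#'   `"measured_uptake"` integrates a measured VO2 time series
#'   (trapezoidal rule) over (0, time to exhaustion).
#' @param uptake_series For `mode = "measured_uptake"`: a data frame with
#'   `time` (s) and `vo2` (mmol s^-1) covering each model's duration.
#' @return A tibble with one row per relation x model:
#'   `accumulated_demand`, `accumulated_uptake`, `deficit` (mmol),
#'   `deficit_per_kg` (mmol kg^-1) and a logical `negative_deficit`
#'   diagnostic flag (a warning, not an error: it marks a demand relation
#'   too low for the assumed uptake).
#' @examples
#' accumulated_o2_deficit(
#'   reference_method_coefficients(),
#'   reference_exercise_models(),
#'   body_mass = 80.15
#' )
#' @export
accumulated_o2_deficit <- function(relations, models, body_mass,
                                   reference_id = "M0",
                                   reference_demand_source = c("model", "relation"),
                                   mode = c("modelled_fraction", "measured_uptake"),
                                   uptake_series = NULL) {
  reference_demand_source <- match.arg(reference_demand_source)
  mode <- match.arg(mode)
  if (inherits(relations, "demand_relation")) {
    relations <- relation_row(relations)
  }
  rel <- as_tibble(relations)
  stopifnot(all(c("method_id", "intercept", "slope") %in% names(rel)))
  mdl <- as_tibble(models)
  stopifnot(all(c(
    "time_to_exhaustion", "aerobic_fraction", "demand_ref", "power"
  ) %in% names(mdl)))

  grid <- tidyr::crossing(
    rel %>% mutate(.rel = row_number()),
    mdl %>% mutate(.mdl = row_number())
  )

  demand_rate <- grid$intercept + grid$slope * grid$power / 1000
  use_model <- reference_demand_source == "model" &
    grid$method_id == reference_id
  demand_rate[use_model] <- grid$demand_ref[use_model]
  acc_demand <- demand_rate * grid$time_to_exhaustion

  if (mode == "modelled_fraction") {
    acc_uptake <- grid$aerobic_fraction * grid$demand_ref *
      grid$time_to_exhaustion
  } else {
    if (is.null(uptake_series)) {
      abort("`measured_uptake` mode needs an `uptake_series`.",
        class = "o2deficit_config_error"
      )
    }
    us <- arrange(as_tibble(uptake_series), .data$time)
    stopifnot(all(c("time", "vo2") %in% names(us)))
    if (min(us$time) > 0 || max(us$time) < max(grid$time_to_exhaustion)) {
      abort("`uptake_series` must cover (0, time_to_exhaustion).",
        class = "o2deficit_config_error"
      )
    }
    acc_uptake <- vapply(grid$time_to_exhaustion, function(tte) {
      keep <- us$time < tte
      tt <- c(us$time[keep], tte)
      vv <- c(us$vo2[keep], stats::approx(us$time, us$vo2, xout = tte)$y)
      pracma::trapz(tt, vv)
    }, numeric(1))
  }

  deficit <- acc_demand - acc_uptake
  if (any(deficit < 0)) {
    warn(sprintf(
      "%d result(s) have a negative deficit (demand relation below the assumed uptake).",
      sum(deficit < 0)
    ))
  }

  if (is.data.frame(body_mass)) {
    stopifnot(
      all(c("subject_id", "body_mass") %in% names(body_mass)),
      "subject_id" %in% names(grid)
    )
    mass <- left_join(
      grid["subject_id"], as_tibble(body_mass)[c("subject_id", "body_mass")],
      by = "subject_id"
    )$body_mass
  } else {
    stopifnot(is.numeric(body_mass), length(body_mass) == 1, body_mass > 0)
    mass <- body_mass
  }

  grid %>%
    mutate(
      accumulated_demand = acc_demand,
      accumulated_uptake = acc_uptake,
      deficit = deficit,
      deficit_per_kg = deficit / mass,
      negative_deficit = deficit < 0
    ) %>%
    select(-all_of(c(".rel", ".mdl")))
}

#' Method-by-model AOD summary table
#'
#' Crosses a relations table with an exercise-model grid and pivots the
#' per-kg deficits into one row per method with one column per model
#' (named by time to exhaustion and intensity) — the shape in which AOD
#' method comparisons are usually reported.
#'
#' @inheritParams accumulated_o2_deficit
#' @return A tibble of class `aod_table`: `method_id`, `intercept`,
#'   `slope`, then one `deficit_per_kg` column per exercise model.
#' @examples
#' aod_table(
#'   reference_method_coefficients(),
#'   reference_exercise_models(),
#'   body_mass = 80.15
#' )
#' @export
aod_table <- function(relations, models, body_mass, reference_id = "M0",
                      reference_demand_source = c("model", "relation")) {
  long <- accumulated_o2_deficit(
    relations, models, body_mass,
    reference_id = reference_id,
    reference_demand_source = match.arg(reference_demand_source)
  )
  out <- long %>%
    mutate(
      model = sprintf(
        "aod_%gs_%g", .data$time_to_exhaustion,
        round(100 * .data$intensity_fraction)
      ),
      model = factor(.data$model, levels = unique(.data$model))
    ) %>%
    select(all_of(c("method_id", "intercept", "slope", "model", "deficit_per_kg"))) %>%
    tidyr::pivot_wider(
      names_from = "model", values_from = "deficit_per_kg"
    ) %>%
    mutate(method_id = factor(.data$method_id, levels = method_ids())) %>%
    arrange(.data$method_id) %>%
    mutate(method_id = as.character(.data$method_id))
  class(out) <- c("aod_table", class(out))
  out
}

#' One-sample paired t-test statistic
#'
#' Matched-pair comparison of a set of per-subject differences against
#' zero: t = mean(d) / (sd(d) / sqrt(n)) with n - 1 degrees of freedom,
#' two-sided p. A zero-variance sample is degenerate: `t` and `p` come
#' back `NA` with a `o2deficit_degenerate_sample` warning.
#'
#' @param differences Numeric vector of paired differences (one per
#'   subject).
#' @return A one-row tibble: `n`, `mean`, `sd`, `t`, `df`, `p`.
#' @export
paired_t <- function(differences) {
  d <- differences[!is.na(differences)]
  if (length(d) < 2) {
    abort("Need at least 2 paired differences.",
      class = "o2deficit_domain_error"
    )
  }
  s <- sd(d)
  if (s == 0) {
    warn("Zero variance among differences; t is undefined.",
      class = "o2deficit_degenerate_sample"
    )
    return(tibble(
      n = length(d), mean = mean(d), sd = 0,
      t = NA_real_, df = length(d) - 1, p = NA_real_
    ))
  }
  t_stat <- mean(d) / (s / sqrt(length(d)))
  tibble(
    n = length(d),
    mean = mean(d),
    sd = s,
    t = t_stat,
    df = length(d) - 1,
    p = 2 * pt(-abs(t_stat), df = length(d) - 1)
  )
}

#' Compare test methods against the reference, per exercise model
#'
#' Computes, per (method, exercise model), the per-subject residuals
#' (test AOD minus reference AOD per kg), their mean bias, the
#' between-subject SD of the residuals, and a one-sample paired t-test
#' of the residuals against zero. With fewer than 2 complete pairs the
#' SD is reported missing; zero-variance residual sets (e.g. a method
#' compared to itself) give `t = NA` and are flagged in `note`.
#'
#' @param aod_results Per-subject long results from
#'   [accumulated_o2_deficit()] (must carry `subject_id`).
#' @param reference_id Reference method id, default `"M0"`.
#' @param adjust `"none"` or `"bonferroni"` across the method contrasts
#'   within each exercise model.
#' @return A tibble of class `aod_comparison`: `method_id`, model
#'   columns, `n`, `bias`, `sd`, `t`, `df`, `p` (and `p_adj` when
#'   adjusted), plus the per-subject `residuals` as a list-column.
#' @export
compare_methods <- function(aod_results, reference_id = "M0",
                            adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  res <- as_tibble(aod_results)
  stopifnot(all(c(
    "subject_id", "method_id", "time_to_exhaustion", "intensity_fraction",
    "deficit_per_kg"
  ) %in% names(res)))
  if (!any(res$method_id == reference_id)) {
    abort(sprintf("No rows for the reference method %s.", reference_id),
      class = "o2deficit_config_error"
    )
  }

  ref <- res %>%
    filter(.data$method_id == reference_id) %>%
    select(all_of(c(
      "subject_id", "time_to_exhaustion", "intensity_fraction", "deficit_per_kg"
    ))) %>%
    rename(ref_deficit_per_kg = "deficit_per_kg")

  paired <- res %>%
    left_join(ref, by = c("subject_id", "time_to_exhaustion", "intensity_fraction")) %>%
    filter(!is.na(.data$ref_deficit_per_kg)) %>%
    mutate(residual = .data$deficit_per_kg - .data$ref_deficit_per_kg)

  out <- paired %>%
    group_by(.data$method_id, .data$time_to_exhaustion, .data$intensity_fraction) %>%
    summarise(residuals = list(.data$residual), .groups = "drop") %>%
    mutate(stats = purrr::map(.data$residuals, function(r) {
      r <- r[!is.na(r)]
      n <- length(r)
      if (n < 2) {
        return(tibble(
          n = n, bias = if (n > 0) mean(r) else NA_real_, sd = NA_real_,
          t = NA_real_, df = NA_real_, p = NA_real_, note = "fewer than 2 pairs"
        ))
      }
      if (sd(r) == 0) {
        return(tibble(
          n = n, bias = mean(r), sd = 0,
          t = NA_real_, df = n - 1, p = NA_real_, note = "zero variance"
        ))
      }
      tt <- paired_t(r)
      tibble(
        n = tt$n, bias = tt$mean, sd = tt$sd, t = tt$t, df = tt$df, p = tt$p,
        note = NA_character_
      )
    })) %>%
    tidyr::unnest("stats")

  if (adjust == "bonferroni") {
    n_contrasts <- dplyr::n_distinct(
      out$method_id[out$method_id != reference_id]
    )
    out <- out %>%
      mutate(p_adj = pmin(1, .data$p * n_contrasts))
  }
  out <- out %>%
    mutate(method_id = factor(.data$method_id, levels = method_ids())) %>%
    arrange(.data$method_id, desc(.data$time_to_exhaustion)) %>%
    mutate(method_id = as.character(.data$method_id))
  class(out) <- c("aod_comparison", class(out))
  out
}

#' Pooled slow-component drift
#'
#' Combines subgroup mean VO2 increases (e.g. below- and at-or-above the
#' lactate threshold) into the overall mean increase by an n-weighted
#' mean.
#'
#' @param data Data frame with columns `mean_increase` (mmol s^-1) and
#'   `n` (subgroup sizes), or two numeric vectors via `mean_increase`
#'   and `n`.
#' @param mean_increase,n Alternative vector interface.
#' @return Pooled mean increase, mmol s^-1.
#' @examples
#' pooled_drift(tibble::tibble(mean_increase = c(0.026, 0.113), n = c(126, 33)))
#' @export
pooled_drift <- function(data = NULL, mean_increase = NULL, n = NULL) {
  if (!is.null(data)) {
    d <- as_tibble(data)
    stopifnot(all(c("mean_increase", "n") %in% names(d)))
    mean_increase <- d$mean_increase
    n <- d$n
  }
  if (is.null(mean_increase) || length(mean_increase) == 0) {
    abort("No subgroups to pool.", class = "o2deficit_domain_error")
  }
  stopifnot(length(mean_increase) == length(n), all(n > 0))
  weighted.mean(mean_increase, w = n)
}
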