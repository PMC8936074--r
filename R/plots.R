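#' Plot demand relations over their measurement points
#'
#' Draws the fitted power-demand lines of a relations table, optionally
#' over the steady-state measurement points, faceted by subject.
#'
#' @param relations Relations table from [fit_demand_relations()].
#' @param measurements Optional measurement table; its 8-10-min bout
#'   points are drawn under the lines.
#' @param power_range Power range (W) over which to draw the lines.
#' @return A ggplot object.
#' @export
plot_relations <- function(relations, measurements = NULL,
                           power_range = c(0, 800)) {
  rel <- as_tibble(relations)
  lines <- rel %>%
    tidyr::crossing(power = seq(power_range[1], power_range[2], length.out = 2)) %>%
    mutate(vo2 = .data$intercept + .data$slope * .data$power / 1000)
  p <- ggplot2::ggplot(lines, ggplot2::aes(
    x = .data$power, y = .data$vo2, colour = .data$method_id
  )) +
    ggplot2::geom_line()
  if (!is.null(measurements)) {
    pts <- as_tibble(measurements) %>%
      filter(
        .data$protocol == "bout10",
        window_phase(.data$window_start, .data$window_end) == "steady"
      )
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$power, y = .data$vo2),
      inherit.aes = FALSE, alpha = 0.5
    )
  }
  if ("subject_id" %in% names(rel) && dplyr::n_distinct(rel$subject_id) > 1) {
    p <- p + ggplot2::facet_wrap(~subject_id)
  }
  p + ggplot2::labs(
    x = "Power (W)", y = expression(O[2] ~ "demand (mmol" ~ s^-1 * ")"),
    colour = "Method"
  )
}

#' @export
autoplot.demand_relation <- function(object, power_range = c(0, 800), ...) {
  plot_relations(relation_row(object), power_range = power_range)
}

#' Residual plot of test methods against the reference
#'
#' The classic AOD method-comparison display: per-subject residuals
#' (test minus reference deficit per kg) against the reference value,
#' one panel per test method, one shape per exercise model.
#'
#' @param object An `aod_comparison` from [compare_methods()], or the
#'   long per-subject results from [accumulated_o2_deficit()] via
#'   `plot_residuals()`.
#' @param aod_results Long per-subject AOD results carrying
#'   `subject_id`, `method_id`, model columns and `deficit_per_kg`.
#' @param reference_id Reference method id.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_residuals <- function(aod_results, reference_id = "M0") {
  res <- as_tibble(aod_results)
  ref <- res %>%
    filter(.data$method_id == reference_id) %>%
    select(all_of(c(
      "subject_id", "time_to_exhaustion", "intensity_fraction", "deficit_per_kg"
    ))) %>%
    rename(reference = "deficit_per_kg")
  res %>%
    filter(.data$method_id != reference_id) %>%
    left_join(ref, by = c(
      "subject_id", "time_to_exhaustion", "intensity_fraction"
    )) %>%
    mutate(
      residual = .data$deficit_per_kg - .data$reference,
      model = sprintf(
        "%g s, %g%%", .data$time_to_exhaustion,
        100 * .data$intensity_fraction
      )
    ) %>%
    ggplot2::ggplot(ggplot2::aes(
      x = .data$reference, y = .data$residual, shape = .data$model
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method_id) +
    ggplot2::labs(
      x = expression("Reference AOD (mmol" ~ kg^-1 * ")"),
      y = expression("Residual, test - reference (mmol" ~ kg^-1 * ")"),
      shape = "Exercise model"
    )
}

#' @rdname plot_residuals
#' @export
autoplot.aod_comparison <- function(object, ...) {
  comp <- as_tibble(object) %>%
    mutate(model = sprintf(
      "%g s, %g%%", .data$time_to_exhaustion, 100 * .data$intensity_fraction
    ))
  ggplot2::ggplot(comp, ggplot2::aes(
    x = .data$model, y = .data$bias, ymin = .data$bias - .data$sd,
    ymax = .data$bias + .data$sd
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~method_id) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(
      x = "Exercise model",
      y = expression("Bias vs reference " %+-% " between-subject SD (mmol" ~ kg^-1 * ")")
    )
}

#' VO2 against pedaling frequency with its polynomial fit
#'
#' @param object A `frequency_polyfit` from [fit_frequency_polynomial()].
#' @param data The points the fit was computed from (`frequency`, `vo2`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_polyfit <- function(object, data = NULL, ...) {
  curve <- tibble(
    frequency = seq(object$domain[1], object$domain[2], length.out = 100)
  )
  curve$vo2 <- predict(object, curve)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$frequency, y = .data$vo2)) +
    ggplot2::geom_line()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = as_tibble(data))
  }
  p + ggplot2::labs(
    x = "Pedaling frequency (Hz)",
    y = expression(O[2] ~ "uptake (mmol" ~ s^-1 * ")")
  )
}
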