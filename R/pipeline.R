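#' Pipeline run configuration
#'
#' Bundles everything a batch run needs: the generator config, the fit
#' config, the exercise-model source and the output directory. Can be
#' read from a YAML file whose top-level keys are `seed`, `out_dir`,
#' `exercise_model_source` (`"reference"` uses the canonical printed
#' grid via [reference_exercise_models()]; `"refit"` recomputes demands
#' and powers from the fitted reference relation), `body_mass` (optional
#' fixed cohort mean mass, kg), `generator` and `fit` (keyword lists
#' passed to [generator_config()] / [fit_config()]).
#'
#' @param seed Integer seed recorded in every output header.
#' @param out_dir Output directory.
#' @param generator A [generator_config()].
#' @param fit A [fit_config()].
#' @param exercise_model_source `"reference"` or `"refit"`.
#' @param body_mass Optional fixed cohort mean body mass (kg); by
#'   default the simulated/loaded subject table's mean is used.
#' @param methods Methods to fit.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = ".",
                       generator = generator_config(seed = seed),
                       fit = fit_config(),
                       exercise_model_source = c("refit", "reference"),
                       body_mass = NULL,
                       methods = method_ids()) {
  structure(
    list(
      seed = as.integer(seed),
      out_dir = out_dir,
      generator = generator,
      fit = fit,
      exercise_model_source = match.arg(exercise_model_source),
      body_mass = body_mass,
      methods = methods
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "o2deficit_io_error")
  }
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  gen_args <- y$generator %||% list()
  if (is.null(gen_args$seed)) gen_args$seed <- seed
  run_config(
    seed = seed,
    out_dir = y$out_dir %||% ".",
    generator = do.call(generator_config, gen_args),
    fit = do.call(fit_config, y$fit %||% list()),
    exercise_model_source = y$exercise_model_source %||% "refit",
    body_mass = y$body_mass,
    methods = y$methods %||% method_ids()
  )
}

# Header comment stamped on every output file: version, config hash, seed.
output_header <- function(config) {
  paste0(
    "# o2deficit ", as.character(utils::packageVersion("o2deficit")),
    " | config ", substr(rlang::hash(config[setdiff(names(config), "out_dir")]), 1, 12),
    " | seed ", config$seed
  )
}

write_csv_with_header <- function(tbl, path, config) {
  writeLines(output_header(config), path)
  readr::write_csv(tbl, path, na = "", append = TRUE, col_names = TRUE,
    progress = FALSE)
  invisible(path)
}

#' Run the simulate / fit / AOD pipeline stages
#'
#' Thin batch runners over the package functions, writing the documented
#' CSV dialects with a header comment carrying the package version,
#' config hash and seed (so identical configs give bit-identical files).
#'
#' * `run_simulate()` writes `measurements.csv`, `subjects.csv` and
#'   `truths.json`.
#' * `run_fit()` reads measurements, fits the requested methods and
#'   writes `relations.csv` (per-subject rows plus cohort-mean rows).
#' * `run_aod()` reads `relations.csv` and `subjects.csv`, computes the
#'   AOD grid and the method comparison and writes `aod_results.csv`,
#'   `comparison.csv` and `residuals.csv` (long format for plotting).
#'
#' @param config A [run_config()].
#' @return A named character vector of the files written, invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    abort(paste0("Cannot create output dir: ", config$out_dir),
      class = "o2deficit_io_error"
    )
  }
  cohort <- simulate_cohort(config$generator)
  paths <- c(
    measurements = file.path(config$out_dir, "measurements.csv"),
    subjects = file.path(config$out_dir, "subjects.csv"),
    truths = file.path(config$out_dir, "truths.json")
  )
  write_csv_with_header(cohort$measurements, paths[["measurements"]], config)
  write_csv_with_header(cohort$subjects, paths[["subjects"]], config)
  write_truths_json(cohort$truths, paths[["truths"]])
  message(sprintf(
    "simulate: %d subjects, %d measurement rows -> %s",
    nrow(cohort$subjects), nrow(cohort$measurements), config$out_dir
  ))
  invisible(paths)
}

#' @rdname run_simulate
#' @param measurements_path Path to a measurements CSV; defaults to the
#'   one `run_simulate()` wrote under `config$out_dir`.
#' @export
run_fit <- function(config = run_config(),
                    measurements_path = file.path(config$out_dir, "measurements.csv")) {
  stopifnot(inherits(config, "run_config"))
  m <- read_measurements(measurements_path)
  relations <- fit_demand_relations(m, methods = config$methods, config = config$fit)
  out <- bind_rows(relations, cohort_mean_relations(relations))
  path <- file.path(config$out_dir, "relations.csv")
  write_csv_with_header(out, path, config)
  message(sprintf("fit: %d relation rows -> %s", nrow(out), path))
  invisible(c(relations = path))
}

#' @rdname run_simulate
#' @param relations_path,subjects_path Paths to the inputs of the AOD
#'   stage; default to the files the earlier stages wrote.
#' @export
run_aod <- function(config = run_config(),
                    relations_path = file.path(config$out_dir, "relations.csv"),
                    subjects_path = file.path(config$out_dir, "subjects.csv")) {
  stopifnot(inherits(config, "run_config"))
  relations <- readr::read_csv(relations_path, comment = "#",
    show_col_types = FALSE, progress = FALSE)
  subjects <- read_subjects(subjects_path)
  if (!any(relations$method_id == "M0")) {
    abort("relations.csv has no reference (M0) rows.",
      class = "o2deficit_config_error"
    )
  }

  per_subject <- filter(relations, .data$subject_id != "cohort-mean")
  cohort_mean <- filter(relations, .data$subject_id == "cohort-mean")
  vo2max_mean <- cohort_mean_vo2max(subjects)
  mass_mean <- config$body_mass %||% cohort_mean_mass(subjects)

  results <- purrr::map(unique(per_subject$frequency), function(f) {
    ref_row <- filter(cohort_mean, .data$method_id == "M0", .data$frequency == f)
    models <- if (config$exercise_model_source == "reference") {
      reference_exercise_models()
    } else {
      exercise_models(vo2max_mean, relation_from_row(ref_row))
    }
    rel_f <- filter(per_subject, .data$frequency == f)
    long <- accumulated_o2_deficit(
      rel_f, models,
      body_mass = subjects,
      reference_demand_source = "relation"
    )
    mean_tbl <- aod_table(
      filter(cohort_mean, .data$frequency == f), models,
      body_mass = mass_mean,
      reference_demand_source = "relation"
    )
    list(long = long, table = mean_tbl, models = models)
  })
  names(results) <- as.character(unique(per_subject$frequency))

  aod_results <- bind_rows(
    purrr::imap(results, ~ mutate(.x$table, frequency = as.numeric(.y)))
  )
  residuals_long <- bind_rows(
    purrr::imap(results, function(r, f) {
      comp_input <- r$long
      ref <- comp_input %>%
        filter(.data$method_id == "M0") %>%
        select(all_of(c(
          "subject_id", "time_to_exhaustion", "intensity_fraction",
          "deficit_per_kg"
        ))) %>%
        rename(ref = "deficit_per_kg")
      comp_input %>%
        left_join(ref, by = c(
          "subject_id", "time_to_exhaustion", "intensity_fraction"
        )) %>%
        mutate(residual = .data$deficit_per_kg - .data$ref,
          frequency = as.numeric(f)) %>%
        select(all_of(c(
          "frequency", "subject_id", "method_id", "time_to_exhaustion",
          "intensity_fraction", "deficit_per_kg", "residual"
        )))
    })
  )
  comparison <- bind_rows(
    purrr::imap(results, ~ mutate(
      compare_methods(.x$long),
      frequency = as.numeric(.y)
    ))
  ) %>%
    select(-all_of("residuals"))

  paths <- c(
    aod_results = file.path(config$out_dir, "aod_results.csv"),
    comparison = file.path(config$out_dir, "comparison.csv"),
    residuals = file.path(config$out_dir, "residuals.csv")
  )
  write_csv_with_header(aod_results, paths[["aod_results"]], config)
  write_csv_with_header(comparison, paths[["comparison"]], config)
  write_csv_with_header(residuals_long, paths[["residuals"]], config)
  message(sprintf(
    "aod: %d table rows, %d comparison rows -> %s",
    nrow(aod_results), nrow(comparison), config$out_dir
  ))
  invisible(paths)
}
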