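#' Measurement and subject tables
#'
#' The package works on two plain tables. The *measurement* table has one
#' row per VO2 observation:
#'
#' * `subject_id` (character) — opaque subject label;
#' * `protocol` (character) — one of [measurement_protocols()]:
#'   `"bout10"` (10-min constant-power bout), `"bout4_rest"` (4-min rested
#'   bout), `"step4"` (4-min stepwise incremental protocol), `"loadless"`
#'   (pedaling at zero braking force), `"rest"` (seated rest);
#' * `frequency` (Hz) — pedaling rate; 0 for `rest`;
#' * `power` (W) — mechanical power; 0 for `loadless`/`rest`;
#' * `window_start`, `window_end` (s) — measurement window within the bout;
#' * `vo2` (mmol s^-1) — steady oxygen uptake over the window;
#' * `hr` (beats min^-1, optional), `lactate` (mmol L^-1, optional).
#'
#' The *subject* table has one row per subject: `subject_id`, `sex`
#' (`"F"`/`"M"`), `body_mass` (kg), `vo2max` (mmol s^-1).
#'
#' @name measurement-tables
NULL

measurement_cols <- c(
  "subject_id", "protocol", "frequency", "power",
  "window_start", "window_end", "vo2", "hr", "lactate"
)

#' @return `measurement_protocols()` returns the recognised protocol labels.
#' @rdname measurement-tables
#' @export
measurement_protocols <- function() {
  c("bout10", "bout4_rest", "step4", "loadless", "rest")
}

#' Validate a measurement table
#'
#' Checks column presence and the per-row physical invariants: `vo2 >= 0`,
#' `power >= 0`, `window_end > window_start >= 0`, `frequency` in (0, 3] Hz
#' (0 allowed for the `rest` protocol), and a recognised `protocol`. Any
#' violation aborts with a diagnostic naming the offending rows and fields.
#'
#' @param measurements A data frame in the measurement dialect.
#' @return The validated measurements as a tibble, invisibly usable in a
#'   pipe.
#' @export
validate_measurements <- function(measurements) {
  m <- as_tibble(measurements)
  required <- setdiff(measurement_cols, c("hr", "lactate"))
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(
      paste0("Missing measurement columns: ", paste(missing, collapse = ", ")),
      class = "o2deficit_format_error"
    )
  }
  if (anyDuplicated(names(m)) > 0) {
    abort("Duplicate column names in measurement table.",
      class = "o2deficit_format_error"
    )
  }
  if (!("hr" %in% names(m))) m$hr <- NA_real_
  if (!("lactate" %in% names(m))) m$lactate <- NA_real_
  m <- m[measurement_cols]
  for (col in c("frequency", "power", "window_start", "window_end", "vo2")) {
    if (!is.numeric(m[[col]])) {
      abort(paste0("Column `", col, "` must be numeric."),
        class = "o2deficit_parse_error"
      )
    }
  }
  if (nrow(m) == 0) {
    warn("Measurement table is empty.")
    return(m)
  }

  problems <- character(0)
  flag <- function(bad, field, why) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, paste0(
        "rows ", paste(head(rows, 5), collapse = ", "),
        if (length(rows) > 5) ", ..." else "",
        ": `", field, "` ", why
      ))
    }
  }
  flag(!(m$protocol %in% measurement_protocols()), "protocol",
    paste0("not one of ", paste(measurement_protocols(), collapse = "/")))
  flag(is.na(m$vo2) | m$vo2 < 0, "vo2", "must be >= 0")
  flag(is.na(m$power) | m$power < 0, "power", "must be >= 0")
  flag(is.na(m$window_start) | m$window_start < 0, "window_start", "must be >= 0")
  flag(is.na(m$window_end) | m$window_end <= m$window_start, "window_end",
    "must exceed window_start")
  non_rest <- m$protocol != "rest"
  # rest rows may carry 0 or NA frequency; every other protocol needs (0, 3]
  flag(non_rest & (is.na(m$frequency) | m$frequency <= 0 | m$frequency > 3),
    "frequency", "must lie in (0, 3] Hz for exercise protocols")
  if (length(problems) > 0) {
    abort(
      paste0("Invalid measurements:\n", paste("-", problems, collapse = "\n")),
      class = "o2deficit_invariant_error"
    )
  }
  m
}

#' Validate a subject table
#'
#' @param subjects A data frame with `subject_id`, `body_mass`, `vo2max`
#'   (and optionally `sex`).
#' @param measurements Optional measurement table; when given, each
#'   subject's measured `vo2` is checked against `vo2max_bound * vo2max`.
#' @param vo2max_bound Sanity multiplier on `vo2max` (default 1.15).
#' @return The validated subjects tibble.
#' @export
validate_subjects <- function(subjects, measurements = NULL, vo2max_bound = 1.15) {
  s <- as_tibble(subjects)
  missing <- setdiff(c("subject_id", "body_mass", "vo2max"), names(s))
  if (length(missing) > 0) {
    abort(
      paste0("Missing subject columns: ", paste(missing, collapse = ", ")),
      class = "o2deficit_format_error"
    )
  }
  if (any(is.na(s$body_mass) | s$body_mass <= 0)) {
    abort("`body_mass` must be positive for every subject.",
      class = "o2deficit_invariant_error"
    )
  }
  if (any(is.na(s$vo2max) | s$vo2max <= 0)) {
    abort("`vo2max` must be positive for every subject.",
      class = "o2deficit_invariant_error"
    )
  }
  if (anyDuplicated(s$subject_id) > 0) {
    abort("Duplicate `subject_id` in subject table.",
      class = "o2deficit_invariant_error"
    )
  }
  if (!is.null(measurements)) {
    joined <- left_join(
      as_tibble(measurements)[c("subject_id", "vo2")],
      s[c("subject_id", "vo2max")],
      by = "subject_id"
    )
    bad <- !is.na(joined$vo2max) & joined$vo2 > vo2max_bound * joined$vo2max
    if (any(bad)) {
      abort(
        paste0(
          "Measured vo2 exceeds ", vo2max_bound, " x vo2max for subject(s): ",
          paste(unique(joined$subject_id[bad]), collapse = ", ")
        ),
        class = "o2deficit_invariant_error"
      )
    }
  }
  s
}

#' Read and write measurement / subject CSV files
#'
#' The CSV dialect is UTF-8, comma-separated, one measurement per row with
#' columns exactly as documented in [measurement-tables]; missing optional
#' values are empty strings. Lines starting with `#` are header comments
#' (written by the pipeline runners) and are skipped on read. Reading
#' validates every row; a file that fails validation is rejected with
#' row-addressed diagnostics.
#'
#' @param path File path.
#' @param measurements,subjects Tables to write.
#' @return `read_measurements()` / `read_subjects()` return validated
#'   tibbles; the writers return `path` invisibly.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "o2deficit_io_error")
  }
  m <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      protocol = readr::col_character(),
      .default = readr::col_double()
    )
  )
  prob <- readr::problems(m)
  if (nrow(prob) > 0) {
    abort(
      paste0(
        "Parse errors in ", path, " at row(s) ",
        paste(head(unique(prob$row), 5), collapse = ", ")
      ),
      class = "o2deficit_parse_error"
    )
  }
  validate_measurements(m)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  m <- validate_measurements(measurements)
  readr::write_csv(m, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "o2deficit_io_error")
  }
  s <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    )
  )
  validate_subjects(s)
}

#' @rdname read_measurements
#' @export
write_subjects <- function(subjects, path) {
  s <- validate_subjects(subjects)
  readr::write_csv(s, path, na = "", progress = FALSE)
  invisible(path)
}

#' Cohort summaries
#'
#' A cohort is a subject table plus its measurement table. The derived
#' summaries are plain arithmetic means over subjects; subjects missing a
#' required field for a given analysis are excluded subject-wise from that
#' analysis (never measurement-wise).
#'
#' @param subjects Subject table.
#' @return A scalar mean in the field's unit (kg, mmol s^-1).
#' @examples
#' s <- tibble::tibble(
#'   subject_id = as.character(1:13),
#'   body_mass = c(rep(74, 3), rep(82, 10)),
#'   vo2max = rep(2.9, 13)
#' )
#' cohort_mean_mass(s) # 80.15 kg
#' @export
cohort_mean_mass <- function(subjects) {
  s <- as_tibble(subjects)
  if (nrow(s) == 0) {
    abort("Cannot take the mean body mass of an empty cohort.",
      class = "o2deficit_domain_error"
    )
  }
  if (any(is.na(s$body_mass))) {
    abort("All subjects need `body_mass`.", class = "o2deficit_domain_error")
  }
  mean(s$body_mass)
}

#' @rdname cohort_mean_mass
#' @export
cohort_mean_vo2max <- function(subjects) {
  s <- as_tibble(subjects)
  if (nrow(s) == 0 || any(is.na(s$vo2max))) {
    abort("All subjects need `vo2max` and the cohort must be non-empty.",
      class = "o2deficit_domain_error"
    )
  }
  mean(s$vo2max)
}

#' Write a cohort summary as JSON
#'
#' Serialises the subject table together with the derived cohort means
#' (`mean_body_mass`, `mean_vo2max`) to a JSON file.
#'
#' @param subjects Subject table.
#' @param path Output path.
#' @export
write_cohort_json <- function(subjects, path) {
  s <- validate_subjects(subjects)
  jsonlite::write_json(
    list(
      subjects = s,
      mean_body_mass = cohort_mean_mass(s),
      mean_vo2max = cohort_mean_vo2max(s)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
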