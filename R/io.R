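#' Read tidy germination time courses from CSV
#'
#' The canonical on-disk form is long/tidy: one row per observation time of
#' one replicate under one condition, with cumulative germinated counts
#' (cumulative dynamics are what the models fit). Required columns:
#' `species_id`, `replicate_id`, `temperature_C`, `time_h`,
#' `cum_germinated`; optional columns `family` (defaults to `NA`),
#' `water_potential_MPa` (defaults to 0 MPa, pure water) and `n_seeds`
#' (defaults to 25 sown seeds). An optional `experiment` column labelling
#' distinct assay series (e.g. a temperature series and a water-potential
#' series with its own pure-water control) is preserved and treated as part
#' of the condition key downstream. Lines starting with `#` are treated as
#' header comments.
#'
#' Validation: within each (species, replicate, condition) series, times must
#' be unique and counts non-decreasing with `0 <= count <= n_seeds`; a
#' violation raises an error naming the series and time.
#'
#' @param path Path to a CSV file (UTF-8, decimal point).
#' @param allow_fractional Allow non-integer cumulative counts (used by
#'   noise-free simulated datasets where counts are expected values).
#'   Default `FALSE`.
#' @return A tibble with the canonical columns, grouped rows ordered by
#'   species, replicate, condition and time.
#' @export
read_time_courses <- function(path, allow_fractional = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "germresp_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("species_id", "replicate_id", "temperature_C", "time_h",
                "cum_germinated")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "germresp_schema_error")
  }
  if (!"water_potential_MPa" %in% names(raw)) raw$water_potential_MPa <- 0
  if (!"n_seeds" %in% names(raw)) raw$n_seeds <- 25L
  if (!"family" %in% names(raw)) raw$family <- NA_character_
  out <- dplyr::arrange(
    dplyr::select(raw, "species_id", "family", "replicate_id",
                  "temperature_C", "water_potential_MPa", "time_h",
                  "cum_germinated", "n_seeds", dplyr::any_of("experiment")),
    .data$species_id, .data$replicate_id, .data$temperature_C,
    .data$water_potential_MPa, .data$time_h
  )
  validate_time_courses(out, allow_fractional = allow_fractional)
  out
}

validate_time_courses <- function(data, allow_fractional = FALSE) {
  if (any(data$water_potential_MPa > 0)) {
    abort("water_potential_MPa must be <= 0 (0 = pure water).",
          class = "germresp_validation_error")
  }
  if (any(!is.finite(data$time_h)) || any(data$time_h < 0)) {
    abort("time_h must be finite and >= 0.", class = "germresp_validation_error")
  }
  if (!allow_fractional && any(data$cum_germinated != round(data$cum_germinated))) {
    abort("cum_germinated must be integer counts.",
          class = "germresp_validation_error")
  }
  key <- paste(data$species_id, data$replicate_id, data$temperature_C,
               data$water_potential_MPa)
  for (grp in split(data, key)) {
    grp <- grp[order(grp$time_h), ]
    if (anyDuplicated(grp$time_h)) {
      abort(sprintf("Duplicated observation times for %s / %s at %g degC, %g MPa.",
                    grp$species_id[1], grp$replicate_id[1],
                    grp$temperature_C[1], grp$water_potential_MPa[1]),
            class = "germresp_validation_error")
    }
    bad <- which(diff(grp$cum_germinated) < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "Cumulative counts decrease for %s / %s at %g degC, %g MPa (time %g h).",
        grp$species_id[1], grp$replicate_id[1], grp$temperature_C[1],
        grp$water_potential_MPa[1], grp$time_h[bad[1] + 1]),
        class = "germresp_validation_error")
    }
    if (any(grp$cum_germinated < 0) || any(grp$cum_germinated > grp$n_seeds)) {
      abort(sprintf("Counts outside [0, n_seeds] for %s / %s.",
                    grp$species_id[1], grp$replicate_id[1]),
            class = "germresp_validation_error")
    }
  }
  invisible(data)
}

#' Packaged cardinal-temperature table for 36 cover crop taxa
#'
#' Seed mass, cardinal temperatures (minimum `t0`, optimum `topt`, maximum
#' `tmax`), and base temperature `tb` for 36 cover crop taxa from six
#' botanical families, with the dispersion of each estimate across the four
#' germination percentiles (20th-50th) in the `*_sd` columns. The
#' `photosynthesis` column flags the two C4 Poaceae. Base water potential is
#' not part of this table.
#'
#' @return A tibble with 36 rows and columns `family`, `species`,
#'   `species_id`, `photosynthesis`, `seed_mass_mg`, `t0`, `t0_sd`, `tmax`,
#'   `tmax_sd`, `topt`, `topt_sd`, `tb`, `tb_sd`.
#' @examples
#' load_table1()
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_cardinal_temperatures.csv",
                      package = "germresp", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a result table to CSV or JSON
#'
#' CSV output carries a `# schema_version` header comment and, for every
#' numeric column, an additional `<name>_display` column rounded to one
#' decimal (the display convention of the field's tables) while the primary
#' columns keep full precision. JSON output wraps the records together with
#' a `schema_version` field. [read_results()] inverts either format
#' loss-free (display columns are dropped on read).
#'
#' @param data A data frame of results (one result type per file).
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(data, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  data <- tibble::as_tibble(data)
  data <- dplyr::select(data, -dplyr::where(is.list))
  if (format == "csv") {
    disp <- dplyr::mutate(data, dplyr::across(
      dplyr::where(is.numeric), ~ round(.x, 1),
      .names = "{.col}_display"))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("# schema_version: 1", con)
    utils::write.csv(disp, con, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(schema_version = 1L, data = data),
      path, dataframe = "rows", digits = NA, auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path File path (`.csv` or `.json`).
#' @return A tibble with the full-precision columns (display columns
#'   dropped).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(obj$data)
  } else {
    out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    out <- dplyr::select(out, -dplyr::ends_with("_display"))
  }
  out
}

#' Write a tidy time-course dataset to CSV
#'
#' Canonical long format consumed by [read_time_courses()], with a
#' `# schema_version` header comment.
#'
#' @param data Tidy time-course tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_time_courses <- function(data, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema_version: 1", con)
  utils::write.csv(tibble::as_tibble(data), con, row.names = FALSE)
  invisible(path)
}
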