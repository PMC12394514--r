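# Validated CSV readers/writers for the campaign's tabular formats. All files
# are UTF-8, comma-separated, dot-decimal; validation errors cite the file
# line (header = line 1).

measurement_cols <- c("colony_id", "species", "site", "condition",
                      "timepoint", "tank_temperature_c", "fvfm")

fail_lines <- function(bad_rows, path, msg) {
  abort(sprintf("%s: %s (line %s).", path, msg,
                paste(bad_rows + 1L, collapse = ", ")),
        class = "coralscreen_validation_error")
}

#' Read and validate a Fv/Fm measurement table
#'
#' Expects the standard measurement schema (`colony_id`, `species`, `site`,
#' `condition`, `timepoint`, `tank_temperature_c`, `fvfm`). Condition labels
#' are case-normalized to `donor` / `nursery`; out-of-range values fail with
#' the offending file line.
#'
#' @param path CSV path.
#' @return validated measurements tibble.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path),
          class = "coralscreen_data_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, measurement_cols, sprintf("%s", path))
  df <- df |>
    dplyr::mutate(condition = tolower(trimws(.data$condition)),
                  tank_temperature_c = suppressWarnings(
                    as.numeric(.data$tank_temperature_c)),
                  fvfm = suppressWarnings(as.numeric(.data$fvfm)))
  bad <- which(!df$condition %in% c("donor", "nursery"))
  if (length(bad)) fail_lines(bad, path, "condition must be donor or nursery")
  bad <- which(!is.finite(df$tank_temperature_c) | df$tank_temperature_c <= 0)
  if (length(bad)) fail_lines(bad, path, "tank_temperature_c must parse to a positive number")
  bad <- which(!is.finite(df$fvfm) | df$fvfm < 0 | df$fvfm > 1)
  if (length(bad)) fail_lines(bad, path, "fvfm must parse to [0, 1]")
  df[measurement_cols]
}

#' Read a tank temperature-logger file
#'
#' Expects columns `timestamp_iso8601`, `tank_id`, `temperature_c` and
#' optionally `light_lux`; timestamps must parse and be non-decreasing within
#' each tank (roughly 1-minute cadence, gaps tolerated).
#'
#' @param path CSV path.
#' @return tibble with `timestamp` (POSIXct, UTC), `tank_id`,
#'   `temperature_c`, `light_lux` (NA when absent).
#' @export
read_logger <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path),
          class = "coralscreen_data_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("timestamp_iso8601", "tank_id", "temperature_c"),
                sprintf("%s", path))
  ts <- as.POSIXct(df$timestamp_iso8601, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  bad <- which(is.na(ts))
  if (length(bad)) fail_lines(bad, path, "timestamp_iso8601 must parse")
  out <- tibble::tibble(timestamp = ts,
                        tank_id = as.character(df$tank_id),
                        temperature_c = as.numeric(df$temperature_c),
                        light_lux = if ("light_lux" %in% names(df)) {
                          as.numeric(df$light_lux)
                        } else NA_real_)
  dec <- out |>
    dplyr::group_by(.data$tank_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!dec$ok)) {
    abort(sprintf("%s: timestamps decrease within tank(s): %s.", path,
                  paste(dec$tank_id[!dec$ok], collapse = ", ")),
          class = "coralscreen_validation_error")
  }
  out
}

growth_long_cols <- c("colony_id", "species", "site", "date",
                      "length_cm", "width_cm", "height_cm")

#' Read growth measurements (long format: one row per colony per date)
#'
#' Each colony must appear at exactly two dates; the earlier is the initial
#' measurement. Returns wide growth records suitable for [growth_rates()].
#'
#' @param path CSV with columns `colony_id`, `species`, `site`, `date`,
#'   `length_cm`, `width_cm`, `height_cm`.
#' @return wide tibble: `colony_id`, `species`, `site`, `date0`, `date1`,
#'   `length0` ... `height1`.
#' @export
read_growth <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path),
          class = "coralscreen_data_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(date = readr::col_date(),
                                                .default = readr::col_guess()))
  check_columns(df, growth_long_cols, sprintf("%s", path))
  dims <- c("length_cm", "width_cm", "height_cm")
  bad <- which(!stats::complete.cases(df[dims]) |
                 df$length_cm <= 0 | df$width_cm <= 0 | df$height_cm <= 0)
  if (length(bad)) fail_lines(bad, path, "dimensions must be positive numbers")
  counts <- table(df$colony_id)
  if (any(counts != 2)) {
    abort(sprintf("%s: every colony needs exactly two measurement dates; offending: %s.",
                  path, paste(names(counts)[counts != 2], collapse = ", ")),
          class = "coralscreen_validation_error")
  }
  df |>
    dplyr::group_by(.data$colony_id, .data$species, .data$site) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(date0 = .data$date[1], date1 = .data$date[2],
                     length0 = .data$length_cm[1], width0 = .data$width_cm[1],
                     height0 = .data$height_cm[1],
                     length1 = .data$length_cm[2], width1 = .data$width_cm[2],
                     height1 = .data$height_cm[2], .groups = "drop")
}

#' Convert wide growth records to the long CSV schema
#'
#' @param records wide growth records (see [read_growth()] /
#'   [simulate_growth()]).
#' @return long tibble with one row per colony per date.
#' @export
growth_to_long <- function(records) {
  check_columns(records, c("colony_id", "species", "site", "date0", "date1",
                           "length0", "width0", "height0",
                           "length1", "width1", "height1"), "growth records")
  dplyr::bind_rows(
    records |>
      dplyr::transmute(.data$colony_id, .data$species, .data$site,
                       date = as.Date(.data$date0), length_cm = .data$length0,
                       width_cm = .data$width0, height_cm = .data$height0),
    records |>
      dplyr::transmute(.data$colony_id, .data$species, .data$site,
                       date = as.Date(.data$date1), length_cm = .data$length1,
                       width_cm = .data$width1, height_cm = .data$height1)) |>
    dplyr::arrange(.data$colony_id, .data$date)
}
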