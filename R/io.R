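#' Read and write matchup tables
#'
#' The on-disk matchup format is a plain CSV with header and columns:
#' `lake_id`, `timestamp` (ISO 8601), `lat`, `lon`, `dist_land_km`,
#' `n_valid_neighbours`, the 0/1 flag columns `flag_*` and per-sensor
#' reflectances `rw_<sensor>_<band>` on the canonical band labels. Missing
#' values are empty fields.
#'
#' @param path CSV path.
#' @return A validated matchup tibble.
#' @export
read_matchups <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, na.strings = "",
                                           check.names = FALSE))
  validate_matchups(tab)
}

#' @rdname read_matchups
#' @param table A matchup tibble.
#' @export
write_matchups <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a matchup table's schema
#'
#' Checks required columns, coordinate ranges, neighbour-count bounds and
#' non-empty lake identifiers; errors name the offending column.
#'
#' @param table A matchup tibble.
#' @return The table, invisibly classed, for piping.
#' @export
validate_matchups <- function(table) {
  req <- c("lake_id", "timestamp", "lat", "lon", "dist_land_km",
           "n_valid_neighbours")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0) {
    stop("matchup table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(table$lake_id) | table$lake_id == "")) {
    stop("column 'lake_id' contains empty identifiers", call. = FALSE)
  }
  if (any(table$n_valid_neighbours < 0 | table$n_valid_neighbours > 8,
          na.rm = TRUE)) {
    stop("column 'n_valid_neighbours' outside 0..8", call. = FALSE)
  }
  if (any(abs(table$lat) > 90, na.rm = TRUE) ||
      any(abs(table$lon) > 180, na.rm = TRUE)) {
    stop("coordinates outside valid ranges", call. = FALSE)
  }
  if (any(table$dist_land_km < 0, na.rm = TRUE)) {
    stop("column 'dist_land_km' must be non-negative", call. = FALSE)
  }
  table
}

#' Read an experiment configuration (YAML or JSON)
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration document.
#' @return A named list.
#' @export
read_experiment_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
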