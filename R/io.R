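# CSV readers and writers for the pipeline's table formats.  Timestamps are
# ISO 8601, interval-ending, in a single timezone per run (UTC by default;
# the study region has no DST).

parse_timestamp <- function(x, what = "timestamp") {
  formats <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
               "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  t <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                  tz = "UTC")
  for (f in formats) {
    idx <- is.na(t) & !is.na(x)
    if (!any(idx)) break
    t[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad) > 0)
    stop(sprintf("unparseable %s in row(s): %s", what,
                 paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  t
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read a heat-pulse logger CSV
#'
#' Expected columns: `tree_id`, `timestamp` (ISO 8601), `depth_cm`,
#' `v1_C`, `v2_C`. Rows are timestamp-sorted; duplicated
#' (tree, timestamp, depth) rows are an error.
#'
#' @param path Path to the CSV file.
#' @return Heat-pulse sample table.
#' @export
read_logger_csv <- function(path) {
  check_that(file.exists(path), paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tree_id", "timestamp", "depth_cm", "v1_C", "v2_C"),
                  path)
  df$timestamp <- parse_timestamp(df$timestamp)
  key <- paste(df$tree_id, format_timestamp(df$timestamp), df$depth_cm)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicated (tree, timestamp, depth) row(s): ",
         paste(utils::head(unique(key[dup]), 5), collapse = "; "),
         call. = FALSE)
  df <- df[order(df$tree_id, df$timestamp, df$depth_cm), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a heat-pulse logger CSV
#' @param samples Heat-pulse table (`tree_id`, `timestamp`, `depth_cm`,
#'   `v1_C`, `v2_C`).
#' @param path Output path.
#' @export
write_logger_csv <- function(samples, path) {
  out <- samples[, c("tree_id", "timestamp", "depth_cm", "v1_C", "v2_C")]
  out$timestamp <- format_timestamp(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a tree-inventory CSV
#'
#' Expected columns: `tree_id`, `site`, `habitat`, `stem_diameter_cm`,
#' `sapwood_depth_cm`, `canopy_area_m2`; `sapwood_area_cm2` and
#' `bark_depth_cm` are optional (areas can come from the allometry).
#'
#' @param path Path to the CSV file.
#' @return Tree inventory data frame.
#' @export
read_inventory_csv <- function(path) {
  check_that(file.exists(path), paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tree_id", "site", "habitat", "stem_diameter_cm",
                        "sapwood_depth_cm", "canopy_area_m2"), path)
  check_that(all(df$stem_diameter_cm > 0), "stem diameters must be > 0")
  df
}

#' Read a weather-station CSV
#'
#' Expected columns: `timestamp`, `solar_wm2`, `air_temp_c`, `rh_pct`,
#' `wind_ms`, `rain_mm`, `pressure_kpa`.
#'
#' @param path Path to the CSV file.
#' @return Weather table sorted by timestamp.
#' @export
read_weather_csv <- function(path) {
  check_that(file.exists(path), paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("timestamp", "solar_wm2", "air_temp_c", "rh_pct",
                        "wind_ms", "rain_mm", "pressure_kpa"), path)
  df$timestamp <- parse_timestamp(df$timestamp)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a table with ISO 8601 timestamps
#' @param df Data frame; a `timestamp` column is formatted as ISO 8601.
#' @param path Output path.
#' @export
write_table_csv <- function(df, path) {
  if ("timestamp" %in% names(df)) df$timestamp <- format_timestamp(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
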