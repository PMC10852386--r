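#' Reading and writing study tables
#'
#' All tables travel as plain CSV; toy geometries as GeoJSON; configuration
#' as YAML. Timestamps are serialized as `"YYYY-mm-dd HH:MM:SS"` in the fixed
#' study timezone.
#'
#' @name io
#' @keywords internal
NULL

#' Read an outage-interval CSV
#'
#' @param path CSV with columns `pol_id`, `interval_start`,
#'   `customers_served`, `customers_out`. An unparseable timestamp raises an
#'   error naming the offending row.
#' @return outage-interval data.frame (see [outage_exposure]).
#' @export
read_outage_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$interval_start, tz = OUTAGECC_TZ,
                   format = "%Y-%m-%d %H:%M:%S")
  bad <- which(is.na(ts) & !is.na(df$interval_start))
  if (length(bad) > 0L)
    stop("unparseable timestamp in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " of ", path)
  df$interval_start <- ts
  df
}

#' Read a hospitalization-record CSV
#' @param path CSV with `record_id`, `admission_ts`, `bg_id`, `age`, `dx1`...
#' @return records data.frame.
#' @export
read_admissions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  ts <- as.POSIXct(df$admission_ts, tz = OUTAGECC_TZ,
                   format = "%Y-%m-%d %H:%M:%S")
  bad <- which(is.na(ts) & !is.na(df$admission_ts))
  if (length(bad) > 0L)
    stop("unparseable timestamp in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " of ", path)
  df$admission_ts <- ts
  df$age <- as.integer(df$age)
  df
}

#' Read a daily weather CSV
#' @param path CSV with `bg_id`, `day`, `tmean`, `ppt`.
#' @return weather data.frame with `day` as `Date`.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$day <- as.Date(df$day)
  df
}

#' Write rectangular geometries as GeoJSON
#'
#' @param df data.frame with an id column and `xmin`, `xmax`, `ymin`, `ymax`.
#' @param path output file.
#' @param id_col name of the id column.
#' @export
write_geojson <- function(df, path, id_col = names(df)[1]) {
  features <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = stats::setNames(list(r[[id_col]]), id_col),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write all tables of a simulated study to a directory
#'
#' Emits `pols.csv`, `outages.csv`, `block_groups.csv`, `weather.csv`,
#' `admissions.csv`, `pols.geojson`, `block_groups.geojson` and
#' `config.yaml`. Output is byte-identical for identical configurations.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%d %H:%M:%S")
  o <- sim$outages
  o$interval_start <- fmt(o$interval_start)
  a <- sim$admissions
  a$admission_ts <- fmt(a$admission_ts)
  utils::write.csv(sim$registry, file.path(dir, "pols.csv"), row.names = FALSE)
  utils::write.csv(o, file.path(dir, "outages.csv"), row.names = FALSE)
  utils::write.csv(sim$block_groups, file.path(dir, "block_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  utils::write.csv(a, file.path(dir, "admissions.csv"), row.names = FALSE)
  write_geojson(sim$registry, file.path(dir, "pols.geojson"), "pol_id")
  write_geojson(sim$block_groups, file.path(dir, "block_groups.geojson"),
                "bg_id")
  cfg <- sim$config
  cfg$period_start <- as.character(cfg$period_start)
  cfg$period_end <- as.character(cfg$period_end)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a simulated-study directory
#' @param dir directory written by [write_sim_tables()].
#' @return list in the shape of [simulate_study()] output.
#' @export
read_sim_tables <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])
  list(registry = utils::read.csv(file.path(dir, "pols.csv"),
                                  stringsAsFactors = FALSE),
       block_groups = utils::read.csv(file.path(dir, "block_groups.csv"),
                                      stringsAsFactors = FALSE),
       outages = read_outage_table(file.path(dir, "outages.csv")),
       weather = read_weather(file.path(dir, "weather.csv")),
       admissions = read_admissions(file.path(dir, "admissions.csv")),
       config = config)
}
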