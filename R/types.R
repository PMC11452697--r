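# Internal data model: validated containers for environmental datasets,
# administrative areas, health events, and linkage specifications.
# Missing observations are represented by NA (the single internal missing
# flag); they are carried, never dropped.

#' Construct a gridded environmental dataset
#'
#' @param dataset_id dataset identifier.
#' @param variables data.frame with columns `name`, `unit`, `definition`.
#' @param lon_axis,lat_axis cell-origin coordinates (degrees), strictly
#'   increasing with constant spacing; each cell is the half-open rectangle
#'   `[lon_i, lon_i + dlon) x [lat_j, lat_j + dlat)`.
#' @param time_axis strictly increasing calendar `Date`s (daily).
#' @param values 4-d array `(variable, time, lat, lon)`; `NA` marks missing.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(dataset_id, variables, lon_axis, lat_axis, time_axis, values) {
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "unit", "definition") %in% names(variables)))
  if (!is.array(values) || length(dim(values)) != 4L) {
    grid_error("values must be a 4-d array (variable, time, lat, lon)")
  }
  expected <- c(nrow(variables), length(time_axis), length(lat_axis), length(lon_axis))
  if (!identical(dim(values), as.integer(expected))) {
    grid_error(sprintf("values shape (%s) does not match axes (%s)",
                       paste(dim(values), collapse = ","), paste(expected, collapse = ",")))
  }
  check_axis <- function(ax, label) {
    if (length(ax) > 1L) {
      d <- diff(ax)
      if (any(d <= 0)) grid_error(sprintf("%s axis not strictly increasing", label))
      if (max(d) - min(d) > 1e-9) grid_error(sprintf("irregular %s axis spacing", label))
    }
  }
  check_axis(lon_axis, "lon"); check_axis(lat_axis, "lat")
  time_axis <- as.Date(time_axis)
  if (anyDuplicated(time_axis)) grid_error("duplicate dates on time axis")
  if (is.unsorted(time_axis, strictly = TRUE)) grid_error("time axis not strictly increasing")
  if (any(!is.finite(values) & !is.na(values))) grid_error("non-finite values present")
  structure(list(
    dataset_id = dataset_id, variables = variables,
    lon_axis = as.numeric(lon_axis), lat_axis = as.numeric(lat_axis),
    time_axis = time_axis, values = values
  ), class = c("env_grid", "env_dataset"))
}

#' Construct a station (point time-series) environmental dataset
#'
#' @param dataset_id dataset identifier.
#' @param stations data.frame with columns `station_id`, `lon`, `lat`.
#' @param observations data.frame with columns `station_id`, `date`,
#'   `variable`, `value` (`NA` = missing).
#' @param variables data.frame with columns `name`, `unit`, `definition`.
#' @return an object of class `env_stations`.
#' @export
env_stations <- function(dataset_id, stations, observations, variables) {
  stations <- as.data.frame(stations, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  stopifnot(all(c("station_id", "lon", "lat") %in% names(stations)))
  stopifnot(all(c("station_id", "date", "variable", "value") %in% names(observations)))
  if (anyDuplicated(stations$station_id)) validation_error("duplicate station_id values")
  unknown <- setdiff(observations$station_id, stations$station_id)
  if (length(unknown) > 0) {
    validation_error(sprintf("observation references unknown station %s", dQuote(unknown[1])))
  }
  observations$date <- as.Date(observations$date)
  key <- paste(observations$station_id, observations$date, observations$variable)
  if (anyDuplicated(key)) {
    validation_error(sprintf("duplicate (station, date, variable) observation: %s",
                             key[anyDuplicated(key)]))
  }
  bad <- !is.na(observations$value) & !is.finite(observations$value)
  if (any(bad)) validation_error("non-finite observation values present")
  structure(list(
    dataset_id = dataset_id, stations = stations,
    observations = observations, variables = variables
  ), class = c("env_stations", "env_dataset"))
}

#' Construct an administrative area
#'
#' @param area_id area identifier.
#' @param label human-readable name.
#' @param geometry an `envlink_geometry` (WGS84 lon/lat polygon/multipolygon).
#' @param parent_area_id optional enclosing area id.
#' @export
admin_area <- function(area_id, label, geometry, parent_area_id = NA_character_) {
  check_geometry(geometry, id = area_id)
  structure(list(
    area_id = area_id, label = label, geometry = geometry,
    parent_area_id = parent_area_id %||% NA_character_
  ), class = "admin_area")
}

#' Check that parent links across a list of admin areas form a forest
#' @keywords internal
check_area_forest <- function(areas) {
  ids <- vapply(areas, function(a) a$area_id, character(1))
  if (anyDuplicated(ids)) nesting_error("duplicate area_id values")
  parent <- vapply(areas, function(a) a$parent_area_id, character(1))
  for (i in seq_along(ids)) {
    seen <- character(0)
    cur <- ids[i]
    while (!is.na(cur)) {
      if (cur %in% seen) nesting_error(sprintf("cyclic parent chain at area %s", dQuote(cur)))
      seen <- c(seen, cur)
      nxt <- parent[match(cur, ids)]
      if (length(nxt) == 0 || is.na(match(cur, ids))) break
      cur <- nxt
    }
  }
  invisible(areas)
}

#' Construct a health-event table
#'
#' One row per event; exactly one of (lon, lat) or area_id per row.
#' @param event_id pseudonymous ids.
#' @param event_date `Date` vector.
#' @param lon,lat numeric (NA where the event is area-located).
#' @param area_id character (NA where the event is point-located).
#' @return data.frame of class `health_events`.
#' @export
health_events <- function(event_id, event_date, lon = NA_real_, lat = NA_real_,
                          area_id = NA_character_) {
  n <- length(event_id)
  df <- data.frame(
    event_id = as.character(event_id), event_date = as.Date(event_date),
    lon = rep_len(as.numeric(lon), n), lat = rep_len(as.numeric(lat), n),
    area_id = rep_len(as.character(area_id), n), stringsAsFactors = FALSE
  )
  has_pt <- !is.na(df$lon) & !is.na(df$lat)
  has_area <- !is.na(df$area_id)
  if (any(has_pt & has_area)) {
    ambiguity_error(sprintf("event row %d has both point coordinates and area_id",
                            which(has_pt & has_area)[1]))
  }
  if (any(!has_pt & !has_area)) {
    validation_error(sprintf("event row %d has neither point coordinates nor area_id",
                             which(!has_pt & !has_area)[1]))
  }
  if (anyDuplicated(df$event_id)) validation_error("duplicate event_id values")
  class(df) <- c("health_events", "data.frame")
  df
}

#' Linkage specification
#'
#' @param spatial_method one of `"area_contains"`, `"nearest_station"`,
#'   `"proximity_polygon"`, `"buffer"`.
#' @param buffer_km buffer radius in km (required iff method is `"buffer"`).
#' @param lag_days days between the end of the exposure window and the event
#'   (>= 0); the event day itself is always excluded.
#' @param window_days length of the exposure window in days (>= 1).
#' @param agg_functions subset of mean, min, max, sum, count, sd.
#' @param agg_level `"window"` (one record per event x variable x function)
#'   or `"daily"` (one record per event x variable x window date).
#' @param min_coverage minimum fraction of window dates that must be observed
#'   for a record not to be flagged.
#' @param exclude_flagged drop flagged records from the analysis CSV (they
#'   are always kept, quality-annotated, in the RDF graph).
#' @export
linkage_spec <- function(spatial_method = c("nearest_station", "area_contains",
                                            "proximity_polygon", "buffer"),
                         buffer_km = NULL, lag_days = 0L, window_days = 7L,
                         agg_functions = "mean", agg_level = c("window", "daily"),
                         min_coverage = 0, exclude_flagged = FALSE) {
  spatial_method <- match.arg(spatial_method)
  agg_level <- match.arg(agg_level)
  if (identical(spatial_method, "buffer")) {
    if (is.null(buffer_km) || !is.numeric(buffer_km) || buffer_km <= 0) {
      config_error("buffer method requires buffer_km > 0")
    }
  } else if (!is.null(buffer_km)) {
    config_error("buffer_km is only valid with spatial_method = 'buffer'")
  }
  if (lag_days < 0) config_error("lag_days must be >= 0")
  if (window_days < 1) config_error("window_days must be >= 1")
  allowed <- c("mean", "min", "max", "sum", "count", "sd")
  if (length(agg_functions) == 0 || !all(agg_functions %in% allowed)) {
    config_error(sprintf("agg_functions must be a non-empty subset of {%s}",
                         paste(allowed, collapse = ", ")))
  }
  if (min_coverage < 0 || min_coverage > 1) config_error("min_coverage must be in [0,1]")
  structure(list(
    spatial_method = spatial_method, buffer_km = buffer_km,
    lag_days = as.integer(lag_days), window_days = as.integer(window_days),
    agg_functions = agg_functions, agg_level = agg_level,
    min_coverage = min_coverage, exclude_flagged = isTRUE(exclude_flagged)
  ), class = "linkage_spec")
}

#' Dataset/run metadata bundle (catalogue + provenance + rights)
#'
#' @param title dataset title.
#' @param licence licence IRI or label (may be NA: recorded as an open
#'   rights statement, not an error).
#' @param version version string.
#' @param temporal_extent length-2 Date vector (start, end).
#' @param spatial_extent numeric bounding box `c(lon_min, lat_min, lon_max,
#'   lat_max)` or an area reference string.
#' @param distribution_url where the distribution lives.
#' @param agents data.frame with columns `name`, `role` (researcher,
#'   software, entity).
#' @param activity list with `used` (character vector of input dataset ids),
#'   `generated` (output dataset id), optional `started`/`ended` (xsd:dateTime
#'   strings; omitted from the graph when absent so outputs stay
#'   byte-reproducible).
#' @export
metadata_bundle <- function(title, licence = NA_character_, version = "1.0.0",
                            temporal_extent = NULL, spatial_extent = NULL,
                            distribution_url = NA_character_,
                            agents = data.frame(name = character(0), role = character(0)),
                            activity = list(used = character(0), generated = NA_character_)) {
  agents <- as.data.frame(agents, stringsAsFactors = FALSE)
  if (nrow(agents) > 0 && !all(agents$role %in% c("researcher", "software", "entity"))) {
    validation_error("agent roles must be one of researcher, software, entity")
  }
  if (!is.null(temporal_extent)) {
    temporal_extent <- as.Date(temporal_extent)
    if (length(temporal_extent) != 2L || temporal_extent[1] > temporal_extent[2]) {
      validation_error("temporal_extent must be (start, end) with start <= end")
    }
  }
  structure(list(
    title = title, licence = licence, version = version,
    temporal_extent = temporal_extent, spatial_extent = spatial_extent,
    distribution_url = distribution_url, agents = agents, activity = activity
  ), class = "metadata_bundle")
}

#' Variables provided by a dataset
#' @param ds an `env_grid` or `env_stations` object.
#' @export
dataset_variables <- function(ds) ds$variables$name

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %s: %d variable(s), %d x %d cells, %d days (%s .. %s)\n",
              x$dataset_id, nrow(x$variables), length(x$lat_axis), length(x$lon_axis),
              length(x$time_axis), min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

#' @export
print.env_stations <- function(x, ...) {
  cat(sprintf("<env_stations> %s: %d variable(s), %d stations, %d observations\n",
              x$dataset_id, nrow(x$variables), nrow(x$stations), nrow(x$observations)))
  invisible(x)
}
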