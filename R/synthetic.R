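# Seeded synthetic fixtures emulating the study's dataset shapes: a gridded
# daily weather-like field, station (point) time series sharing the same
# value model, nested administrative areas, and daily patient-event records.
# Every generator is a pure function of its spec: each draws from its own
# RNG stream derived from (seed, generator name), so adding one generator
# call never perturbs another.

#' Specification for the synthetic generators
#'
#' The default values define the package's reference study conditions: a
#' country-scale 8 x 6 degree extent, a 10 x 10 daily grid over 120 days, 25
#' stations, 50 events, one temperature-like and one PM10-like variable, and
#' 5% missing observations.
#'
#' @param seed integer seed; fully determines every generated artifact.
#' @param extent bounding box `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param n_days number of daily steps (>= 1).
#' @param start_date first date.
#' @param grid_shape `c(n_lat, n_lon)` cells.
#' @param n_stations number of stations.
#' @param n_events number of health events.
#' @param variables data.frame with columns `name`, `unit`, `definition`,
#'   `base_level`, `daily_amplitude`, `noise_sd`, `spatial_gradient`
#'   (per degree latitude).
#' @param missing_rate fraction of observations flagged missing, in [0, 1).
#' @export
synth_spec <- function(seed = 1L,
                       extent = c(-4, 50, 4, 56),
                       n_days = 120L,
                       start_date = as.Date("2021-01-01"),
                       grid_shape = c(10L, 10L),
                       n_stations = 25L,
                       n_events = 50L,
                       variables = NULL,
                       missing_rate = 0.05) {
  if (is.null(variables)) {
    variables <- data.frame(
      name = c("temperature", "pm10"),
      unit = c("degC", "ug/m3"),
      definition = c("daily mean air temperature at 2 m",
                     "daily mean particulate matter < 10 um"),
      base_level = c(10, 20),
      daily_amplitude = c(8, 5),
      noise_sd = c(2, 4),
      spatial_gradient = c(-0.5, 0),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(length(extent) == 4, extent[1] < extent[3], extent[2] < extent[4])
  if (n_days < 1) config_error("n_days must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) config_error("missing_rate must be in [0, 1)")
  if (n_stations < 1 || n_events < 1 || any(grid_shape < 1)) {
    config_error("counts must be positive")
  }
  structure(list(
    seed = as.integer(seed), extent = as.numeric(extent), n_days = as.integer(n_days),
    start_date = as.Date(start_date), grid_shape = as.integer(grid_shape),
    n_stations = as.integer(n_stations), n_events = as.integer(n_events),
    variables = variables, missing_rate = missing_rate
  ), class = "synth_spec")
}

# run code under a private RNG stream derived from (seed, stream id)
with_gen_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 131L + stream) %% 2147483647L)
  force(code)
}

# shared value model: seasonal sine + latitudinal gradient + Gaussian noise
synth_value <- function(var, t_index, lat, lat0) {
  var$base_level + var$daily_amplitude * sin(2 * pi * t_index / 365) +
    var$spatial_gradient * (lat - lat0)
}

#' Generate a gridded daily environmental dataset
#'
#' `value(var, t, lat, lon) = base_level + daily_amplitude * sin(2 pi t/365)
#' + spatial_gradient * (lat - lat0) + N(0, noise_sd)`, with missing flags
#' applied at `missing_rate`; fully determined by the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @param dataset_id dataset identifier.
#' @return an [env_grid()].
#' @export
gen_grid <- function(spec, dataset_id = "synthetic_grid") {
  n_lat <- spec$grid_shape[1]; n_lon <- spec$grid_shape[2]
  dlon <- (spec$extent[3] - spec$extent[1]) / n_lon
  dlat <- (spec$extent[4] - spec$extent[2]) / n_lat
  lon_axis <- spec$extent[1] + (seq_len(n_lon) - 1L) * dlon
  lat_axis <- spec$extent[2] + (seq_len(n_lat) - 1L) * dlat
  time_axis <- spec$start_date + seq_len(spec$n_days) - 1L
  nv <- nrow(spec$variables)
  values <- array(NA_real_, dim = c(nv, spec$n_days, n_lat, n_lon))
  with_gen_seed(spec$seed, 1L, {
    for (k in seq_len(nv)) {
      v <- spec$variables[k, ]
      for (t in seq_len(spec$n_days)) {
        det <- outer(lat_axis, rep(1, n_lon)) # (lat, lon) latitude matrix
        base <- synth_value(v, t - 1L, det, spec$extent[2])
        noise <- matrix(stats::rnorm(n_lat * n_lon, 0, v$noise_sd), n_lat, n_lon)
        values[k, t, , ] <- base + noise
      }
    }
    if (spec$missing_rate > 0) {
      miss <- stats::runif(length(values)) < spec$missing_rate
      values[miss] <- NA_real_
    }
    values
  })
  env_grid(dataset_id, spec$variables[, c("name", "unit", "definition")],
           lon_axis, lat_axis, time_axis, values)
}

#' Generate a station (point time-series) dataset
#'
#' Station coordinates are uniform in the extent; observations are drawn
#' from the same value model as [gen_grid()], sampled at the station
#' coordinates.  Station ids are `st000`, `st001`, ... (unique, sorted).
#'
#' @param spec a [synth_spec()].
#' @param dataset_id dataset identifier.
#' @return an [env_stations()].
#' @export
gen_stations_dataset <- function(spec, dataset_id = "synthetic_stations") {
  time_axis <- spec$start_date + seq_len(spec$n_days) - 1L
  nv <- nrow(spec$variables)
  obs <- with_gen_seed(spec$seed, 2L, {
    stations <- data.frame(
      station_id = sprintf("st%03d", seq_len(spec$n_stations) - 1L),
      lon = stats::runif(spec$n_stations, spec$extent[1], spec$extent[3]),
      lat = stats::runif(spec$n_stations, spec$extent[2], spec$extent[4]),
      stringsAsFactors = FALSE
    )
    grid_idx <- expand.grid(st = seq_len(spec$n_stations), t = seq_len(spec$n_days),
                            v = seq_len(nv))
    vars <- spec$variables[grid_idx$v, ]
    det <- synth_value(vars, grid_idx$t - 1L, stations$lat[grid_idx$st], spec$extent[2])
    value <- det + stats::rnorm(nrow(grid_idx), 0, vars$noise_sd)
    if (spec$missing_rate > 0) {
      value[stats::runif(length(value)) < spec$missing_rate] <- NA_real_
    }
    list(stations = stations, df = data.frame(
      station_id = stations$station_id[grid_idx$st],
      date = time_axis[grid_idx$t],
      variable = spec$variables$name[grid_idx$v],
      value = value, stringsAsFactors = FALSE
    ))
  })
  env_stations(dataset_id, obs$stations, obs$df,
               spec$variables[, c("name", "unit", "definition")])
}

#' Generate nested administrative areas over the extent
#'
#' One parent rectangle covering the extent and two child rectangles
#' splitting it west/east — the minimal nested-geometry fixture.
#'
#' @param spec a [synth_spec()].
#' @return list of `admin_area` objects (parent first).
#' @export
gen_areas <- function(spec) {
  e <- spec$extent
  rect <- function(x1, y1, x2, y2) {
    new_geometry(list(list(rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2), c(x1, y1)))))
  }
  mid <- (e[1] + e[3]) / 2
  list(
    admin_area("region0", "Whole region", rect(e[1], e[2], e[3], e[4])),
    admin_area("areaW", "Western half", rect(e[1], e[2], mid, e[4]), "region0"),
    admin_area("areaE", "Eastern half", rect(mid, e[2], e[3], e[4]), "region0")
  )
}

#' Generate pseudonymous health events
#'
#' Event dates are uniform in `[start_date + margin, start_date + n_days)`
#' with a 60-day margin so default exposure windows fit inside data
#' coverage; the margin auto-shrinks (with a warning) when `n_days <= 60`.
#' Locations are uniform points in the extent, or area ids drawn from
#' `areas` when given.
#'
#' @param spec a [synth_spec()].
#' @param areas optional list of `admin_area`: events get `area_id`
#'   locations instead of points.
#' @return a `health_events` table.
#' @export
gen_events <- function(spec, areas = NULL) {
  margin <- 60L
  if (spec$n_days <= margin) {
    margin <- max(spec$n_days - 1L, 0L)
    warning(sprintf("n_days <= 60: event-date margin shrunk to %d days", margin),
            call. = FALSE)
  }
  with_gen_seed(spec$seed, 3L, {
    offsets <- sample.int(spec$n_days - margin, spec$n_events, replace = TRUE) - 1L
    dates <- spec$start_date + margin + offsets
    ids <- sprintf("ev%04d", seq_len(spec$n_events) - 1L)
    if (is.null(areas)) {
      health_events(
        event_id = ids, event_date = dates,
        lon = stats::runif(spec$n_events, spec$extent[1], spec$extent[3]),
        lat = stats::runif(spec$n_events, spec$extent[2], spec$extent[4])
      )
    } else {
      area_ids <- vapply(areas, function(a) a$area_id, character(1))
      health_events(event_id = ids, event_date = dates,
                    area_id = sample(area_ids, spec$n_events, replace = TRUE))
    }
  })
}

#' Write a full synthetic fixture set to disk
#'
#' Emits the grid (NetCDF), stations (CSV), areas (GeoJSON) and events
#' (CSV) in the dialects [read_env_dataset()], [read_areas()] and
#' [read_events()] read.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_synth_fixtures <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    grid = file.path(out_dir, "synthetic_grid.nc"),
    stations = file.path(out_dir, "synthetic_stations.csv"),
    areas = file.path(out_dir, "synthetic_areas.geojson"),
    events = file.path(out_dir, "synthetic_events.csv")
  )
  write_env_dataset(gen_grid(spec), paths[["grid"]])
  write_env_dataset(gen_stations_dataset(spec), paths[["stations"]])
  write_areas_geojson(gen_areas(spec), paths[["areas"]])
  write_events(gen_events(spec), paths[["events"]])
  paths
}
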