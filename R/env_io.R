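# Readers and writers for environmental datasets (NetCDF grid, CSV/TSV
# stations), administrative geometries (GeoJSON, WKT-bearing CSV) and
# health-event tables.  All coordinates are WGS84 lon/lat; all dates are
# calendar dates (sub-daily inputs are rejected, not resampled).

NC_FILL_DOUBLE <- 9.969209968386869e+36

default_station_schema <- function() {
  list(station_id = "station_id", lon = "lon", lat = "lat",
       date = "date", variable = "variable", value = "value")
}

#' Read an environmental dataset
#'
#' Accepted formats: `netcdf` (.nc; CF-style lon/lat/time grid) yielding an
#' [env_grid()], and `csv` / `tsv` / `grid` (tabular station observations;
#' `.grid` is the same tabular dialect with the default header) yielding an
#' [env_stations()].  Missing values (NetCDF fill values, empty cells) map to
#' `NA` and are kept, never dropped.
#'
#' @param path input file.
#' @param format one of `"netcdf"`, `"csv"`, `"tsv"`, `"grid"`; inferred from
#'   the file extension when `NULL`.
#' @param schema for tabular input, a named list mapping the roles
#'   station_id, lon, lat, date, variable, value to column names (defaults to
#'   those names); for NetCDF, an optional list with `vars` (data variable
#'   names to read; default all non-coordinate variables).
#' @param dataset_id identifier; defaults to the file base name.
#' @return an `env_grid` or `env_stations` object.
#' @export
read_env_dataset <- function(path, format = NULL, schema = NULL, dataset_id = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (is.null(format)) {
    format <- switch(ext, nc = "netcdf", csv = "csv", tsv = "tsv", grid = "grid",
                     format_error(sprintf(
                       "unsupported input extension %s (accepted: .nc, .grid, .csv, .tsv)",
                       dQuote(paste0(".", ext)))))
  }
  if (!format %in% c("netcdf", "csv", "tsv", "grid")) {
    format_error(sprintf("unsupported format %s", dQuote(format)))
  }
  dataset_id <- dataset_id %||% tools::file_path_sans_ext(basename(path))
  if (format == "netcdf") {
    read_grid_netcdf(path, schema, dataset_id)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    read_stations_tabular(path, sep, schema %||% default_station_schema(), dataset_id)
  }
}

read_grid_netcdf <- function(path, schema, dataset_id) {
  nc <- nc3_read(path)
  coord_names <- c("lon", "lat", "time", "longitude", "latitude")
  axis_var <- function(cands) {
    nm <- intersect(cands, names(nc$vars))
    if (length(nm) == 0) schema_error(sprintf("NetCDF file lacks a %s coordinate variable", cands[1]))
    nc$vars[[nm[1]]]
  }
  lon_v <- axis_var(c("lon", "longitude"))
  lat_v <- axis_var(c("lat", "latitude"))
  time_v <- axis_var("time")
  t_units <- trimws(time_v$atts[["units"]] %||% "days since 1970-01-01")
  m <- regmatches(t_units, regexec("^days since (\\d{4}-\\d{2}-\\d{2})", t_units))[[1]]
  if (length(m) < 2) {
    format_error(sprintf(
      "unsupported time units %s (daily resolution required)", dQuote(t_units)))
  }
  origin <- as.Date(m[2])
  tvals <- time_v$data
  if (any(tvals != round(tvals))) {
    format_error("sub-daily time values are not supported (daily resolution required)")
  }
  time_axis <- origin + round(tvals)

  data_names <- schema$vars %||% setdiff(names(nc$vars), c(coord_names, "time"))
  missing_vars <- setdiff(data_names, names(nc$vars))
  if (length(missing_vars) > 0) {
    schema_error(sprintf("variable %s not present in NetCDF file", dQuote(missing_vars[1])))
  }
  if (length(data_names) == 0) schema_error("NetCDF file contains no data variables")

  nlon <- length(lon_v$data); nlat <- length(lat_v$data); nt <- length(time_axis)
  values <- array(NA_real_, dim = c(length(data_names), nt, nlat, nlon))
  variables <- data.frame(name = data_names, unit = NA_character_,
                          definition = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(data_names)) {
    v <- nc$vars[[data_names[k]]]
    want <- c("time", lon_v$name, lat_v$name)
    if (!setequal(v$dims, c("time", lat_v$name, lon_v$name))) {
      schema_error(sprintf("variable %s does not span (time, lat, lon)", dQuote(v$name)))
    }
    fill <- v$atts[["_FillValue"]] %||% NC_FILL_DOUBLE
    dat <- v$data
    dat[!is.na(dat) & (dat == fill | abs(dat) > 1e35)] <- NA_real_
    # NetCDF order: last dim fastest.  v$dims is slowest-first.
    shape_rev <- rev(unlist(nc$dims[v$dims], use.names = FALSE))
    arr <- array(dat, dim = shape_rev)                       # (fastest .. slowest)
    arr <- aperm(arr, rev(seq_along(shape_rev)))             # back to header order
    perm <- match(c("time", lat_v$name, lon_v$name), v$dims)
    values[k, , , ] <- aperm(arr, perm)
    variables$unit[k] <- (v$atts[["units"]] %||% NA_character_)[1]
    variables$definition[k] <- (v$atts[["long_name"]] %||% NA_character_)[1]
  }
  env_grid(dataset_id, variables, as.numeric(lon_v$data), as.numeric(lat_v$data),
           time_axis, values)
}

read_stations_tabular <- function(path, sep, schema, dataset_id) {
  roles <- c("station_id", "lon", "lat", "date", "variable", "value")
  missing_roles <- setdiff(roles, names(schema))
  if (length(missing_roles) > 0) {
    schema_error(sprintf("schema lacks a column mapping for %s", dQuote(missing_roles[1])))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "\"", comment.char = "")
  unknown <- setdiff(unlist(schema[roles]), names(df))
  if (length(unknown) > 0) {
    schema_error(sprintf("schema names column %s which is absent from %s",
                         dQuote(unknown[1]), basename(path)))
  }
  dates <- parse_iso_date(df[[schema$date]], context = "date")
  value_raw <- trimws(df[[schema$value]])
  value <- suppressWarnings(as.numeric(value_raw))
  bad <- which(value_raw != "" & !toupper(value_raw) %in% c("NA", "NAN") & is.na(value))
  if (length(bad) > 0) {
    format_error(sprintf("non-numeric value %s at row %d", dQuote(value_raw[bad[1]]), bad[1]))
  }
  obs <- data.frame(
    station_id = df[[schema$station_id]],
    date = dates,
    variable = df[[schema$variable]],
    value = value,
    stringsAsFactors = FALSE
  )
  st <- unique(data.frame(
    station_id = df[[schema$station_id]],
    lon = as.numeric(df[[schema$lon]]),
    lat = as.numeric(df[[schema$lat]]),
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(st$station_id)) {
    validation_error("station coordinates differ between rows with the same station_id")
  }
  var_names <- sort(unique(obs$variable))
  variables <- data.frame(name = var_names, unit = NA_character_,
                          definition = NA_character_, stringsAsFactors = FALSE)
  env_stations(dataset_id, st[order(st$station_id), , drop = FALSE], obs, variables)
}

#' Write an environmental dataset in the dialect read_env_dataset() reads
#'
#' Grids are written as CF-style NetCDF-3 classic; station datasets as CSV
#' (or TSV) with the default column names.  Missing values become the NetCDF
#' fill value / empty cells.
#' @param ds dataset object.
#' @param path output path.
#' @export
write_env_dataset <- function(ds, path) {
  if (inherits(ds, "env_grid")) {
    nt <- length(ds$time_axis); nlat <- length(ds$lat_axis); nlon <- length(ds$lon_axis)
    dims <- list(time = nt, lat = nlat, lon = nlon)
    vars <- list(
      list(name = "lon", dims = "lon", type = "double", data = ds$lon_axis,
           atts = list(units = "degrees_east")),
      list(name = "lat", dims = "lat", type = "double", data = ds$lat_axis,
           atts = list(units = "degrees_north")),
      list(name = "time", dims = "time", type = "int",
           data = as.integer(ds$time_axis - as.Date("1970-01-01")),
           atts = list(units = "days since 1970-01-01"))
    )
    for (k in seq_len(nrow(ds$variables))) {
      arr <- ds$values[k, , , , drop = TRUE]
      dim(arr) <- c(nt, nlat, nlon)
      flat <- as.vector(aperm(arr, c(3, 2, 1)))  # lon fastest, time slowest
      flat[is.na(flat)] <- NC_FILL_DOUBLE
      atts <- list(`_FillValue` = NC_FILL_DOUBLE)
      if (!is.na(ds$variables$unit[k])) atts$units <- ds$variables$unit[k]
      if (!is.na(ds$variables$definition[k])) atts$long_name <- ds$variables$definition[k]
      vars[[length(vars) + 1L]] <- list(
        name = ds$variables$name[k], dims = c("time", "lat", "lon"),
        type = "double", data = flat, atts = atts)
    }
    nc3_write(path, dims, vars, gatts = list(title = ds$dataset_id, Conventions = "CF-1.6"))
  } else if (inherits(ds, "env_stations")) {
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
    df <- merge(ds$observations, ds$stations, by = "station_id", sort = FALSE)
    df <- df[order(df$station_id, df$date, df$variable),
             c("station_id", "lon", "lat", "date", "variable", "value")]
    df$date <- format(df$date, "%Y-%m-%d")
    df$value <- ifelse(is.na(df$value), "", sprintf("%.17g", df$value))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    format_error("write_env_dataset: unsupported dataset class")
  }
  invisible(path)
}

#' Read a health-event table
#'
#' CSV with header; columns `event_id`, `date`, and either (`lon`, `lat`) or
#' `area_id`.  A row carrying both a point and an area is an ambiguity error.
#' Row order is preserved.
#' @param path CSV file.
#' @return a `health_events` data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = character(0), check.names = FALSE)
  if (!all(c("event_id", "date") %in% names(df))) {
    schema_error("events file must have columns event_id and date")
  }
  blank_to_na <- function(x) { x <- trimws(x); x[x == ""] <- NA_character_; x }
  get_col <- function(nm) if (nm %in% names(df)) blank_to_na(df[[nm]]) else rep(NA_character_, nrow(df))
  miss <- which(is.na(blank_to_na(df$date)))
  if (length(miss) > 0) {
    validation_error(sprintf("missing date at event row %d", miss[1]))
  }
  dates <- parse_iso_date(df$date, context = "event date")
  health_events(
    event_id = df$event_id, event_date = dates,
    lon = suppressWarnings(as.numeric(get_col("lon"))),
    lat = suppressWarnings(as.numeric(get_col("lat"))),
    area_id = get_col("area_id")
  )
}

#' Write a health-event table in the dialect read_events() reads
#' @keywords internal
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$date <- format(df$event_date, "%Y-%m-%d")
  df <- df[, c("event_id", "date", "lon", "lat", "area_id")]
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read administrative areas (GeoJSON or WKT-bearing CSV)
#'
#' Geometries must be valid WGS84 lon/lat polygons/multipolygons; parent
#' links are checked to form a forest (no cycles).
#' @param path input file.
#' @param format `"geojson"` or `"wkt-csv"` (columns
#'   `area_id,label,wkt,parent`); inferred from the extension when `NULL`.
#' @return list of `admin_area` objects.
#' @export
read_areas <- function(path, format = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, geojson = "geojson", json = "geojson", csv = "wkt-csv",
                     format_error(sprintf("cannot infer area format from extension .%s", ext)))
  }
  areas <- if (format == "geojson") read_areas_geojson(path) else read_areas_wktcsv(path)
  check_area_forest(areas)
  areas
}

read_areas_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) format_error("GeoJSON must be a FeatureCollection")
  lapply(gj$features, function(f) {
    props <- f$properties %||% list()
    geom <- f$geometry
    rings_from <- function(poly_coords) {
      lapply(poly_coords, function(ring) {
        ring_close(do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2]))))
      })
    }
    g <- switch(geom$type,
      Polygon = new_geometry(list(rings_from(geom$coordinates))),
      MultiPolygon = new_geometry(lapply(geom$coordinates, rings_from)),
      geometry_error(sprintf("unsupported GeoJSON geometry type %s", dQuote(geom$type)))
    )
    admin_area(
      area_id = props$area_id %||% props$id %||% geometry_error("feature lacks an area_id"),
      label = props$label %||% props$area_id,
      geometry = g,
      parent_area_id = props$parent_area_id %||% props$parent %||% NA_character_
    )
  })
}

read_areas_wktcsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = character(0), check.names = FALSE)
  need <- c("area_id", "label", "wkt", "parent")
  if (!all(need %in% names(df))) {
    schema_error(sprintf("WKT-CSV must have columns %s", paste(need, collapse = ",")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    parent <- trimws(df$parent[i])
    admin_area(df$area_id[i], df$label[i], parse_wkt(df$wkt[i]),
               if (parent == "") NA_character_ else parent)
  })
}

#' Write administrative areas as GeoJSON
#' @keywords internal
write_areas_geojson <- function(areas, path) {
  features <- lapply(areas, function(a) {
    coords <- lapply(a$geometry$polys, function(rings) {
      lapply(rings, function(ring) lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
    })
    geom <- if (length(coords) == 1L) {
      list(type = "Polygon", coordinates = coords[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    props <- list(area_id = a$area_id, label = a$label)
    if (!is.na(a$parent_area_id)) props$parent_area_id <- a$parent_area_id
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
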