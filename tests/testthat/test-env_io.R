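# Reading and validating environmental datasets, events and areas.

test_that("NetCDF grid round-trips with the documented (var, time, lat, lon) shape", {
  spec <- synth_spec(seed = 5, n_days = 10, grid_shape = c(4, 4), n_stations = 3,
                     n_events = 2, missing_rate = 0.2,
                     variables = data.frame(name = "temp", unit = "degC", definition = "t",
                                            base_level = 4, daily_amplitude = 2,
                                            noise_sd = 1, spatial_gradient = 0.1))
  g <- gen_grid(spec)
  expect_identical(dim(g$values), c(1L, 10L, 4L, 4L))
  path <- withr::local_tempfile(fileext = ".nc")
  write_env_dataset(g, path)
  g2 <- read_env_dataset(path)
  expect_identical(dim(g2$values), c(1L, 10L, 4L, 4L))
  expect_equal(g2$lon_axis, g$lon_axis)
  expect_equal(g2$time_axis, g$time_axis)
  # missing flags survive; non-missing values survive at full precision
  expect_identical(is.na(g2$values), is.na(g$values))
  expect_equal(g2$values, g$values)
})

test_that("NetCDF reading agrees with an independent scipy reader", {
  spec <- synth_spec(seed = 11, n_days = 6, grid_shape = c(3, 5), n_stations = 3,
                     n_events = 2, missing_rate = 0.15)
  g <- gen_grid(spec)
  path <- withr::local_tempfile(fileext = ".nc")
  write_env_dataset(g, path)
  script <- paste(
    "from scipy.io import netcdf_file; import numpy as np; import sys",
    sprintf("f = netcdf_file('%s', mmap=False)", path),
    "t = np.asarray(f.variables['temperature'][:], dtype=float)",
    "t = np.where(np.abs(t) > 1e35, np.nan, t)",
    "print(t.shape[0], t.shape[1], t.shape[2], int(np.isnan(t).sum()), repr(float(np.nansum(t))))",
    sep = "; ")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)), stdout = TRUE))
  expect_length(out, 1L)
  parts <- strsplit(out, " ")[[1]]
  vals <- g$values[1, , , ]
  expect_identical(as.integer(parts[1:3]), dim(vals))          # (time, lat, lon)
  expect_identical(as.integer(parts[4]), sum(is.na(vals)))
  expect_equal(as.numeric(parts[5]), sum(vals, na.rm = TRUE), tolerance = 1e-12)
})

test_that("tabular station input keeps every row and the declared column mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "station_id,lon,lat,date,variable,value",
    "a,0.0,50.0,2021-01-01,no2,10.5",
    "a,0.0,50.0,2021-01-02,no2,",
    "a,0.0,50.0,2021-01-01,pm10,3",
    "b,1.0,51.0,2021-01-01,no2,11",
    "b,1.0,51.0,2021-01-02,no2,12",
    "b,1.0,51.0,2021-01-01,pm10,4"), path)
  ds <- read_env_dataset(path)
  expect_s3_class(ds, "env_stations")
  expect_identical(nrow(ds$observations), 6L)          # input rows == stored observations
  expect_identical(sum(is.na(ds$observations$value)), 1L)  # empty cell -> missing flag, kept
  expect_identical(sort(ds$stations$station_id), c("a", "b"))
  # round-trip through the writer
  out <- withr::local_tempfile(fileext = ".csv")
  write_env_dataset(ds, out)
  ds2 <- read_env_dataset(out)
  o1 <- ds$observations[order(ds$observations$station_id, ds$observations$date,
                              ds$observations$variable), ]
  o2 <- ds2$observations
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("schema errors, format errors and date errors are typed and name the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sid,lon,lat,date,variable,value", "a,0,50,2021-01-01,no2,1"), path)
  expect_error(read_env_dataset(path), class = "envlink_schema_error")
  expect_error(
    read_env_dataset(path, schema = list(station_id = "sid", lon = "lon", lat = "lat",
                                         date = "date", variable = "variable",
                                         value = "nope")),
    class = "envlink_schema_error")
  ok <- read_env_dataset(path, schema = list(station_id = "sid", lon = "lon", lat = "lat",
                                             date = "date", variable = "variable",
                                             value = "value"))
  expect_identical(nrow(ok$observations), 1L)

  bad_date <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,lon,lat,date,variable,value", "a,0,50,01/02/2021,no2,1"), bad_date)
  err <- expect_error(read_env_dataset(bad_date), class = "envlink_validation_error")
  expect_match(conditionMessage(err), "row 1")

  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  file.create(xlsx)
  expect_error(read_env_dataset(xlsx), class = "envlink_format_error")
})

test_that("sub-daily NetCDF time axes are rejected, not resampled", {
  path <- withr::local_tempfile(fileext = ".nc")
  nc3_write(path,
            dims = list(time = 2L, lat = 1L, lon = 1L),
            vars = list(
              list(name = "lon", dims = "lon", type = "double", data = 0),
              list(name = "lat", dims = "lat", type = "double", data = 50),
              list(name = "time", dims = "time", type = "double", data = c(0, 0.5),
                   atts = list(units = "days since 2021-01-01")),
              list(name = "x", dims = c("time", "lat", "lon"), type = "double", data = c(1, 2))))
  expect_error(read_env_dataset(path), class = "envlink_format_error")
})

test_that("irregular grid spacing is a grid error", {
  expect_error(
    env_grid("g", data.frame(name = "x", unit = "u", definition = "d"),
             lon_axis = c(0, 1, 2.5), lat_axis = c(0, 1),
             time_axis = as.Date("2021-01-01"),
             values = array(0, c(1, 1, 2, 3))),
    class = "envlink_grid_error")
})

test_that("event tables parse points, reject bad dates and ambiguous locations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,date,lon,lat", "e1,2021-05-01,0.5,50.5", "e2,2021-05-02,1.5,51.5"), path)
  ev <- read_events(path)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$event_id, c("e1", "e2"))   # row order preserved
  expect_true(all(!is.na(ev$lon)))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,date,lon,lat", "e1,2021-13-01,0.5,50.5"), bad)
  expect_error(read_events(bad), class = "envlink_validation_error")

  amb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,date,lon,lat,area_id", "e1,2021-05-01,0.5,50.5,areaX"), amb)
  expect_error(read_events(amb), class = "envlink_ambiguity_error")

  nodate <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,date,lon,lat", "e1,,0.5,50.5"), nodate)
  err <- expect_error(read_events(nodate), class = "envlink_validation_error")
  expect_match(conditionMessage(err), "row 1")
})

test_that("GeoJSON and WKT-CSV area readers agree on the same nested fixture", {
  areas <- nested_areas()
  gj <- withr::local_tempfile(fileext = ".geojson")
  envlink:::write_areas_geojson(areas, gj)
  from_gj <- read_areas(gj)
  expect_length(from_gj, 2L)
  expect_identical(from_gj[[2]]$parent_area_id, "outer")

  wkt_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "area_id,label,wkt,parent",
    sprintf("outer,Outer region,\"%s\",", envlink:::format_wkt(areas[[1]]$geometry)),
    sprintf("inner,Inner district,\"%s\",outer", envlink:::format_wkt(areas[[2]]$geometry))
  ), wkt_csv)
  from_wkt <- read_areas(wkt_csv)
  for (i in 1:2) {
    expect_identical(from_wkt[[i]]$area_id, from_gj[[i]]$area_id)
    expect_identical(from_wkt[[i]]$parent_area_id, from_gj[[i]]$parent_area_id)
    expect_equal(from_wkt[[i]]$geometry$polys, from_gj[[i]]$geometry$polys, tolerance = 1e-9)
  }
})

test_that("invalid geometries and cyclic nesting are rejected", {
  zero <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area_id,label,wkt,parent",
               "z,Zero,\"POLYGON ((0 0, 0 0, 0 0, 0 0))\","), zero)
  expect_error(read_areas(zero), class = "envlink_geometry_error")

  bowtie <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area_id,label,wkt,parent",
               "b,Bowtie,\"POLYGON ((0 0, 1 1, 1 0, 0 1, 0 0))\","), bowtie)
  expect_error(read_areas(bowtie), class = "envlink_geometry_error")

  cyc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area_id,label,wkt,parent",
               "a,A,\"POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))\",b",
               "b,B,\"POLYGON ((0 0, 2 0, 2 2, 0 2, 0 0))\",a"), cyc)
  expect_error(read_areas(cyc), class = "envlink_nesting_error")
})
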