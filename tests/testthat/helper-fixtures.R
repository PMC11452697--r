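# Fixture builders used across the suite.  Everything is constructed in
# code; nothing is read from checked-in binary data.

# tiny hand-built station dataset: n stations on the equator-ish line,
# full daily coverage
tiny_stations <- function(n_stations = 2, n_days = 10, variables = "temp",
                          start = as.Date("2021-03-01"), dataset_id = "tiny",
                          value_fun = function(st, t, v) st * 100 + t) {
  stations <- data.frame(
    station_id = sprintf("st%02d", seq_len(n_stations)),
    lon = seq(0, by = 1, length.out = n_stations),
    lat = rep(50, n_stations), stringsAsFactors = FALSE
  )
  idx <- expand.grid(st = seq_len(n_stations), t = seq_len(n_days),
                     v = seq_along(variables))
  obs <- data.frame(
    station_id = stations$station_id[idx$st],
    date = start + idx$t - 1L,
    variable = variables[idx$v],
    value = value_fun(idx$st, idx$t, idx$v),
    stringsAsFactors = FALSE
  )
  env_stations(dataset_id, stations, obs,
               data.frame(name = variables, unit = "u", definition = "synthetic test variable",
                          stringsAsFactors = FALSE))
}

# nested rectangle areas: outer [0,10]x[0,10], inner child [2,8]x[2,8]
nested_areas <- function() {
  rect <- function(x1, y1, x2, y2) {
    new_geometry(list(list(rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2), c(x1, y1)))))
  }
  list(
    admin_area("outer", "Outer region", rect(0, 0, 10, 10)),
    admin_area("inner", "Inner district", rect(2, 2, 8, 8), parent_area_id = "outer")
  )
}

# events table with point locations
point_events <- function(lons, lats, dates, ids = sprintf("ev%02d", seq_along(lons))) {
  health_events(event_id = ids, event_date = as.Date(dates), lon = lons, lat = lats)
}

# the "standard fixture": 3 events, 2 variables, full coverage
standard_fixture <- function() {
  ds <- tiny_stations(n_stations = 4, n_days = 30, variables = c("temp", "pm10"),
                      start = as.Date("2021-02-01"), dataset_id = "stdfix",
                      value_fun = function(st, t, v) v * 1000 + st * 10 + t)
  ev <- point_events(c(0.1, 1.2, 2.6), c(50.01, 49.99, 50.02),
                     c("2021-02-20", "2021-02-25", "2021-03-01"))
  list(ds = ds, ev = ev)
}

expect_triple <- function(g, s, p, o) {
  expect_true(any(g$subject == s & g$predicate == p & g$object == o),
              label = sprintf("graph contains (%s %s %s)", s, p, o))
}
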