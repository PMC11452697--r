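# Exposure windows, spatial assignment, query template, link materialization.

test_that("exposure windows are half-open and always exclude the event day", {
  w <- temporal_window(as.Date("2021-03-10"), lag_days = 0, window_days = 7)
  expect_identical(w$dates, seq(as.Date("2021-03-03"), as.Date("2021-03-09"), by = "day"))
  expect_identical(w$end_date_exclusive, as.Date("2021-03-10"))

  # lag 30, window 14: enumerated by hand on the calendar
  w2 <- temporal_window(as.Date("2021-03-10"), lag_days = 30, window_days = 14)
  expect_identical(w2$dates[1], as.Date("2021-01-25"))
  expect_identical(w2$dates[length(w2$dates)], as.Date("2021-02-07"))
  expect_length(w2$dates, 14L)

  # minimal window is exactly the day before the event
  w3 <- temporal_window(as.Date("2021-07-01"), lag_days = 0, window_days = 1)
  expect_identical(w3$dates, as.Date("2021-06-30"))
})

test_that("window arithmetic law holds over random (date, lag, window) triples", {
  set.seed(2024)
  for (i in 1:200) {
    d <- as.Date("2015-01-01") + sample.int(4000, 1)
    lag <- sample(0:60, 1); win <- sample(1:90, 1)
    w <- temporal_window(d, lag, win)
    expect_length(w$dates, win)
    expect_identical(max(w$dates), d - lag - 1L)
    expect_true(all(w$dates < d))
  }
})

test_that("nearest-station picks the closest station with lexicographic tie-break", {
  ds <- env_stations("ns",
    stations = data.frame(station_id = c("B", "A"), lon = c(1, 0), lat = c(0, 0)),
    observations = data.frame(station_id = "A", date = as.Date("2021-01-01"),
                              variable = "x", value = 1),
    variables = data.frame(name = "x", unit = "u", definition = "d"))
  near <- point_events(0.4, 0, "2021-02-01")
  ctx <- assign_spatial(near[1, ], ds, method = "nearest_station")
  expect_identical(ctx$sources$source_id, "A")
  tie <- point_events(0.5, 0, "2021-02-01")
  ctx2 <- assign_spatial(tie[1, ], ds, method = "nearest_station")
  expect_identical(ctx2$sources$source_id, "A")  # equidistant: smaller id wins
})

test_that("proximity-polygon assignment equals brute-force planar nearest (seed 2718)", {
  spec <- synth_spec(seed = 2718, n_stations = 50, n_events = 60, n_days = 120)
  ds <- gen_stations_dataset(spec)
  ev <- gen_events(spec)
  lon0 <- mean(ds$stations$lon); lat0 <- mean(ds$stations$lat)
  proj <- function(lon, lat) {
    cbind((lon - lon0) * 111.32 * cos(lat0 * pi / 180), (lat - lat0) * 111.32)
  }
  sxy <- proj(ds$stations$lon, ds$stations$lat)
  for (i in seq_len(nrow(ev))) {
    got <- assign_spatial(ev[i, ], ds, method = "proximity_polygon")$sources$source_id
    pxy <- proj(ev$lon[i], ev$lat[i])
    d2 <- (sxy[, 1] - pxy[1])^2 + (sxy[, 2] - pxy[2])^2
    expect_identical(got, ds$stations$station_id[which.min(d2)])
  }
})

test_that("buffer contexts are monotone in the radius", {
  spec <- synth_spec(seed = 31, n_stations = 20, n_events = 10, n_days = 120)
  ds <- gen_stations_dataset(spec)
  ev <- gen_events(spec)
  for (i in 1:5) {
    n_prev <- -1L
    for (r in c(50, 150, 400, 1000)) {
      ctx <- assign_spatial(ev[i, ], ds, method = "buffer", params = list(buffer_km = r))
      expect_gte(nrow(ctx$sources), n_prev)
      n_prev <- nrow(ctx$sources)
      expect_true(all(ctx$sources$distance_km <= r))
    }
  }
})

test_that("area containment selects the most specific area and respects nesting", {
  areas <- nested_areas()
  ds <- env_stations("st",
    stations = data.frame(station_id = c("in", "out"), lon = c(5, 9.5), lat = c(5, 9.5)),
    observations = data.frame(station_id = "in", date = as.Date("2021-01-01"),
                              variable = "x", value = 1),
    variables = data.frame(name = "x", unit = "u", definition = "d"))
  ev <- point_events(c(5, 9, 20), c(5, 9, 20), rep("2021-02-01", 3))

  ctx_inner <- assign_spatial(ev[1, ], ds, areas, method = "area_contains")
  expect_identical(unique(ctx_inner$sources$area_id), "inner")
  expect_identical(ctx_inner$sources$source_id, "in")
  # nesting rule: the selected area's polygon lies inside the containing ancestor
  inner <- areas[[2]]; outer <- areas[[1]]
  for (v in seq_len(nrow(inner$geometry$polys[[1]][[1]]))) {
    expect_true(envlink:::point_in_geometry(inner$geometry$polys[[1]][[1]][v, ],
                                            outer$geometry))
  }

  ctx_outer <- assign_spatial(ev[2, ], ds, areas, method = "area_contains")
  expect_identical(unique(ctx_outer$sources$area_id), "outer")
  expect_setequal(ctx_outer$sources$source_id, c("in", "out"))

  # a point outside every area yields an empty context, not an error
  ctx_none <- assign_spatial(ev[3, ], ds, areas, method = "area_contains")
  expect_identical(nrow(ctx_none$sources), 0L)
})

test_that("area-located events use their own area geometry", {
  areas <- nested_areas()
  ds <- tiny_stations(n_stations = 2, n_days = 10)
  ds$stations$lon <- c(5, 50); ds$stations$lat <- c(5, 50)
  ev <- health_events("evA", as.Date("2021-03-08"), area_id = "inner")
  ctx <- assign_spatial(ev[1, ], ds, areas, method = "area_contains")
  expect_identical(ctx$sources$source_id, "st01")
})

test_that("grid datasets resolve point methods to the single containing half-open cell", {
  vars <- data.frame(name = "x", unit = "u", definition = "d", base_level = 1,
                     daily_amplitude = 0, noise_sd = 0, spatial_gradient = 0)
  spec <- synth_spec(seed = 1, extent = c(0, 0, 4, 4), grid_shape = c(4, 4),
                     n_days = 70, n_stations = 1, n_events = 1, variables = vars,
                     missing_rate = 0)
  g <- gen_grid(spec)
  ev <- point_events(c(0.5, 1.0, 3.999), c(0.5, 1.0, 3.999),
                     rep("2021-03-01", 3), c("a", "b", "c"))
  expect_identical(assign_spatial(ev[1, ], g, method = "nearest_station")$sources$source_id,
                   "cell_001_001")
  # boundary point maps to exactly one cell (the half-open convention)
  expect_identical(assign_spatial(ev[2, ], g, method = "proximity_polygon")$sources$source_id,
                   "cell_002_002")
  expect_identical(assign_spatial(ev[3, ], g, method = "buffer",
                                  params = list(buffer_km = 1))$sources$source_id,
                   "cell_004_004")
  outside <- point_events(5, 5, "2021-03-01")
  expect_identical(nrow(assign_spatial(outside[1, ], g,
                                       method = "nearest_station")$sources), 0L)
})

test_that("the query template binds dates exactly window_days apart", {
  spec <- linkage_spec("nearest_station", lag_days = 0, window_days = 7)
  template <- build_query_template(spec)
  expect_match(template, "\\{\\{window_start\\}\\}")
  expect_match(template, "\\{\\{window_end_exclusive\\}\\}")
  expect_match(template, "xsd:date")
  w <- temporal_window(as.Date("2021-03-10"), spec$lag_days, spec$window_days)
  bound <- bind_query_template(template, list(
    event_iri = "<https://ex.org/event/e1>",
    dataset_iri = "<https://ex.org/dataset/d>",
    link_predicate = "<https://ex.org/prop/linkedTo>",
    location_dimension = "<https://ex.org/prop/refLocation>",
    date_dimension = "<https://ex.org/prop/refDate>",
    measure_base = "https://ex.org/measure/",
    window_start = format(w$start_date, "%Y-%m-%d"),
    window_end_exclusive = format(w$end_date_exclusive, "%Y-%m-%d")
  ))
  expect_false(grepl("\\{\\{", bound))
  dates <- regmatches(bound, gregexpr("\\d{4}-\\d{2}-\\d{2}", bound))[[1]]
  expect_identical(as.integer(as.Date(dates[2]) - as.Date(dates[1])), 7L)
})

test_that("direct and graph backends return identical link multisets", {
  fx <- standard_fixture()
  spec <- linkage_spec("nearest_station", window_days = 7)
  for (method in c("nearest_station", "proximity_polygon")) {
    sp <- linkage_spec(method, window_days = 7)
    direct <- link_events(fx$ev, fx$ds, spec = sp)$links
    graph <- link_events(fx$ev, fx$ds, spec = sp, backend = "graph")$links
    norm <- function(d) { d <- d[do.call(order, d), ]; rownames(d) <- NULL; d }
    expect_equal(norm(direct), norm(graph))
  }
})

test_that("full-coverage linkage yields window_days rows per variable per event", {
  fx <- standard_fixture()
  spec <- linkage_spec("nearest_station", window_days = 7)
  res <- link_events(fx$ev, fx$ds, spec = spec)
  counts <- table(res$links$event_id, res$links$variable)
  expect_true(all(counts == 7L))
  expect_identical(nrow(res$skip_log), 0L)
})

test_that("events outside data coverage land in the skip log with a reason code", {
  fx <- standard_fixture()
  early <- point_events(0.1, 50.0, "2021-01-15", "early")  # before dataset start
  spec <- linkage_spec("nearest_station", window_days = 7)
  res <- link_events(early, fx$ds, spec = spec)
  expect_identical(nrow(res$links), 0L)
  expect_identical(res$skip_log$reason_code, "window_outside_coverage")
  expect_identical(res$skip_log$event_id, "early")
})

test_that("variable-name clashes across datasets error unless renamed", {
  ds1 <- tiny_stations(dataset_id = "d1")
  ds2 <- tiny_stations(dataset_id = "d2")
  ev <- point_events(0.1, 50, "2021-03-09")
  spec <- linkage_spec("nearest_station", window_days = 3)
  expect_error(link_events(ev, list(ds1, ds2), spec = spec),
               class = "envlink_ambiguity_error")
  res <- link_events(ev, list(ds1, ds2), spec = spec,
                     rename_map = list(d2 = c(temp = "temp_d2")))
  expect_setequal(unique(res$links$variable), c("temp", "temp_d2"))
})
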