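# The linkage engine: pre-event exposure windows, spatial-context
# assignment (area containment, nearest station, Voronoi proximity
# polygons, distance buffers), and event-observation link materialization
# with two interchangeable backends (direct tabular; query over the
# uplifted graph).

#' Pre-event exposure window
#'
#' Covers the half-open date range
#' `[event_date - lag_days - window_days, event_date - lag_days)`:
#' exactly `window_days` dates, all strictly before the event day, which is
#' always excluded.
#'
#' @param event_date event `Date`.
#' @param lag_days days between the window end and the event (>= 0).
#' @param window_days window length in days (>= 1).
#' @return list with `start_date` (inclusive), `end_date_exclusive`, and the
#'   covered `dates`.
#' @export
temporal_window <- function(event_date, lag_days = 0L, window_days = 7L) {
  if (lag_days < 0) config_error("lag_days must be >= 0")
  if (window_days < 1) config_error("window_days must be >= 1")
  event_date <- as.Date(event_date)
  end_excl <- event_date - lag_days
  start <- end_excl - window_days
  structure(list(
    start_date = start, end_date_exclusive = end_excl,
    dates = seq(start, end_excl - 1L, by = "day")
  ), class = "exposure_window")
}

# ---- spatial assignment ---------------------------------------------------

dataset_sources <- function(ds) {
  if (inherits(ds, "env_stations")) {
    data.frame(source_kind = "station", source_id = ds$stations$station_id,
               lon = ds$stations$lon, lat = ds$stations$lat, stringsAsFactors = FALSE)
  } else {
    idx <- expand.grid(ilat = seq_along(ds$lat_axis), ilon = seq_along(ds$lon_axis))
    data.frame(source_kind = "grid_cell", source_id = grid_cell_id(idx$ilat, idx$ilon),
               lon = ds$lon_axis[idx$ilon], lat = ds$lat_axis[idx$ilat],
               stringsAsFactors = FALSE)
  }
}

grid_cell_at_point <- function(ds, lon, lat) {
  # half-open cells [lon_i, lon_i + dlon) x [lat_j, lat_j + dlat)
  dlon <- if (length(ds$lon_axis) > 1) diff(ds$lon_axis[1:2]) else 1
  dlat <- if (length(ds$lat_axis) > 1) diff(ds$lat_axis[1:2]) else 1
  ilon <- floor((lon - ds$lon_axis[1]) / dlon) + 1
  ilat <- floor((lat - ds$lat_axis[1]) / dlat) + 1
  if (ilon < 1 || ilon > length(ds$lon_axis) || ilat < 1 || ilat > length(ds$lat_axis)) {
    return(NULL)
  }
  c(ilat = as.integer(ilat), ilon = as.integer(ilon))
}

empty_sources <- function() {
  data.frame(source_kind = character(0), source_id = character(0),
             distance_km = numeric(0), stringsAsFactors = FALSE)
}

most_specific_area <- function(pt, areas) {
  containing <- Filter(function(a) point_in_geometry(pt, a$geometry), areas)
  if (length(containing) == 0) return(NULL)
  areas_sz <- vapply(containing, function(a) geometry_area(a$geometry), numeric(1))
  ids <- vapply(containing, function(a) a$area_id, character(1))
  ord <- order(areas_sz, ids)
  containing[[ord[1]]]
}

#' Assign the spatial context of an event for one dataset
#'
#' Methods: `area_contains` (the most specific containing area, mapped to
#' the stations inside it / grid cells whose origins fall inside it),
#' `nearest_station` (great-circle nearest, ties broken by lexicographically
#' smallest id), `proximity_polygon` (the station whose planar Voronoi cell
#' contains the event point, in an equirectangular projection centred on the
#' station centroid), and `buffer` (all stations within `buffer_km`
#' great-circle km).  For gridded datasets the point methods select the
#' single half-open cell containing the point.  An event outside every area
#' yields an empty context, never an error.
#'
#' @param event one-row `health_events` slice.
#' @param ds dataset.
#' @param areas list of `admin_area` (needed for `area_contains`).
#' @param method spatial method name.
#' @param params list; `buffer_km` for the buffer method.
#' @return list (`event_id`, `dataset_id`, `sources` data.frame with
#'   source_kind, source_id, distance_km).
#' @export
assign_spatial <- function(event, ds, areas = NULL,
                           method = c("nearest_station", "area_contains",
                                      "proximity_polygon", "buffer"),
                           params = list()) {
  method <- match.arg(method)
  is_point <- !is.na(event$lon) && !is.na(event$lat)
  ctx <- function(sources) list(event_id = event$event_id, dataset_id = ds$dataset_id,
                                sources = sources)

  if (method == "area_contains") {
    if (is_point) {
      if (is.null(areas) || length(areas) == 0) config_error("area_contains requires areas")
      area <- most_specific_area(c(event$lon, event$lat), areas)
    } else {
      ids <- vapply(areas %||% list(), function(a) a$area_id, character(1))
      hit <- match(event$area_id, ids)
      if (is.na(hit)) validation_error(sprintf("event %s references unknown area %s",
                                               event$event_id, dQuote(event$area_id)))
      area <- areas[[hit]]
    }
    if (is.null(area)) return(ctx(empty_sources()))
    src <- dataset_sources(ds)
    inside <- vapply(seq_len(nrow(src)), function(i) {
      point_in_geometry(c(src$lon[i], src$lat[i]), area$geometry)
    }, logical(1))
    src <- src[inside, , drop = FALSE]
    if (nrow(src) == 0) return(ctx(empty_sources()))
    src <- src[order(src$source_id), , drop = FALSE]
    out <- data.frame(source_kind = src$source_kind, source_id = src$source_id,
                      distance_km = NA_real_, stringsAsFactors = FALSE)
    out$area_id <- area$area_id
    return(ctx(out))
  }

  if (!is_point) {
    validation_error(sprintf("event %s: method %s requires a point location",
                             event$event_id, method))
  }

  if (inherits(ds, "env_grid")) {
    cell <- grid_cell_at_point(ds, event$lon, event$lat)
    if (is.null(cell)) return(ctx(empty_sources()))
    return(ctx(data.frame(source_kind = "grid_cell",
                          source_id = grid_cell_id(cell["ilat"], cell["ilon"]),
                          distance_km = NA_real_, stringsAsFactors = FALSE)))
  }

  st <- ds$stations
  if (nrow(st) == 0) config_error("dataset has zero stations")

  if (method == "nearest_station") {
    d <- dist_km(st$lon, st$lat, event$lon, event$lat)
    cand <- which(d <= min(d) + 1e-9)
    pick <- cand[order(st$station_id[cand])][1]
    return(ctx(data.frame(source_kind = "station", source_id = st$station_id[pick],
                          distance_km = d[pick], stringsAsFactors = FALSE)))
  }
  if (method == "proximity_polygon") {
    lon0 <- mean(st$lon); lat0 <- mean(st$lat)
    xy <- project_equirect(st$lon, st$lat, lon0, lat0)
    pt <- project_equirect(event$lon, event$lat, lon0, lat0)[1, ]
    cells <- voronoi_cells(xy)
    hit <- vapply(cells, function(cell) {
      nrow(cell) >= 3 && point_in_geometry(pt, new_geometry(list(list(ring_close(cell)))))
    }, logical(1))
    if (!any(hit)) return(ctx(empty_sources()))
    pick <- which(hit)[order(st$station_id[hit])][1]
    return(ctx(data.frame(source_kind = "station", source_id = st$station_id[pick],
                          distance_km = dist_km(st$lon[pick], st$lat[pick], event$lon, event$lat),
                          stringsAsFactors = FALSE)))
  }
  # buffer
  buffer_km <- params$buffer_km %||% config_error("buffer method requires params$buffer_km")
  d <- dist_km(st$lon, st$lat, event$lon, event$lat)
  keep <- which(d <= buffer_km)
  if (length(keep) == 0) return(ctx(empty_sources()))
  keep <- keep[order(st$station_id[keep])]
  ctx(data.frame(source_kind = "station", source_id = st$station_id[keep],
                 distance_km = d[keep], stringsAsFactors = FALSE))
}

# ---- query template -------------------------------------------------------

#' SPARQL 1.1 template for the graph-query backend
#'
#' Spatial relations are consumed as pre-materialized link triples
#' (`envlink:linkedTo`), temporal filtering as half-open `xsd:date`
#' comparisons.  Placeholders (`{{event_iri}}`, `{{dataset_iri}}`,
#' `{{measure_base}}`, `{{window_start}}`, `{{window_end_exclusive}}`) are
#' bound per event with [bind_query_template()].
#'
#' @param spec a [linkage_spec()].
#' @return the query template text.
#' @export
build_query_template <- function(spec) {
  if (!inherits(spec, "linkage_spec")) config_error("spec must be a linkage_spec")
  paste0(
    "PREFIX qb: <", KG_NAMESPACES[["qb"]], ">\n",
    "PREFIX xsd: <", KG_NAMESPACES[["xsd"]], ">\n",
    "# spatial method: ", spec$spatial_method,
    " (links pre-materialized as envlink:linkedTo triples)\n",
    "SELECT ?source ?date ?variable ?value WHERE {\n",
    "  {{event_iri}} {{link_predicate}} ?source .\n",
    "  ?obs qb:dataSet {{dataset_iri}} ;\n",
    "       {{location_dimension}} ?source ;\n",
    "       {{date_dimension}} ?date ;\n",
    "       ?variable ?value .\n",
    "  FILTER(STRSTARTS(STR(?variable), \"{{measure_base}}\"))\n",
    "  FILTER(?date >= \"{{window_start}}\"^^xsd:date &&\n",
    "         ?date <  \"{{window_end_exclusive}}\"^^xsd:date)\n",
    "}\n"
  )
}

#' Bind named placeholders in a query template
#' @param template template text from [build_query_template()].
#' @param bindings named list/character of placeholder values.
#' @export
bind_query_template <- function(template, bindings) {
  for (nm in names(bindings)) {
    template <- gsub(paste0("{{", nm, "}}"), as.character(bindings[[nm]]), template, fixed = TRUE)
  }
  template
}

# executes the bound template's semantics over the triple table
run_linkage_query <- function(g, base, event_iri, dataset_id, window) {
  p_date <- iri(kg_prop_iri(base, "refDate"))
  p_loc <- iri(kg_prop_iri(base, "refLocation"))
  p_link <- iri(kg_prop_iri(base, "linkedTo"))
  measure_prefix <- paste0("<", mint_iri(base, "measure"), "/")
  ds_iri <- iri(kg_dataset_iri(base, dataset_id))

  linked <- g$object[g$subject == event_iri & g$predicate == p_link]
  obs_nodes <- g$subject[g$predicate == ns("qb", "dataSet") & g$object == ds_iri]
  sub <- g[g$subject %in% obs_nodes, , drop = FALSE]
  locs <- sub[sub$predicate == p_loc & sub$object %in% linked, c("subject", "object")]
  if (nrow(locs) == 0) return(NULL)
  dates <- sub[sub$predicate == p_date, c("subject", "object")]
  meas <- sub[startsWith(sub$predicate, measure_prefix), ]
  df <- merge(merge(locs, dates, by = "subject"), meas, by = "subject")
  if (nrow(df) == 0) return(NULL)
  out <- data.frame(
    source_id = vapply(df$object.x, iri_local, character(1)),
    date = as.Date(vapply(df$object.y, lit_value, character(1))),
    variable = vapply(df$predicate, iri_local, character(1)),
    value = as.numeric(vapply(df$object, lit_value, character(1))),
    stringsAsFactors = FALSE
  )
  out[out$date >= window$start_date & out$date < window$end_date_exclusive, , drop = FALSE]
}

# ---- link materialization -------------------------------------------------

normalize_datasets <- function(datasets) {
  if (inherits(datasets, "env_dataset")) datasets <- list(datasets)
  names(datasets) <- vapply(datasets, function(d) d$dataset_id, character(1))
  datasets
}

check_variable_clash <- function(datasets, rename_map = NULL) {
  tabs <- lapply(datasets, function(d) {
    v <- d$variables$name
    rn <- rename_map[[d$dataset_id]]
    if (!is.null(rn)) v <- ifelse(v %in% names(rn), unname(rn[v]), v)
    v
  })
  all_vars <- unlist(tabs, use.names = FALSE)
  dup <- unique(all_vars[duplicated(all_vars)])
  if (length(dup) > 0) {
    ambiguity_error(sprintf(
      "variable %s appears in more than one dataset; supply a rename_map to disambiguate",
      dQuote(dup[1])))
  }
  invisible(TRUE)
}

apply_rename <- function(df, dataset_id, rename_map) {
  rn <- rename_map[[dataset_id]]
  if (!is.null(rn)) {
    hit <- df$variable %in% names(rn)
    df$variable[hit] <- unname(rn[df$variable[hit]])
  }
  df
}

raw_rows_direct <- function(ds, sources, window) {
  if (inherits(ds, "env_stations")) {
    obs <- ds$observations
    keep <- obs$station_id %in% sources$source_id &
      obs$date >= window$start_date & obs$date < window$end_date_exclusive &
      !is.na(obs$value)
    df <- obs[keep, , drop = FALSE]
    data.frame(source_id = df$station_id, date = df$date, variable = df$variable,
               value = df$value, stringsAsFactors = FALSE)
  } else {
    tsel <- which(ds$time_axis >= window$start_date & ds$time_axis < window$end_date_exclusive)
    if (length(tsel) == 0 || nrow(sources) == 0) {
      return(data.frame(source_id = character(0), date = as.Date(character(0)),
                        variable = character(0), value = numeric(0)))
    }
    m <- regmatches(sources$source_id, regexec("^cell_(\\d+)_(\\d+)$", sources$source_id))
    ilat <- vapply(m, function(x) as.integer(x[2]), integer(1))
    ilon <- vapply(m, function(x) as.integer(x[3]), integer(1))
    grid <- expand.grid(si = seq_len(nrow(sources)), t = tsel, v = seq_len(nrow(ds$variables)))
    vals <- ds$values[cbind(grid$v, grid$t, ilat[grid$si], ilon[grid$si])]
    df <- data.frame(source_id = sources$source_id[grid$si], date = ds$time_axis[grid$t],
                     variable = ds$variables$name[grid$v], value = vals,
                     stringsAsFactors = FALSE)
    df[!is.na(df$value), , drop = FALSE]
  }
}

dataset_date_range <- function(ds) {
  if (inherits(ds, "env_stations")) range(ds$observations$date) else range(ds$time_axis)
}

#' Link health events to environmental observations
#'
#' For every event x dataset pair, selects the spatial context with
#' [assign_spatial()] and the pre-event window with [temporal_window()], and
#' emits the raw observations whose source lies in the context and whose
#' date falls in the window.  Events with no context or no observations are
#' reported in the skip log with a reason code
#' (`no_spatial_context`, `window_outside_coverage`, `no_observations`),
#' never silently dropped.
#'
#' @param events `health_events` table.
#' @param datasets one dataset or a list of datasets.
#' @param areas list of `admin_area` (required for `area_contains`).
#' @param spec a [linkage_spec()].
#' @param backend `"direct"` (tabular) or `"graph"` (query over the uplifted
#'   triple graph with pre-materialized spatial links).
#' @param base base IRI for the graph backend.
#' @param rename_map optional per-dataset variable rename list, e.g.
#'   `list(ds1 = c(temp = "temp_ds1"))`, used to disambiguate variable names
#'   that occur in several datasets.
#' @return list with `links` (event_id, dataset_id, source_id, date,
#'   variable, value), `contexts`, `windows`, and `skip_log` (event_id,
#'   dataset_id, reason_code).
#' @export
link_events <- function(events, datasets, areas = NULL, spec = linkage_spec(),
                        backend = c("direct", "graph"),
                        base = "https://example.org/envlink/", rename_map = NULL) {
  backend <- match.arg(backend)
  datasets <- normalize_datasets(datasets)
  check_variable_clash(datasets, rename_map)

  graph <- NULL
  if (backend == "graph") {
    graph <- do.call(tg_union, lapply(datasets, uplift_dataset, areas = areas, base = base))
  }

  links <- list(); skip <- list(); contexts <- list(); windows <- list()
  p_link <- iri(kg_prop_iri(base, "linkedTo"))

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    window <- temporal_window(ev$event_date, spec$lag_days, spec$window_days)
    windows[[ev$event_id]] <- window
    for (ds in datasets) {
      ctx <- assign_spatial(ev, ds, areas, spec$spatial_method,
                            params = list(buffer_km = spec$buffer_km))
      contexts[[paste(ev$event_id, ds$dataset_id, sep = "\r")]] <- ctx
      if (nrow(ctx$sources) == 0) {
        skip[[length(skip) + 1L]] <- data.frame(
          event_id = ev$event_id, dataset_id = ds$dataset_id,
          reason_code = "no_spatial_context", stringsAsFactors = FALSE)
        next
      }
      cov <- dataset_date_range(ds)
      if (window$end_date_exclusive <= cov[1] || window$start_date > cov[2]) {
        skip[[length(skip) + 1L]] <- data.frame(
          event_id = ev$event_id, dataset_id = ds$dataset_id,
          reason_code = "window_outside_coverage", stringsAsFactors = FALSE)
        next
      }
      if (backend == "direct") {
        rows <- raw_rows_direct(ds, ctx$sources, window)
      } else {
        ev_iri <- iri(kg_event_iri(base, ev$event_id))
        link_triples <- tg(ev_iri, p_link,
                           vapply(ctx$sources$source_id, function(s) {
                             iri(kg_source_iri(base, ds$dataset_id, s))
                           }, character(1)))
        g_ev <- tg_union(graph, link_triples)
        rows <- run_linkage_query(g_ev, base, ev_iri, ds$dataset_id, window)
        if (is.null(rows)) rows <- data.frame(source_id = character(0),
                                              date = as.Date(character(0)),
                                              variable = character(0), value = numeric(0))
      }
      rows <- apply_rename(rows, ds$dataset_id, rename_map)
      if (nrow(rows) == 0) {
        skip[[length(skip) + 1L]] <- data.frame(
          event_id = ev$event_id, dataset_id = ds$dataset_id,
          reason_code = "no_observations", stringsAsFactors = FALSE)
        next
      }
      rows <- rows[order(rows$source_id, rows$date, rows$variable), , drop = FALSE]
      links[[length(links) + 1L]] <- data.frame(
        event_id = ev$event_id, dataset_id = ds$dataset_id, rows,
        stringsAsFactors = FALSE)
    }
  }
  empty_links <- data.frame(event_id = character(0), dataset_id = character(0),
                            source_id = character(0), date = as.Date(character(0)),
                            variable = character(0), value = numeric(0))
  list(
    links = if (length(links) > 0) do.call(rbind, c(links, list(empty_links))) else empty_links,
    contexts = contexts,
    windows = windows,
    skip_log = if (length(skip) > 0) do.call(rbind, skip) else
      data.frame(event_id = character(0), dataset_id = character(0),
                 reason_code = character(0), stringsAsFactors = FALSE)
  )
}

#' Write the skip log as CSV
#' @keywords internal
write_skip_log <- function(skip_log, path) {
  utils::write.csv(skip_log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
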