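# Aggregation of linked observations into exposure records, and export of
# the linked (meta)data as the three-artifact bundle: analysis table (CSV),
# linked-data graph (Turtle), self-contained HTML report — plus the skip
# log.  Aggregation order is fixed: spatial first (per-day mean over
# sources), then temporal over the daily series; sd uses the n-1
# denominator; count counts distinct observed dates.

EXPOSURE_CSV_COLUMNS <- c("event_id", "dataset_id", "variable", "window_start",
                          "window_end", "agg", "value", "coverage", "n_sources")

agg_fun <- function(name) {
  switch(name,
    mean = mean, min = min, max = max, sum = sum,
    sd = function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
    count = length,
    config_error(sprintf("unknown aggregation function %s", dQuote(name)))
  )
}

#' Aggregate linked observations into exposure records
#'
#' Multi-source days are averaged first (spatial step), then the requested
#' temporal aggregation runs over the daily series.  `coverage` is the
#' fraction of window dates with at least one observation; records below
#' `spec$min_coverage` are flagged (and excluded from the CSV only when
#' `spec$exclude_flagged` is set — they always stay in the RDF graph with a
#' quality annotation).
#'
#' @param linkage result of [link_events()].
#' @param spec the [linkage_spec()] used for linking.
#' @return data.frame of exposure records (one per event x dataset x
#'   variable x agg function at window level; one per event x dataset x
#'   variable x observed window date at daily level), with columns
#'   `r paste(EXPOSURE_CSV_COLUMNS, collapse = ", ")`, `source_ids`, `flagged`.
#' @export
aggregate_exposures <- function(linkage, spec) {
  links <- linkage$links
  recs <- list()
  emit <- function(...) recs[[length(recs) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  groups <- unique(links[, c("event_id", "dataset_id", "variable")])
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    rows <- links[links$event_id == g$event_id & links$dataset_id == g$dataset_id &
                    links$variable == g$variable, , drop = FALSE]
    window <- linkage$windows[[g$event_id]]
    source_ids <- sort(unique(rows$source_id))
    if (nrow(rows) == 0) {
      emit(event_id = g$event_id, dataset_id = g$dataset_id, variable = g$variable,
           window_start = window$start_date, window_end = window$end_date_exclusive,
           agg = spec$agg_functions[1], value = NA_real_, coverage = 0,
           n_sources = 0L, source_ids = "", flagged = TRUE)
      next
    }
    # spatial step: one value per day
    daily <- stats::aggregate(value ~ date, data = rows, FUN = mean)
    daily <- daily[order(daily$date), , drop = FALSE]
    coverage <- nrow(daily) / spec$window_days
    flagged <- coverage < spec$min_coverage
    if (spec$agg_level == "daily") {
      for (di in seq_len(nrow(daily))) {
        emit(event_id = g$event_id, dataset_id = g$dataset_id, variable = g$variable,
             window_start = daily$date[di], window_end = daily$date[di] + 1L,
             agg = "daily_mean", value = daily$value[di], coverage = 1,
             n_sources = length(unique(rows$source_id[rows$date == daily$date[di]])),
             source_ids = paste(source_ids, collapse = ";"), flagged = flagged)
      }
    } else {
      for (fn in spec$agg_functions) {
        emit(event_id = g$event_id, dataset_id = g$dataset_id, variable = g$variable,
             window_start = window$start_date, window_end = window$end_date_exclusive,
             agg = fn, value = as.numeric(agg_fun(fn)(daily$value)), coverage = coverage,
             n_sources = length(source_ids),
             source_ids = paste(source_ids, collapse = ";"), flagged = flagged)
      }
    }
  }
  out <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(event_id = character(0), dataset_id = character(0), variable = character(0),
               window_start = as.Date(character(0)), window_end = as.Date(character(0)),
               agg = character(0), value = numeric(0), coverage = numeric(0),
               n_sources = integer(0), source_ids = character(0), flagged = logical(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$event_id, out$dataset_id, out$variable, out$agg, out$window_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- RDF export of exposure records ---------------------------------------

#' Uplift exposure records as derived QB observations
#' @param records exposure-record data.frame from [aggregate_exposures()].
#' @param derived_id dataset id for the derived (linked) dataset.
#' @param base base IRI.
#' @keywords internal
uplift_exposures <- function(records, derived_id, base = "https://example.org/envlink/") {
  ds_iri <- iri(kg_dataset_iri(base, derived_id))
  triples <- list(tg(ds_iri, ns("rdf", "type"), ns("qb", "DataSet")),
                  tg(ds_iri, ns("dct", "identifier"), lit(derived_id)))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    o <- iri(mint_iri(base, c("exposure", derived_id, r$event_id, r$dataset_id, r$variable,
                              r$agg, format(r$window_start, "%Y-%m-%d"))))
    triples <- c(triples, list(
      tg(o, ns("rdf", "type"), ns("qb", "Observation")),
      tg(o, ns("qb", "dataSet"), ds_iri),
      tg(o, iri(kg_prop_iri(base, "event")), iri(kg_event_iri(base, r$event_id))),
      tg(o, iri(kg_prop_iri(base, "sourceDataset")), iri(kg_dataset_iri(base, r$dataset_id))),
      tg(o, iri(kg_prop_iri(base, "variable")), lit(r$variable)),
      tg(o, iri(kg_prop_iri(base, "windowStart")), date_lit(r$window_start)),
      tg(o, iri(kg_prop_iri(base, "windowEnd")), date_lit(r$window_end)),
      tg(o, iri(kg_prop_iri(base, "aggFunction")), lit(r$agg)),
      tg(o, iri(kg_prop_iri(base, "coverage")), num_lit(r$coverage)),
      tg(o, iri(kg_prop_iri(base, "nSources")), xsd_lit(as.character(r$n_sources), "integer"))
    ))
    if (!is.na(r$value)) {
      triples <- c(triples, list(tg(o, iri(kg_measure_iri(base, "exposureValue")), num_lit(r$value))))
    }
    if (isTRUE(r$flagged)) {
      triples <- c(triples, list(tg(o, iri(kg_prop_iri(base, "qualityFlag")), lit("low_coverage"))))
    }
  }
  tg_union(do.call(rbind, triples))
}

# ---- export bundle --------------------------------------------------------

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

records_to_csv_table <- function(records, spec) {
  keep <- records
  if (isTRUE(spec$exclude_flagged)) keep <- keep[!keep$flagged, , drop = FALSE]
  data.frame(
    event_id = keep$event_id, dataset_id = keep$dataset_id, variable = keep$variable,
    window_start = format(keep$window_start, "%Y-%m-%d"),
    window_end = format(keep$window_end, "%Y-%m-%d"),
    agg = keep$agg, value = fmt_num(keep$value), coverage = fmt_num(keep$coverage),
    n_sources = keep$n_sources, stringsAsFactors = FALSE
  )
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, caption) {
  if (nrow(df) == 0) {
    return(sprintf("<h2>%s</h2>\n<p class=\"empty\">none</p>", html_escape(caption)))
  }
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>", collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, ], function(x) html_escape(as.character(x)), character(1))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, character(1))
  sprintf("<h2>%s</h2>\n<table>\n%s\n%s\n</table>", html_escape(caption), head_row,
          paste(body, collapse = "\n"))
}

render_report_html <- function(records, skip_log, linkage, run_md, spec) {
  windows <- do.call(rbind, lapply(names(linkage$windows), function(eid) {
    w <- linkage$windows[[eid]]
    data.frame(event_id = eid, window_start = format(w$start_date, "%Y-%m-%d"),
               window_end_exclusive = format(w$end_date_exclusive, "%Y-%m-%d"),
               days = length(w$dates), stringsAsFactors = FALSE)
  }))
  if (is.null(windows)) windows <- data.frame(event_id = character(0))
  cov_sum <- if (nrow(records) > 0) {
    agg <- stats::aggregate(cbind(coverage, flagged) ~ dataset_id + variable, data = records,
                            FUN = function(x) mean(as.numeric(x)))
    data.frame(dataset_id = agg$dataset_id, variable = agg$variable,
               mean_coverage = sprintf("%.3f", agg$coverage),
               flagged_fraction = sprintf("%.3f", agg$flagged), stringsAsFactors = FALSE)
  } else data.frame(dataset_id = character(0))
  summary_df <- data.frame(
    quantity = c("events linked", "events/datasets skipped", "exposure records",
                 "spatial method", "lag (days)", "window (days)", "aggregation level"),
    value = c(length(unique(records$event_id)), nrow(skip_log), nrow(records),
              spec$spatial_method, spec$lag_days, spec$window_days, spec$agg_level),
    stringsAsFactors = FALSE
  )
  paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>", html_escape(run_md$title), "</title>\n",
    "<style>body{font-family:sans-serif;margin:2em;max-width:65em}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #999;padding:0.25em 0.6em;text-align:left}",
    "th{background:#eee}h1{border-bottom:2px solid #333}.empty{color:#666}</style>\n",
    "</head>\n<body>\n",
    "<h1>", html_escape(run_md$title), "</h1>\n",
    "<p>Linked environmental exposures per health event: each event is linked to the ",
    "observations of its spatial context over a pre-event exposure window, and the linked ",
    "values are aggregated into the exposure records below.</p>\n",
    html_table(summary_df, "Linkage summary"), "\n",
    html_table(windows, "Per-event exposure windows"), "\n",
    html_table(cov_sum, "Coverage by dataset and variable"), "\n",
    html_table(utils::head(records_to_csv_table(records, spec), 200),
               "Exposure records (first 200)"), "\n",
    html_table(skip_log, "Skip log"), "\n",
    "</body>\n</html>\n"
  )
}

#' Export the linked-data bundle
#'
#' Writes exactly three artifacts into `out_dir` — `linked_data.csv` (one
#' row per exposure record, fixed column order), `linked_data.ttl` (exposure
#' records as derived QB observations plus the full metadata graph including
#' the linkage activity), `report.html` (self-contained linkage report) —
#' plus `skip_log.csv`.  Output is deterministic for fixed inputs.
#'
#' @param records exposure records from [aggregate_exposures()].
#' @param graphs list of additional `triple_graph`s to include (dataset
#'   uplift and metadata graphs).
#' @param run_md [metadata_bundle()] describing the linkage run; its
#'   activity must name every input dataset in `used`.
#' @param out_dir output directory (must exist and be writable).
#' @param linkage [link_events()] result (for the report and skip log).
#' @param spec the [linkage_spec()].
#' @param base base IRI.
#' @return invisible character vector of written paths.
#' @export
export_bundle <- function(records, graphs, run_md, out_dir, linkage, spec,
                          base = "https://example.org/envlink/") {
  if (!dir.exists(out_dir)) format_error(sprintf("output directory does not exist: %s", out_dir))
  if (file.access(out_dir, 2) != 0) format_error(sprintf("output directory not writable: %s", out_dir))
  skip_log <- linkage$skip_log
  if (nrow(records) == 0 && nrow(skip_log) == 0) {
    validation_error("nothing to export: no exposure records and empty skip log")
  }
  derived_id <- run_md$activity$generated %||% "linked_exposures"

  csv_path <- file.path(out_dir, "linked_data.csv")
  ttl_path <- file.path(out_dir, "linked_data.ttl")
  html_path <- file.path(out_dir, "report.html")
  skip_path <- file.path(out_dir, "skip_log.csv")

  utils::write.csv(records_to_csv_table(records, spec), csv_path, row.names = FALSE, quote = FALSE)

  full_graph <- tg_union(
    uplift_exposures(records, derived_id, base),
    build_metadata_graph(run_md, base),
    do.call(tg_union, c(unname(graphs), list(triple_graph())))
  )
  serialize_turtle(full_graph, ttl_path)

  html <- render_report_html(records, skip_log, linkage, run_md, spec)
  con <- file(html_path, open = "wb")
  writeLines(html, con, sep = "", useBytes = TRUE)
  close(con)

  write_skip_log(skip_log, skip_path)
  invisible(c(csv = csv_path, ttl = ttl_path, html = html_path, skip = skip_path))
}
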