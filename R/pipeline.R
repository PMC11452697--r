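# Pipeline wiring: one run configuration drives read -> uplift -> link ->
# aggregate -> export, mirroring the four interface steps (deposit
# environmental data, upload health data, define linkage options, export
# linked datasets).  The command-line entry point (inst/cli/envlink) is a
# thin wrapper over run_pipeline()/run_synth(); there is no CLI-only
# behaviour.

RUN_CONFIG_KEYS <- c("datasets", "areas", "events", "linkage", "base_iri",
                     "output_dir", "seed", "metadata", "backend",
                     "rename_map", "include_observation_graph")

#' Validate and normalize a run configuration
#'
#' @param config a named list or the path of a YAML file with keys among
#'   `r paste(RUN_CONFIG_KEYS, collapse = ", ")`.  Required: `datasets`
#'   (list of `path`/`format`/`dataset_id`/`schema`), `events` (CSV path),
#'   `output_dir`.  Optional: `areas` (`path`/`format`), `linkage`
#'   (fields of [linkage_spec()]), `base_iri`, `seed`, `metadata`
#'   (`title`, `licence`, `version`, `distribution_url`, `agents`,
#'   `started`, `ended`), `backend` (`direct`/`graph`), `rename_map`,
#'   `include_observation_graph`.
#' @return validated config list with a `linkage_spec` attached.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    config_error(sprintf("unknown config key %s; valid keys: %s",
                         dQuote(unknown[1]), paste(RUN_CONFIG_KEYS, collapse = ", ")))
  }
  for (key in c("datasets", "events", "output_dir")) {
    if (is.null(config[[key]])) config_error(sprintf("config lacks required key %s", dQuote(key)))
  }
  if (!file.exists(config$events)) {
    config_error(sprintf("events: file not found: %s", config$events))
  }
  for (d in config$datasets) {
    if (is.null(d$path)) config_error("each datasets entry needs a path")
    if (!file.exists(d$path)) config_error(sprintf("datasets: file not found: %s", d$path))
  }
  if (!is.null(config$areas) && !file.exists(config$areas$path %||% "")) {
    config_error(sprintf("areas: file not found: %s", config$areas$path %||% "<missing path>"))
  }
  lk <- config$linkage %||% list()
  config$spec <- do.call(linkage_spec, lk)
  config$base_iri <- config$base_iri %||% "https://example.org/envlink/"
  config$backend <- config$backend %||% "direct"
  if (!config$backend %in% c("direct", "graph")) {
    config_error("backend must be 'direct' or 'graph'")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[envlink] ", fmt), ...))
}

#' Run the full linkage pipeline from a configuration
#'
#' Executes read -> uplift -> link -> aggregate -> export and writes the
#' export bundle (CSV, Turtle, HTML report, skip log) plus a machine-readable
#' `run_summary.json` into the output directory.  Skipped events are data,
#' not failures: the run succeeds whenever the configuration is valid and
#' every stage completes.  On a stage failure, partial outputs are removed.
#'
#' @param config config list or YAML path (see [load_run_config()]).
#' @param output_dir overrides the configured output directory.
#' @param seed overrides the configured seed.
#' @param dry_run validate the config and return the query template without
#'   linking or writing anything.
#' @param verbose log each stage with counts to stderr.
#' @return (invisibly) a list with `files`, `summary`, and the linkage
#'   result; for `dry_run`, the query template text.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         dry_run = FALSE, verbose = FALSE) {
  t0 <- Sys.time()
  config <- load_run_config(config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (!is.null(seed)) config$seed <- as.integer(seed)

  if (dry_run) {
    template <- build_query_template(config$spec)
    return(invisible(list(dry_run = TRUE, query_template = template, config = config)))
  }

  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_files <- file.path(out_dir, c("linked_data.csv", "linked_data.ttl",
                                    "report.html", "skip_log.csv", "run_summary.json"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out_files[file.exists(out_files)])
      stop_envlink("envlink_stage_error",
                   sprintf("stage %s failed: %s", dQuote(name), conditionMessage(e)))
    })
  }

  datasets <- stage("read", {
    ds <- lapply(config$datasets, function(d) {
      read_env_dataset(d$path, format = d$format, schema = d$schema,
                       dataset_id = d$dataset_id)
    })
    normalize_datasets(ds)
  })
  pipeline_log(verbose, "read: %d dataset(s): %s", length(datasets),
               paste(names(datasets), collapse = ", "))
  areas <- if (!is.null(config$areas)) {
    stage("read", read_areas(config$areas$path, format = config$areas$format))
  } else NULL
  events <- stage("read", read_events(config$events))
  pipeline_log(verbose, "read: %d event(s), %d area(s)", nrow(events), length(areas %||% list()))

  graphs <- list()
  if (isTRUE(config$include_observation_graph)) {
    graphs <- stage("uplift", lapply(datasets, uplift_dataset, areas = areas,
                                     base = config$base_iri))
    pipeline_log(verbose, "uplift: %d triples",
                 sum(vapply(graphs, tg_size, integer(1))))
  }

  linkage <- stage("link", {
    set.seed(config$seed)
    link_events(events, datasets, areas, config$spec, backend = config$backend,
                base = config$base_iri, rename_map = config$rename_map)
  })
  pipeline_log(verbose, "link: %d linked rows, %d skip-log entries",
               nrow(linkage$links), nrow(linkage$skip_log))

  records <- stage("aggregate", aggregate_exposures(linkage, config$spec))
  pipeline_log(verbose, "aggregate: %d exposure record(s)", nrow(records))

  md <- config$metadata %||% list()
  agents <- if (!is.null(md$agents)) {
    do.call(rbind, lapply(md$agents, function(a) {
      data.frame(name = a$name, role = a$role, stringsAsFactors = FALSE)
    }))
  } else data.frame(name = "envlink", role = "software", stringsAsFactors = FALSE)
  temporal <- if (nrow(linkage$links) > 0) range(linkage$links$date) else NULL
  run_md <- metadata_bundle(
    title = md$title %||% "Linked event-environment exposures",
    licence = md$licence %||% NA_character_,
    version = md$version %||% "1.0.0",
    temporal_extent = temporal,
    spatial_extent = md$spatial_extent %||% NULL,
    distribution_url = md$distribution_url %||% NA_character_,
    agents = agents,
    activity = list(used = names(datasets), generated = "linked_exposures",
                    started = md$started %||% NULL, ended = md$ended %||% NULL)
  )

  files <- stage("export", export_bundle(records, graphs, run_md, out_dir,
                                         linkage, config$spec, base = config$base_iri))
  summary <- list(
    datasets = length(datasets),
    events = nrow(events),
    linked_rows = nrow(linkage$links),
    exposure_records = nrow(records),
    skipped = nrow(linkage$skip_log),
    backend = config$backend,
    seed = config$seed,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"), auto_unbox = TRUE)
  pipeline_log(verbose, "done in %.2fs", summary$elapsed_s)
  invisible(list(files = files, summary = summary, linkage = linkage,
                 records = records, config = config))
}

#' Generate and write synthetic fixtures from a spec config
#'
#' @param config named list or YAML path with [synth_spec()] field names
#'   (unknown keys rejected).
#' @param out_dir output directory.
#' @return named vector of written paths.
#' @export
run_synth <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  allowed <- setdiff(names(formals(synth_spec)), "")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    config_error(sprintf("unknown synth key %s; valid keys: %s",
                         dQuote(unknown[1]), paste(allowed, collapse = ", ")))
  }
  if (!is.null(config$variables)) {
    config$variables <- as.data.frame(do.call(rbind, lapply(config$variables, as.data.frame)))
  }
  spec <- do.call(synth_spec, config)
  write_synth_fixtures(spec, out_dir)
}
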