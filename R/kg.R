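# Observation knowledge graph: RDF Data Cube uplift of environmental
# datasets, GeoSPARQL geometries, DCAT/PROV-O/ODRL metadata, and a
# canonical Turtle serialization.
#
# Terms are stored in N-Triples-like text form: IRIs as "<iri>", literals as
# '"lexical"^^<datatype-iri>'.  A graph is a data.frame (subject, predicate,
# object) with set semantics and a fixed namespace table, so serialization
# is canonical (sorted triples, stable prefixes) and byte-reproducible.

KG_NAMESPACES <- c(
  dcat = "http://www.w3.org/ns/dcat#",
  dct  = "http://purl.org/dc/terms/",
  geo  = "http://www.opengis.net/ont/geosparql#",
  odrl = "http://www.w3.org/ns/odrl/2/",
  prov = "http://www.w3.org/ns/prov#",
  qb   = "http://purl.org/linked-data/cube#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

CRS84_IRI <- "http://www.opengis.net/def/crs/OGC/1.3/CRS84"

iri <- function(x) paste0("<", x, ">")
ns <- function(prefix, local) iri(paste0(KG_NAMESPACES[[prefix]], local))

lit <- function(lexical, datatype = NULL) {
  esc <- gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", lexical))
  if (is.null(datatype)) sprintf("\"%s\"", esc)
  else sprintf("\"%s\"^^<%s>", esc, datatype)
}

xsd_lit <- function(lexical, type) lit(lexical, paste0(KG_NAMESPACES[["xsd"]], type))

date_lit <- function(d) xsd_lit(format(as.Date(d), "%Y-%m-%d"), "date")

num_lit <- function(v) {
  lex <- sprintf("%.17g", v)
  if (grepl("[eE]", lex)) xsd_lit(lex, "double") else xsd_lit(lex, "decimal")
}

wkt_lit <- function(wkt_text) {
  lit(paste0("<", CRS84_IRI, "> ", wkt_text),
      paste0(KG_NAMESPACES[["geo"]], "wktLiteral"))
}

#' Create an (empty) triple graph
#' @param triples optional data.frame with columns subject, predicate, object.
#' @return a `triple_graph` data.frame with set semantics.
#' @export
triple_graph <- function(triples = NULL) {
  if (is.null(triples)) {
    triples <- data.frame(subject = character(0), predicate = character(0),
                          object = character(0), stringsAsFactors = FALSE)
  }
  g <- unique(triples[, c("subject", "predicate", "object")])
  rownames(g) <- NULL
  class(g) <- c("triple_graph", "data.frame")
  g
}

tg <- function(s, p, o) data.frame(subject = s, predicate = p, object = o,
                                   stringsAsFactors = FALSE)

#' Union of triple graphs (set semantics)
#' @param ... triple graphs or triple data.frames.
#' @export
tg_union <- function(...) triple_graph(do.call(rbind, lapply(list(...), as.data.frame)))

#' Number of triples in a graph
#' @param g a triple graph.
#' @export
tg_size <- function(g) nrow(g)

#' Mint a deterministic IRI from a base and path parts
#'
#' Parts are percent-encoded and joined with `/`; identical inputs always
#' yield identical IRIs.
#' @param base absolute IRI ending in `/` or `#` (a `/` is appended if not).
#' @param parts non-empty character vector of non-empty path parts.
#' @return the IRI as a plain string (no angle brackets).
#' @export
mint_iri <- function(base, parts) {
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", base)) {
    validation_error(sprintf("base IRI must be absolute: %s", dQuote(base)))
  }
  parts <- as.character(parts)
  if (length(parts) == 0 || any(!nzchar(parts))) validation_error("empty IRI part")
  if (!grepl("[/#]$", base)) base <- paste0(base, "/")
  enc <- vapply(parts, function(p) utils::URLencode(p, reserved = TRUE), character(1))
  paste0(base, paste(enc, collapse = "/"))
}

iri_local <- function(term) {
  # last path segment of an <iri> term, percent-decoded
  utils::URLdecode(sub(".*/", "", sub(">$", "", term)))
}

lit_value <- function(term) {
  # lexical form of a literal term, unescaped
  m <- regmatches(term, regexec('^"((?:[^"\\\\]|\\\\.)*)"', term))[[1]]
  gsub("\\\\(.)", "\\1", m[2])
}

# ---- dataset uplift -------------------------------------------------------

grid_cell_id <- function(ilat, ilon) sprintf("cell_%03d_%03d", ilat, ilon)

grid_cell_wkt <- function(ds, ilat, ilon) {
  dlon <- if (length(ds$lon_axis) > 1) diff(ds$lon_axis[1:2]) else 1
  dlat <- if (length(ds$lat_axis) > 1) diff(ds$lat_axis[1:2]) else 1
  x0 <- ds$lon_axis[ilon]; y0 <- ds$lat_axis[ilat]
  ring <- rbind(c(x0, y0), c(x0 + dlon, y0), c(x0 + dlon, y0 + dlat), c(x0, y0 + dlat), c(x0, y0))
  format_wkt(new_geometry(list(list(ring))))
}

#' Tidy observation table of a dataset
#'
#' One row per (source, date, variable); `source_id` is the station id for
#' station datasets and `cell_<ilat>_<ilon>` for grids.  Missing values keep
#' their rows with `value = NA`.
#' @param ds dataset.
#' @return data.frame (source_id, date, variable, value).
#' @export
observation_table <- function(ds) {
  if (inherits(ds, "env_stations")) {
    df <- ds$observations
    data.frame(source_id = df$station_id, date = df$date,
               variable = df$variable, value = df$value, stringsAsFactors = FALSE)
  } else {
    nv <- nrow(ds$variables); nt <- length(ds$time_axis)
    nlat <- length(ds$lat_axis); nlon <- length(ds$lon_axis)
    idx <- expand.grid(var = seq_len(nv), t = seq_len(nt),
                       ilat = seq_len(nlat), ilon = seq_len(nlon))
    data.frame(
      source_id = grid_cell_id(idx$ilat, idx$ilon),
      date = ds$time_axis[idx$t],
      variable = ds$variables$name[idx$var],
      value = ds$values[as.matrix(idx)],
      stringsAsFactors = FALSE
    )
  }
}

kg_dataset_iri <- function(base, dataset_id) mint_iri(base, c("dataset", dataset_id))
kg_source_iri <- function(base, dataset_id, source_id) mint_iri(base, c("source", dataset_id, source_id))
kg_measure_iri <- function(base, variable) mint_iri(base, c("measure", variable))
kg_prop_iri <- function(base, name) mint_iri(base, c("prop", name))
kg_obs_iri <- function(base, dataset_id, source_id, date, variable) {
  mint_iri(base, c("obs", dataset_id, source_id, format(as.Date(date), "%Y-%m-%d"), variable))
}
kg_event_iri <- function(base, event_id) mint_iri(base, c("event", event_id))
kg_area_iri <- function(base, area_id) mint_iri(base, c("area", area_id))

#' Uplift an environmental dataset to an RDF Data Cube graph
#'
#' Every non-missing (source, date, variable) value becomes one
#' `qb:Observation` carrying exactly five triples: a type assertion, the
#' `qb:dataSet` membership, a date dimension (`xsd:date` literal), a location
#' dimension (station/cell IRI) and one measure literal.  Structural triples
#' describe the dataset, its data-structure definition, component
#' specifications, variable definitions with units, and source geometries as
#' GeoSPARQL WKT literals.  Administrative-area geometries, when supplied,
#' are included as `geo:Feature` nodes.
#'
#' @param ds validated dataset.
#' @param areas optional list of `admin_area`s to include.
#' @param base base IRI for minted identifiers.
#' @return a `triple_graph`.
#' @export
uplift_dataset <- function(ds, areas = NULL, base = "https://example.org/envlink/") {
  ds_iri <- iri(kg_dataset_iri(base, ds$dataset_id))
  dsd_iri <- iri(mint_iri(base, c("dsd", ds$dataset_id)))
  p_date <- iri(kg_prop_iri(base, "refDate"))
  p_loc <- iri(kg_prop_iri(base, "refLocation"))

  structural <- list(
    tg(ds_iri, ns("rdf", "type"), ns("qb", "DataSet")),
    tg(ds_iri, ns("qb", "structure"), dsd_iri),
    tg(ds_iri, ns("dct", "identifier"), lit(ds$dataset_id)),
    tg(dsd_iri, ns("rdf", "type"), ns("qb", "DataStructureDefinition")),
    tg(p_date, ns("rdf", "type"), ns("qb", "DimensionProperty")),
    tg(p_loc, ns("rdf", "type"), ns("qb", "DimensionProperty"))
  )
  comp <- function(name, role_pred, target) {
    c_iri <- iri(mint_iri(base, c("dsd", ds$dataset_id, "component", name)))
    list(tg(dsd_iri, ns("qb", "component"), c_iri),
         tg(c_iri, ns("rdf", "type"), ns("qb", "ComponentSpecification")),
         tg(c_iri, ns("qb", role_pred), target))
  }
  structural <- c(structural, comp("refDate", "dimension", p_date),
                  comp("refLocation", "dimension", p_loc))
  for (k in seq_len(nrow(ds$variables))) {
    v <- ds$variables[k, ]
    m_iri <- iri(kg_measure_iri(base, v$name))
    structural <- c(structural, comp(v$name, "measure", m_iri), list(
      tg(m_iri, ns("rdf", "type"), ns("qb", "MeasureProperty")),
      tg(m_iri, ns("rdfs", "label"), lit(v$name))
    ))
    if (!is.na(v$unit)) {
      structural <- c(structural, list(tg(m_iri, iri(kg_prop_iri(base, "unitText")), lit(v$unit))))
    }
    if (!is.na(v$definition)) {
      structural <- c(structural, list(tg(m_iri, ns("rdfs", "comment"), lit(v$definition))))
    }
  }

  # source geometry nodes
  src_feature <- function(source_id, wkt_text) {
    s_iri <- iri(kg_source_iri(base, ds$dataset_id, source_id))
    g_iri <- iri(mint_iri(base, c("source", ds$dataset_id, source_id, "geom")))
    list(tg(s_iri, ns("rdf", "type"), ns("geo", "Feature")),
         tg(s_iri, ns("rdfs", "label"), lit(source_id)),
         tg(s_iri, ns("geo", "hasGeometry"), g_iri),
         tg(g_iri, ns("rdf", "type"), ns("geo", "Geometry")),
         tg(g_iri, ns("geo", "asWKT"), wkt_lit(wkt_text)))
  }
  if (inherits(ds, "env_stations")) {
    for (i in seq_len(nrow(ds$stations))) {
      st <- ds$stations[i, ]
      pt <- structure(list(point = c(st$lon, st$lat)), class = "envlink_point")
      structural <- c(structural, src_feature(st$station_id, format_wkt(pt)))
    }
  } else {
    for (ilat in seq_along(ds$lat_axis)) {
      for (ilon in seq_along(ds$lon_axis)) {
        structural <- c(structural,
                        src_feature(grid_cell_id(ilat, ilon), grid_cell_wkt(ds, ilat, ilon)))
      }
    }
  }
  if (!is.null(areas)) {
    for (a in areas) {
      if (is.null(a$geometry)) uplift_error(sprintf("area %s has no geometry", dQuote(a$area_id)))
      a_iri <- iri(kg_area_iri(base, a$area_id))
      g_iri <- iri(mint_iri(base, c("area", a$area_id, "geom")))
      structural <- c(structural, list(
        tg(a_iri, ns("rdf", "type"), ns("geo", "Feature")),
        tg(a_iri, ns("rdfs", "label"), lit(a$label)),
        tg(a_iri, ns("geo", "hasGeometry"), g_iri),
        tg(g_iri, ns("rdf", "type"), ns("geo", "Geometry")),
        tg(g_iri, ns("geo", "asWKT"), wkt_lit(format_wkt(a$geometry)))
      ))
    }
  }

  obs <- observation_table(ds)
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  if (nrow(obs) > 0) {
    o_iri <- vapply(seq_len(nrow(obs)), function(i) {
      iri(kg_obs_iri(base, ds$dataset_id, obs$source_id[i], obs$date[i], obs$variable[i]))
    }, character(1))
    s_iri <- vapply(obs$source_id, function(s) iri(kg_source_iri(base, ds$dataset_id, s)), character(1))
    m_iri <- vapply(obs$variable, function(v) iri(kg_measure_iri(base, v)), character(1))
    observation_triples <- rbind(
      tg(o_iri, ns("rdf", "type"), ns("qb", "Observation")),
      tg(o_iri, ns("qb", "dataSet"), ds_iri),
      tg(o_iri, p_date, vapply(as.character(obs$date), function(d) date_lit(d), character(1))),
      tg(o_iri, p_loc, s_iri),
      tg(o_iri, m_iri, vapply(obs$value, num_lit, character(1)))
    )
  } else {
    observation_triples <- tg(character(0), character(0), character(0))
  }
  tg_union(do.call(rbind, structural), observation_triples)
}

#' Read the (source, date, variable, value) table back out of an uplifted graph
#'
#' Inverse of [uplift_dataset()] for a single dataset: finds every
#' `qb:Observation` belonging to the dataset and reconstructs its dimensions
#' and measure value.
#' @param g triple graph.
#' @param dataset_id dataset to extract.
#' @param base base IRI used at uplift time.
#' @return data.frame (source_id, date, variable, value), sorted.
#' @export
kg_observation_table <- function(g, dataset_id, base = "https://example.org/envlink/") {
  ds_iri <- iri(kg_dataset_iri(base, dataset_id))
  p_date <- iri(kg_prop_iri(base, "refDate"))
  p_loc <- iri(kg_prop_iri(base, "refLocation"))
  measure_prefix <- paste0("<", mint_iri(base, "measure"), "/")
  obs_nodes <- g$subject[g$predicate == ns("qb", "dataSet") & g$object == ds_iri]
  sub <- g[g$subject %in% obs_nodes, , drop = FALSE]
  dates <- sub[sub$predicate == p_date, c("subject", "object")]
  locs <- sub[sub$predicate == p_loc, c("subject", "object")]
  meas <- sub[startsWith(sub$predicate, measure_prefix), c("subject", "predicate", "object")]
  df <- merge(merge(dates, locs, by = "subject"), meas, by = "subject")
  out <- data.frame(
    source_id = vapply(df$object.y, iri_local, character(1)),
    date = as.Date(vapply(df$object.x, lit_value, character(1))),
    variable = vapply(df$predicate, iri_local, character(1)),
    value = as.numeric(vapply(df$object, lit_value, character(1))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$source_id, out$date, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- metadata graph -------------------------------------------------------

#' Build the DCAT/PROV-O/ODRL metadata graph for a dataset or linkage run
#'
#' Emits a catalogued `dcat:Dataset` (title, licence, version, temporal and
#' spatial extents, distribution), a `prov:Activity` with one `prov:used`
#' link per input dataset and a `prov:generated` link to the output, one
#' `prov:Agent` per agent with its role, and an `odrl:Policy` rights node.
#' A missing licence is recorded in the graph as an open rights statement,
#' never raised as an error.
#'
#' @param md a [metadata_bundle()].
#' @param base base IRI.
#' @return a `triple_graph`.
#' @export
build_metadata_graph <- function(md, base = "https://example.org/envlink/") {
  out_id <- md$activity$generated %||% NA_character_
  if (is.na(out_id)) out_id <- gsub("[^A-Za-z0-9_-]+", "_", tolower(md$title))
  ds_iri <- iri(kg_dataset_iri(base, out_id))
  triples <- list(
    tg(ds_iri, ns("rdf", "type"), ns("dcat", "Dataset")),
    tg(ds_iri, ns("dct", "title"), lit(md$title)),
    tg(ds_iri, ns("dcat", "version"), lit(md$version))
  )
  policy_iri <- iri(mint_iri(base, c("policy", out_id)))
  triples <- c(triples, list(
    tg(ds_iri, ns("odrl", "hasPolicy"), policy_iri),
    tg(policy_iri, ns("rdf", "type"), ns("odrl", "Policy")),
    tg(policy_iri, ns("odrl", "target"), ds_iri)
  ))
  if (!is.na(md$licence)) {
    lic <- if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", md$licence)) iri(md$licence) else lit(md$licence)
    triples <- c(triples, list(tg(ds_iri, ns("dct", "license"), lic)))
  } else {
    triples <- c(triples, list(
      tg(policy_iri, ns("rdfs", "comment"),
         lit("No licence supplied: rights are open/unspecified pending a licence statement."))
    ))
  }
  if (!is.null(md$temporal_extent)) {
    t_iri <- iri(mint_iri(base, c("dataset", out_id, "temporal")))
    triples <- c(triples, list(
      tg(ds_iri, ns("dct", "temporal"), t_iri),
      tg(t_iri, ns("rdf", "type"), ns("dct", "PeriodOfTime")),
      tg(t_iri, ns("dcat", "startDate"), date_lit(md$temporal_extent[1])),
      tg(t_iri, ns("dcat", "endDate"), date_lit(md$temporal_extent[2]))
    ))
  }
  if (!is.null(md$spatial_extent)) {
    sp <- md$spatial_extent
    sp_obj <- if (is.numeric(sp) && length(sp) == 4) {
      ring <- rbind(c(sp[1], sp[2]), c(sp[3], sp[2]), c(sp[3], sp[4]), c(sp[1], sp[4]), c(sp[1], sp[2]))
      wkt_lit(format_wkt(new_geometry(list(list(ring)))))
    } else lit(as.character(sp))
    triples <- c(triples, list(tg(ds_iri, ns("dct", "spatial"), sp_obj)))
  }
  if (!is.na(md$distribution_url)) {
    d_iri <- iri(mint_iri(base, c("dataset", out_id, "distribution")))
    triples <- c(triples, list(
      tg(ds_iri, ns("dcat", "distribution"), d_iri),
      tg(d_iri, ns("rdf", "type"), ns("dcat", "Distribution")),
      tg(d_iri, ns("dcat", "downloadURL"), iri(md$distribution_url))
    ))
  }
  act_iri <- iri(mint_iri(base, c("activity", out_id)))
  triples <- c(triples, list(tg(act_iri, ns("rdf", "type"), ns("prov", "Activity"))))
  for (u in md$activity$used) {
    triples <- c(triples, list(tg(act_iri, ns("prov", "used"), iri(kg_dataset_iri(base, u)))))
  }
  triples <- c(triples, list(
    tg(act_iri, ns("prov", "generated"), ds_iri),
    tg(ds_iri, ns("prov", "wasGeneratedBy"), act_iri)
  ))
  if (!is.null(md$activity$started)) {
    triples <- c(triples, list(tg(act_iri, ns("prov", "startedAtTime"),
                                  xsd_lit(md$activity$started, "dateTime"))))
  }
  if (!is.null(md$activity$ended)) {
    triples <- c(triples, list(tg(act_iri, ns("prov", "endedAtTime"),
                                  xsd_lit(md$activity$ended, "dateTime"))))
  }
  if (nrow(md$agents) > 0) {
    for (i in seq_len(nrow(md$agents))) {
      ag <- md$agents[i, ]
      ag_iri <- iri(mint_iri(base, c("agent", gsub("[^A-Za-z0-9_-]+", "_", ag$name))))
      triples <- c(triples, list(
        tg(ag_iri, ns("rdf", "type"), ns("prov", "Agent")),
        tg(ag_iri, ns("rdfs", "label"), lit(ag$name)),
        tg(ag_iri, ns("dct", "type"), lit(ag$role)),
        tg(act_iri, ns("prov", "wasAssociatedWith"), ag_iri)
      ))
    }
  }
  tg_union(do.call(rbind, triples))
}

# ---- Turtle serialization -------------------------------------------------

term_to_turtle <- function(term) {
  if (startsWith(term, "<")) {
    full <- substr(term, 2L, nchar(term) - 1L)
    for (p in names(KG_NAMESPACES)) {
      base <- KG_NAMESPACES[[p]]
      if (startsWith(full, base)) {
        local <- substring(full, nchar(base) + 1L)
        if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)) return(paste0(p, ":", local))
      }
    }
    return(term)
  }
  # literal: compress a known datatype IRI to a prefixed name
  m <- regmatches(term, regexec('\\^\\^<([^>]*)>$', term))[[1]]
  if (length(m) == 2) {
    for (p in names(KG_NAMESPACES)) {
      base <- KG_NAMESPACES[[p]]
      if (startsWith(m[2], base)) {
        local <- substring(m[2], nchar(base) + 1L)
        return(sub('\\^\\^<[^>]*>$', paste0("^^", p, ":", local), term))
      }
    }
  }
  term
}

#' Serialize a triple graph to canonical Turtle
#'
#' Fixed prefix table, prefixed names where possible, one triple per line,
#' C-collation sort: two graphs with the same triples serialize to
#' byte-identical files.
#' @param g triple graph.
#' @param path output path.
#' @export
serialize_turtle <- function(g, path) {
  header <- sprintf("@prefix %s: <%s> .", names(KG_NAMESPACES), unname(KG_NAMESPACES))
  lines <- sprintf("%s %s %s .",
                   vapply(g$subject, term_to_turtle, character(1), USE.NAMES = FALSE),
                   vapply(g$predicate, term_to_turtle, character(1), USE.NAMES = FALSE),
                   vapply(g$object, term_to_turtle, character(1), USE.NAMES = FALSE))
  lines <- sort(unique(lines), method = "radix")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, "", lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

turtle_term_parse <- function(token, prefixes) {
  if (startsWith(token, "<")) return(token)
  if (startsWith(token, "\"")) {
    m <- regmatches(token, regexec('^("(?:[^"\\\\]|\\\\.)*")(?:\\^\\^(.*))?$', token))[[1]]
    if (is.na(m[3]) || m[3] == "") return(m[2])
    dt <- m[3]
    if (startsWith(dt, "<")) return(paste0(m[2], "^^", dt))
    pp <- strsplit(dt, ":", fixed = TRUE)[[1]]
    return(paste0(m[2], "^^<", prefixes[[pp[1]]], pp[2], ">"))
  }
  pp <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(pp) == 2 && pp[1] %in% names(prefixes)) {
    return(iri(paste0(prefixes[[pp[1]]], pp[2])))
  }
  format_error(sprintf("cannot parse Turtle term %s", dQuote(token)))
}

#' Parse the canonical Turtle subset written by serialize_turtle()
#' @param path Turtle file.
#' @return a `triple_graph`.
#' @export
parse_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prefixes <- list()
  triples <- list()
  for (line in lines) {
    line <- trimws(line)
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec("^@prefix\\s+([A-Za-z0-9_-]*):\\s+<([^>]*)>\\s*\\.$", line))[[1]]
      if (length(m) != 3) format_error(sprintf("malformed @prefix line: %s", line))
      prefixes[[m[2]]] <- m[3]
      next
    }
    if (!endsWith(line, " .")) format_error(sprintf("malformed triple line: %s", line))
    body <- substr(line, 1L, nchar(line) - 2L)
    # tokenize: three terms; the object may contain spaces inside a quoted literal
    toks <- character(0)
    rest <- body
    for (k in 1:2) {
      sp <- regexpr(" ", rest, fixed = TRUE)
      toks <- c(toks, substr(rest, 1L, sp - 1L))
      rest <- substring(rest, sp + 1L)
    }
    toks <- c(toks, rest)
    triples[[length(triples) + 1L]] <- tg(
      turtle_term_parse(toks[1], prefixes),
      turtle_term_parse(toks[2], prefixes),
      turtle_term_parse(toks[3], prefixes)
    )
  }
  triple_graph(do.call(rbind, c(triples, list(tg(character(0), character(0), character(0))))))
}
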