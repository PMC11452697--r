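# Semantic uplift: IRI minting, RDF Data Cube observation graphs,
# DCAT/PROV-O/ODRL metadata, canonical Turtle.

BASE <- "https://ex.org/"

test_that("mint_iri is a deterministic percent-encoding concatenation", {
  expect_identical(mint_iri("https://ex.org/", c("obs", "st01", "2021-03-01", "pm10")),
                   "https://ex.org/obs/st01/2021-03-01/pm10")
  expect_identical(mint_iri("https://ex.org/", "no 2"), "https://ex.org/no%202")
  expect_identical(mint_iri("https://ex.org", c("a", "b")),
                   mint_iri("https://ex.org", c("a", "b")))
  expect_error(mint_iri("https://ex.org/", c("a", "")), class = "envlink_validation_error")
  expect_error(mint_iri("not-an-iri", "a"), class = "envlink_validation_error")
})

test_that("a 2-observation dataset uplifts to exactly the hand-enumerated graph", {
  ds <- env_stations(
    "tiny2",
    stations = data.frame(station_id = "s1", lon = 0.5, lat = 1.5),
    observations = data.frame(station_id = "s1", date = as.Date(c("2021-03-01", "2021-03-02")),
                              variable = "pm10", value = c(7, 8.5)),
    variables = data.frame(name = "pm10", unit = "ug/m3", definition = "particulates")
  )
  g <- uplift_dataset(ds, base = BASE)

  i <- function(x) paste0("<", x, ">")
  ns <- envlink:::ns; lit <- envlink:::lit
  dsx <- i("https://ex.org/dataset/tiny2"); dsd <- i("https://ex.org/dsd/tiny2")
  p_date <- i("https://ex.org/prop/refDate"); p_loc <- i("https://ex.org/prop/refLocation")
  c_date <- i("https://ex.org/dsd/tiny2/component/refDate")
  c_loc <- i("https://ex.org/dsd/tiny2/component/refLocation")
  c_pm <- i("https://ex.org/dsd/tiny2/component/pm10")
  meas <- i("https://ex.org/measure/pm10")
  src <- i("https://ex.org/source/tiny2/s1"); geom <- i("https://ex.org/source/tiny2/s1/geom")
  obs1 <- i("https://ex.org/obs/tiny2/s1/2021-03-01/pm10")
  obs2 <- i("https://ex.org/obs/tiny2/s1/2021-03-02/pm10")
  wkt <- paste0("\"<http://www.opengis.net/def/crs/OGC/1.3/CRS84> POINT (0.5 1.5)\"",
                "^^<http://www.opengis.net/ont/geosparql#wktLiteral>")
  xsd_date <- function(d) sprintf("\"%s\"^^<http://www.w3.org/2001/XMLSchema#date>", d)
  dec <- function(v) sprintf("\"%s\"^^<http://www.w3.org/2001/XMLSchema#decimal>", v)

  expected <- rbind(
    c(dsx, ns("rdf", "type"), ns("qb", "DataSet")),
    c(dsx, ns("qb", "structure"), dsd),
    c(dsx, ns("dct", "identifier"), lit("tiny2")),
    c(dsd, ns("rdf", "type"), ns("qb", "DataStructureDefinition")),
    c(p_date, ns("rdf", "type"), ns("qb", "DimensionProperty")),
    c(p_loc, ns("rdf", "type"), ns("qb", "DimensionProperty")),
    c(dsd, ns("qb", "component"), c_date),
    c(c_date, ns("rdf", "type"), ns("qb", "ComponentSpecification")),
    c(c_date, ns("qb", "dimension"), p_date),
    c(dsd, ns("qb", "component"), c_loc),
    c(c_loc, ns("rdf", "type"), ns("qb", "ComponentSpecification")),
    c(c_loc, ns("qb", "dimension"), p_loc),
    c(dsd, ns("qb", "component"), c_pm),
    c(c_pm, ns("rdf", "type"), ns("qb", "ComponentSpecification")),
    c(c_pm, ns("qb", "measure"), meas),
    c(meas, ns("rdf", "type"), ns("qb", "MeasureProperty")),
    c(meas, ns("rdfs", "label"), lit("pm10")),
    c(meas, i("https://ex.org/prop/unitText"), lit("ug/m3")),
    c(meas, ns("rdfs", "comment"), lit("particulates")),
    c(src, ns("rdf", "type"), ns("geo", "Feature")),
    c(src, ns("rdfs", "label"), lit("s1")),
    c(src, ns("geo", "hasGeometry"), geom),
    c(geom, ns("rdf", "type"), ns("geo", "Geometry")),
    c(geom, ns("geo", "asWKT"), wkt),
    c(obs1, ns("rdf", "type"), ns("qb", "Observation")),
    c(obs1, ns("qb", "dataSet"), dsx),
    c(obs1, p_date, xsd_date("2021-03-01")),
    c(obs1, p_loc, src),
    c(obs1, meas, dec("7")),
    c(obs2, ns("rdf", "type"), ns("qb", "Observation")),
    c(obs2, ns("qb", "dataSet"), dsx),
    c(obs2, p_date, xsd_date("2021-03-02")),
    c(obs2, p_loc, src),
    c(obs2, meas, dec("8.5"))
  )
  expected <- data.frame(subject = expected[, 1], predicate = expected[, 2],
                         object = expected[, 3], stringsAsFactors = FALSE)
  got <- as.data.frame(g)[order(g$subject, g$predicate, g$object), ]
  exp_sorted <- expected[order(expected$subject, expected$predicate, expected$object), ]
  rownames(got) <- rownames(exp_sorted) <- NULL
  expect_identical(got, exp_sorted)
})

test_that("an empty dataset yields only structural triples", {
  ds <- env_stations(
    "empty",
    stations = data.frame(station_id = "s1", lon = 0, lat = 0),
    observations = data.frame(station_id = character(0), date = as.Date(character(0)),
                              variable = character(0), value = numeric(0)),
    variables = data.frame(name = "x", unit = NA_character_, definition = NA_character_)
  )
  g <- uplift_dataset(ds, base = BASE)
  expect_false(any(startsWith(g$subject, "<https://ex.org/obs/")))
  expect_gt(tg_size(g), 0)
})

test_that("the 5-triples-per-observation law holds against an independent count", {
  spec <- synth_spec(seed = 7, n_days = 30, n_stations = 10, n_events = 3,
                     missing_rate = 0.1)
  ds <- gen_stations_dataset(spec)
  g <- uplift_dataset(ds, base = BASE)
  # independent oracle: loop over the raw observation table
  n_obs <- 0L
  for (i in seq_len(nrow(ds$observations))) {
    if (!is.na(ds$observations$value[i])) n_obs <- n_obs + 1L
  }
  obs_triples <- sum(startsWith(g$subject, "<https://ex.org/obs/"))
  expect_identical(obs_triples, 5L * n_obs)
})

test_that("querying the graph back reproduces the source observation table exactly", {
  spec <- synth_spec(seed = 13, n_days = 12, n_stations = 4, n_events = 2,
                     missing_rate = 0.2)
  ds <- gen_stations_dataset(spec)
  g <- uplift_dataset(ds, base = BASE)
  back <- kg_observation_table(g, ds$dataset_id, base = BASE)
  src <- observation_table(ds)
  src <- src[!is.na(src$value), ]
  src <- src[order(src$source_id, src$date, src$variable), ]
  rownames(src) <- NULL
  expect_identical(back$source_id, src$source_id)
  expect_identical(back$date, src$date)
  expect_identical(back$variable, src$variable)
  expect_identical(back$value, src$value)   # exact, via 17-significant-digit literals
})

test_that("uplift is idempotent under graph union", {
  ds <- tiny_stations(n_stations = 2, n_days = 3)
  g1 <- uplift_dataset(ds, base = BASE)
  g2 <- uplift_dataset(ds, base = BASE)
  expect_identical(tg_size(tg_union(g1, g2)), tg_size(g1))
})

test_that("metadata graph carries catalogue, provenance, agents and rights", {
  md <- metadata_bundle(
    title = "Linked run", licence = "https://creativecommons.org/licenses/by/4.0/",
    version = "2.1.0", temporal_extent = as.Date(c("2021-01-01", "2021-03-01")),
    spatial_extent = c(-4, 50, 4, 56), distribution_url = "https://ex.org/dist.ttl",
    agents = data.frame(name = c("Ana", "linker"), role = c("researcher", "software")),
    activity = list(used = c("weather", "pollution"), generated = "linked")
  )
  g <- build_metadata_graph(md, base = BASE)
  act <- "<https://ex.org/activity/linked>"
  used <- g[g$subject == act & g$predicate == envlink:::ns("prov", "used"), ]
  expect_identical(nrow(used), 2L)
  gen <- g[g$subject == act & g$predicate == envlink:::ns("prov", "generated"), ]
  expect_identical(nrow(gen), 1L)
  dsx <- "<https://ex.org/dataset/linked>"
  expect_triple(g, dsx, envlink:::ns("dct", "title"), envlink:::lit("Linked run"))
  expect_triple(g, dsx, envlink:::ns("dcat", "version"), envlink:::lit("2.1.0"))
  expect_triple(g, dsx, envlink:::ns("dct", "license"),
                "<https://creativecommons.org/licenses/by/4.0/>")
  assoc <- g[g$subject == act & g$predicate == envlink:::ns("prov", "wasAssociatedWith"), ]
  expect_identical(nrow(assoc), 2L)
  agent_types <- g[g$predicate == envlink:::ns("rdf", "type") &
                     g$object == envlink:::ns("prov", "Agent"), ]
  expect_identical(nrow(agent_types), 2L)
  # no timestamps were supplied, so none may appear (byte-reproducibility)
  expect_false(any(grepl("AtTime", g$predicate)))
})

test_that("a missing licence becomes an open rights statement, not an error", {
  md <- metadata_bundle(title = "No licence", activity = list(used = "a", generated = "out"))
  g <- build_metadata_graph(md, base = BASE)
  expect_false(any(g$predicate == envlink:::ns("dct", "license")))
  policy <- g[g$object == envlink:::ns("odrl", "Policy"), "subject"]
  expect_length(policy, 1L)
  comment <- g[g$subject == policy & g$predicate == envlink:::ns("rdfs", "comment"), "object"]
  expect_match(comment, "open")
})

test_that("canonical Turtle round-trips and two serializations are byte-identical", {
  ds <- tiny_stations(n_stations = 3, n_days = 4, variables = c("temp", "pm10"))
  g <- uplift_dataset(ds, base = BASE)
  f1 <- withr::local_tempfile(fileext = ".ttl")
  f2 <- withr::local_tempfile(fileext = ".ttl")
  serialize_turtle(g, f1)
  serialize_turtle(g[sample(nrow(g)), ], f2)   # order must not matter
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  g2 <- parse_turtle(f1)
  expect_identical(tg_size(g2), tg_size(g))
  expect_identical(nrow(merge(as.data.frame(g), as.data.frame(g2))), tg_size(g))
})

test_that("emitted Turtle is valid RDF for an independent parser", {
  ds <- tiny_stations(n_stations = 2, n_days = 3)
  g <- uplift_dataset(ds, base = BASE)
  f <- withr::local_tempfile(fileext = ".ttl")
  serialize_turtle(g, f)
  script <- sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='turtle'); print(len(g))", f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)), stdout = TRUE))
  expect_identical(as.integer(out[length(out)]), tg_size(g))
})
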