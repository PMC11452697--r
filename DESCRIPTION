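Package: envlink
Title: Spatiotemporal Linkage of Health Events to Environmental Observations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Links pseudonymous health events to environmental observations
    through a spatial context (administrative-area containment, nearest
    station, Voronoi proximity polygons, or distance buffers) and a
    configurable pre-event exposure window.  Environmental datasets (gridded
    daily NetCDF or station time series in CSV/TSV) and administrative
    geometries (GeoJSON or WKT-bearing CSV) are validated into a common data
    model, uplifted to an RDF Data Cube observation graph with GeoSPARQL
    geometries and DCAT/PROV-O/ODRL provenance metadata, and the linked
    exposures are exported as an analysis table (CSV), a linked-data graph
    (Turtle) and a self-contained HTML report.  A seeded synthetic-data
    module generates grid, station, area and event fixtures so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
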