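---
title: "Methods: linking health events to environmental observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking health events to environmental observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envlink)
```

## The problem

Environmental epidemiology studies — particularly of rare diseases such as
the vasculitides, where events are geographically sparse and registries
small — need to attach an *exposure* to each health event: a summary of the
environmental conditions the patient plausibly experienced before the event.
Health records carry a pseudonymous id, a date and a location (a point or an
administrative area); environmental data arrive as gridded daily fields
(weather reanalyses in NetCDF) or station time series (air-quality monitors
in CSV/TSV). The two share no identifier, so the link must be constructed
from space and time alone, and — because linked health-environment datasets
are re-used, published and audited — the construction must be transparent,
reproducible and carried with provenance metadata.

`envlink` implements that construction as a pipeline:

1. **read** environmental datasets, administrative geometries and health
   events into a validated internal model (`read_env_dataset()`,
   `read_areas()`, `read_events()`);
2. **uplift** the observations to an RDF Data Cube graph with GeoSPARQL
   geometries and DCAT/PROV-O/ODRL metadata (`uplift_dataset()`,
   `build_metadata_graph()`);
3. **link** each event to a spatial context and a pre-event exposure window
   (`assign_spatial()`, `temporal_window()`, `link_events()`);
4. **aggregate** the linked observations into exposure records
   (`aggregate_exposures()`); and
5. **export** an analysis table (CSV), a linked-data graph (Turtle) and a
   self-contained HTML report (`export_bundle()`, `run_pipeline()`).

## The exposure window

For an event on day $t_e$, a lag $L \ge 0$ and a window length $W \ge 1$
(both in days), the window is the half-open interval

$$\mathcal{W}(t_e) = [\, t_e - L - W,\; t_e - L \,),$$

i.e. exactly $W$ calendar days, the latest of which is $t_e - L - 1$. The
event day itself is **always excluded**, including at $L = 0$: exposures are
meant to precede the outcome, and including the event day would let the
outcome's own day leak into its putative cause. This convention is enforced
by `temporal_window()` and asserted as a property over random
$(t_e, L, W)$ triples in the test suite.

The defaults ($L = 0$, $W = 7$ days) are a deliberately neutral choice —
short enough to represent an acute-exposure hypothesis, long enough to
smooth day-scale noise — and are configurable; substantive studies should
choose them from the hypothesis under test, not from these defaults.

## Spatial context

Four interchangeable methods attach an event to observation sources:

* **`area_contains`** — the event's administrative area (its own `area_id`,
  or for point events the *most specific* — smallest planar area —
  containing polygon), mapped to all stations inside the polygon, or all
  grid cells whose origins fall inside it. Point-in-polygon uses the
  even-odd rule with boundary points counted as inside; the smallest-area
  rule resolves nested geometries (district before region), with ties broken
  by area id.
* **`nearest_station`** — the station minimising great-circle (haversine)
  distance, computed with `geosphere`; ties within 1 m are broken by the
  lexicographically smallest station id so assignment is deterministic.
* **`proximity_polygon`** — classical Thiessen/Voronoi assignment. Station
  coordinates are projected with an equirectangular projection centred on
  the station centroid; each station's cell is built geometrically by
  clipping an enclosing rectangle with the perpendicular-bisector half-plane
  against every other station (Sutherland–Hodgman), and the event point is
  located in a cell by the even-odd test. Because cell construction and
  point location are a genuinely different computation from a
  nearest-neighbour argmin, the identity "Voronoi cell membership = planar
  nearest station" is a meaningful correctness property, and the suite
  asserts it against a brute-force oracle over seeded random configurations
  (it holds everywhere except exactly on cell boundaries, where the
  lexicographic tie-break applies).
* **`buffer`** — all stations within `buffer_km` great-circle kilometres;
  enlarging the radius never removes a source (monotonicity is tested).

Gridded datasets treat cells as half-open rectangles
$[\lambda_i, \lambda_i + \Delta\lambda) \times [\phi_j, \phi_j + \Delta\phi)$
anchored at stored cell origins, so every boundary point belongs to exactly
one cell; the point methods select the single containing cell, and
`area_contains` selects cells by origin-in-polygon. No areal weighting is
applied — cell selection is binary and deterministic; areal-weighted
intersection is a possible future extension.

Planar areas (shoelace) are used only for *relative* comparisons among
candidate polygons at similar latitudes, never reported in physical units.
An event outside every area or grid is not an error: it yields an empty
context and a `no_spatial_context` entry in the skip log. Skips are data,
not failures.

## The observation knowledge graph

Each non-missing (source, date, variable) value becomes one
`qb:Observation` carrying exactly five triples: the type assertion, the
`qb:dataSet` membership, an `xsd:date` dimension literal, a location
dimension IRI (station, grid cell, or area), and one measure literal. One
measure per observation node keeps the cube shape minimal and makes the
triple count a law — $|\text{observation triples}| = 5 \times
|\text{non-missing observations}|$ — that the tests verify with an
independent count. Structural triples describe the dataset, its
`qb:DataStructureDefinition`, component specifications, measure definitions
with units, and source geometries as GeoSPARQL `geo:wktLiteral`s in CRS84
lon/lat order.

Numeric literals are serialized with 17 significant digits, which
round-trips IEEE doubles exactly; the round-trip invariant (query the graph,
recover the source table bit-for-bit) is asserted in the tests. Turtle
output is canonical — fixed prefix table, one triple per line, C-collation
sort — so two graphs with the same triples serialize byte-identically, which
is what makes end-to-end determinism testable. The uplift is a direct
programmatic mapping to the Data Cube target shape; no mapping-language
(R2RML) engine is embedded, since the graph, not the mapping formalism, is
the contract consumers depend on.

Metadata follows the catalogue/provenance/rights split: a `dcat:Dataset`
node (title, licence, version, temporal and spatial extents, distribution),
a `prov:Activity` with one `prov:used` link per input dataset and a
`prov:generated` link to the derived output, `prov:Agent` nodes with roles
(researcher, software, entity), and an `odrl:Policy` rights node. A missing
licence is recorded *in the graph* as an open rights statement rather than
raised as an error, so incomplete rights information remains visible instead
of blocking the run. Activity timestamps are taken from the configuration
when supplied and omitted otherwise — never from the wall clock — so that
two identical runs produce byte-identical Turtle; wall-clock timings go to
the run-summary JSON.

## Two linkage backends

The **direct** backend filters the tabular observations. The **graph**
backend runs the linkage over the uplifted triples: spatial relations are
pre-materialized as `envlink:linkedTo` link triples computed by the same
spatial engine, and the query template (`build_query_template()`, SPARQL 1.1
with named placeholders) reduces to a basic graph pattern plus half-open
`xsd:date` comparisons, which the package evaluates directly over the triple
table. In-process GeoSPARQL function evaluation is deliberately out of
scope; what the package guarantees — and tests on every fixture — is
*backend equivalence*: both backends return identical
(event, source, date, variable, value) multisets.

## Aggregation

Aggregation order is fixed and documented because it changes results for
non-linear statistics: **spatial first** (multi-source days are averaged
into one value per day), **then temporal** (the requested statistic over the
daily series). `sd` uses the $n-1$ denominator; `count` counts distinct
observed dates. `coverage` is the fraction of window dates with at least one
observation; records below `min_coverage` are flagged, and excluded from the
analysis CSV only when `exclude_flagged` is set — flagged records always
remain in the RDF graph with a `low_coverage` quality annotation, so the
published graph never silently hides weak records. At `agg_level = "daily"`
each observed day becomes its own record (`agg = "daily_mean"`,
`window_start` = the day, `window_end` = day + 1), reusing the same
nine-column table schema.

## The synthetic generators

The generators emulate the shapes of the study's data landscape — a gridded
daily field, station time series, nested administrative geometries, daily
patient events — under a shared value model

$$v(k, t, \phi) = \mu_k + A_k \sin(2\pi t / 365) + \gamma_k(\phi - \phi_0)
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_k^2),$$

with missingness applied completely at random at `missing_rate`. Sharing one
model between grids and stations makes grid-vs-station linkage comparisons
meaningful. Every generator draws from its own RNG stream derived from
(seed, generator name), so adding a generator call never perturbs another —
generated fixtures are pure functions of the spec.

Defaults (chosen once as country-scale, plausible magnitudes): an 8°x6°
extent, a 10x10 grid and 25 stations over 120 days, 50 events, a
temperature-like variable (10 °C base, 8 °C seasonal amplitude, 2 °C noise,
−0.5 °C/degree latitude) and a PM10-like variable (20 µg/m³ base, 5
amplitude, 4 noise), 5 % missing. Event dates keep a 60-day margin after
the series start so default windows fit inside coverage; the margin shrinks
with a warning for short series.

What the generators do **not** emulate: spatial autocorrelation of the noise
field, instrument drift or station outages (missingness is MCAR), pollution
chemistry, population density of events, or patients moving between
addresses. Passing tests therefore demonstrate the correctness of the
*linkage machinery* under controlled conditions, not the epidemiological
validity of any particular exposure model on real data.

## Numerical choices and degenerate inputs

* Grid axes must be regular to within 1e−9 degrees; irregular grids are
  rejected rather than silently resampled.
* Sub-daily time axes are rejected: daily resolution is the contract, and
  resampling is a modelling choice the pipeline refuses to make implicitly.
* Distance ties use a 1e−9 km tolerance and then the lexicographic id rule;
  all other tie-breaks (areas, Voronoi boundaries) are lexicographic too.
* NetCDF fill values and empty tabular cells map to the single internal
  missing flag (`NA`); missing values are carried and accounted, never
  dropped on read.
* The NetCDF-3 classic reader/writer is implemented in the package
  (big-endian, 4-byte alignment, CDF-1/CDF-2, record dimension on read) and
  is cross-checked in the tests against an independent SciPy reader.
* Zero stations is a configuration error; zero observations in a window is
  a skip-log entry; an empty dataset uplifts to a purely structural graph.

Test and acceptance problem sizes (50 stations / 200 events for the Voronoi
property; 10x30x2 observations for the graph round trip; 1000 random
window triples; a 4x4x80-day constant grid with 10 events end-to-end) were
chosen as the smallest sizes at which each property is non-trivial while
keeping the default suite fast to run routinely.

## Known limitations

* One location per event: moving-address exposure histories must be
  represented as multiple events per patient.
* No kriging/interpolation between stations and no areal weighting of
  grid-area intersections; the spatial methods are selection rules, not
  spatial models.
* The proximity-polygon metric is planar (equirectangular); at continental
  scales or high latitudes nearest-by-haversine and Voronoi-by-projection
  can disagree near cell boundaries.
* The graph backend evaluates the fixed linkage template, not arbitrary
  SPARQL; the template text is emitted for use with a full triplestore.
* `.grid` input is read as the tabular dialect with the default header; the
  format has no independent definition.
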