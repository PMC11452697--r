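# Planar geometry primitives for WGS84 lon/lat polygons.
#
# Geometries are lists: list(polys = list(polygon)), where a polygon is a
# list of rings (outer first, then holes) and a ring is a closed two-column
# matrix (lon, lat; first row == last row).  Point-in-polygon uses the
# even-odd rule with boundary points counted as inside.  Areas are planar
# (shoelace, squared degrees): only used for relative "most specific area"
# comparisons, never reported in physical units.

EPS_GEOM <- 1e-12

new_geometry <- function(polys) {
  structure(list(polys = polys), class = "envlink_geometry")
}

ring_close <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ], tolerance = 0))) m <- rbind(m, m[1, ])
  m
}

# ---- WKT ------------------------------------------------------------------

wkt_parse_ring <- function(txt) {
  pts <- strsplit(trimws(txt), ",")[[1]]
  coords <- t(vapply(pts, function(p) {
    xy <- as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    if (length(xy) < 2 || anyNA(xy)) geometry_error(sprintf("malformed WKT coordinate %s", dQuote(p)))
    xy[1:2]
  }, numeric(2)))
  dimnames(coords) <- NULL
  ring_close(coords)
}

wkt_split_groups <- function(body) {
  # split a "( ... ) , ( ... )" body at top-level commas
  depth <- 0L; start <- 1L; out <- character(0)
  chars <- strsplit(body, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "," && depth == 0L) {
      out <- c(out, substr(body, start, i - 1L)); start <- i + 1L
    }
  }
  c(out, substr(body, start, nchar(body)))
}

strip_parens <- function(x) {
  x <- trimws(x)
  if (!startsWith(x, "(") || !endsWith(x, ")")) geometry_error("malformed WKT: unbalanced parentheses")
  substr(x, 2L, nchar(x) - 1L)
}

#' Parse a WKT POLYGON or MULTIPOLYGON (lon/lat order)
#' @keywords internal
parse_wkt <- function(wkt) {
  wkt <- trimws(wkt)
  # tolerate an explicit CRS84 prefix as used in GeoSPARQL literals
  wkt <- sub("^<[^>]+>\\s*", "", wkt)
  up <- toupper(wkt)
  if (startsWith(up, "MULTIPOLYGON")) {
    body <- strip_parens(sub("^MULTIPOLYGON\\s*", "", wkt, ignore.case = TRUE))
    polys <- lapply(wkt_split_groups(body), function(g) {
      rings_txt <- wkt_split_groups(strip_parens(g))
      lapply(rings_txt, function(r) wkt_parse_ring(strip_parens(r)))
    })
    new_geometry(polys)
  } else if (startsWith(up, "POLYGON")) {
    body <- strip_parens(sub("^POLYGON\\s*", "", wkt, ignore.case = TRUE))
    rings <- lapply(wkt_split_groups(body), function(r) wkt_parse_ring(strip_parens(r)))
    new_geometry(list(rings))
  } else if (startsWith(up, "POINT")) {
    body <- strip_parens(sub("^POINT\\s*", "", wkt, ignore.case = TRUE))
    xy <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
    structure(list(point = xy[1:2]), class = "envlink_point")
  } else {
    geometry_error(sprintf("unsupported WKT geometry type in %s", dQuote(substr(wkt, 1, 30))))
  }
}

fmt_coord <- function(x) {
  # round-trip-safe, locale-independent coordinate text
  sub("\\.?0+$", "", sprintf("%.10f", x))
}

format_wkt_ring <- function(ring) {
  paste0("(", paste(apply(ring, 1, function(p) paste(fmt_coord(p[1]), fmt_coord(p[2]))), collapse = ", "), ")")
}

#' Serialize a geometry to WKT (lon/lat order)
#' @keywords internal
format_wkt <- function(geom) {
  if (inherits(geom, "envlink_point")) {
    return(sprintf("POINT (%s %s)", fmt_coord(geom$point[1]), fmt_coord(geom$point[2])))
  }
  poly_txt <- vapply(geom$polys, function(rings) {
    paste0("(", paste(vapply(rings, format_wkt_ring, character(1)), collapse = ", "), ")")
  }, character(1))
  if (length(poly_txt) == 1L) paste0("POLYGON ", poly_txt)
  else paste0("MULTIPOLYGON (", paste(poly_txt, collapse = ", "), ")")
}

# ---- measures & validity --------------------------------------------------

ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Planar polygon area (outer rings minus holes), squared degrees
#' @keywords internal
geometry_area <- function(geom) {
  sum(vapply(geom$polys, function(rings) {
    a <- abs(ring_area_signed(rings[[1]]))
    if (length(rings) > 1) a <- a - sum(vapply(rings[-1], function(r) abs(ring_area_signed(r)), numeric(1)))
    a
  }, numeric(1)))
}

seg_intersect <- function(p1, p2, p3, p4) {
  # proper or improper intersection of segments p1p2 and p3p4
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - EPS_GEOM <= c[1] && c[1] <= max(a[1], b[1]) + EPS_GEOM &&
      min(a[2], b[2]) - EPS_GEOM <= c[2] && c[2] <= max(a[2], b[2]) + EPS_GEOM
  }
  (abs(d1) < EPS_GEOM && on_seg(p3, p4, p1)) || (abs(d2) < EPS_GEOM && on_seg(p3, p4, p2)) ||
    (abs(d3) < EPS_GEOM && on_seg(p1, p2, p3)) || (abs(d4) < EPS_GEOM && on_seg(p1, p2, p4))
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L  # segments
  if (n < 3L) return(TRUE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next  # first and last share the closing vertex
      if (seg_intersect(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

#' Validate a polygonal geometry: closed rings, positive area, simple rings
#' @keywords internal
check_geometry <- function(geom, id = "geometry") {
  for (rings in geom$polys) {
    for (ring in rings) {
      if (nrow(ring) < 4L) geometry_error(sprintf("%s: ring with fewer than 3 distinct vertices", id))
      if (ring_self_intersects(ring)) geometry_error(sprintf("%s: self-intersecting ring", id))
    }
  }
  if (geometry_area(geom) <= EPS_GEOM) geometry_error(sprintf("%s: zero or negative area", id))
  invisible(geom)
}

# ---- point in polygon -----------------------------------------------------

point_on_ring <- function(pt, ring) {
  n <- nrow(ring) - 1L
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[i + 1L, ]
    cross <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
    if (abs(cross) < 1e-9 &&
        min(a[1], b[1]) - EPS_GEOM <= pt[1] && pt[1] <= max(a[1], b[1]) + EPS_GEOM &&
        min(a[2], b[2]) - EPS_GEOM <= pt[2] && pt[2] <= max(a[2], b[2]) + EPS_GEOM) return(TRUE)
  }
  FALSE
}

ring_crossings_odd <- function(pt, ring) {
  # even-odd ray casting, ray towards +x
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[i + 1L, ]
    if ((a[2] > pt[2]) != (b[2] > pt[2])) {
      xint <- a[1] + (pt[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (pt[1] < xint) inside <- !inside
    }
  }
  inside
}

#' Even-odd point-in-polygon; boundary points count as inside
#' @keywords internal
point_in_geometry <- function(pt, geom) {
  for (rings in geom$polys) {
    crossings <- FALSE
    on_boundary <- FALSE
    for (ring in rings) {
      if (point_on_ring(pt, ring)) { on_boundary <- TRUE; break }
      if (ring_crossings_odd(pt, ring)) crossings <- !crossings
    }
    if (on_boundary || crossings) return(TRUE)
  }
  FALSE
}

# ---- projection & distance ------------------------------------------------

#' Equirectangular projection to km, centred at (lon0, lat0)
#' @keywords internal
project_equirect <- function(lon, lat, lon0, lat0) {
  kx <- 111.32 * cos(lat0 * pi / 180)
  cbind(x = (lon - lon0) * kx, y = (lat - lat0) * 111.32)
}

#' Great-circle distance in km (haversine)
#' @keywords internal
dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# ---- Voronoi cells by half-plane clipping ---------------------------------

clip_halfplane <- function(poly, a, b, c) {
  # keep points with a*x + b*y <= c (Sutherland-Hodgman); poly open (no repeat)
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  val <- a * poly[, 1] + b * poly[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- val[i] <= EPS_GEOM
    pj_in <- val[j] <= EPS_GEOM
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Planar Voronoi (Thiessen) cells for a set of sites
#'
#' Each cell is the bounding rectangle (sites' extent padded by `pad`)
#' clipped by the perpendicular-bisector half-plane against every other
#' site.  Sites are projected coordinates (km); returns one open polygon
#' matrix per site.
#' @keywords internal
voronoi_cells <- function(xy, pad = NULL) {
  n <- nrow(xy)
  if (n == 0L) config_error("voronoi_cells: zero sites")
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  if (is.null(pad)) pad <- max(diff(rng_x), diff(rng_y), 1) * 2
  box <- cbind(
    c(rng_x[1] - pad, rng_x[2] + pad, rng_x[2] + pad, rng_x[1] - pad),
    c(rng_y[1] - pad, rng_y[1] - pad, rng_y[2] + pad, rng_y[2] + pad)
  )
  lapply(seq_len(n), function(i) {
    cell <- box
    for (j in seq_len(n)) {
      if (j == i || nrow(cell) == 0L) next
      # bisector: points closer to i than j  =>  a*x + b*y <= c
      a <- 2 * (xy[j, 1] - xy[i, 1])
      b <- 2 * (xy[j, 2] - xy[i, 2])
      c <- sum(xy[j, ]^2) - sum(xy[i, ]^2)
      cell <- clip_halfplane(cell, a, b, c)
    }
    cell
  })
}
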