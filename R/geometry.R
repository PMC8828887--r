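# Minimal planar geometry for region topology: WKT multipolygons,
# point-in-polygon, touch/overlap predicates and centroids. Coordinates are
# geographic degrees used as planar coordinates; only topology matters here,
# never planar distance.

#' Parse a WKT POLYGON or MULTIPOLYGON string
#'
#' A multipolygon is represented as a list of polygons; each polygon is a
#' list of rings (first ring exterior, the rest holes); each ring is a
#' two-column numeric matrix of vertices with the closing vertex removed.
#'
#' @param text a single WKT string (`POLYGON (...)` or `MULTIPOLYGON (...)`).
#' @return a multipolygon (list of list of matrices).
#' @examples
#' wkt_parse_multipolygon("POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))")
#' @export
wkt_parse_multipolygon <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty WKT geometry string")
  }
  s <- trimws(text)
  type <- toupper(sub("^\\s*([A-Za-z]+).*$", "\\1", s))
  body <- trimws(sub("^\\s*[A-Za-z]+\\s*", "", s))
  if (!type %in% c("POLYGON", "MULTIPOLYGON")) {
    stop("unsupported WKT type: ", type)
  }
  if (!startsWith(body, "(") || !endsWith(body, ")")) {
    stop("malformed WKT: ", substr(s, 1, 60))
  }
  body <- substr(body, 2L, nchar(body) - 1L)
  polys <- if (type == "POLYGON") list(body) else split_wkt_groups(body)
  lapply(polys, function(p) {
    rings <- split_wkt_groups(p)
    lapply(rings, parse_wkt_ring)
  })
}

# split "( ... ), ( ... )" at depth-0 commas, stripping one paren level
split_wkt_groups <- function(body) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  depth <- 0L
  start <- NULL
  out <- list()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1L
      if (depth == 1L) start <- i + 1L
    } else if (ch == ")") {
      if (depth == 1L) out[[length(out) + 1L]] <- paste(chars[start:(i - 1L)], collapse = "")
      depth <- depth - 1L
      if (depth < 0L) stop("malformed WKT: unbalanced parentheses")
    }
  }
  if (depth != 0L || length(out) == 0L) stop("malformed WKT: unbalanced parentheses")
  out
}

parse_wkt_ring <- function(txt) {
  pts <- strsplit(trimws(strsplit(txt, ",", fixed = TRUE)[[1]]), "\\s+")
  coords <- vapply(pts, function(p) {
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (length(p) < 2L || anyNA(v)) stop("malformed WKT coordinate: '", paste(p, collapse = " "), "'")
    v
  }, numeric(2))
  m <- t(coords)
  # drop explicit closing vertex
  if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("WKT ring with fewer than 3 distinct vertices")
  m
}

#' Serialise a multipolygon to WKT
#'
#' @param mp a multipolygon as returned by [wkt_parse_multipolygon()].
#' @return a `MULTIPOLYGON` WKT string.
#' @export
wkt_multipolygon <- function(mp) {
  fmt_ring <- function(r) {
    r <- rbind(r, r[1, ])
    paste0("(", paste(sprintf("%.10g %.10g", r[, 1], r[, 2]), collapse = ", "), ")")
  }
  polys <- vapply(mp, function(p) {
    paste0("(", paste(vapply(p, fmt_ring, character(1)), collapse = ", "), ")")
  }, character(1))
  paste0("MULTIPOLYGON (", paste(polys, collapse = ", "), ")")
}

# all edges of a multipolygon as an n x 4 matrix (x1 y1 x2 y2)
mp_edges <- function(mp) {
  segs <- lapply(unlist(mp, recursive = FALSE), function(r) {
    nxt <- c(seq_len(nrow(r))[-1], 1L)
    cbind(r, r[nxt, , drop = FALSE])
  })
  do.call(rbind, segs)
}

mp_vertices <- function(mp) do.call(rbind, unlist(mp, recursive = FALSE))

orient2d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)

# inclusive segment intersection (shared endpoints / collinear overlap count)
segments_meet <- function(p, q, eps = 1e-9) {
  d1 <- orient2d(q[1], q[2], q[3], q[4], p[1], p[2])
  d2 <- orient2d(q[1], q[2], q[3], q[4], p[3], p[4])
  d3 <- orient2d(p[1], p[2], p[3], p[4], q[1], q[2])
  d4 <- orient2d(p[1], p[2], p[3], p[4], q[3], q[4])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(ax, ay, bx, by, px, py) {
    abs(orient2d(ax, ay, bx, by, px, py)) <= eps &&
      px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
      py >= min(ay, by) - eps && py <= max(ay, by) + eps
  }
  on_seg(q[1], q[2], q[3], q[4], p[1], p[2]) ||
    on_seg(q[1], q[2], q[3], q[4], p[3], p[4]) ||
    on_seg(p[1], p[2], p[3], p[4], q[1], q[2]) ||
    on_seg(p[1], p[2], p[3], p[4], q[3], q[4])
}

# strict transversal crossing at an interior point of both segments
segments_cross <- function(p, q, eps = 1e-9) {
  d1 <- orient2d(q[1], q[2], q[3], q[4], p[1], p[2])
  d2 <- orient2d(q[1], q[2], q[3], q[4], p[3], p[4])
  d3 <- orient2d(p[1], p[2], p[3], p[4], q[1], q[2])
  d4 <- orient2d(p[1], p[2], p[3], p[4], q[3], q[4])
  ((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
    ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))
}

point_on_edges <- function(x, y, edges, eps = 1e-9) {
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (x < min(e[1], e[3]) - eps || x > max(e[1], e[3]) + eps ||
        y < min(e[2], e[4]) - eps || y > max(e[2], e[4]) + eps) next
    dx <- e[3] - e[1]; dy <- e[4] - e[2]
    len2 <- dx * dx + dy * dy
    d <- if (len2 == 0) {
      sqrt((x - e[1])^2 + (y - e[2])^2)
    } else {
      abs(dy * (x - e[1]) - dx * (y - e[2])) / sqrt(len2)
    }
    if (d <= eps) return(TRUE)
  }
  FALSE
}

# even-odd ray cast over every ring (holes handled by parity)
point_in_rings <- function(x, y, mp) {
  inside <- FALSE
  for (ring in unlist(mp, recursive = FALSE)) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y)) {
        xint <- (ring[j, 1] - ring[i, 1]) * (y - yi) / (yj - yi) + ring[i, 1]
        if (x < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

#' Test whether points fall inside a multipolygon
#'
#' Even-odd rule; points on the boundary count as inside.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param mp a multipolygon.
#' @param eps boundary snap tolerance.
#' @return logical vector.
#' @export
point_in_multipolygon <- function(x, y, mp, eps = 1e-9) {
  edges <- mp_edges(mp)
  vapply(seq_along(x), function(i) {
    point_in_rings(x[i], y[i], mp) || point_on_edges(x[i], y[i], edges, eps)
  }, logical(1))
}

# a point strictly interior to the multipolygon (point-on-surface):
# horizontal line through a y between distinct vertex levels, midpoint of the
# first inside interval
mp_interior_point <- function(mp, eps = 1e-9) {
  ys <- sort(unique(mp_vertices(mp)[, 2]))
  cand_y <- if (length(ys) == 1L) ys else (ys[-length(ys)] + ys[-1]) / 2
  edges <- mp_edges(mp)
  for (y0 in cand_y) {
    xs <- c()
    for (i in seq_len(nrow(edges))) {
      y1 <- edges[i, 2]; y2 <- edges[i, 4]
      if ((y1 > y0) != (y2 > y0)) {
        xs <- c(xs, edges[i, 1] + (edges[i, 3] - edges[i, 1]) * (y0 - y1) / (y2 - y1))
      }
    }
    xs <- sort(xs)
    if (length(xs) >= 2L && (xs[2] - xs[1]) > eps) {
      return(c((xs[1] + xs[2]) / 2, y0))
    }
  }
  # degenerate sliver: fall back to vertex mean
  colMeans(mp_vertices(mp))
}

#' Topological relation between two multipolygons
#'
#' Classifies a pair as `"disjoint"`, `"touch"` (boundaries share at least one
#' point, interiors do not intersect) or `"overlap"` (interiors intersect).
#' A shared corner point counts as touching (queen-style contiguity).
#'
#' @param a,b multipolygons.
#' @param eps geometric tolerance.
#' @return one of `"disjoint"`, `"touch"`, `"overlap"`.
#' @export
mp_relation <- function(a, b, eps = 1e-9) {
  va <- mp_vertices(a); vb <- mp_vertices(b)
  # fast bounding-box reject
  if (min(va[, 1]) > max(vb[, 1]) + eps || min(vb[, 1]) > max(va[, 1]) + eps ||
      min(va[, 2]) > max(vb[, 2]) + eps || min(vb[, 2]) > max(va[, 2]) + eps) {
    return("disjoint")
  }
  ea <- mp_edges(a); eb <- mp_edges(b)
  meet <- FALSE
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      if (segments_cross(ea[i, ], eb[j, ], eps)) return("overlap")
      if (!meet && segments_meet(ea[i, ], eb[j, ], eps)) meet <- TRUE
    }
  }
  strictly_inside <- function(pts, mp, edges) {
    for (i in seq_len(nrow(pts))) {
      if (point_in_rings(pts[i, 1], pts[i, 2], mp) &&
          !point_on_edges(pts[i, 1], pts[i, 2], edges, eps)) return(TRUE)
    }
    FALSE
  }
  if (strictly_inside(va, b, eb) || strictly_inside(vb, a, ea)) return("overlap")
  # coincident shapes: all vertices on each other's boundary; test interior points
  ia <- mp_interior_point(a, eps); ib <- mp_interior_point(b, eps)
  if ((point_in_rings(ia[1], ia[2], b) && !point_on_edges(ia[1], ia[2], eb, eps)) ||
      (point_in_rings(ib[1], ib[2], a) && !point_on_edges(ib[1], ib[2], ea, eps))) {
    return("overlap")
  }
  if (meet) "touch" else "disjoint"
}

#' Area-weighted centroid of a multipolygon
#'
#' Shoelace centroid over exterior rings (holes ignored); used as the
#' representative point of a region for the shortest-distance estimator.
#'
#' @param mp a multipolygon.
#' @return numeric length-2 vector (x, y).
#' @export
mp_centroid <- function(mp) {
  cx <- 0; cy <- 0; atot <- 0
  for (poly in mp) {
    r <- poly[[1]]
    nxt <- c(seq_len(nrow(r))[-1], 1L)
    cross <- r[, 1] * r[nxt, 2] - r[nxt, 1] * r[, 2]
    a <- sum(cross) / 2
    if (abs(a) < 1e-12) next
    cx <- cx + sum((r[, 1] + r[nxt, 1]) * cross) / 6
    cy <- cy + sum((r[, 2] + r[nxt, 2]) * cross) / 6
    atot <- atot + a
  }
  if (atot == 0) return(colMeans(mp_vertices(mp)))
  c(cx / atot, cy / atot)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised).
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

# axis-aligned rectangle as a multipolygon
rect_mp <- function(xmin, ymin, xmax, ymax) {
  list(list(matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
                   ncol = 2, byrow = TRUE)))
}
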