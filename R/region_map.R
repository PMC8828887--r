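#' Region maps: polygon adjacency graphs for concentric-ring estimation
#'
#' A `region_map` holds a set of labelled regions (e.g. UK postcode areas),
#' their multipolygon geometries and a symmetric, irreflexive adjacency
#' ("neighbour") relation. Concentric rings are breadth-first shells over
#' this graph.
#'
#' @param region_id character vector of unique region labels.
#' @param geometry optional list of multipolygons (one per region, may be
#'   `NULL` entries when adjacency is supplied directly).
#' @param neighbours optional named list of character vectors; symmetrised
#'   and made irreflexive on construction.
#' @param meta optional data.frame of per-region attributes (population etc.).
#' @return an object of class `region_map`.
#' @export
region_map <- function(region_id, geometry = NULL, neighbours = NULL, meta = NULL) {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id)) {
    stop("duplicate region ids: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  }
  if (!is.null(geometry)) {
    stopifnot(length(geometry) == length(region_id))
    names(geometry) <- region_id
  }
  if (!is.null(neighbours)) {
    stopifnot(length(neighbours) == length(region_id))
    names(neighbours) <- region_id
    unknown <- setdiff(unlist(neighbours), region_id)
    if (length(unknown)) {
      stop("neighbour ids not in map: ", paste(unknown, collapse = ", "))
    }
    # enforce symmetry + irreflexivity
    for (id in region_id) {
      nb <- setdiff(unique(neighbours[[id]]), id)
      neighbours[[id]] <- nb
      for (other in nb) {
        if (!id %in% neighbours[[other]]) {
          neighbours[[other]] <- c(neighbours[[other]], id)
        }
      }
    }
  }
  structure(
    list(region_id = region_id, geometry = geometry, neighbours = neighbours,
         overlaps = data.frame(a = character(), b = character()),
         meta = meta),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  n_adj <- if (is.null(x$neighbours)) NA_integer_ else
    sum(lengths(x$neighbours)) / 2
  cat("region_map:", length(x$region_id), "regions,",
      if (is.na(n_adj)) "adjacency not computed" else paste(n_adj, "adjacencies"),
      "\n")
  if (nrow(x$overlaps)) {
    cat("  overlapping pairs:",
        paste(x$overlaps$a, x$overlaps$b, sep = "~", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read region metadata from CSV
#'
#' Expects columns `region_id` and `geometry` (WKT `POLYGON`/`MULTIPOLYGON`),
#' and optionally `neighbours` (semicolon-separated region ids). When a
#' non-empty neighbour column is present it is used verbatim (symmetrised);
#' otherwise adjacency is computed from the geometries with
#' [compute_adjacency()].
#'
#' @param path CSV file path.
#' @return a `region_map`.
#' @export
read_region_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"region_id" %in% names(df)) stop("region metadata must have a region_id column")
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region ids in ", path, ": ",
         paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "))
  }
  geometry <- NULL
  if ("geometry" %in% names(df)) {
    geometry <- lapply(seq_len(nrow(df)), function(i) {
      g <- df$geometry[i]
      if (is.na(g) || !nzchar(trimws(g))) return(NULL)
      tryCatch(wkt_parse_multipolygon(g),
               error = function(e) stop("row ", i, " (region ", df$region_id[i],
                                        "): ", conditionMessage(e)))
    })
  }
  neighbours <- NULL
  if ("neighbours" %in% names(df) && any(nzchar(trimws(ifelse(is.na(df$neighbours), "", df$neighbours))))) {
    neighbours <- lapply(df$neighbours, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) return(character())
      trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  extra <- df[setdiff(names(df), c("geometry", "neighbours"))]
  map <- region_map(df$region_id, geometry = geometry, neighbours = neighbours,
                    meta = extra)
  if (is.null(neighbours)) {
    if (is.null(geometry)) stop("region metadata needs a geometry or neighbours column")
    map <- compute_adjacency(map)
  }
  map
}

#' Write region metadata to CSV
#'
#' Inverse of [read_region_metadata()]: emits `region_id`, `geometry` (WKT)
#' and `neighbours` (semicolon-separated) columns plus any metadata columns.
#'
#' @param map a `region_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_metadata <- function(map, path) {
  df <- data.frame(region_id = map$region_id, stringsAsFactors = FALSE)
  if (!is.null(map$geometry)) {
    df$geometry <- vapply(map$geometry, function(g) {
      if (is.null(g)) "" else wkt_multipolygon(g)
    }, character(1))
  }
  if (!is.null(map$neighbours)) {
    df$neighbours <- vapply(map$neighbours, paste, character(1), collapse = ";")
  }
  if (!is.null(map$meta)) {
    for (col in setdiff(names(map$meta), names(df))) df[[col]] <- map$meta[[col]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Compute region adjacency from geometries
#'
#' Two regions are neighbours iff their geometries touch: they share at least
#' one boundary point but their interiors do not intersect. Corner-only
#' contact counts (queen-style contiguity). Pairs whose interiors overlap are
#' recorded in `map$overlaps` and reported with a warning; the overlapping
#' pair is still treated as adjacent so that estimation can proceed.
#'
#' @param map a `region_map` with geometries.
#' @param eps geometric tolerance.
#' @return the map with `neighbours` (and `overlaps`) populated.
#' @export
compute_adjacency <- function(map, eps = 1e-9) {
  stopifnot(inherits(map, "region_map"))
  if (is.null(map$geometry)) stop("map has no geometries to compute adjacency from")
  ids <- map$region_id
  for (id in ids) {
    g <- map$geometry[[id]]
    if (is.null(g)) stop("region ", id, " has no geometry")
    ok <- vapply(unlist(g, recursive = FALSE),
                 function(r) nrow(r) >= 3 && all(is.finite(r)), logical(1))
    if (!all(ok)) stop("invalid geometry for region ", id)
  }
  nb <- stats::setNames(rep(list(character()), length(ids)), ids)
  ov <- list()
  n <- length(ids)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        rel <- mp_relation(map$geometry[[ids[i]]], map$geometry[[ids[j]]], eps)
        if (rel == "disjoint") next
        if (rel == "overlap") ov[[length(ov) + 1L]] <- c(ids[i], ids[j])
        nb[[ids[i]]] <- c(nb[[ids[i]]], ids[j])
        nb[[ids[j]]] <- c(nb[[ids[j]]], ids[i])
      }
    }
  }
  map$neighbours <- nb
  if (length(ov)) {
    ovm <- do.call(rbind, ov)
    map$overlaps <- data.frame(a = ovm[, 1], b = ovm[, 2], stringsAsFactors = FALSE)
    warning("overlapping region pairs treated as adjacent: ",
            paste(ovm[, 1], ovm[, 2], sep = "~", collapse = ", "))
  } else {
    map$overlaps <- data.frame(a = character(), b = character())
  }
  map
}

#' Regions at a given ring (graph distance) from an origin
#'
#' Ring 0 is the origin itself; ring k is the set of regions at breadth-first
#' graph distance exactly k over the neighbour relation.
#'
#' @param map a `region_map` with adjacency populated.
#' @param origin a region id present in the map.
#' @param k nonnegative integer ring index.
#' @return character vector of region ids (possibly empty).
#' @export
region_ring <- function(map, origin, k) {
  stopifnot(inherits(map, "region_map"), k >= 0)
  d <- ring_distances(map, origin)
  names(d)[!is.na(d) & d == k]
}

#' Breadth-first graph distances from an origin region
#'
#' @param map a `region_map` with adjacency populated.
#' @param origin a region id present in the map.
#' @return named integer vector over all regions; `NA` where unreachable.
#' @export
ring_distances <- function(map, origin) {
  stopifnot(inherits(map, "region_map"))
  if (is.null(map$neighbours)) stop("adjacency not computed; run compute_adjacency()")
  if (!origin %in% map$region_id) stop("unknown origin region: ", origin)
  d <- stats::setNames(rep(NA_integer_, length(map$region_id)), map$region_id)
  d[origin] <- 0L
  frontier <- origin
  k <- 0L
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(map$neighbours[frontier], use.names = FALSE)),
                   names(d)[!is.na(d)])
    k <- k + 1L
    d[nxt] <- k
    frontier <- nxt
  }
  d
}
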