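# Shared fixtures and independent oracles.

# grid map whose region ids encode (row, col); adjacency oracle below uses
# only these indices, never the geometry code under test
grid_map <- function(rows, cols) {
  make_region_map(synth_config(rows = rows, cols = cols))
}

grid_rc <- function(ids) {
  data.frame(id = ids,
             r = as.integer(substr(ids, 2, 3)),
             c = as.integer(substr(ids, 4, 5)),
             stringsAsFactors = FALSE)
}

# queen contiguity straight from grid indices
oracle_grid_adjacency <- function(ids) {
  rc <- grid_rc(ids)
  out <- lapply(seq_along(ids), function(i) {
    hit <- abs(rc$r - rc$r[i]) <= 1 & abs(rc$c - rc$c[i]) <= 1 &
      !(rc$r == rc$r[i] & rc$c == rc$c[i])
    ids[hit]
  })
  names(out) <- ids
  out
}

# graph distances by repeated boolean matrix products (no BFS code shared
# with the implementation)
oracle_distances <- function(adj, origin) {
  ids <- names(adj)
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (id in ids) A[id, adj[[id]]] <- TRUE
  d <- setNames(rep(NA_integer_, length(ids)), ids)
  d[origin] <- 0L
  reach <- setNames(ids == origin, ids)
  for (k in seq_along(ids)) {
    nxt <- (as.vector(reach %*% A) > 0) & !reach
    if (!any(nxt)) break
    d[nxt] <- k
    reach <- reach | nxt
  }
  d
}

# filter-and-mean estimation oracle over oracle distances
oracle_estimate <- function(adj, origin, values_by_region) {
  d <- oracle_distances(adj, origin)
  have <- intersect(names(values_by_region), names(d)[!is.na(d)])
  if (!length(have)) return(list(value = NA_real_, rings = NA_integer_))
  k <- min(d[have])
  list(value = mean(unlist(values_by_region[have[d[have] == k]])),
       rings = as.integer(k))
}

# sites placed at region centroids of a map
centroid_sites <- function(map, regions = map$region_id,
                           types = "urban background") {
  pts <- t(vapply(regions, function(r) mp_centroid(map$geometry[[r]]), numeric(2)))
  data.frame(site_id = paste0("s_", regions),
             longitude = pts[, 1], latitude = pts[, 2],
             network = "AQ",
             environment_type = rep_len(types, length(regions)),
             region_id = regions,
             stringsAsFactors = FALSE)
}

# small correlated hourly network used across imputation tests
bench_network <- function(rho = 0.9, n_days = 90, missing_fraction = 0.25,
                          missing_mode = "random", seed = 42, n_sites = 6) {
  cfg <- synth_config(n_sites = n_sites, n_days = n_days, rho = rho,
                      missing_fraction = missing_fraction,
                      missing_mode = missing_mode, seed = seed)
  map <- make_region_map(cfg)
  net <- make_sensor_network(map, cfg)
  net$map <- map
  net$config <- cfg
  net
}
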