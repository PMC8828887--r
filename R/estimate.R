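#' Concentric-regions estimation of regional exposure values
#'
#' Estimates a measurement for a region and timestamp as the arithmetic mean
#' of the sensor values found in the smallest nonempty ring of regions
#' around it: ring 0 is the region itself, ring k the regions at graph
#' distance k over the adjacency relation. The ring count at which sensors
#' were found is reported alongside the value as a confidence proxy (0 =
#' in-region). No upper bound is placed on the number of rings; if the
#' origin's connected component is exhausted without finding a valued
#' sensor, both the value and the ring count are missing. A site counts as
#' having a station for a timestamp only when its value is non-missing
#' then, so rings expand past dormant sensors.
#'
#' @param map a `region_map` with adjacency populated.
#' @param sites site metadata with a `region_id` column (see
#'   [assign_sites_to_regions()]); sites with no region are ignored.
#' @param data site-level values: data.frame with `site_id`, a timestamp
#'   column (`time_stamp` or `timestamp`) and one column per measurement.
#' @param region_id target region id.
#' @param timestamp target timestamp (compared as formatted string/Date).
#' @param measurement name of the value column to estimate.
#' @return list with `value` (mean of contributing sensors, or `NA`),
#'   `rings` (integer, or `NA`), `n_sites` (number of contributing sensors).
#' @export
estimate_region <- function(map, sites, data, region_id, timestamp, measurement) {
  stopifnot(inherits(map, "region_map"))
  if (!region_id %in% map$region_id) stop("unknown region: ", region_id)
  if (!measurement %in% names(data)) stop("unknown measurement: ", measurement)
  vals <- site_values_at(sites, data, timestamp, measurement)
  ring_mean(map, region_id, vals)
}

ts_col <- function(data) {
  if ("time_stamp" %in% names(data)) "time_stamp"
  else if ("timestamp" %in% names(data)) "timestamp"
  else stop("data needs a time_stamp or timestamp column")
}

# per-region non-missing site values at one timestamp: list(region -> values)
site_values_at <- function(sites, data, timestamp, measurement) {
  tc <- ts_col(data)
  rows <- data[format_timestamps(data[[tc]]) == format_timestamps(timestamp) &
                 !is.na(data[[measurement]]), c("site_id", measurement)]
  if (!nrow(rows)) return(list())
  reg <- sites$region_id[match(rows$site_id, sites$site_id)]
  keep <- !is.na(reg)
  split(rows[[measurement]][keep], reg[keep])
}

ring_mean <- function(map, region_id, values_by_region) {
  empty <- list(value = NA_real_, rings = NA_integer_, n_sites = 0L)
  if (!length(values_by_region)) return(empty)
  d <- ring_distances(map, region_id)
  have <- intersect(names(values_by_region), names(d)[!is.na(d)])
  if (!length(have)) return(empty)
  k <- min(d[have])
  contrib <- unlist(values_by_region[have[d[have] == k]], use.names = FALSE)
  list(value = mean(contrib), rings = as.integer(k), n_sites = length(contrib))
}

#' Regional estimates over all regions, timestamps and measurements
#'
#' Applies [estimate_region()] (or the shortest-distance alternative) over
#' the cross product of regions, timestamps and measurements. The output
#' mirrors the regional-estimates CSV schema: index columns `time_stamp`
#' and `region_id`, one value column per measurement and a matching
#' `rings_<measurement>` column (all-missing for the distance method),
#' ordered by (time_stamp, region_id).
#'
#' @inheritParams estimate_region
#' @param measurements value columns to estimate; default all numeric ones.
#' @param timestamps timestamps to estimate; default all present in `data`.
#' @param method `"rings"` (concentric regions) or `"distance"`
#'   (nearest valued sensor to the region centroid).
#' @return data.frame of regional estimates.
#' @export
estimate_all <- function(map, sites, data, measurements = NULL,
                         timestamps = NULL, method = c("rings", "distance")) {
  method <- match.arg(method)
  tc <- ts_col(data)
  if (is.null(measurements)) {
    measurements <- setdiff(names(data), c("site_id", tc))
    measurements <- measurements[vapply(data[measurements], is.numeric, logical(1))]
  }
  if (is.null(timestamps)) {
    timestamps <- sort(unique(format_timestamps(data[[tc]])))
  } else {
    timestamps <- format_timestamps(timestamps)
  }
  regions <- map$region_id
  out <- expand.grid(region_id = regions, time_stamp = timestamps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[c("time_stamp", "region_id")]
  out <- out[order(out$time_stamp, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  dists <- if (method == "rings") {
    lapply(stats::setNames(regions, regions), function(r) ring_distances(map, r))
  }
  cents <- if (method == "distance") region_centroids(map)
  for (m in measurements) {
    val <- rep(NA_real_, nrow(out))
    rng <- rep(NA_integer_, nrow(out))
    for (ts in timestamps) {
      vals <- site_values_at(sites, data, ts, m)
      rows <- which(out$time_stamp == ts)
      if (method == "rings") {
        if (length(vals)) {
          for (i in rows) {
            d <- dists[[out$region_id[i]]]
            have <- intersect(names(vals), names(d)[!is.na(d)])
            if (!length(have)) next
            k <- min(d[have])
            contrib <- unlist(vals[have[d[have] == k]], use.names = FALSE)
            val[i] <- mean(contrib)
            rng[i] <- as.integer(k)
          }
        }
      } else {
        for (i in rows) {
          est <- nearest_site_value(sites, data, ts, m, cents[out$region_id[i], ])
          val[i] <- est
        }
      }
    }
    out[[m]] <- val
    out[[paste0("rings_", m)]] <- rng
  }
  out
}

region_centroids <- function(map) {
  if (is.null(map$geometry)) stop("map has no geometries for the distance method")
  cents <- t(vapply(map$region_id, function(r) mp_centroid(map$geometry[[r]]),
                    numeric(2)))
  rownames(cents) <- map$region_id
  cents
}

nearest_site_value <- function(sites, data, timestamp, measurement, centre) {
  tc <- ts_col(data)
  rows <- data[format_timestamps(data[[tc]]) == format_timestamps(timestamp) &
                 !is.na(data[[measurement]]), c("site_id", measurement)]
  if ("region_id" %in% names(sites)) {
    rows <- rows[rows$site_id %in% sites$site_id[!is.na(sites$region_id)], ,
                 drop = FALSE]
  }
  if (!nrow(rows)) return(NA_real_)
  s <- sites[match(rows$site_id, sites$site_id), ]
  d <- haversine_km(centre[1], centre[2], s$longitude, s$latitude)
  ord <- order(d, rows$site_id)
  rows[[measurement]][ord[1]]
}

#' Shortest-distance regional estimate
#'
#' Baseline alternative to the concentric-regions method: the value of the
#' valued sensor nearest (great-circle, spherical Earth of radius 6371 km)
#' to the target region's area centroid. The ring count is not defined for
#' this method and is returned missing.
#'
#' @inheritParams estimate_region
#' @return list with `value`, `rings` (always `NA`), `n_sites` (0 or 1).
#' @export
estimate_distance <- function(map, sites, data, region_id, timestamp,
                              measurement) {
  stopifnot(inherits(map, "region_map"))
  if (!region_id %in% map$region_id) stop("unknown region: ", region_id)
  if (!measurement %in% names(data)) stop("unknown measurement: ", measurement)
  centre <- mp_centroid(map$geometry[[region_id]])
  v <- nearest_site_value(sites, data, timestamp, measurement, centre)
  list(value = v, rings = NA_integer_, n_sites = as.integer(!is.na(v)))
}

#' Site-type stratified regional estimates
#'
#' Runs the concentric-regions estimator restricted to monitoring sites of
#' one environment type. Output value columns carry the type abbreviation
#' (`Ind`, `UB`, `RB`, `UT`): a measurement column `NO2_mean` becomes
#' `NO2_Ind_mean` for industrial sites, with ring columns named
#' `rings_NO2_Ind_mean`.
#'
#' @inheritParams estimate_all
#' @param site_type one of `"industrial"`, `"urban background"`,
#'   `"rural background"`, `"urban traffic"`, `"other"`.
#' @return data.frame of stratified regional estimates.
#' @export
estimate_stratified <- function(map, sites, data, site_type,
                                measurements = NULL, timestamps = NULL) {
  if (!site_type %in% names(SITE_TYPE_ABBREV)) {
    stop("unknown site type: ", site_type, " (expected one of ",
         paste(names(SITE_TYPE_ABBREV), collapse = ", "), ")")
  }
  ab <- SITE_TYPE_ABBREV[[site_type]]
  sub <- sites[!is.na(sites$environment_type) &
                 sites$environment_type == site_type, , drop = FALSE]
  est <- estimate_all(map, sub, data, measurements = measurements,
                      timestamps = timestamps, method = "rings")
  rename <- function(m) {
    if (grepl("_(mean|max)$", m)) sub("_(mean|max)$", paste0("_", ab, "_\\1"), m)
    else paste0(m, "_", ab)
  }
  vals <- setdiff(names(est), c("time_stamp", "region_id"))
  vals <- vals[!startsWith(vals, "rings_")]
  for (m in vals) {
    nm <- rename(m)
    names(est)[names(est) == m] <- nm
    names(est)[names(est) == paste0("rings_", m)] <- paste0("rings_", nm)
  }
  est
}
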