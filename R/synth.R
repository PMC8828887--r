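#' Configuration for the synthetic-data generator
#'
#' Describes the study conditions emulated by the generator: a grid region
#' map (optionally with islands and overlapping pairs for edge-case
#' testing), a small sensor network, and hourly series with the structure
#' the cleaning/imputation/estimation methods assume - a seasonal harmonic,
#' a diurnal harmonic, a shared spatial factor giving inter-site correlation
#' `rho`, and independent noise.
#'
#' @param rows,cols grid dimensions (unit-square regions).
#' @param n_islands isolated regions touching nothing.
#' @param n_overlaps pairs of mutually overlapping regions.
#' @param n_sites number of monitoring sites to place.
#' @param start first day (ISO date string).
#' @param n_days number of days of data.
#' @param hourly hourly series (`TRUE`) or daily (`FALSE`).
#' @param rho inter-site correlation of the stochastic component, in
#'   \[0, 1).
#' @param diurnal_amp,seasonal_amp harmonic amplitudes (measurement units).
#' @param noise_sd standard deviation of the stochastic component.
#' @param base_level series mean level.
#' @param missing_fraction fraction of points withheld per site (0 = none).
#' @param missing_mode removal mode, as in [remove_data()].
#' @param pollen_season inclusive month-day window (`"%m-%d"`) outside which
#'   pollen series are wholly missing; default March 1 to September 9.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(rows = 5, cols = 5, n_islands = 0, n_overlaps = 0,
                         n_sites = 6, start = "2016-01-01", n_days = 90,
                         hourly = TRUE, rho = 0.9, diurnal_amp = 2,
                         seasonal_amp = 5, noise_sd = 1, base_level = 10,
                         missing_fraction = 0, missing_mode = "random",
                         pollen_season = c("03-01", "09-09"), seed = 42) {
  stopifnot(rho >= 0, rho < 1, diurnal_amp >= 0, seasonal_amp >= 0,
            noise_sd >= 0, missing_fraction >= 0, missing_fraction < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic region map
#'
#' A `rows x cols` grid of unit squares (interior regions have 8 neighbours
#' under corner contiguity), plus optional islands (regions touching
#' nothing) and overlapping pairs, which [compute_adjacency()] flags.
#'
#' @param config a [synth_config()] (or use the individual arguments).
#' @return a `region_map` with adjacency computed from the geometries.
#' @export
make_region_map <- function(config = synth_config()) {
  ids <- character(); geoms <- list()
  for (r in seq_len(config$rows)) {
    for (c in seq_len(config$cols)) {
      id <- sprintf("g%02d%02d", r, c)
      ids <- c(ids, id)
      geoms[[id]] <- rect_mp(c - 1, r - 1, c, r)
    }
  }
  x0 <- config$cols + 2
  for (i in seq_len(config$n_islands)) {
    id <- paste0("island", i)
    ids <- c(ids, id)
    geoms[[id]] <- rect_mp(x0 + 2 * i, 0, x0 + 2 * i + 1, 1)
  }
  for (i in seq_len(config$n_overlaps)) {
    ya <- 3 * i
    ida <- paste0("ovl", i, "a"); idb <- paste0("ovl", i, "b")
    ids <- c(ids, ida, idb)
    geoms[[ida]] <- rect_mp(x0, ya, x0 + 1, ya + 1)
    geoms[[idb]] <- rect_mp(x0 + 0.5, ya + 0.5, x0 + 1.5, ya + 1.5)
  }
  compute_adjacency(region_map(ids, geometry = geoms[ids]))
}

#' A two-shell demonstration map
#'
#' Twelve regions built so that a central region A touches exactly three
#' neighbours (B, C, D) and a second shell of eight regions (E, F, G, H, I,
#' L, M, N) touches only the first shell: the classic worked example for
#' the concentric-regions method, realised with actual polygon geometry.
#'
#' @return a `region_map` with adjacency computed from the geometries.
#' @export
make_two_shell_map <- function() {
  g <- list(
    A = rect_mp(1, 1, 2, 2),
    B = rect_mp(0, 1.2, 1, 1.8),      # west of A
    C = rect_mp(2, 1.2, 3, 1.8),      # east of A
    D = rect_mp(1.2, 2, 1.8, 3),      # north of A
    E = rect_mp(-1, 1.20, 0, 1.40),   # on B's outward face
    F = rect_mp(-1, 1.45, 0, 1.60),
    G = rect_mp(-1, 1.65, 0, 1.80),
    H = rect_mp(3, 1.20, 4, 1.40),    # on C's outward face
    I = rect_mp(3, 1.45, 4, 1.60),
    L = rect_mp(3, 1.65, 4, 1.80),
    M = rect_mp(1.20, 3, 1.50, 4),    # on D's outward face
    N = rect_mp(1.55, 3, 1.80, 4)
  )
  compute_adjacency(region_map(names(g), geometry = g))
}

# uniform point inside a region's multipolygon (rejection sampling)
random_point_in <- function(mp) {
  v <- mp_vertices(mp)
  for (i in 1:1000) {
    x <- stats::runif(1, min(v[, 1]), max(v[, 1]))
    y <- stats::runif(1, min(v[, 2]), max(v[, 2]))
    if (point_in_rings(x, y, mp)) return(c(x, y))
  }
  mp_centroid(mp)
}

#' Generate a synthetic sensor network with time series
#'
#' Places `config$n_sites` sites uniformly inside distinct regions (cycling
#' when there are more sites than regions), assigns environment types, and
#' simulates each requested measurement as
#' `base + seasonal + diurnal + noise_sd * (sqrt(rho) Z + sqrt(1-rho) eps)`
#' with a shared hourly factor `Z` giving inter-site correlation `rho`.
#' Measurement kinds:
#'
#' * `"met"`: the signal as-is (can go negative, like temperature);
#' * `"pollutant"`: exponentiated signal, strictly positive and
#'   right-skewed; with `emep = TRUE` a model-forecast channel
#'   `<m>_EMEP = truth + bias + noise` is added;
#' * `"pollen"`: nonnegative daily counts, wholly missing outside the
#'   configured season window.
#'
#' Missingness (`config$missing_fraction`, `config$missing_mode`) is
#' injected per site after generation; the complete series are returned as
#' `truth`.
#'
#' @param map a `region_map` with geometries.
#' @param config a [synth_config()].
#' @param measurements names of the measurements to generate.
#' @param kinds `"met"`, `"pollutant"` or `"pollen"`, recycled over
#'   `measurements`.
#' @param emep add `<m>_EMEP` model-covariate channels for pollutant kinds?
#' @return list with `sites` (metadata incl. region assignment), `data`
#'   (readings with injected missingness), `truth` (complete readings) and
#'   `mask_removed` (logical data.frame of withheld points).
#' @export
make_sensor_network <- function(map, config = synth_config(),
                                measurements = "temperature",
                                kinds = "met", emep = FALSE) {
  set.seed(config$seed)
  kinds <- rep_len(kinds, length(measurements))
  pick <- rep_len(sample(map$region_id), config$n_sites)
  pts <- t(vapply(pick, function(r) random_point_in(map$geometry[[r]]), numeric(2)))
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(config$n_sites)),
    longitude = pts[, 1], latitude = pts[, 2],
    network = "WEATHER",
    environment_type = sample(c("industrial", "urban background",
                                "rural background", "urban traffic"),
                              config$n_sites, replace = TRUE),
    region_id = pick,
    stringsAsFactors = FALSE
  )
  start <- as.Date(config$start)
  if (config$hourly) {
    times <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
                 by = "hour", length.out = config$n_days * 24)
    hour <- as.numeric(format(times, "%H"))
  } else {
    times <- seq(start, by = "day", length.out = config$n_days)
    hour <- rep(12, length(times))
  }
  doy <- as.numeric(format(as.Date(format_timestamps(times)), "%j"))
  nt <- length(times)
  base <- config$base_level +
    config$seasonal_amp * sin(2 * pi * doy / 365.25) +
    config$diurnal_amp * sin(2 * pi * hour / 24)

  data <- truth <- data.frame(
    site_id = rep(sites$site_id, each = nt),
    timestamp = rep(times, config$n_sites),
    stringsAsFactors = FALSE
  )
  mask_removed <- data[c("site_id", "timestamp")]

  in_season <- function(tms) {
    md <- format(as.Date(format_timestamps(tms)), "%m-%d")
    md >= config$pollen_season[1] & md <= config$pollen_season[2]
  }

  for (mi in seq_along(measurements)) {
    m <- measurements[mi]
    z <- stats::rnorm(nt)
    col_truth <- col_emep <- numeric(0)
    for (s in seq_len(config$n_sites)) {
      eps <- stats::rnorm(nt)
      sig <- base + config$noise_sd *
        (sqrt(config$rho) * z + sqrt(1 - config$rho) * eps)
      v <- switch(kinds[mi],
        met = sig,
        pollutant = exp((sig - config$base_level) / (2 * config$noise_sd +
                          config$seasonal_amp + config$diurnal_amp)) *
                    config$base_level,
        pollen = {
          cnt <- round(pmax(sig - config$base_level / 2, 0))
          cnt[!in_season(times)] <- NA_real_
          cnt
        },
        stop("unknown kind: ", kinds[mi]))
      col_truth <- c(col_truth, v)
      if (emep && kinds[mi] == "pollutant") {
        col_emep <- c(col_emep, v + 2 + stats::rnorm(nt, sd = config$noise_sd / 2))
      }
    }
    truth[[m]] <- col_truth
    holed <- col_truth
    removed <- rep(FALSE, length(col_truth))
    if (config$missing_fraction > 0) {
      for (s in seq_len(config$n_sites)) {
        idx <- (s - 1) * nt + seq_len(nt)
        rm <- remove_data(col_truth[idx], config$missing_fraction,
                          config$missing_mode,
                          seed = config$seed + 31 * s + 7 * mi)
        holed[idx] <- rm$series
        removed[idx[rm$withheld]] <- TRUE
      }
    }
    data[[m]] <- holed
    mask_removed[[m]] <- removed
    if (emep && kinds[mi] == "pollutant") {
      data[[paste0(m, "_EMEP")]] <- truth[[paste0(m, "_EMEP")]] <- col_emep
    }
  }
  list(sites = sites, data = data, truth = truth, mask_removed = mask_removed)
}
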