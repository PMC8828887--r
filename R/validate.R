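#' Withhold data from a series under a removal scenario
#'
#' Removes exactly `floor(fraction * n_observed)` observed points, either at
#' random (seeded, reproducible) or as one contiguous block at the start,
#' middle or end of the observed part of the series. The middle block starts
#' at observed position `floor((n_observed - block) / 2)`.
#'
#' @param x numeric vector (may already contain missing values; only
#'   observed points are eligible for removal).
#' @param fraction fraction of observed points to withhold, in (0, 1).
#' @param mode `"random"`, `"start"`, `"middle"` or `"end"`.
#' @param seed RNG seed for random mode.
#' @return list with `series` (x with withheld points set missing),
#'   `withheld` (integer indices into `x`) and `truth` (withheld values).
#' @export
remove_data <- function(x, fraction, mode = c("random", "start", "middle", "end"),
                        seed = 42) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  obs_idx <- which(!is.na(x))
  n_rm <- floor(fraction * length(obs_idx))
  withheld <- if (n_rm == 0L) {
    integer()
  } else if (mode == "random") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    idx <- sort(sample(obs_idx, n_rm))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    idx
  } else {
    s <- switch(mode,
                start = 0L,
                end = length(obs_idx) - n_rm,
                middle = floor((length(obs_idx) - n_rm) / 2))
    obs_idx[(s + 1L):(s + n_rm)]
  }
  out <- x
  out[withheld] <- NA_real_
  list(series = out, withheld = withheld, truth = x[withheld])
}

#' Fit statistics between original and imputed values
#'
#' Spearman rank correlation and the ordinary-least-squares slope (with
#' intercept) of imputed values regressed on original values.
#'
#' @param original,imputed numeric vectors.
#' @param positions optional indices at which to evaluate; default: all
#'   positions where both are non-missing.
#' @return list with `spearman_rho`, `slope` and `n`; statistics are missing
#'   when `n < 3` or a series is constant.
#' @export
fit_stats <- function(original, imputed, positions = NULL) {
  if (!is.null(positions)) {
    original <- original[positions]
    imputed <- imputed[positions]
  }
  ok <- !is.na(original) & !is.na(imputed)
  o <- original[ok]; m <- imputed[ok]
  n <- length(o)
  if (n < 3 || stats::sd(o) == 0 || stats::sd(m) == 0) {
    return(list(spearman_rho = NA_real_,
                slope = if (n >= 3 && stats::sd(o) > 0)
                  unname(stats::coef(stats::lm(m ~ o))[2]) else NA_real_,
                n = n))
  }
  rho <- stats::cor(o, m, method = "spearman")
  slope <- unname(stats::coef(stats::lm(m ~ o))[2])
  list(spearman_rho = rho, slope = slope, n = n)
}

#' Data-removal imputation validation grid
#'
#' For each (site, measurement, fraction, mode) cell: withhold data from
#' that site's hourly series with [remove_data()], re-impute it from its
#' nearest reference sites with [iterative_impute()], and report
#' [fit_stats()] at three resolutions: hourly (withheld positions only) and
#' daily mean / daily max (over all days, so days mixing original and
#' imputed points are included).
#'
#' @param data hourly readings data.frame.
#' @param sites site metadata.
#' @param test_sites site ids to put through the removal scenarios.
#' @param measurements measurement columns to test.
#' @param fractions removal fractions (default 0.25 and 0.5).
#' @param modes removal modes (default random, start, end).
#' @param config an [imputation_config()].
#' @param seed base seed for the random scenarios.
#' @return data.frame with one row per (site, measurement, fraction, mode,
#'   resolution): `spearman_rho`, `slope`, `n`.
#' @export
scenario_grid <- function(data, sites, test_sites, measurements,
                          fractions = c(0.25, 0.5),
                          modes = c("random", "start", "end"),
                          config = imputation_config(), seed = 42) {
  times <- sort(unique(format_timestamps(data$timestamp)))
  day <- as_utc_day(parse_timestamps(times))
  rows <- list()
  for (m in measurements) {
    wide <- wide_series(data, m, times, sites$site_id)
    method <- transform_method_for(config, m)
    for (sid in test_sites) {
      x <- wide[, sid]
      others <- sites[sites$site_id != sid, , drop = FALSE]
      near <- nearest_references(sites[sites$site_id == sid, ], others,
                                 config$n_references)
      covars <- wide[, near, drop = FALSE]
      for (fr in fractions) {
        for (mode in modes) {
          holed <- remove_data(x, fr, mode, seed = seed + round(1000 * fr))
          res <- iterative_impute(holed$series, covars, config,
                                  methods = rep(method, length(near) + 1L))
          hr <- fit_stats(x, res$values, holed$withheld)
          dstat <- function(f) {
            fit_stats(tapply(x, day, f, na.rm = TRUE),
                      tapply(res$values, day, f, na.rm = TRUE))
          }
          stats_by_res <- list(hourly = hr, daily_mean = dstat(mean),
                               daily_max = dstat(max))
          for (res_name in names(stats_by_res)) {
            st <- stats_by_res[[res_name]]
            rows[[length(rows) + 1L]] <- data.frame(
              site_id = sid, measurement = m, fraction = fr, mode = mode,
              resolution = res_name, spearman_rho = st$spearman_rho,
              slope = st$slope, n = st$n, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Leave-one-sensor-out validation of regional estimation
#'
#' Every (site, timestamp) observation is compared with the
#' concentric-regions estimate for the site's region computed as if that
#' sensor were missing. Differences are sensor minus estimate; observations
#' whose exclusion leaves no estimable value (e.g. the only sensor on the
#' map) are skipped.
#'
#' @inheritParams estimate_region
#' @return list with `diffs` (one row per usable observation: observed,
#'   estimated, rings, diff) and `summary` (count, mean, std and adjusted
#'   Fisher-Pearson skew of the differences).
#' @export
loo_region_diffs <- function(map, sites, data, measurement) {
  tc <- ts_col(data)
  if (!measurement %in% names(data)) stop("unknown measurement: ", measurement)
  stamps <- sort(unique(format_timestamps(data[[tc]])))
  site_region <- stats::setNames(sites$region_id, sites$site_id)
  dist_cache <- new.env(parent = emptyenv())
  dists <- function(r) {
    if (is.null(dist_cache[[r]])) dist_cache[[r]] <- ring_distances(map, r)
    dist_cache[[r]]
  }
  rows <- list()
  for (ts in stamps) {
    sel <- format_timestamps(data[[tc]]) == ts & !is.na(data[[measurement]])
    obs <- data[sel, c("site_id", measurement)]
    reg <- site_region[obs$site_id]
    keep <- !is.na(reg)
    obs <- obs[keep, , drop = FALSE]; reg <- reg[keep]
    if (!nrow(obs)) next
    vals <- split(obs[[measurement]], reg)
    for (i in seq_len(nrow(obs))) {
      r <- reg[i]
      v <- obs[[measurement]][i]
      loo_vals <- vals
      left <- loo_vals[[r]][-match(v, loo_vals[[r]])]
      if (length(left)) loo_vals[[r]] <- left else loo_vals[[r]] <- NULL
      d <- dists(r)
      have <- intersect(names(loo_vals), names(d)[!is.na(d)])
      if (!length(have)) next
      k <- min(d[have])
      contrib <- unlist(loo_vals[have[d[have] == k]], use.names = FALSE)
      est <- mean(contrib)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = obs$site_id[i], region_id = r, time_stamp = ts,
        observed = v, estimated = est, rings = as.integer(k),
        diff = v - est, stringsAsFactors = FALSE)
    }
  }
  diffs <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
           else data.frame(site_id = character(), region_id = character(),
                           time_stamp = character(), observed = numeric(),
                           estimated = numeric(), rings = integer(),
                           diff = numeric())
  summary <- data.frame(
    measurement = measurement,
    count = nrow(diffs),
    mean = if (nrow(diffs)) mean(diffs$diff) else NA_real_,
    std = if (nrow(diffs) > 1) stats::sd(diffs$diff) else NA_real_,
    skew = if (nrow(diffs) > 2) e1071::skewness(diffs$diff, type = 2) else NA_real_)
  list(diffs = diffs, summary = summary)
}
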