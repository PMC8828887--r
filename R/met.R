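#' Saturation vapour pressure over water
#'
#' Magnus-type approximation in the Bolton (1980) form,
#' \eqn{e_s(t) = 6.112 \exp(17.67 t / (t + 243.5))} with `t` in degrees
#' Celsius and the result in hPa. Accurate to within 0.3% over -35..35 C.
#'
#' @param t air or dewpoint temperature in degrees C, in \[-60, 60\].
#' @return saturation vapour pressure in hPa.
#' @examples
#' saturation_vapour_pressure(0)   # 6.112
#' @export
saturation_vapour_pressure <- function(t) {
  if (any(!is.na(t) & (t < -60 | t > 60))) {
    stop("temperature out of supported range [-60, 60] degC")
  }
  6.112 * exp(17.67 * t / (t + 243.5))
}

#' Relative humidity from air and dewpoint temperature
#'
#' RH is the ratio of actual to saturation vapour pressure,
#' \eqn{100 \, e_s(t_d) / e_s(t)}. Both temperatures are required; a missing
#' one yields a missing RH. A dewpoint above the air temperature produces
#' RH > 100, which is returned as-is (the `flagged` attribute marks such
#' points) so that suspect sensors remain visible downstream.
#'
#' @param t air temperature, degrees C (vectorised).
#' @param td dewpoint temperature, degrees C.
#' @return relative humidity in percent, with attribute `flagged`: logical
#'   vector, `TRUE` where `td > t`.
#' @export
relative_humidity <- function(t, td) {
  rh <- 100 * saturation_vapour_pressure(td) / saturation_vapour_pressure(t)
  flagged <- !is.na(t) & !is.na(td) & td > t
  if (any(flagged)) {
    warning(sum(flagged), " points with dewpoint above air temperature (RH > 100)")
  }
  attr(rh, "flagged") <- flagged
  rh
}

#' Aggregate hourly series to daily mean/max with imputed-fraction flags
#'
#' For every site, UTC calendar day and measurement: the mean and maximum
#' over non-missing hourly points, plus a flag giving the fraction of the
#' points used that were imputed rather than observed (0 = all observed,
#' 1 = fully imputed). Days with no points get missing mean/max/flag.
#' Partial days at the ends of a series aggregate over whatever points exist.
#'
#' @param data hourly readings data.frame (`site_id`, `timestamp`,
#'   measurement columns).
#' @param mask optional logical data.frame aligned with `data` (same rows,
#'   same measurement columns): `TRUE` where a point was imputed. Missing
#'   mask means nothing was imputed.
#' @param measurements columns to aggregate; defaults to all numeric ones.
#' @return data.frame with `site_id`, `time_stamp` (Date) and
#'   `<m>_mean`, `<m>_max`, `<m>_flag` columns, sorted by (time_stamp,
#'   site_id).
#' @export
daily_aggregate <- function(data, mask = NULL, measurements = NULL) {
  if (is.null(measurements)) {
    measurements <- setdiff(names(data), c("site_id", "timestamp"))
    measurements <- measurements[vapply(data[measurements], is.numeric, logical(1))]
  }
  day <- as_utc_day(data$timestamp)
  key <- data.frame(site_id = data$site_id, time_stamp = day,
                    stringsAsFactors = FALSE)
  groups <- unique(key)
  groups <- groups[order(groups$time_stamp, groups$site_id), , drop = FALSE]
  gid <- match(paste(key$site_id, key$time_stamp),
               paste(groups$site_id, groups$time_stamp))
  out <- groups
  rownames(out) <- NULL
  for (m in measurements) {
    v <- data[[m]]
    imp <- if (!is.null(mask) && m %in% names(mask)) mask[[m]] else rep(FALSE, length(v))
    imp[is.na(imp)] <- FALSE
    ok <- !is.na(v)
    n <- tapply(ok, gid, sum)
    idx <- as.integer(names(n))
    mean_v <- max_v <- flag_v <- rep(NA_real_, nrow(out))
    sums <- tapply(ifelse(ok, v, 0), gid, sum)
    maxs <- tapply(ifelse(ok, v, -Inf), gid, max)
    nimp <- tapply(ok & imp, gid, sum)
    has <- n > 0
    mean_v[idx[has]] <- sums[has] / n[has]
    max_v[idx[has]] <- maxs[has]
    flag_v[idx[has]] <- nimp[has] / n[has]
    out[[paste0(m, "_mean")]] <- mean_v
    out[[paste0(m, "_max")]] <- max_v
    out[[paste0(m, "_flag")]] <- flag_v
  }
  out
}
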