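#' Deterministic cleaning rules for raw sensor series
#'
#' Readings are long-by-site, wide-by-measurement data.frames with columns
#' `site_id`, `timestamp` (POSIXct UTC or dates) and one numeric column per
#' measurement. All rules are idempotent and never invent values: they only
#' turn observed values into missing ones or drop rows/sites.
#'
#' @name cleaning
NULL

# calendar day (UTC) of a timestamp column
as_utc_day <- function(ts) {
  if (inherits(ts, "Date")) return(ts)
  if (is.character(ts)) ts <- parse_timestamps(ts)
  as.Date(ts, tz = "UTC")
}

#' Replace nonpositive pollutant values with missing
#'
#' Pollutant concentrations (ug m-3) that are zero or negative are
#' nonphysical and are blanked out.
#'
#' @param data readings data.frame.
#' @param measurements columns to clean; defaults to every numeric
#'   measurement column.
#' @return list with `data` (cleaned) and `report` (per site/measurement
#'   removal counts).
#' @export
clean_pollutants <- function(data, measurements = NULL) {
  if (is.null(measurements)) {
    measurements <- setdiff(names(data), c("site_id", "timestamp"))
    measurements <- measurements[vapply(data[measurements], is.numeric, logical(1))]
  }
  rep_rows <- list()
  for (m in measurements) {
    bad <- !is.na(data[[m]]) & data[[m]] <= 0
    if (any(bad)) {
      counts <- table(data$site_id[bad])
      rep_rows[[m]] <- data.frame(site_id = names(counts), measurement = m,
                                  n_removed = as.integer(counts),
                                  stringsAsFactors = FALSE)
      data[[m]][bad] <- NA_real_
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, c(rep_rows, make.row.names = FALSE))
            else data.frame(site_id = character(), measurement = character(),
                            n_removed = integer())
  list(data = data, report = report)
}

#' Resolve duplicated meteorological readings
#'
#' Co-located networks can report the same (site, timestamp) twice. Per
#' duplicate group, the first row carrying a pressure value is kept; when no
#' row (or every row) has pressure, the first row in file order is kept.
#'
#' @param readings data.frame with `site_id`, `timestamp` and a `pressure`
#'   column (possibly all-`NA`).
#' @return readings with unique (site, timestamp) keys, in file order.
#' @export
dedupe_met_readings <- function(readings) {
  key <- paste(readings$site_id, format_timestamps(readings$timestamp), sep = "\r")
  has_p <- if ("pressure" %in% names(readings)) !is.na(readings$pressure)
           else rep(FALSE, nrow(readings))
  keep <- !duplicated(key)  # default: first in file order
  dup_keys <- unique(key[duplicated(key)])
  for (kk in dup_keys) {
    idx <- which(key == kk)
    pick <- if (any(has_p[idx])) idx[has_p[idx]][1] else idx[1]
    keep[idx] <- FALSE
    keep[pick] <- TRUE
  }
  readings[keep, , drop = FALSE]
}

#' Drop sites that only ever take one reading per day
#'
#' Synoptic spot-reading stations report a single temperature value per day
#' and carry no information about diurnal variability, so they are removed
#' before hourly imputation. A site is dropped iff every day on which it
#' reports temperature has exactly one temperature measurement.
#'
#' @param data readings data.frame with a `temperature` column.
#' @return list with `data` (spot sites removed) and `dropped` (site ids).
#' @export
drop_spot_sites <- function(data, measurement = "temperature") {
  if (!measurement %in% names(data)) stop("no '", measurement, "' column in data")
  obs <- !is.na(data[[measurement]])
  dropped <- character()
  for (sid in unique(data$site_id)) {
    sel <- data$site_id == sid & obs
    if (!any(sel)) next
    per_day <- table(as_utc_day(data$timestamp[sel]))
    if (all(per_day == 1L)) dropped <- c(dropped, sid)
  }
  list(data = data[!data$site_id %in% dropped, , drop = FALSE], dropped = dropped)
}

#' Site blacklist and temperature-floor filters
#'
#' Blacklisted sites (e.g. stations with systematically suspect humidity)
#' are removed wholesale. Any reading whose temperature is strictly below
#' `temp_floor` has all its meteorological values set to missing: a frozen
#' or faulty sensor taints the whole record.
#'
#' @param data readings data.frame.
#' @param blacklist site ids to remove entirely.
#' @param temp_floor temperature floor in degrees C (default -20; the rule is
#'   strictly "lower than", so a reading at exactly the floor is kept).
#' @param met_vars measurement columns blanked by the floor rule.
#' @return filtered readings data.frame.
#' @export
apply_filters <- function(data, blacklist = character(), temp_floor = -20,
                          met_vars = c("temperature", "dewpoint", "pressure")) {
  data <- data[!data$site_id %in% blacklist, , drop = FALSE]
  if ("temperature" %in% names(data)) {
    cold <- !is.na(data$temperature) & data$temperature < temp_floor
    for (v in intersect(met_vars, names(data))) data[[v]][cold] <- NA_real_
  }
  data
}

#' Coverage criteria for retained and reference sites
#'
#' Coverage of a (site, measurement) pair is the number of distinct days
#' with at least one non-missing point. Sites need two years of coverage
#' (730 days, with a 365.25-day year) to be retained for imputation, and
#' 3.5 years (1278 days) to serve as imputation reference stations.
#'
#' @param retain_days minimum coverage (days) to retain a site.
#' @param reference_days minimum coverage (days) for a reference site.
#' @return an object of class `coverage_criteria`.
#' @export
coverage_criteria <- function(retain_days = 730, reference_days = 1278) {
  stopifnot(retain_days > 0, reference_days >= retain_days)
  structure(list(retain_days = retain_days, reference_days = reference_days),
            class = "coverage_criteria")
}

#' Select retained and reference sites by coverage
#'
#' @param data readings data.frame.
#' @param measurements measurement columns to assess.
#' @param criteria a [coverage_criteria()] object.
#' @return list with `coverage` (site x measurement day counts), `retained`
#'   (named list: per measurement, site ids meeting `retain_days`) and
#'   `reference` (site ids meeting `reference_days` on every measurement).
#' @export
select_sites <- function(data, measurements = NULL,
                         criteria = coverage_criteria()) {
  stopifnot(inherits(criteria, "coverage_criteria"))
  if (is.null(measurements)) {
    measurements <- setdiff(names(data), c("site_id", "timestamp"))
    measurements <- measurements[vapply(data[measurements], is.numeric, logical(1))]
  }
  day <- as_utc_day(data$timestamp)
  sites <- unique(data$site_id)
  cov <- expand.grid(site_id = sites, measurement = measurements,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cov$days <- mapply(function(sid, m) {
    sel <- data$site_id == sid & !is.na(data[[m]])
    length(unique(day[sel]))
  }, cov$site_id, cov$measurement)
  cov$retained <- cov$days >= criteria$retain_days
  cov$reference <- cov$days >= criteria$reference_days
  retained <- lapply(split(cov, cov$measurement),
                     function(d) d$site_id[d$retained])
  ref_ok <- tapply(cov$reference, cov$site_id, all)
  list(coverage = cov,
       retained = retained[measurements],
       reference = sort(names(ref_ok)[ref_ok]))
}
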