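# CSV readers/writers for the daily-dataset and regional-estimates schemas,
# plus timestamp canonicalisation shared across modules.

#' Parse timestamp strings
#'
#' Accepts ISO-8601 date (`2016-03-01`) and datetime (`2016-03-01 13:00:00`,
#' `2016-03-01T13:00:00`) forms, always interpreted as UTC. Date-only input
#' yields `Date`, otherwise `POSIXct`.
#'
#' @param x character vector (or already-parsed Date/POSIXct, returned
#'   unchanged).
#' @return Date or POSIXct vector.
#' @export
parse_timestamps <- function(x) {
  if (inherits(x, "Date") || inherits(x, "POSIXct")) return(x)
  x <- trimws(as.character(x))
  if (all(is.na(x) | grepl("^\\d{4}-\\d{2}-\\d{2}$", x))) {
    return(as.Date(x))
  }
  x <- sub("T", " ", x, fixed = TRUE)
  out <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")),
    error = function(e) stop("unparseable timestamps: ",
                             paste(utils::head(x[!is.na(x)], 3), collapse = ", "),
                             call. = FALSE))
  if (anyNA(out) && !all(is.na(x) == is.na(out))) {
    bad <- x[is.na(out) & !is.na(x)]
    stop("unparseable timestamps: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  out
}

# canonical string form used for joining/grouping timestamps
format_timestamps <- function(x) {
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  if (inherits(x, "POSIXct")) return(format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  trimws(as.character(x))
}

#' Read a daily (or hourly) measurement dataset
#'
#' Expects index columns `time_stamp` and `site_id` plus measurement value
#' columns following the `<var>_mean` / `<var>_max` / `<var>_flag`
#' convention. Network tags in `site_id` (`[AQ]`, `[WEATHER]`, `[POLLEN]`)
#' are parsed into a `network` column. Value columns without a matching
#' `_flag` column are readable; their flags are treated as missing, with a
#' warning.
#'
#' @param path CSV file path.
#' @return data.frame with `time_stamp`, `site_id`, `network` and value
#'   columns.
#' @export
read_daily_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("time_stamp", "site_id"), names(df))
  if (length(missing)) {
    stop("malformed daily dataset ", path, ": missing columns ",
         paste(missing, collapse = ", "))
  }
  df$time_stamp <- parse_timestamps(df$time_stamp)
  tags <- parse_site_tag(as.character(df$site_id))
  df$site_id <- tags$site_id
  if (!"network" %in% names(df)) df$network <- tags$network
  bases <- unique(sub("_(mean|max)$", "",
                      grep("_(mean|max)$", names(df), value = TRUE)))
  bases <- bases[!startsWith(bases, "rings_")]
  noflag <- bases[!paste0(bases, "_flag") %in% names(df)]
  if (length(noflag)) {
    warning("no _flag columns for: ", paste(noflag, collapse = ", "),
            "; flags treated as missing")
    for (b in noflag) df[[paste0(b, "_flag")]] <- NA_real_
  }
  df
}

#' Write a daily dataset CSV
#'
#' Emits deterministic output: rows sorted by (time_stamp, site_id), index
#' columns first. When a `network` column is present the site id is written
#' with its network tag (`"MAN3 [AQ]"`).
#'
#' @param daily data.frame with `time_stamp`, `site_id` and value columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_dataset <- function(daily, path) {
  out <- daily[order(format_timestamps(daily$time_stamp), daily$site_id), ,
               drop = FALSE]
  if ("network" %in% names(out)) {
    tagged <- !is.na(out$network)
    out$site_id[tagged] <- paste0(out$site_id[tagged], " [", out$network[tagged], "]")
    out$network <- NULL
  }
  out$time_stamp <- format_timestamps(out$time_stamp)
  idx <- c("time_stamp", "site_id")
  out <- out[c(idx, setdiff(names(out), idx))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write and read regional-estimates CSVs
#'
#' Regional estimates are indexed by `time_stamp` and `region_id`, with one
#' column per estimated measurement and matching `rings_<measurement>`
#' columns. Rows are written sorted by (time_stamp, region_id).
#'
#' @param estimates data.frame from [estimate_all()] or
#'   [estimate_stratified()].
#' @param path CSV file path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_estimates <- function(estimates, path) {
  out <- estimates[order(format_timestamps(estimates$time_stamp),
                         estimates$region_id), , drop = FALSE]
  out$time_stamp <- format_timestamps(out$time_stamp)
  idx <- c("time_stamp", "region_id")
  out <- out[c(idx, setdiff(names(out), idx))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("time_stamp", "region_id"), names(df))
  if (length(missing)) {
    stop("malformed estimates file ", path, ": missing columns ",
         paste(missing, collapse = ", "))
  }
  df$time_stamp <- parse_timestamps(df$time_stamp)
  df
}

#' Read/write hourly readings with an optional imputation mask
#'
#' Hourly readings are stored as `site_id`, `timestamp`, one column per
#' measurement; the imputation mask is a parallel CSV of logicals with the
#' same layout.
#'
#' @param path readings CSV path.
#' @param mask_path optional mask CSV path.
#' @return list with `data` (and `mask` when requested).
#' @export
read_hourly_dataset <- function(path, mask_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("site_id", "timestamp"), names(df))
  if (length(missing)) {
    stop("malformed hourly dataset ", path, ": missing columns ",
         paste(missing, collapse = ", "))
  }
  df$timestamp <- parse_timestamps(df$timestamp)
  out <- list(data = df)
  if (!is.null(mask_path)) {
    mk <- utils::read.csv(mask_path, stringsAsFactors = FALSE, check.names = FALSE)
    mk$timestamp <- parse_timestamps(mk$timestamp)
    out$mask <- mk
  }
  out
}

#' @rdname read_hourly_dataset
#' @param data hourly readings data.frame.
#' @param mask optional aligned logical data.frame.
#' @export
write_hourly_dataset <- function(data, path, mask = NULL, mask_path = NULL) {
  out <- data[order(format_timestamps(data$timestamp), data$site_id), ,
              drop = FALSE]
  ord <- order(format_timestamps(data$timestamp), data$site_id)
  out$timestamp <- format_timestamps(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(mask) && !is.null(mask_path)) {
    mk <- mask[ord, , drop = FALSE]
    mk$timestamp <- format_timestamps(mk$timestamp)
    utils::write.csv(mk, mask_path, row.names = FALSE)
  }
  invisible(path)
}
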