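# Site metadata handling: network tags, region assignment, nearest references.

#' Abbreviations for site environment types
#'
#' Maps the monitoring-network environment classes to the column-header
#' abbreviations used in stratified regional estimates: industrial `Ind`,
#' urban background `UB`, rural background `RB`, urban traffic `UT`.
#'
#' @export
SITE_TYPE_ABBREV <- c(
  "industrial"       = "Ind",
  "urban background" = "UB",
  "rural background" = "RB",
  "urban traffic"    = "UT",
  "other"            = "Other"
)

#' Split a tagged site id into id and network
#'
#' Published site ids carry the source network in a suffix tag: `[AQ]` for
#' air-quality stations, `[WEATHER]` for meteorological stations, `[POLLEN]`
#' for pollen traps (e.g. `"MAN3 [AQ]"`).
#'
#' @param site_id character vector of possibly tagged ids.
#' @return data.frame with columns `site_id` (tag stripped) and `network`
#'   (`NA` where untagged).
#' @export
parse_site_tag <- function(site_id) {
  m <- regmatches(site_id, regexec("^\\s*(.*?)\\s*\\[([A-Z]+)\\]\\s*$", site_id))
  data.frame(
    site_id = vapply(seq_along(site_id), function(i) {
      if (length(m[[i]])) m[[i]][2] else trimws(site_id[i])
    }, character(1)),
    network = vapply(seq_along(site_id), function(i) {
      if (length(m[[i]])) m[[i]][3] else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Read site metadata from CSV
#'
#' Expects columns `site_id`, `longitude`, `latitude`, and optionally
#' `environment_type` and `network`. Network tags embedded in `site_id`
#' (e.g. `"MAN3 [AQ]"`) are parsed into the `network` column.
#'
#' @param path CSV file path.
#' @return data.frame of site metadata.
#' @export
read_site_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site_id", "longitude", "latitude")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("site metadata missing columns: ", paste(missing, collapse = ", "))
  tags <- parse_site_tag(as.character(df$site_id))
  df$site_id <- tags$site_id
  if (!"network" %in% names(df)) df$network <- tags$network
  else df$network[is.na(df$network)] <- tags$network[is.na(df$network)]
  if (!"environment_type" %in% names(df)) df$environment_type <- "other"
  bad <- which(abs(df$longitude) > 180 | abs(df$latitude) > 90)
  if (length(bad)) stop("coordinates out of range for sites: ",
                        paste(df$site_id[bad], collapse = ", "))
  df
}

#' Write site metadata to CSV
#'
#' @param sites site metadata data.frame.
#' @param path output CSV path.
#' @param tag_network if `TRUE`, re-embed the network tag in `site_id`.
#' @return `path`, invisibly.
#' @export
write_site_metadata <- function(sites, path, tag_network = FALSE) {
  out <- sites
  if (tag_network && "network" %in% names(out)) {
    tagged <- !is.na(out$network)
    out$site_id[tagged] <- paste0(out$site_id[tagged], " [", out$network[tagged], "]")
    out$network <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assign monitoring sites to regions by point-in-polygon
#'
#' Each site gets the `region_id` whose multipolygon contains its coordinates
#' (boundary points count as inside; with overlapping regions the first
#' containing region in map order wins). Sites outside every region get
#' `NA` and a warning, and are ignored by the regional estimators.
#'
#' @param sites site metadata data.frame with `longitude`/`latitude`.
#' @param map a `region_map` with geometries.
#' @return `sites` with a `region_id` column.
#' @export
assign_sites_to_regions <- function(sites, map) {
  stopifnot(inherits(map, "region_map"))
  if (is.null(map$geometry)) stop("map has no geometries for point-in-polygon assignment")
  ids <- map$region_id
  region <- rep(NA_character_, nrow(sites))
  for (id in ids) {
    g <- map$geometry[[id]]
    if (is.null(g)) next
    open <- is.na(region)
    if (!any(open)) break
    hit <- point_in_multipolygon(sites$longitude[open], sites$latitude[open], g)
    region[which(open)[hit]] <- id
  }
  if (anyNA(region)) {
    warning("sites outside all regions (excluded from estimation): ",
            paste(sites$site_id[is.na(region)], collapse = ", "))
  }
  sites$region_id <- region
  sites
}

#' Nearest reference sites by great-circle distance
#'
#' Orders candidate reference sites by ascending haversine distance from a
#' target site (ties broken by site id) and returns the closest `k`.
#'
#' @param site a single-row site data.frame (or list) with
#'   `longitude`/`latitude`.
#' @param references site metadata data.frame of candidate reference sites.
#' @param k number of references to return (default 5).
#' @return character vector of `k` reference site ids, nearest first.
#' @export
nearest_references <- function(site, references, k = 5) {
  if (is.null(references) || nrow(references) == 0) stop("no reference sites available")
  k <- min(k, nrow(references))
  d <- haversine_km(site$longitude, site$latitude,
                    references$longitude, references$latitude)
  ord <- order(d, references$site_id)
  references$site_id[ord][seq_len(k)]
}
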