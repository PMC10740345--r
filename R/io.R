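## CSV / GeoJSON readers and writers. Telemetry CSV columns: individual_id,
## species, timestamp, lat, lon, loc_class, smaj_m, smin_m, eor_deg.
## Resighting CSV columns: individual_id, species, date, site_id, site_lat,
## site_lon. Site CSV column order is fixed (see writeSites).

.parseTimestamps <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read a telemetry CSV into a TrackSet
#'
#' Fixes are grouped by individual and sorted by time. Rows duplicating an
#' (individual, timestamp) pair are collapsed to the one with the best
#' location class (3 > 2 > 1 > 0 > A > B > Z; ties keep the first row in
#' file order).
#'
#' @param path CSV file with header; timestamps ISO-8601 (UTC assumed).
#' @return a \code{\link{TrackSet}}.
#' @export
readTracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "species", "timestamp", "lat", "lon",
           "loc_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("telemetry CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("smaj_m", "smin_m", "eor_deg"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (nrow(df) == 0) return(TrackSet(list()))
  ts <- .parseTimestamps(df$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp at data row(s): ",
         paste(head(which(is.na(ts)), 5), collapse = ", "))
  cls <- trimws(as.character(df$loc_class))
  bad <- !(cls %in% .LOC_CLASSES)
  if (any(bad))
    stop("invalid location class at data row(s): ",
         paste(head(which(bad), 5), collapse = ", "))
  df$timestamp <- ts
  df$loc_class <- cls
  tracks <- lapply(split(seq_len(nrow(df)), df$individual_id), function(ix) {
    sub <- df[ix, , drop = FALSE]
    ## stable order by (time, class rank, file order) then keep first per time
    o <- order(sub$timestamp, .CLASS_RANK[sub$loc_class], seq_len(nrow(sub)))
    sub <- sub[o, , drop = FALSE]
    dup <- duplicated(sub$timestamp)
    if (any(dup)) {
      message(sum(dup), " duplicate-timestamp fix(es) dropped for ",
              sub$individual_id[1], " (kept best location class)")
      sub <- sub[!dup, , drop = FALSE]
    }
    Track(individualId = sub$individual_id[1], species = sub$species[1],
          fixes = data.frame(timestamp = sub$timestamp, lat = sub$lat,
                             lon = sub$lon, locClass = sub$loc_class,
                             smajM = as.numeric(sub$smaj_m),
                             sminM = as.numeric(sub$smin_m),
                             eorDeg = as.numeric(sub$eor_deg)))
  })
  TrackSet(unname(tracks))
}

#' Write a TrackSet to a telemetry CSV
#' @param tracks a \code{\link{TrackSet}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTracksCsv <- function(tracks, path) {
  rows <- lapply(trackList(tracks), function(t) {
    fx <- fixes(t)
    data.frame(individual_id = individualId(t), species = speciesOf(t),
               timestamp = format(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
               lat = round(fx$lat, 6), lon = round(fx$lon, 6),
               loc_class = fx$locClass, smaj_m = fx$smajM,
               smin_m = fx$sminM, eor_deg = fx$eorDeg)
  })
  out <- .rbindRows(rows)
  if (is.null(out))
    out <- data.frame(individual_id = character(), species = character(),
                      timestamp = character(), lat = numeric(),
                      lon = numeric(), loc_class = character(),
                      smaj_m = numeric(), smin_m = numeric(),
                      eor_deg = numeric())
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a resighting CSV
#'
#' Duplicate (individual, site, date) rows are collapsed. Records lacking a
#' site id get one synthesised from coordinates rounded to
#' \code{cfg$resightSiteRoundDeg} (default 0.25 degrees, ~27 km), which is
#' stable under write/read round trips.
#'
#' @param path CSV with columns individual_id, species, date, site_id,
#'   site_lat, site_lon (site_id may be empty).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return data.frame with columns \code{individual_id}, \code{species},
#'   \code{date} (Date), \code{site_id}, \code{site_lat}, \code{site_lon}.
#' @export
readResightings <- function(path, cfg = pipelineConfig()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "species", "date", "site_lat", "site_lon")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("resighting CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$site_id)) df$site_id <- NA_character_
  if (nrow(df) == 0) {
    df$date <- as.Date(character())
    return(df[c("individual_id", "species", "date", "site_id",
                "site_lat", "site_lon")])
  }
  d <- as.Date(as.character(df$date))
  if (anyNA(d))
    stop("unparseable date at data row(s): ",
         paste(head(which(is.na(d)), 5), collapse = ", "))
  df$date <- d
  df$site_lon <- normalizeLon(df$site_lon)
  noId <- is.na(df$site_id) | trimws(as.character(df$site_id)) == ""
  if (any(noId))
    df$site_id[noId] <- syntheticSiteId(df$site_lat[noId], df$site_lon[noId],
                                        cfg$resightSiteRoundDeg)
  df <- df[!duplicated(df[c("individual_id", "site_id", "date")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[c("individual_id", "species", "date", "site_id", "site_lat",
       "site_lon")]
}

#' Synthesise a site id from rounded coordinates
#' @param lat,lon coordinates.
#' @param roundDeg rounding grid in degrees.
#' @return character vector of ids like \code{"s-18.00_122.25"}.
#' @export
syntheticSiteId <- function(lat, lon, roundDeg = 0.25) {
  sprintf("s%.2f_%.2f", round(lat / roundDeg) * roundDeg,
          round(lon / roundDeg) * roundDeg)
}


#' Write stopover sites to CSV or GeoJSON
#'
#' CSV column order is fixed: site_id, individual_id, species, season, year,
#' centroid_lat, centroid_lon, n_locs, first_time, last_time, arrival_time,
#' departure_time (coordinates at 6 decimal places). GeoJSON (RFC 7946)
#' writes one Point feature per site with the non-coordinate fields as
#' properties.
#'
#' @param sites site data.frame as produced by \code{\link{buildItinerary}}.
#' @param path output path.
#' @param format \code{"csv"} or \code{"geojson"}.
#' @return \code{path}, invisibly.
#' @export
writeSites <- function(sites, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  sites <- as.data.frame(sites)
  fmtT <- function(x) ifelse(is.na(x), "",
                             format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  if (format == "csv") {
    out <- data.frame(site_id = as.character(sites$siteId),
                      individual_id = as.character(sites$individualId),
                      species = as.character(sites$species),
                      season = as.character(sites$season),
                      year = as.integer(sites$year),
                      centroid_lat = round(sites$centroidLat, 6),
                      centroid_lon = round(sites$centroidLon, 6),
                      n_locs = as.integer(sites$nLocs),
                      first_time = fmtT(sites$firstTime),
                      last_time = fmtT(sites$lastTime),
                      arrival_time = fmtT(sites$arrivalTime),
                      departure_time = fmtT(sites$departureTime))
    if (nrow(sites) == 0) out <- out[0, , drop = FALSE]
    write.csv(out, path, row.names = FALSE)
  } else {
    features <- lapply(seq_len(nrow(sites)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(round(sites$centroidLon[i], 6),
                                           round(sites$centroidLat[i], 6))),
           properties = list(site_id = sites$siteId[i],
                             individual_id = sites$individualId[i],
                             species = sites$species[i],
                             season = sites$season[i],
                             year = as.integer(sites$year[i]),
                             n_locs = as.integer(sites$nLocs[i]),
                             arrival = fmtT(sites$arrivalTime[i]),
                             departure = fmtT(sites$departureTime[i])))
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Read a site CSV written by \code{\link{writeSites}}
#' @param path CSV path.
#' @return site data.frame in the internal column naming.
#' @export
readSitesCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(site_id = "character"))
  parseT <- function(x) {
    out <- .parseTimestamps(x)
    out[trimws(as.character(x)) == ""] <- NA
    out
  }
  data.frame(siteId = df$site_id, individualId = df$individual_id,
             species = df$species, season = df$season, year = df$year,
             centroidLat = df$centroid_lat, centroidLon = df$centroid_lon,
             nLocs = df$n_locs,
             firstTime = parseT(df$first_time),
             lastTime = parseT(df$last_time),
             arrivalTime = parseT(df$arrival_time),
             departureTime = parseT(df$departure_time))
}
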