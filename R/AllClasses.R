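## Central S4 containers: a Track (one individual's time-ordered Argos fixes)
## and a TrackSet (a named collection of Tracks).

.LOC_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")
.STANDARD_CLASSES <- c("3", "2", "1")
## rank 1 = best; used when collapsing duplicate timestamps
.CLASS_RANK <- setNames(seq_along(.LOC_CLASSES), .LOC_CLASSES)

.FIX_COLUMNS <- c("timestamp", "lat", "lon", "locClass",
                  "smajM", "sminM", "eorDeg")

#' @rdname Track-class
#' @export
setClass("Track",
         representation(individualId = "character",
                        species = "character",
                        releaseTime = "POSIXct",
                        fixes = "data.frame"))

setValidity("Track", function(object) {
  msgs <- character(0)
  if (length(object@individualId) != 1L)
    msgs <- c(msgs, "individualId must be a single string")
  if (length(object@species) != 1L)
    msgs <- c(msgs, "species must be a single string")
  fx <- object@fixes
  missing_cols <- setdiff(.FIX_COLUMNS, names(fx))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("fixes lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  if (!length(msgs) && nrow(fx)) {
    if (any(diff(as.numeric(fx$timestamp)) <= 0))
      msgs <- c(msgs, "fix timestamps must be strictly increasing")
    if (any(fx$lat < -90 | fx$lat > 90, na.rm = TRUE))
      msgs <- c(msgs, "lat out of [-90, 90]")
    if (!all(fx$locClass %in% .LOC_CLASSES))
      msgs <- c(msgs, paste0("locClass values must be in {",
                             paste(.LOC_CLASSES, collapse = ", "), "}"))
    both <- !is.na(fx$smajM) & !is.na(fx$sminM)
    if (any(both & (fx$sminM > fx$smajM | fx$sminM < 0)))
      msgs <- c(msgs, "error ellipse requires smajM >= sminM >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Track: time-ordered Argos fixes for one individual
#'
#' A \code{Track} holds the satellite fixes of a single tagged bird, sorted
#' strictly by time, together with its species label and release time. The
#' fix table has columns \code{timestamp} (POSIXct, UTC), \code{lat},
#' \code{lon} (WGS84 decimal degrees, longitude normalised to (-180, 180]),
#' \code{locClass} (Argos class, one of 3/2/1/0/A/B/Z), and the optional
#' error-ellipse columns \code{smajM}, \code{sminM} (metres) and
#' \code{eorDeg} (orientation, degrees clockwise from north). Smoothed
#' tracks additionally carry \code{fittedLat}, \code{fittedLon} and
#' \code{fittedVarKm2}.
#'
#' @param individualId single string identifying the bird.
#' @param species species code, e.g. \code{"BTG"} or \code{"GK"}.
#' @param fixes data.frame of fixes (see Details); rows are sorted by time
#'   and longitudes normalised on construction.
#' @param releaseTime POSIXct release instant; defaults to the first fix.
#'
#' @return A \code{Track} object.
#' @examples
#' fx <- data.frame(timestamp = as.POSIXct("2015-10-01 00:00", tz = "UTC") +
#'                    3600 * (0:2),
#'                  lat = c(-18, -18.01, -18.02), lon = 122.3,
#'                  locClass = "3", smajM = NA, sminM = NA, eorDeg = NA)
#' tr <- Track("bird1", "GK", fx)
#' nFixes(tr)
#' @aliases Track-class
#' @export
Track <- function(individualId, species, fixes, releaseTime = NULL) {
  fixes <- as.data.frame(fixes)
  for (col in c("smajM", "sminM", "eorDeg"))
    if (is.null(fixes[[col]])) fixes[[col]] <- NA_real_
  fixes <- fixes[union(.FIX_COLUMNS[.FIX_COLUMNS %in% names(fixes)],
                       names(fixes))]
  fixes$locClass <- as.character(fixes$locClass)
  fixes$lon <- normalizeLon(fixes$lon)
  if (nrow(fixes)) {
    fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
    rownames(fixes) <- NULL
  }
  if (is.null(releaseTime))
    releaseTime <- if (nrow(fixes)) fixes$timestamp[1] else
      as.POSIXct(NA, tz = "UTC")
  new("Track", individualId = as.character(individualId),
      species = as.character(species),
      releaseTime = releaseTime, fixes = fixes)
}

#' @rdname TrackSet-class
#' @export
setClass("TrackSet", representation(tracks = "list"))

setValidity("TrackSet", function(object) {
  ok <- vapply(object@tracks, is, logical(1), class2 = "Track")
  if (!all(ok)) return("all elements must be Track objects")
  ids <- unname(vapply(object@tracks, function(t) t@individualId,
                       character(1)))
  if (length(ids) && !identical(names(object@tracks), ids))
    return("tracks must be named by individualId")
  TRUE
})

#' TrackSet: a collection of Tracks
#'
#' Named list-like container of \code{\link{Track}} objects, one per
#' individual, as returned by \code{\link{readTracks}}.
#'
#' @param tracks list of \code{Track} objects.
#' @return A \code{TrackSet}.
#' @aliases TrackSet-class
#' @export
TrackSet <- function(tracks = list()) {
  names(tracks) <- vapply(tracks, function(t) t@individualId, character(1))
  new("TrackSet", tracks = tracks)
}

## ---- accessors -------------------------------------------------------------

#' @rdname Track-class
#' @param object,x a \code{Track} or \code{TrackSet}.
#' @export
setGeneric("individualId", function(object) standardGeneric("individualId"))
#' @rdname Track-class
#' @export
setMethod("individualId", "Track", function(object) object@individualId)

#' @rdname Track-class
#' @export
setGeneric("speciesOf", function(object) standardGeneric("speciesOf"))
#' @rdname Track-class
#' @export
setMethod("speciesOf", "Track", function(object) object@species)

#' @rdname Track-class
#' @export
setGeneric("fixes", function(object) standardGeneric("fixes"))
#' @rdname Track-class
#' @export
setMethod("fixes", "Track", function(object) object@fixes)

#' @rdname Track-class
#' @export
setGeneric("releaseTime", function(object) standardGeneric("releaseTime"))
#' @rdname Track-class
#' @export
setMethod("releaseTime", "Track", function(object) object@releaseTime)

#' @rdname Track-class
#' @export
setGeneric("nFixes", function(object) standardGeneric("nFixes"))
#' @rdname Track-class
#' @export
setMethod("nFixes", "Track", function(object) nrow(object@fixes))

#' @rdname Track-class
#' @export
setMethod("show", "Track", function(object) {
  fx <- object@fixes
  cat("Track of", object@individualId, "(", object@species, "):",
      nrow(fx), "fixes")
  if (nrow(fx))
    cat(" from", format(fx$timestamp[1], "%Y-%m-%d"),
        "to", format(fx$timestamp[nrow(fx)], "%Y-%m-%d"))
  cat("\n")
  if ("fittedLat" %in% names(fx)) cat("  (smoothed locations present)\n")
  invisible(NULL)
})

#' @rdname TrackSet-class
#' @param x,i a \code{TrackSet} and index.
#' @export
setMethod("length", "TrackSet", function(x) length(x@tracks))
#' @rdname TrackSet-class
#' @export
setMethod("names", "TrackSet", function(x) names(x@tracks))
#' @rdname TrackSet-class
#' @export
setMethod("[[", "TrackSet", function(x, i) x@tracks[[i]])
#' @rdname TrackSet-class
#' @param object a \code{TrackSet}.
#' @export
setMethod("show", "TrackSet", function(object) {
  sp <- vapply(object@tracks, function(t) t@species, character(1))
  cat("TrackSet of", length(object@tracks), "tracks")
  if (length(sp)) cat(" (", paste(sprintf("%s: %d", names(table(sp)),
                                          as.integer(table(sp))),
                                  collapse = ", "), ")")
  cat("\n")
  invisible(NULL)
})

#' @rdname TrackSet-class
#' @export
trackList <- function(x) x@tracks

#' Replace a track's working coordinates with smoothed ones when present
#'
#' Returns the coordinate columns to use for analysis: the fitted positions
#' if the track was smoothed, otherwise the raw fix positions.
#' @param track a \code{Track}.
#' @return data.frame with \code{timestamp}, \code{lat}, \code{lon}.
#' @keywords internal
workingCoords <- function(track) {
  fx <- fixes(track)
  if (all(c("fittedLat", "fittedLon") %in% names(fx)) &&
      !anyNA(fx$fittedLat)) {
    data.frame(timestamp = fx$timestamp, lat = fx$fittedLat,
               lon = fx$fittedLon)
  } else {
    data.frame(timestamp = fx$timestamp, lat = fx$lat, lon = fx$lon)
  }
}
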