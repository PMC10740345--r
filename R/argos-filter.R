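## Hybrid Argos quality filter: all standard-class fixes (3/2/1) are kept
## unconditionally; auxiliary fixes (0/A/B/Z) are kept only if they are
## spatially redundant with an adjacent retained fix or pass a plausible-
## speed test against both adjacent retained fixes.

#' Hybrid speed / redundant-distance filter for Argos tracks
#'
#' Standard location classes 3, 2 and 1 are always retained. An auxiliary
#' fix (class 0, A, B or Z) is retained iff either (a) its distance to the
#' nearest temporally adjacent retained fix is at most
#' \code{cfg$maxredunKm} (redundancy), or (b) both implied segment speeds to
#' its adjacent retained fixes are at most \code{cfg$vmaxKmh}. Violating
#' fixes are removed iteratively, worst offender first (largest minimum
#' implied speed; ties broken by earlier timestamp), recomputing adjacency
#' after each removal, which makes the result order-independent and the
#' filter idempotent.
#'
#' @param track a \code{\link{Track}} (time-ordered).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with elements \code{retained} (a \code{Track}) and
#'   \code{removed} (data.frame of dropped fixes with a \code{reason}
#'   column, here always \code{"speed"}).
#' @examples
#' cfg <- pipelineConfig()
#' t0 <- as.POSIXct("2016-04-01 00:00", tz = "UTC")
#' fx <- data.frame(timestamp = t0 + 3600 * c(0, 1, 2),
#'                  lat = c(35, 39.5, 35.02), lon = 121,
#'                  locClass = c("3", "B", "3"))
#' res <- hybridFilter(Track("b1", "GK", fx), cfg)
#' res$removed$locClass  # the implausible B-class spike
#' @export
hybridFilter <- function(track, cfg = pipelineConfig()) {
  fx <- fixes(track)
  n <- nrow(fx)
  emptyRemoved <- cbind(fx[0, , drop = FALSE],
                        data.frame(reason = character(0)))
  if (n < 2) {
    warning("track '", individualId(track),
            "' has fewer than 2 fixes; returned unchanged")
    return(list(retained = track, removed = emptyRemoved))
  }
  aux <- !(fx$locClass %in% .STANDARD_CLASSES)
  keep <- rep(TRUE, n)
  tnum <- as.numeric(fx$timestamp)
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    lat <- fx$lat[idx]; lon <- fx$lon[idx]; tt <- tnum[idx]
    m <- length(idx)
    dPrev <- c(NA, gcDistKm(lat[-m], lon[-m], lat[-1], lon[-1]))
    dNext <- c(dPrev[-1], NA)
    spPrev <- dPrev / c(NA, diff(tt) / 3600)
    spNext <- c(spPrev[-1], NA)
    redun <- pmin(dPrev, dNext, na.rm = TRUE) <= cfg$maxredunKm
    rateOk <- (is.na(spPrev) | spPrev <= cfg$vmaxKmh) &
      (is.na(spNext) | spNext <= cfg$vmaxKmh)
    viol <- aux[idx] & !redun & !rateOk
    if (!any(viol, na.rm = TRUE)) break
    minSp <- pmin(spPrev, spNext, na.rm = TRUE)
    cand <- which(viol)
    worst <- cand[order(-minSp[cand], tt[cand])][1]
    keep[idx[worst]] <- FALSE
  }
  removed <- fx[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- "speed"
    rownames(removed) <- NULL
  } else removed <- emptyRemoved
  retained <- Track(individualId(track), speciesOf(track),
                    fx[keep, , drop = FALSE],
                    releaseTime = releaseTime(track))
  list(retained = retained, removed = removed)
}

#' Apply the hybrid filter to every track in a TrackSet
#' @param tracks a \code{\link{TrackSet}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{retained} (TrackSet) and \code{removed}
#'   (data.frame across individuals).
#' @export
hybridFilterSet <- function(tracks, cfg = pipelineConfig()) {
  res <- lapply(trackList(tracks), hybridFilter, cfg = cfg)
  removed <- .rbindRows(lapply(names(res), function(id) {
    r <- res[[id]]$removed
    if (nrow(r)) cbind(individual_id = id, r) else NULL
  }))
  list(retained = TrackSet(unname(lapply(res, `[[`, "retained"))),
       removed = removed)
}
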