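## Tracking-based fidelity metrics: non-breeding single-site residency,
## return to the non-breeding site after a complete migration, and seasonal
## revisitation of Yellow Sea stopover sites.

#' Non-breeding analysis window for a species
#'
#' Runs from the release time to one week (configurable) before the first
#' recorded departure date of a tracked conspecific, so that pre-migratory
#' movements are excluded.
#'
#' @param species species code with a configured first-departure date
#'   (defaults: Great Knot 22 March, Bar-tailed Godwit 4 April).
#' @param releaseTime POSIXct release instant.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with POSIXct \code{start} and \code{end}.
#' @examples
#' cfg <- pipelineConfig()
#' nonbreedingWindow("GK", as.POSIXct("2015-10-01", tz = "UTC"), cfg)$end
#' @export
nonbreedingWindow <- function(species, releaseTime, cfg = pipelineConfig()) {
  dep <- cfg$firstDeparture[species]
  if (is.na(dep) || is.null(dep))
    stop("no first-departure date configured for species '", species, "'")
  relYear <- as.POSIXlt(releaseTime, tz = "UTC")$year + 1900L
  for (yr in c(relYear, relYear + 1L)) {
    end <- as.POSIXct(paste0(yr, "-", dep), tz = "UTC") -
      cfg$nonbreedingBufferDays * 86400
    if (end > releaseTime)
      return(list(start = releaseTime, end = end))
  }
  stop("release time falls after the non-breeding window end")
}

#' Non-breeding site usage of one tracked individual
#'
#' Windows the track to the non-breeding period, identifies sites within
#' the non-breeding region using the full stopover machinery (25 km
#' containment, 50 km merging), and reports the number of distinct sites
#' used. The individual is classified as having moved when it used two or
#' more sites or any site centroid lies more than \code{cfg$revisitKm} from
#' the release-site centroid (the earliest-occupied site).
#'
#' @param track a filtered \code{\link{Track}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return one-row data.frame with \code{individualId}, \code{species},
#'   \code{nSitesUsed}, \code{moved}, \code{windowStart}, \code{windowEnd},
#'   or NULL when the window holds no usable fixes (excluded, with a
#'   message).
#' @export
nonbreedingUsage <- function(track, cfg = pipelineConfig()) {
  win <- nonbreedingWindow(speciesOf(track), releaseTime(track), cfg)
  fx <- fixes(track)
  inWin <- fx$timestamp >= win$start & fx$timestamp <= win$end
  if (!any(inWin)) {
    message("no fixes in the non-breeding window for ",
            individualId(track), "; excluded")
    return(NULL)
  }
  sub <- Track(individualId(track), speciesOf(track),
               fx[inWin, , drop = FALSE], releaseTime = releaseTime(track))
  coords <- workingCoords(sub)
  locs <- detectStationary(sub, cfg$regions$nonbreeding, cfg)
  sites <- .identifySites(locs, coords, cfg)
  if (nrow(sites) == 0) {
    message("no non-breeding site resolved for ", individualId(track),
            "; excluded")
    return(NULL)
  }
  origin <- sites[which.min(sites$arrivalTime), ]
  dOrigin <- gcDistKm(sites$centroidLat, sites$centroidLon,
                      origin$centroidLat, origin$centroidLon)
  moved <- nrow(sites) >= 2 || any(dOrigin > cfg$revisitKm)
  data.frame(individualId = individualId(track),
             species = speciesOf(track),
             nSitesUsed = nrow(sites), moved = moved,
             windowStart = win$start, windowEnd = win$end)
}

#' Did a bird return to its non-breeding site after migration?
#'
#' For tracks with a completed round trip (the bird reached the breeding
#' grounds, latitude above \code{cfg$breedingMinLat}, and later returned
#' below \code{cfg$returnMaxLat}), finds the first post-migration site in
#' the non-breeding region occupied for at least
#' \code{cfg$postMigResidencyDays} days and reports whether its centroid
#' lies within \code{cfg$revisitKm} of the original non-breeding centroid.
#'
#' @param track a filtered \code{\link{Track}}.
#' @param originCentroid named numeric \code{c(lat, lon)} of the original
#'   non-breeding site.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return TRUE/FALSE, or NA when no post-migration residency could be
#'   determined (excluded, with a message).
#' @export
returnedAfterMigration <- function(track, originCentroid,
                                   cfg = pipelineConfig()) {
  co <- workingCoords(track)
  atBreeding <- which(co$lat >= cfg$breedingMinLat)
  if (!length(atBreeding)) {
    message("no breeding-ground residency in track ", individualId(track),
            "; excluded")
    return(NA)
  }
  back <- which(co$lat <= cfg$returnMaxLat &
                  seq_len(nrow(co)) > max(atBreeding))
  if (!length(back)) {
    message("tag stopped before return of ", individualId(track),
            "; excluded")
    return(NA)
  }
  fx <- fixes(track)[min(back):nrow(co), , drop = FALSE]
  sub <- Track(individualId(track), speciesOf(track), fx,
               releaseTime = releaseTime(track))
  locs <- detectStationary(sub, cfg$regions$nonbreeding, cfg)
  sites <- .identifySites(locs, workingCoords(sub), cfg)
  if (nrow(sites) == 0) {
    message("no post-migration site resolved for ", individualId(track),
            "; excluded")
    return(NA)
  }
  sites <- sites[order(sites$arrivalTime), , drop = FALSE]
  stayD <- as.numeric(difftime(sites$departureTime, sites$arrivalTime,
                               units = "days"))
  ## an open-ended final site counts with its observed span
  resident <- which(stayD >= cfg$postMigResidencyDays)
  if (!length(resident)) {
    message("no post-migration residency of ", cfg$postMigResidencyDays,
            "+ days for ", individualId(track), "; excluded")
    return(NA)
  }
  s <- sites[resident[1], ]
  gcDistKm(s$centroidLat, s$centroidLon,
           originCentroid["lat"], originCentroid["lon"]) <= cfg$revisitKm
}

#' Seasonal revisitation of Yellow Sea stopover sites
#'
#' A southward site is a revisit when its centroid lies within
#' \code{cfg$revisitKm} of any northward site centroid of the same
#' individual's first tracked migration. The proportion of time at
#' revisited sites is the summed southward stay duration (arrival to
#' departure) at matched sites divided by the total southward stay
#' duration.
#'
#' @param sitesNorth,sitesSouth site data.frames (one individual's
#'   northward and southward itineraries).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return one-row data.frame with \code{revisited},
#'   \code{propTimeRevisited}, \code{nSitesNorth}, \code{nSitesSouth}, or
#'   NULL when the southward itinerary is empty (excluded).
#' @export
seasonalRevisit <- function(sitesNorth, sitesSouth,
                            cfg = pipelineConfig()) {
  if (nrow(sitesSouth) == 0) return(NULL)
  matched <- vapply(seq_len(nrow(sitesSouth)), function(i) {
    if (nrow(sitesNorth) == 0) return(FALSE)
    any(gcDistKm(sitesSouth$centroidLat[i], sitesSouth$centroidLon[i],
                 sitesNorth$centroidLat, sitesNorth$centroidLon) <=
          cfg$revisitKm)
  }, logical(1))
  stay <- as.numeric(difftime(sitesSouth$departureTime,
                              sitesSouth$arrivalTime, units = "hours"))
  total <- sum(stay)
  prop <- if (total > 0) sum(stay[matched]) / total else 0
  data.frame(revisited = any(matched), propTimeRevisited = prop,
             nSitesNorth = nrow(sitesNorth), nSitesSouth = nrow(sitesSouth))
}

#' Species-level summary of tracking-based fidelity with exact tests
#'
#' Aggregates per-individual non-breeding usages, return outcomes and
#' seasonal revisits into species percentages, medians and ranges, builds
#' the 2x2 contingency tables and runs the exact Fisher test on each; the
#' proportion of time at revisited sites is compared by fractional logit
#' regression.
#'
#' @param usages data.frame of rows from \code{\link{nonbreedingUsage}}.
#' @param revisits optional data.frame of rows from
#'   \code{\link{seasonalRevisit}} with \code{individualId} and
#'   \code{species} columns attached.
#' @param returns optional data.frame with \code{species} and a logical
#'   \code{returned} column (NAs excluded).
#' @param speciesOrder order of the two species in tables (rows).
#' @return list of summary blocks; each contains the contingency table,
#'   per-species percentages and the test result.
#' @export
speciesSummary <- function(usages = NULL, revisits = NULL, returns = NULL,
                           speciesOrder = c("BTG", "GK")) {
  out <- list()
  twoByTwo <- function(df, okCol) {
    t(vapply(speciesOrder, function(sp) {
      ok <- df[[okCol]][df$species == sp]
      c(sum(ok), sum(!ok))
    }, numeric(2)))
  }
  if (!is.null(usages) && nrow(usages)) {
    usages$stayed <- !usages$moved
    tab <- twoByTwo(usages, "stayed")
    colnames(tab) <- c("stayed", "moved")
    out$nonbreedingStay <- list(
      table = tab,
      percentStayed = 100 * tab[, 1] / rowSums(tab),
      n = rowSums(tab),
      fisher = fisherExact2x2(tab))
  }
  if (!is.null(returns) && nrow(returns)) {
    ret <- returns[!is.na(returns$returned), , drop = FALSE]
    if (nrow(ret)) {
      tab <- twoByTwo(ret, "returned")
      colnames(tab) <- c("returned", "elsewhere")
      out$postMigrationReturn <- list(
        table = tab,
        percentReturned = 100 * tab[, 1] / rowSums(tab),
        n = rowSums(tab),
        fisher = fisherExact2x2(tab))
    }
  }
  if (!is.null(revisits) && nrow(revisits)) {
    tab <- twoByTwo(revisits, "revisited")
    colnames(tab) <- c("revisited", "notRevisited")
    med <- function(col) {
      vapply(speciesOrder, function(sp) {
        v <- revisits[[col]][revisits$species == sp]
        if (length(v)) median(v) else NA_real_
      }, numeric(1))
    }
    rng <- function(col) {
      vapply(speciesOrder, function(sp) {
        v <- revisits[[col]][revisits$species == sp]
        if (length(v)) paste(range(v), collapse = "-") else ""
      }, character(1))
    }
    frac <- tryCatch(
      fractionalLogit(revisits$propTimeRevisited,
                      factor(revisits$species, levels = speciesOrder)),
      error = function(e) NULL)
    out$seasonalRevisit <- list(
      table = tab,
      percentRevisited = 100 * tab[, 1] / rowSums(tab),
      n = rowSums(tab),
      medianSitesNorth = med("nSitesNorth"),
      rangeSitesNorth = rng("nSitesNorth"),
      medianSitesSouth = med("nSitesSouth"),
      rangeSitesSouth = rng("nSitesSouth"),
      medianPropTime = med("propTimeRevisited"),
      fisher = fisherExact2x2(tab),
      fractional = frac)
  }
  out
}
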