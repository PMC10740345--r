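## Pipeline configuration: every numeric constant of the analysis lives here
## and can be overridden per call.

#' Pipeline configuration
#'
#' Returns the full set of tunable constants used by the filtering,
#' smoothing, stopover-detection and fidelity stages. Every argument has the
#' study default; pass overrides as named arguments.
#'
#' @param vmaxKmh maximum sustainable movement rate for the hybrid Argos
#'   filter (km/h).
#' @param maxredunKm maximum redundant distance for the hybrid filter (km).
#' @param stationarySpeedKmh fixes moving strictly slower than this are
#'   "stationary" (km/h).
#' @param siteRadiusKm site containment radius: >= \code{containmentFrac} of
#'   a site's members must lie within this distance of its centroid (km).
#' @param containmentFrac required fraction of members within
#'   \code{siteRadiusKm}.
#' @param mergeKm sites whose centroids are closer than this are merged (km).
#' @param revisitKm a southward site matches a northward site when their
#'   centroids are within this distance (km); also the resighting site-match
#'   radius.
#' @param minSiteLocs minimum stationary locations per retained site.
#' @param minSiteSpanH minimum hours between a site's first and last fix.
#' @param dutyOnH,dutyOffH transmitter duty cycle (hours on / hours off).
#' @param firstDeparture named character vector of month-day first-departure
#'   dates per species (earliest conspecific departure across years).
#' @param nonbreedingBufferDays days subtracted from the first departure to
#'   end the non-breeding window (avoids pre-migratory movements).
#' @param nonbreedingResightStart month-day opening the non-breeding
#'   resighting window.
#' @param minSightings minimum sightings for an individual-period to enter
#'   the resighting analysis.
#' @param northWindow,southWindow month-day ranges of the northward and
#'   southward migration seasons.
#' @param regions named list of \code{\link{region}} objects; must contain
#'   \code{yellowSea} and \code{nonbreeding}.
#' @param breedingMinLat latitude above which a bird is considered on the
#'   breeding grounds (deg N).
#' @param returnMaxLat latitude below which a bird is considered back in the
#'   non-breeding range (deg).
#' @param postMigResidencyDays minimum stay (days) for the first
#'   post-migration site used in the returned-after-migration metric.
#' @param classR68Km named vector of default radial 68th-percentile Argos
#'   errors per location class (km), used when no error ellipse is present.
#' @param sigmaBoundsKmSqrtH search bounds for the smoother's process-noise
#'   scale (km per square-root hour).
#' @param resightSiteRoundDeg grid (degrees) for synthesising a site id from
#'   coordinates when a resighting lacks one (0.25 deg is about 27 km,
#'   consistent with the ~50 km resolution of reported resightings).
#' @param rngSeed seed recorded with the configuration (the pipeline itself
#'   is deterministic; only the simulator draws random numbers).
#'
#' @return object of class \code{"pipelineConfig"} (a validated list).
#' @examples
#' cfg <- pipelineConfig()
#' cfg$vmaxKmh
#' @export
pipelineConfig <- function(vmaxKmh = 120,
                           maxredunKm = 10,
                           stationarySpeedKmh = 5,
                           siteRadiusKm = 25,
                           containmentFrac = 0.95,
                           mergeKm = 50,
                           revisitKm = 50,
                           minSiteLocs = 3,
                           minSiteSpanH = 2,
                           dutyOnH = 8,
                           dutyOffH = 25,
                           firstDeparture = c(GK = "03-22", BTG = "04-04"),
                           nonbreedingBufferDays = 7,
                           nonbreedingResightStart = "11-01",
                           minSightings = 2,
                           northWindow = c("03-01", "06-30"),
                           southWindow = c("07-01", "11-30"),
                           regions = defaultRegions(),
                           breedingMinLat = 60,
                           returnMaxLat = -10,
                           postMigResidencyDays = 7,
                           classR68Km = c("3" = 0.25, "2" = 0.5, "1" = 1.5,
                                          "0" = 5, "A" = 8, "B" = 15,
                                          "Z" = 15),
                           sigmaBoundsKmSqrtH = c(0.01, 100),
                           resightSiteRoundDeg = 0.25,
                           rngSeed = 1L) {
  cfg <- list(vmaxKmh = vmaxKmh, maxredunKm = maxredunKm,
              stationarySpeedKmh = stationarySpeedKmh,
              siteRadiusKm = siteRadiusKm, containmentFrac = containmentFrac,
              mergeKm = mergeKm, revisitKm = revisitKm,
              minSiteLocs = minSiteLocs, minSiteSpanH = minSiteSpanH,
              dutyOnH = dutyOnH, dutyOffH = dutyOffH,
              firstDeparture = firstDeparture,
              nonbreedingBufferDays = nonbreedingBufferDays,
              nonbreedingResightStart = nonbreedingResightStart,
              minSightings = minSightings,
              northWindow = northWindow, southWindow = southWindow,
              regions = regions, breedingMinLat = breedingMinLat,
              returnMaxLat = returnMaxLat,
              postMigResidencyDays = postMigResidencyDays,
              classR68Km = classR68Km,
              sigmaBoundsKmSqrtH = sigmaBoundsKmSqrtH,
              resightSiteRoundDeg = resightSiteRoundDeg,
              rngSeed = rngSeed)
  thr <- c(vmaxKmh, maxredunKm, stationarySpeedKmh, siteRadiusKm, mergeKm,
           revisitKm, minSiteLocs, minSiteSpanH, dutyOnH, dutyOffH)
  if (any(thr <= 0)) stop("all thresholds must be > 0")
  if (containmentFrac <= 0 || containmentFrac > 1)
    stop("containmentFrac must be in (0, 1]")
  if (!all(c("yellowSea", "nonbreeding") %in% names(regions)))
    stop("regions must include 'yellowSea' and 'nonbreeding'")
  structure(cfg, class = "pipelineConfig")
}

#' Default study regions
#'
#' Bounding boxes for the Yellow Sea staging area (covering Bohai Bay, Yalu
#' Jiang and the Korean west coast) and the Northwest Australia non-breeding
#' range (Roebuck Bay / Eighty Mile Beach, extended east to include the
#' Northern Territory).
#'
#' @return named list of \code{\link{region}} objects.
#' @export
defaultRegions <- function() {
  list(yellowSea = boxRegion("Yellow Sea", 32, 41.5, 117, 127),
       nonbreeding = boxRegion("Northwest Australia", -26, -9, 112, 138))
}

#' @export
print.pipelineConfig <- function(x, ...) {
  cat("pipelineConfig:\n")
  scal <- vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))
  for (nm in names(x)[scal]) cat(sprintf("  %-24s %s\n", nm, x[[nm]]))
  cat(sprintf("  %-24s %s\n", "firstDeparture",
              paste(names(x$firstDeparture), x$firstDeparture,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  %-24s %s\n", "regions",
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

## month-day helpers ----------------------------------------------------------

## "03-22" -> 322 for calendar comparisons
.mdNum <- function(md) {
  parts <- do.call(rbind, strsplit(md, "-", fixed = TRUE))
  as.integer(parts[, 1]) * 100L + as.integer(parts[, 2])
}

.dateMdNum <- function(dates) {
  lt <- as.POSIXlt(dates, tz = "UTC")
  (lt$mon + 1L) * 100L + lt$mday
}

## month-day of (firstDeparture - buffer days) for a species
.departureCutoffMd <- function(species, cfg) {
  dep <- cfg$firstDeparture[species]
  if (is.na(dep)) stop("no first-departure date configured for species '",
                       species, "'")
  d <- as.Date(paste0("2001-", dep)) - cfg$nonbreedingBufferDays
  format(d, "%m-%d")
}
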