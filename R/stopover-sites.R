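## Stopover-site identification. Per individual and migration season:
## (1) fixes inside the study region moving slower than 5 km/h are
## "stationary"; (2) stationary fixes are clustered by complete-linkage
## agglomeration on great-circle distances, the number of clusters chosen
## by maximum mean silhouette width; (3) clusters must contain >= 95% of
## members within 25 km of their centroid, re-clustering with one more
## cluster until they do; sites closer than 50 km are merged, sites with
## < 3 members or < 2 h of occupancy are discarded; arrival and departure
## are extrapolated across the 25 km site radius.

## pairwise great-circle distance matrix (km)
.distMatrixKm <- function(lat, lon) {
  rl <- lat * pi / 180; rn <- lon * pi / 180
  V <- cbind(cos(rl) * cos(rn), cos(rl) * sin(rn), sin(rl))
  G <- tcrossprod(V)
  G[G > 1] <- 1; G[G < -1] <- -1
  .EARTH_RADIUS_KM * acos(G)
}

#' Stationary locations of a track within a region
#'
#' A fix is stationary when it lies inside \code{reg} and its ground speed
#' (over the preceding segment; the first fix uses its following segment)
#' is strictly below \code{cfg$stationarySpeedKmh}. Smoothed coordinates
#' are used when the track carries them.
#'
#' @param track a filtered (optionally smoothed) \code{\link{Track}}.
#' @param reg a \code{\link{region}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return data.frame with columns \code{fixIdx}, \code{timestamp},
#'   \code{lat}, \code{lon}, \code{speedKmh}.
#' @export
detectStationary <- function(track, reg, cfg = pipelineConfig()) {
  co <- workingCoords(track)
  if (nrow(co) == 0)
    return(data.frame(fixIdx = integer(), timestamp = as.POSIXct(character(),
                                                                 tz = "UTC"),
                      lat = numeric(), lon = numeric(),
                      speedKmh = numeric()))
  sp <- segmentSpeeds(co$timestamp, co$lat, co$lon)
  keep <- !is.na(sp) & sp < cfg$stationarySpeedKmh &
    pointInRegion(co$lat, co$lon, reg)
  data.frame(fixIdx = which(keep), timestamp = co$timestamp[keep],
             lat = co$lat[keep], lon = co$lon[keep], speedKmh = sp[keep])
}

#' Cluster stationary locations into candidate sites
#'
#' Complete-linkage agglomerative clustering on the great-circle distance
#' matrix. Candidate cluster numbers k = 2, ..., min(n - 1, 15) are scored
#' by mean silhouette width and the maximiser chosen (ties: smallest k).
#' One-cluster shortcut: when all points lie within
#' \code{cfg$siteRadiusKm} of their common centroid, a single cluster is
#' returned without silhouette scoring (silhouette is undefined at k = 1).
#'
#' @param locs data.frame from \code{\link{detectStationary}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{labels} (integer vector), \code{k}, and
#'   \code{tree} (the hclust object, or NULL when the shortcut applied).
#' @export
clusterStationary <- function(locs, cfg = pipelineConfig()) {
  n <- nrow(locs)
  if (n == 0) stop("cannot cluster zero stationary locations")
  ctr <- sphericalCentroid(locs$lat, locs$lon)
  within <- gcDistKm(locs$lat, locs$lon, ctr["lat"], ctr["lon"]) <=
    cfg$siteRadiusKm
  ## the shortcut must be strict ("all within"): a tolerant version would
  ## silently absorb a genuine second site holding < 5% of the fixes;
  ## noise strays instead take the silhouette path and are merged back or
  ## discarded downstream
  if (all(within) || n == 1)
    return(list(labels = rep(1L, n), k = 1L, tree = NULL))
  if (n == 2)  # too few points for silhouette; split apart
    return(list(labels = 1:2, k = 2L, tree = NULL))
  D <- .distMatrixKm(locs$lat, locs$lon)
  tree <- hclust(as.dist(D), method = "complete")
  kCand <- 2:min(n - 1, 15)
  silW <- vapply(kCand, function(k) {
    sil <- cluster::silhouette(cutree(tree, k), dmatrix = D)
    mean(sil[, "sil_width"])
  }, numeric(1))
  k <- kCand[which.max(silW)]  # which.max takes the first (smallest) tie
  list(labels = unname(cutree(tree, k)), k = k, tree = tree)
}

## per-cluster containment check: TRUE when every cluster holds at least
## containmentFrac of its members within siteRadiusKm of its centroid
.containmentOk <- function(locs, labels, cfg) {
  for (g in unique(labels)) {
    ix <- labels == g
    ctr <- sphericalCentroid(locs$lat[ix], locs$lon[ix])
    beyond <- gcDistKm(locs$lat[ix], locs$lon[ix],
                       ctr["lat"], ctr["lon"]) > cfg$siteRadiusKm
    if (mean(beyond) > 1 - cfg$containmentFrac) return(FALSE)
  }
  TRUE
}

#' Enforce the 25 km containment criterion
#'
#' While any cluster has more than 5% of members beyond
#' \code{cfg$siteRadiusKm} of its centroid, re-cluster with one more
#' cluster (cut the same complete-linkage tree at k + 1, capped at n - 1).
#' Returns the first compliant labelling, or the maximum-k labelling with a
#' warning if none complies.
#'
#' @param locs data.frame from \code{\link{detectStationary}}.
#' @param clustering result of \code{\link{clusterStationary}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{labels} and \code{k}.
#' @export
enforceContainment <- function(locs, clustering, cfg = pipelineConfig()) {
  labels <- clustering$labels; k <- clustering$k
  tree <- clustering$tree
  n <- nrow(locs)
  if (is.null(tree) && n >= 3 && !.containmentOk(locs, labels, cfg)) {
    D <- .distMatrixKm(locs$lat, locs$lon)
    tree <- hclust(as.dist(D), method = "complete")
  }
  while (!.containmentOk(locs, labels, cfg)) {
    if (is.null(tree) || k >= n - 1) {
      if (!.containmentOk(locs, labels, cfg))
        warning("containment criterion unmet at maximum cluster count")
      break
    }
    k <- k + 1L
    labels <- unname(cutree(tree, k))
  }
  list(labels = labels, k = k)
}

## assemble raw site records (members are row indices into locs)
.sitesFromLabels <- function(locs, labels) {
  lapply(sort(unique(labels)), function(g) {
    ix <- which(labels == g)
    ctr <- sphericalCentroid(locs$lat[ix], locs$lon[ix])
    list(members = ix, centroidLat = unname(ctr["lat"]),
         centroidLon = unname(ctr["lon"]),
         firstTime = min(locs$timestamp[ix]),
         lastTime = max(locs$timestamp[ix]))
  })
}

#' Merge sites whose centroids are closer than 50 km
#'
#' Iteratively merges the closest centroid pair below \code{cfg$mergeKm},
#' recomputing the merged centroid as the spherical centroid of all member
#' locations (member-weighted), until all pairwise centroid distances are
#' at least \code{cfg$mergeKm}.
#'
#' @param sites list of site records (internal form) from one
#'   individual-season.
#' @param locs the stationary-location table the member indices refer to.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list of merged site records.
#' @export
mergeCloseSites <- function(sites, locs, cfg = pipelineConfig()) {
  repeat {
    ns <- length(sites)
    if (ns < 2) break
    lat <- vapply(sites, `[[`, numeric(1), "centroidLat")
    lon <- vapply(sites, `[[`, numeric(1), "centroidLon")
    D <- .distMatrixKm(lat, lon)
    diag(D) <- Inf
    if (min(D) >= cfg$mergeKm) break
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    ix <- sort(c(sites[[i]]$members, sites[[j]]$members))
    ctr <- sphericalCentroid(locs$lat[ix], locs$lon[ix])
    sites[[i]] <- list(members = ix, centroidLat = unname(ctr["lat"]),
                       centroidLon = unname(ctr["lon"]),
                       firstTime = min(locs$timestamp[ix]),
                       lastTime = max(locs$timestamp[ix]))
    sites[[j]] <- NULL
  }
  sites
}

#' Discard undersized or short-lived sites
#'
#' Retains sites with at least \code{cfg$minSiteLocs} stationary locations
#' and an occupancy span (first to last fix) of at least
#' \code{cfg$minSiteSpanH} hours.
#'
#' @param sites list of site records.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return filtered list.
#' @export
filterSites <- function(sites, cfg = pipelineConfig()) {
  Filter(function(s) {
    length(s$members) >= cfg$minSiteLocs &&
      as.numeric(difftime(s$lastTime, s$firstTime, units = "hours")) >=
        cfg$minSiteSpanH
  }, sites)
}

#' Extrapolate arrival and departure times for a site
#'
#' Departure: the bird is assumed to travel at constant speed from its last
#' fix at the site towards the next track fix; the departure time is when
#' it crosses the \code{cfg$siteRadiusKm} circle around the site centroid,
#' \code{tDep = tLast + dt * max(0, r - dLast) / dSeg} (clamped to the next
#' fix time). Arrival is computed symmetrically from the fix preceding the
#' first site fix. Without a next (or previous) fix the last (first) fix
#' time is used.
#'
#' @param site a site record (internal form).
#' @param coords full-track coordinates (data.frame with \code{timestamp},
#'   \code{lat}, \code{lon}) that the site's \code{fixIdx} members index.
#' @param locs stationary-location table holding the member rows.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{arrivalTime} and \code{departureTime}.
#' @export
estimateTimes <- function(site, coords, locs, cfg = pipelineConfig()) {
  memFix <- locs$fixIdx[site$members]
  r <- cfg$siteRadiusKm
  ## departure
  iLast <- max(memFix)
  tLast <- coords$timestamp[iLast]
  dep <- tLast
  if (iLast < nrow(coords)) {
    iNext <- iLast + 1
    dLast <- gcDistKm(coords$lat[iLast], coords$lon[iLast],
                      site$centroidLat, site$centroidLon)
    dSeg <- gcDistKm(coords$lat[iLast], coords$lon[iLast],
                     coords$lat[iNext], coords$lon[iNext])
    dt <- as.numeric(difftime(coords$timestamp[iNext], tLast,
                              units = "secs"))
    if (dSeg > 0) {
      frac <- min(1, max(0, r - dLast) / dSeg)
      dep <- tLast + dt * frac
    } else if (gcDistKm(coords$lat[iNext], coords$lon[iNext],
                        site$centroidLat, site$centroidLon) > r) {
      warning("zero-length segment with next fix outside the site radius; ",
              "departure set to the last site fix")
    }
  }
  ## arrival (mirror image)
  iFirst <- min(memFix)
  tFirst <- coords$timestamp[iFirst]
  arr <- tFirst
  if (iFirst > 1) {
    iPrev <- iFirst - 1
    dFirst <- gcDistKm(coords$lat[iFirst], coords$lon[iFirst],
                       site$centroidLat, site$centroidLon)
    dSeg <- gcDistKm(coords$lat[iFirst], coords$lon[iFirst],
                     coords$lat[iPrev], coords$lon[iPrev])
    dt <- as.numeric(difftime(tFirst, coords$timestamp[iPrev],
                              units = "secs"))
    if (dSeg > 0) {
      frac <- min(1, max(0, r - dFirst) / dSeg)
      arr <- tFirst - dt * frac
    }
  }
  list(arrivalTime = arr, departureTime = dep)
}

## run cluster -> containment -> merge -> filter -> times on one set of
## stationary locations; returns a site data.frame (no season columns yet)
.identifySites <- function(locs, coords, cfg) {
  empty <- data.frame(centroidLat = numeric(), centroidLon = numeric(),
                      nLocs = integer(),
                      firstTime = as.POSIXct(character(), tz = "UTC"),
                      lastTime = as.POSIXct(character(), tz = "UTC"),
                      arrivalTime = as.POSIXct(character(), tz = "UTC"),
                      departureTime = as.POSIXct(character(), tz = "UTC"))
  empty$memberIdx <- I(list())
  if (nrow(locs) == 0) return(empty)
  cl <- clusterStationary(locs, cfg)
  cl <- enforceContainment(locs, cl, cfg)
  sites <- .sitesFromLabels(locs, cl$labels)
  sites <- mergeCloseSites(sites, locs, cfg)
  sites <- filterSites(sites, cfg)
  if (length(sites) == 0) return(empty)
  rows <- lapply(sites, function(s) {
    tm <- estimateTimes(s, coords, locs, cfg)
    data.frame(centroidLat = s$centroidLat, centroidLon = s$centroidLon,
               nLocs = length(s$members), firstTime = s$firstTime,
               lastTime = s$lastTime, arrivalTime = tm$arrivalTime,
               departureTime = tm$departureTime,
               memberIdx = I(list(locs$fixIdx[s$members])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arrivalTime), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## season of a calendar date given the configured month-day windows
.assignSeason <- function(dates, cfg) {
  mdn <- .dateMdNum(dates)
  nw <- .mdNum(cfg$northWindow); sw <- .mdNum(cfg$southWindow)
  out <- rep(NA_character_, length(dates))
  out[mdn >= nw[1] & mdn <= nw[2]] <- "northward"
  out[mdn >= sw[1] & mdn <= sw[2]] <- "southward"
  out
}

#' Identify stopover sites per migration season for one track
#'
#' Splits the region-resident portion of the track into northward and
#' southward seasons by the configured calendar windows (per calendar
#' year), then runs the full stationary-detection, clustering, containment,
#' merging, occupancy-filter and timing chain on each season. Site ids are
#' deterministic: individual, year, season, rank by arrival.
#'
#' @param track a filtered (optionally smoothed) \code{\link{Track}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param reg region to search; defaults to the configured Yellow Sea box.
#' @return data.frame of sites with columns \code{siteId},
#'   \code{individualId}, \code{species}, \code{season}, \code{year},
#'   \code{centroidLat}, \code{centroidLon}, \code{nLocs},
#'   \code{firstTime}, \code{lastTime}, \code{arrivalTime},
#'   \code{departureTime}, and a \code{memberIdx} list-column of member fix
#'   indices into the track's (working) coordinates; zero rows when the
#'   track never enters the region.
#' @export
buildItinerary <- function(track, cfg = pipelineConfig(),
                           reg = cfg$regions$yellowSea) {
  coords <- workingCoords(track)
  locs <- detectStationary(track, reg, cfg)
  emptySites <- data.frame(siteId = character(), individualId = character(),
                           species = character(), season = character(),
                           year = integer(), centroidLat = numeric(),
                           centroidLon = numeric(), nLocs = integer(),
                           firstTime = as.POSIXct(character(), tz = "UTC"),
                           lastTime = as.POSIXct(character(), tz = "UTC"),
                           arrivalTime = as.POSIXct(character(), tz = "UTC"),
                           departureTime = as.POSIXct(character(),
                                                      tz = "UTC"))
  emptySites$memberIdx <- I(list())
  if (nrow(locs) == 0) return(emptySites)
  season <- .assignSeason(locs$timestamp, cfg)
  year <- as.POSIXlt(locs$timestamp, tz = "UTC")$year + 1900L
  groups <- split(seq_len(nrow(locs)),
                  interaction(season, year, drop = TRUE))
  out <- lapply(groups, function(ix) {
    sub <- locs[ix, , drop = FALSE]
    sites <- .identifySites(sub, coords, cfg)
    if (nrow(sites) == 0) return(NULL)
    sites$season <- season[ix][1]
    sites$year <- year[ix][1]
    sites
  })
  out <- .rbindRows(out)
  if (is.null(out) || nrow(out) == 0) return(emptySites)
  out <- out[order(out$year, out$season, out$arrivalTime), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(out)),
                     paste(out$year, out$season),
                     FUN = seq_along)
  out$siteId <- sprintf("%s_%d_%s_%d", individualId(track), out$year,
                        out$season, rank)
  out$individualId <- individualId(track)
  out$species <- speciesOf(track)
  rownames(out) <- NULL
  out[names(emptySites)]
}
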