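## Telemetry and resighting simulator with known ground truth. Individuals
## follow a stay/transit itinerary (non-breeding residency in Northwest
## Australia with optional within-season moves, a northward Yellow Sea
## passage of 1-4 staging sites, Arctic breeding residency, a southward
## passage that reuses each northward site with a configured probability,
## and return). Tracks sample the path only inside the 8 h-on windows of
## the 33 h transmitter duty cycle; each fix draws an Argos class and is
## perturbed by isotropic bivariate error whose radial 68th percentile
## matches the class scale. Resightings arise from a site/date survey
## schedule with imperfect detection and no false positives.

#' Simulation configuration
#'
#' Defaults emulate the tracked study cohorts: 24 Bar-tailed Godwits and 41
#' Great Knots released at Roebuck Bay in the austral spring, Great Knots
#' with a 7/41 within-season mover fraction (godwits none), godwits using a
#' median of 2 and knots a median of 3 Yellow Sea sites, and a higher
#' per-site seasonal revisit probability for godwits than knots. Mover
#' displacements follow the observed movement templates (80-920 km).
#'
#' @param nIndividuals named vector: birds per species.
#' @param moverProb named vector: probability an individual moves away from
#'   its release site within the non-breeding season.
#' @param nMovers optional named vector fixing the exact mover count per
#'   species (overrides \code{moverProb}).
#' @param revisitProb named vector: probability each northward Yellow Sea
#'   site is reused during southward migration.
#' @param nSitesProbs named list of probability vectors over the number of
#'   northward Yellow Sea sites (names give the counts).
#' @param siteSepKm min/max great-circle separation (km) drawn between
#'   consecutive Yellow Sea site centres.
#' @param origin named \code{c(lat, lon)} of the release site (Roebuck
#'   Bay).
#' @param moverDistKm displacement templates (km) for non-breeding moves.
#' @param moverStayDays min/max stay (days) at the alternative site.
#' @param stayDaysYs min/max stay (days) at each Yellow Sea site.
#' @param breedingSite named \code{c(lat, lon)} of the Arctic breeding
#'   residency.
#' @param southDepartWindow month-day window of breeding-ground departure
#'   (southward Yellow Sea passage runs July-November).
#' @param fixesPerOnHour expected fixes per hour of transmitter-on time.
#' @param transitSpeedKmh min/max migratory flight speed (km/h).
#' @param stayJitterKm standard deviation (km) of true within-site
#'   wandering.
#' @param dutyOnH,dutyOffH transmitter duty cycle (hours).
#' @param classProbs Argos class mixture for the fixes.
#' @param classR68Km radial 68th-percentile error (km) per class.
#' @param spikeRate probability a fix is replaced by an auxiliary-class
#'   outlier spike.
#' @param spikeKm displacement (km) of outlier spikes.
#' @param heavyTail use t-distributed (df = \code{tDf}) instead of normal
#'   error components (off by default).
#' @param tDf degrees of freedom of the heavy-tailed option.
#' @param withEllipse emit isotropic error-ellipse columns matching the
#'   drawn class scale.
#' @param detectionProb probability a present marked bird is recorded on a
#'   survey day.
#' @param surveyedSiteKeys which true sites carry surveys
#'   (\code{"origin"} = only the release site; \code{"all"} = every site
#'   used by any itinerary).
#' @param surveysPerWeek survey frequency at surveyed sites.
#' @param releaseWindow month-day range of release dates.
#' @param releaseYear calendar year of release.
#' @param includeMigration simulate the full migration (TRUE) or stop the
#'   itinerary at the northward departure (FALSE).
#' @param departureSpreadDays days added (uniformly) to the species first
#'   departure date for each individual.
#' @return list of class \code{"simConfig"}.
#' @export
simConfig <- function(nIndividuals = c(BTG = 24, GK = 41),
                      moverProb = c(BTG = 0, GK = 7 / 41),
                      nMovers = NULL,
                      revisitProb = c(BTG = 0.85, GK = 0.4),
                      nSitesProbs = list(
                        BTG = c("1" = 0.25, "2" = 0.5, "3" = 0.25),
                        GK = c("1" = 0.1, "2" = 0.25, "3" = 0.4,
                               "4" = 0.25)),
                      siteSepKm = c(100, 400),
                      origin = c(lat = -18.07, lon = 122.33),
                      moverDistKm = c(80, 170, 250, 320, 920),
                      moverStayDays = c(5, 40),
                      stayDaysYs = c(5, 20),
                      breedingSite = c(lat = 66, lon = 160),
                      southDepartWindow = c("07-08", "07-28"),
                      fixesPerOnHour = 0.4,
                      transitSpeedKmh = c(50, 70),
                      stayJitterKm = 1.5,
                      dutyOnH = 8, dutyOffH = 25,
                      classProbs = c("3" = 0.15, "2" = 0.2, "1" = 0.25,
                                     "0" = 0.1, "A" = 0.15, "B" = 0.15,
                                     "Z" = 0),
                      classR68Km = c("3" = 0.25, "2" = 0.5, "1" = 1.5,
                                     "0" = 5, "A" = 8, "B" = 15,
                                     "Z" = 15),
                      spikeRate = 0.02, spikeKm = 500,
                      heavyTail = FALSE, tDf = 4,
                      withEllipse = FALSE,
                      detectionProb = 0.5,
                      surveyedSiteKeys = "origin",
                      surveysPerWeek = 2,
                      releaseWindow = c("09-15", "10-31"),
                      releaseYear = 2015,
                      includeMigration = TRUE,
                      departureSpreadDays = 20) {
  cfg <- as.list(environment())
  stopifnot(all(moverProb >= 0 & moverProb <= 1),
            all(revisitProb >= 0 & revisitProb <= 1),
            fixesPerOnHour > 0, detectionProb >= 0, detectionProb <= 1)
  structure(cfg, class = "simConfig")
}

#' The study-cohort simulation preset
#'
#' Exactly 24 godwits (no movers) and 41 knots (exactly 7 movers) released
#' at Roebuck Bay, tracked through the non-breeding season; mover
#' displacements use the 80-920 km movement templates.
#'
#' @param ... overrides passed on to \code{\link{simConfig}}.
#' @return a \code{"simConfig"}.
#' @export
studyCohortConfig <- function(...) {
  simConfig(nIndividuals = c(BTG = 24, GK = 41),
            nMovers = c(BTG = 0, GK = 7),
            moverStayDays = c(7, 60),
            includeMigration = FALSE, ...)
}

.destKm <- function(lat, lon, bearingDeg, distKm) {
  p <- geosphere::destPoint(cbind(unname(lon), unname(lat)),
                            unname(bearingDeg), unname(distKm) * 1000,
                            r = .EARTH_RADIUS_KM * 1000)
  c(lat = unname(p[1, 2]), lon = unname(normalizeLon(p[1, 1])))
}

#' Simulate one individual's true itinerary
#'
#' @param sc a \code{\link{simConfig}}.
#' @param species species code.
#' @param individualId id string.
#' @param mover force the mover flag (NULL: draw from
#'   \code{sc$moverProb}).
#' @return list of class \code{"trueItinerary"}: \code{stays} (data.frame
#'   with siteKey, phase, lat, lon, arrival, departure), \code{mover},
#'   \code{nSitesNorth}, \code{revisit} (logical per northward site),
#'   \code{origin}, \code{release}.
#' @export
simulateItinerary <- function(sc, species, individualId, mover = NULL) {
  origin <- sc$origin
  relStart <- as.POSIXct(paste0(sc$releaseYear, "-", sc$releaseWindow[1]),
                         tz = "UTC")
  relEnd <- as.POSIXct(paste0(sc$releaseYear, "-", sc$releaseWindow[2]),
                       tz = "UTC")
  release <- relStart + runif(1, 0, as.numeric(relEnd - relStart,
                                               units = "secs"))
  if (is.null(mover)) mover <- runif(1) < sc$moverProb[species]
  depDate <- as.POSIXct(paste0(sc$releaseYear + 1, "-",
                               unname(pipelineConfig()$firstDeparture[
                                 species])), tz = "UTC") +
    runif(1, 0, sc$departureSpreadDays) * 86400
  speed <- function() runif(1, sc$transitSpeedKmh[1], sc$transitSpeedKmh[2])
  stays <- list()
  addStay <- function(key, phase, lat, lon, arrival, departure) {
    stays[[length(stays) + 1]] <<- data.frame(
      siteKey = key, phase = phase, lat = lat, lon = lon,
      arrival = arrival, departure = departure)
  }
  if (mover) {
    ## split the non-breeding season: origin, excursion, (mostly) return
    d <- if (length(sc$moverDistKm) == 1) sc$moverDistKm else
      sample(sc$moverDistKm, 1)
    brg <- if (d > 500) 60 else 205  # NE to the Northern Territory, or SSW
    ## alternative sites are shared named locations: the same displacement
    ## always maps to the same place (movers congregate at real sites)
    altKey <- paste0("alt", d)
    alt <- .destKm(origin["lat"], origin["lon"], brg, d)
    tOut <- release + runif(1, 20, 60) * 86400
    stayAlt <- runif(1, sc$moverStayDays[1], sc$moverStayDays[2]) * 86400
    travel <- (d / speed()) * 3600
    altDep <- tOut + travel + stayAlt
    returns <- runif(1) < 0.6 && (altDep + travel < depDate - 5 * 86400)
    addStay("origin", "nonbreeding", origin["lat"], origin["lon"],
            release, tOut)
    if (returns) {
      addStay(altKey, "nonbreeding", alt["lat"], alt["lon"],
              tOut + travel, altDep)
      addStay("origin", "nonbreeding", origin["lat"], origin["lon"],
              altDep + travel, depDate)
    } else {
      addStay(altKey, "nonbreeding", alt["lat"], alt["lon"],
              tOut + travel, depDate)
    }
  } else {
    addStay("origin", "nonbreeding", origin["lat"], origin["lon"],
            release, depDate)
  }
  nNorth <- 0L; revisit <- logical(0)
  if (sc$includeMigration) {
    probs <- sc$nSitesProbs[[species]]
    nNorth <- as.integer(sample(names(probs), 1, prob = probs))
    ## Yellow Sea site centres: south-to-north chain with drawn separation
    ysLat <- numeric(nNorth); ysLon <- numeric(nNorth)
    for (attempt in 1:1000) {
      ysLat[1] <- runif(1, 33, 35.5); ysLon[1] <- runif(1, 119, 126)
      ok <- TRUE
      if (nNorth > 1) for (i in 2:nNorth) {
        sep <- runif(1, sc$siteSepKm[1], sc$siteSepKm[2])
        p <- .destKm(ysLat[i - 1], ysLon[i - 1], runif(1, -60, 60), sep)
        ysLat[i] <- p["lat"]; ysLon[i] <- p["lon"]
        if (!pointInRegion(p["lat"], p["lon"],
                           defaultRegions()$yellowSea)) ok <- FALSE
        if (i > 2 && any(gcDistKm(p["lat"], p["lon"], ysLat[1:(i - 2)],
                                  ysLon[1:(i - 2)]) < sc$siteSepKm[1]))
          ok <- FALSE
      }
      if (ok) break
      if (attempt == 1000) stop("could not place Yellow Sea sites under ",
                                "the separation constraints")
    }
    lastStay <- stays[[length(stays)]]
    t <- depDate
    prevLat <- lastStay$lat; prevLon <- lastStay$lon
    for (i in seq_len(nNorth)) {
      travel <- gcDistKm(prevLat, prevLon, ysLat[i], ysLon[i]) / speed() *
        3600
      arr <- t + travel
      dep <- arr + runif(1, sc$stayDaysYs[1], sc$stayDaysYs[2]) * 86400
      addStay(paste0("ys", i), "northward", ysLat[i], ysLon[i], arr, dep)
      t <- dep; prevLat <- ysLat[i]; prevLon <- ysLon[i]
    }
    ## breeding residency
    travel <- gcDistKm(prevLat, prevLon, sc$breedingSite["lat"],
                       sc$breedingSite["lon"]) / speed() * 3600
    arrB <- t + travel
    ## southward departure no earlier than the configured window (the
    ## southward Yellow Sea passage runs July-November)
    sd0 <- as.POSIXct(paste0(sc$releaseYear + 1, "-",
                             sc$southDepartWindow[1]), tz = "UTC")
    sd1 <- as.POSIXct(paste0(sc$releaseYear + 1, "-",
                             sc$southDepartWindow[2]), tz = "UTC")
    depB <- max(arrB + 20 * 86400,
                sd0 + runif(1, 0, as.numeric(sd1 - sd0, units = "secs")))
    addStay("breeding", "breeding", sc$breedingSite["lat"],
            sc$breedingSite["lon"], arrB, depB)
    ## southward: reuse each northward site with the revisit probability,
    ## in reverse (north-to-south) order; ensure at least one stop
    revisit <- runif(nNorth) < sc$revisitProb[species]
    southIdx <- rev(which(revisit))
    t <- depB; prevLat <- sc$breedingSite["lat"]
    prevLon <- sc$breedingSite["lon"]
    southSites <- list()
    for (i in southIdx)
      southSites[[length(southSites) + 1]] <-
        c(lat = ysLat[i], lon = ysLon[i])
    if (length(southSites) == 0) {
      ## a fresh site well away from every northward site
      for (attempt in 1:1000) {
        cand <- c(lat = runif(1, 33, 40), lon = runif(1, 119, 126))
        if (all(gcDistKm(cand["lat"], cand["lon"], ysLat, ysLon) >
                  sc$siteSepKm[1])) break
      }
      southSites[[1]] <- cand
    }
    j <- 0
    for (s in southSites) {
      j <- j + 1
      travel <- gcDistKm(prevLat, prevLon, s["lat"], s["lon"]) / speed() *
        3600
      arr <- t + travel
      dep <- arr + runif(1, sc$stayDaysYs[1], sc$stayDaysYs[2]) * 86400
      addStay(paste0("ys_s", j), "southward", s["lat"], s["lon"], arr, dep)
      t <- dep; prevLat <- s["lat"]; prevLon <- s["lon"]
    }
    ## return to the non-breeding origin
    travel <- gcDistKm(prevLat, prevLon, origin["lat"], origin["lon"]) /
      speed() * 3600
    arr <- t + travel
    addStay("origin", "nonbreeding2", origin["lat"], origin["lon"],
            arr, arr + 120 * 86400)
  }
  stays <- .rbindRows(stays)
  structure(list(individualId = individualId, species = species,
                 stays = stays, mover = mover, nSitesNorth = nNorth,
                 revisit = revisit, origin = origin, release = release),
            class = "trueItinerary")
}

## true position at arbitrary times along an itinerary (stays + great-circle
## transits); returns a lat/lon matrix
.truePosition <- function(itin, times) {
  st <- itin$stays
  n <- length(times)
  lat <- numeric(n); lon <- numeric(n)
  tnum <- as.numeric(times)
  arr <- as.numeric(st$arrival); dep <- as.numeric(st$departure)
  for (i in seq_len(n)) {
    t <- tnum[i]
    k <- which(t >= arr & t <= dep)
    if (length(k)) {                        # inside a stay
      lat[i] <- st$lat[k[1]]; lon[i] <- st$lon[k[1]]
    } else {
      k <- which(t > dep)
      k <- if (length(k)) max(k) else 0
      if (k == 0) {                         # before the first stay
        lat[i] <- st$lat[1]; lon[i] <- st$lon[1]
      } else if (k == nrow(st)) {           # after the last stay
        lat[i] <- st$lat[k]; lon[i] <- st$lon[k]
      } else {                              # in transit between k and k+1
        f <- (t - dep[k]) / (arr[k + 1] - dep[k])
        p <- gcInterpolate(st$lat[k], st$lon[k], st$lat[k + 1],
                           st$lon[k + 1], f)
        lat[i] <- p[1, "lat"]; lon[i] <- p[1, "lon"]
      }
    }
  }
  cbind(lat = lat, lon = lon)
}

#' Simulate an Argos track from a true itinerary
#'
#' Fix times are drawn as a Poisson process (rate
#' \code{sc$fixesPerOnHour}) restricted to the 8 h-on windows of the 33 h
#' duty cycle anchored at release. Each fix draws a location class from the
#' mixture and is perturbed by isotropic bivariate error whose radial 68th
#' percentile matches the class scale (heavy-tailed t option available);
#' within-stay wandering of scale \code{sc$stayJitterKm} is added to the
#' true position. A small fraction of fixes become auxiliary-class outlier
#' spikes displaced by \code{sc$spikeKm}.
#'
#' @param itin a \code{\link{simulateItinerary}} result.
#' @param sc a \code{\link{simConfig}}.
#' @return a \code{\link{Track}}.
#' @export
simulateTrack <- function(itin, sc) {
  st <- itin$stays
  t0 <- as.numeric(itin$release)
  tEnd <- as.numeric(st$departure[nrow(st)])
  cycle <- (sc$dutyOnH + sc$dutyOffH) * 3600
  onLen <- sc$dutyOnH * 3600
  nCycles <- max(0, floor((tEnd - t0) / cycle)) + 1
  times <- numeric(0)
  for (k in 0:(nCycles - 1)) {
    wStart <- t0 + k * cycle
    wEnd <- min(wStart + onLen, tEnd)
    if (wEnd <= wStart) next
    nf <- rpois(1, sc$fixesPerOnHour * (wEnd - wStart) / 3600)
    if (nf > 0) times <- c(times, sort(runif(nf, wStart, wEnd)))
  }
  times <- unique(round(times))
  if (length(times) < 2) {
    fx <- data.frame(timestamp = as.POSIXct(times, tz = "UTC",
                                            origin = "1970-01-01"),
                     lat = rep(unname(itin$origin["lat"]), length(times)),
                     lon = rep(unname(itin$origin["lon"]), length(times)),
                     locClass = rep("3", length(times)),
                     smajM = rep(NA_real_, length(times)),
                     sminM = rep(NA_real_, length(times)),
                     eorDeg = rep(NA_real_, length(times)))
    return(Track(itin$individualId, itin$species, fx,
                 releaseTime = itin$release))
  }
  pos <- .truePosition(itin, times)
  n <- length(times)
  cls <- sample(names(sc$classProbs), n, replace = TRUE,
                prob = sc$classProbs)
  sig <- unname(sc$classR68Km[cls]) / .R68_FACTOR
  drawNoise <- function(n) {
    if (sc$heavyTail) {
      sc0 <- sqrt((sc$tDf - 2) / sc$tDf)  # unit-variance t components
      cbind(stats::rt(n, sc$tDf) * sc0, stats::rt(n, sc$tDf) * sc0)
    } else cbind(rnorm(n), rnorm(n))
  }
  ## within-stay wandering (true movement), then measurement error, in a
  ## local plane anchored per fix
  wander <- drawNoise(n) * sc$stayJitterKm
  inStay <- vapply(times, function(t)
    any(t >= as.numeric(st$arrival) & t <= as.numeric(st$departure)),
    logical(1))
  wander[!inStay, ] <- 0
  err <- drawNoise(n) * sig
  dx <- wander[, 1] + err[, 1]
  dy <- wander[, 2] + err[, 2]
  spike <- runif(n) < sc$spikeRate
  if (any(spike)) {
    ang <- runif(sum(spike), 0, 2 * pi)
    dx[spike] <- dx[spike] + sc$spikeKm * sin(ang)
    dy[spike] <- dy[spike] + sc$spikeKm * cos(ang)
    cls[spike] <- sample(c("A", "B"), sum(spike), replace = TRUE)
  }
  d <- sqrt(dx^2 + dy^2)
  brg <- atan2(dx, dy) * 180 / pi
  obs <- geosphere::destPoint(cbind(pos[, "lon"], pos[, "lat"]), brg,
                              d * 1000, r = .EARTH_RADIUS_KM * 1000)
  smaj <- if (sc$withEllipse) sig * 1000 else NA_real_
  smin <- if (sc$withEllipse) sig * 1000 else NA_real_
  eor <- if (sc$withEllipse) 0 else NA_real_
  Track(itin$individualId, itin$species,
        data.frame(timestamp = as.POSIXct(times, tz = "UTC",
                                          origin = "1970-01-01"),
                   lat = obs[, 2], lon = normalizeLon(obs[, 1]),
                   locClass = cls, smajM = smaj, sminM = smin,
                   eorDeg = eor),
        releaseTime = itin$release)
}

#' Simulate survey-based resightings of marked individuals
#'
#' Builds a survey schedule (default: the surveyed site keys, visited
#' \code{sc$surveysPerWeek} times a week over the simulated span) and
#' records each individual present at a surveyed site on a survey date
#' with probability \code{sc$detectionProb}; absent individuals are never
#' recorded.
#'
#' @param itins list of \code{\link{simulateItinerary}} results.
#' @param sc a \code{\link{simConfig}}.
#' @param schedule optional data.frame with \code{site_key},
#'   \code{site_lat}, \code{site_lon}, \code{date} overriding the default
#'   schedule.
#' @return resighting data.frame (same shape as
#'   \code{\link{readResightings}}).
#' @export
simulateResightings <- function(itins, sc, schedule = NULL) {
  if (is.null(schedule)) {
    keys <- unique(unlist(lapply(itins, function(it) it$stays$siteKey)))
    if (!identical(sc$surveyedSiteKeys, "all"))
      keys <- intersect(sc$surveyedSiteKeys, keys)
    span <- range(do.call(c, lapply(itins, function(it)
      c(it$stays$arrival, it$stays$departure))))
    days <- seq(as.Date(span[1]), as.Date(span[2]),
                by = max(1, round(7 / sc$surveysPerWeek)))
    schedule <- do.call(rbind, lapply(keys, function(k) {
      pos <- NULL
      for (it in itins) {
        hit <- it$stays[it$stays$siteKey == k, ]
        if (nrow(hit)) { pos <- hit[1, c("lat", "lon")]; break }
      }
      data.frame(site_key = k, site_lat = pos$lat, site_lon = pos$lon,
                 date = days)
    }))
  }
  recs <- list()
  for (it in itins) {
    st <- it$stays
    for (r in seq_len(NROW(schedule))) {
      tMid <- as.POSIXct(paste(schedule$date[r], "04:00:00"), tz = "UTC")
      here <- st$arrival <= tMid & st$departure >= tMid &
        gcDistKm(st$lat, st$lon, schedule$site_lat[r],
                 schedule$site_lon[r]) <= 25
      if (any(here) && runif(1) < sc$detectionProb)
        recs[[length(recs) + 1]] <- data.frame(
          individual_id = it$individualId, species = it$species,
          date = schedule$date[r],
          site_id = as.character(schedule$site_key[r]),
          site_lat = schedule$site_lat[r],
          site_lon = schedule$site_lon[r])
    }
  }
  out <- .rbindRows(recs)
  if (is.null(out))
    out <- data.frame(individual_id = character(), species = character(),
                      date = as.Date(character()), site_id = character(),
                      site_lat = numeric(), site_lon = numeric())
  out
}

#' Generate a full benchmark dataset with truth tables
#'
#' Simulates itineraries, tracks and resightings for every configured
#' individual and returns them with per-individual truth. Fully
#' reproducible from \code{seed}; optionally writes the telemetry CSV,
#' resighting CSV and truth CSV to \code{dir}.
#'
#' @param sc a \code{\link{simConfig}}.
#' @param seed integer RNG seed.
#' @param dir optional output directory for the CSV bundle.
#' @param withTracks simulate telemetry tracks (disable for
#'   resighting-only studies, which only need itineraries).
#' @return list with \code{tracks} (\code{\link{TrackSet}}, NULL when
#'   \code{withTracks = FALSE}), \code{resightings} (data.frame),
#'   \code{itineraries} (list of truth itineraries) and \code{truth}
#'   (per-individual truth data.frame).
#' @export
makeBenchmark <- function(sc = simConfig(), seed = 1, dir = NULL,
                          withTracks = TRUE) {
  set.seed(seed)
  itins <- list()
  for (sp in names(sc$nIndividuals)) {
    nInd <- sc$nIndividuals[[sp]]
    moverFlags <- if (!is.null(sc$nMovers)) {
      sample(rep(c(TRUE, FALSE),
                 c(sc$nMovers[[sp]], nInd - sc$nMovers[[sp]])))
    } else rep(list(NULL), nInd)
    for (i in seq_len(nInd)) {
      id <- sprintf("%s%02d", sp, i)
      mv <- if (is.list(moverFlags)) moverFlags[[i]] else moverFlags[i]
      itins[[id]] <- simulateItinerary(sc, sp, id, mover = mv)
    }
  }
  tracks <- if (withTracks)
    TrackSet(lapply(itins, simulateTrack, sc = sc)) else NULL
  resightings <- simulateResightings(itins, sc)
  truth <- .rbindRows(lapply(itins, function(it) {
    data.frame(individual_id = it$individualId, species = it$species,
               mover = it$mover, n_sites_north = it$nSitesNorth,
               n_revisited = sum(it$revisit))
  }))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (withTracks) writeTracksCsv(tracks, file.path(dir, "telemetry.csv"))
    write.csv(resightings, file.path(dir, "resightings.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(tracks = tracks, resightings = resightings, itineraries = itins,
       truth = truth)
}
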