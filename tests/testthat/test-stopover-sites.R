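cfg <- pipelineConfig()
ys <- cfg$regions$yellowSea

test_that("stationary detection applies the strict 5 km/h and region gates", {
  ## consecutive fixes 1 h apart at ~4.9, ~5.2, ~4.9 km spacing
  tr <- kmTrack(hours = 0:3, eastKm = cumsum(c(0, 4.9, 5.2, 4.9)),
                northKm = 0, baseLat = 35, baseLon = 121)
  st <- detectStationary(tr, ys, cfg)
  ## fix 2 (preceding speed 4.9) and fix 4 (4.9) are in; fix 3 (5.2) is out
  expect_true(2 %in% st$fixIdx)
  expect_false(3 %in% st$fixIdx)
  expect_true(4 %in% st$fixIdx)
  ## the threshold is strict: a fix moving at exactly the threshold speed
  ## is excluded (set the threshold to the fix's own achieved speed)
  co <- fixes(tr)
  sp <- segmentSpeeds(co$timestamp, co$lat, co$lon)
  cfgEq <- pipelineConfig(stationarySpeedKmh = sp[2])
  expect_false(2 %in% detectStationary(tr, ys, cfgEq)$fixIdx)
  ## slow fix outside the region is excluded
  trOut <- kmTrack(hours = 0:1, eastKm = c(0, 4), northKm = 0,
                   baseLat = -18, baseLon = 122)
  expect_equal(nrow(detectStationary(trOut, ys, cfg)), 0L)
})

test_that("clustering recovers well-separated groups exactly", {
  set.seed(51)
  t0 <- utc("2016-04-10 00:00")
  a <- scatterLocs(20, 34, 120, 5, t0)
  b <- scatterLocs(20, 34, 120 + 300 / (111.1951 * cos(34 * pi / 180)), 5,
                   t0 + 40 * 3600)
  locs <- rbind(a, b); locs$fixIdx <- seq_len(nrow(locs))
  cl <- clusterStationary(locs, cfg)
  expect_equal(cl$k, 2L)
  ## agreement with brute-force nearest-centre assignment
  ctrs <- lapply(split(seq_len(40), cl$labels), function(ix)
    sphericalCentroid(locs$lat[ix], locs$lon[ix]))
  nearest <- vapply(seq_len(40), function(i)
    which.min(vapply(ctrs, function(ctr)
      gcDistKm(locs$lat[i], locs$lon[i], ctr["lat"], ctr["lon"]),
      numeric(1))), integer(1))
  expect_equal(unname(nearest), cl$labels)
})

test_that("identical points collapse to a single cluster via the shortcut", {
  locs <- scatterLocs(10, 34, 120, 0, utc("2016-04-10 00:00"))
  cl <- clusterStationary(locs, cfg)
  expect_equal(cl$k, 1L)
  expect_equal(cl$labels, rep(1L, 10))
})

test_that("three groups 200 km apart are found by the silhouette scan", {
  set.seed(52)
  t0 <- utc("2016-04-10 00:00")
  step <- 200 / (111.1951 * cos(35 * pi / 180))
  locs <- rbind(scatterLocs(15, 35, 119, 4, t0),
                scatterLocs(15, 35, 119 + step, 4, t0 + 60 * 3600),
                scatterLocs(15, 35, 119 + 2 * step, 4, t0 + 120 * 3600))
  locs$fixIdx <- seq_len(nrow(locs))
  cl <- clusterStationary(locs, cfg)
  expect_equal(cl$k, 3L)
  ## verified against an exhaustive k scan: silhouette is maximal at 3
  D <- siteFidelity:::.distMatrixKm(locs$lat, locs$lon)
  tree <- hclust(as.dist(D), method = "complete")
  silW <- vapply(2:10, function(k)
    mean(cluster::silhouette(cutree(tree, k), dmatrix = D)[, "sil_width"]),
    numeric(1))
  expect_equal(which.max(silW) + 1L, 3L)
})

test_that("containment enforcement splits contaminated clusters", {
  set.seed(53)
  t0 <- utc("2016-04-10 00:00")
  core <- scatterLocs(17, 35, 121, 3, t0)
  stray <- scatterLocs(3, 35, 121 + 40 / (111.1951 * cos(35 * pi / 180)),
                       1, t0 + 60 * 3600)
  locs <- rbind(core, stray); locs$fixIdx <- seq_len(nrow(locs))
  ## force everything into one cluster: 15% of members beyond 25 km
  forced <- list(labels = rep(1L, 20), k = 1L, tree = NULL)
  fixed <- enforceContainment(locs, forced, cfg)
  expect_gt(fixed$k, 1L)
  expect_true(siteFidelity:::.containmentOk(locs, fixed$labels, cfg))
  ## the strays form their own cluster
  expect_equal(length(unique(fixed$labels[18:20])), 1L)
  expect_false(fixed$labels[18] %in% fixed$labels[1:17])
})

test_that("a compliant labelling is returned unchanged", {
  set.seed(54)
  locs <- scatterLocs(30, 35, 121, 5, utc("2016-04-10 00:00"))
  cl <- clusterStationary(locs, cfg)
  fixed <- enforceContainment(locs, cl, cfg)
  expect_equal(fixed$labels, cl$labels)
})

test_that("a uniform 24 km disc is accepted as a single cluster", {
  set.seed(55)
  n <- 100
  r <- 24 * sqrt(runif(n)); ang <- runif(n, 0, 2 * pi)
  t0 <- utc("2016-04-10 00:00")
  locs <- data.frame(fixIdx = 1:n, timestamp = t0 + (0:(n - 1)) * 3600,
                     lat = 35 + r * cos(ang) / 111.1951,
                     lon = 121 + r * sin(ang) /
                       (111.1951 * cos(35 * pi / 180)),
                     speedKmh = 0)
  cl <- clusterStationary(locs, cfg)
  expect_equal(cl$k, 1L)
})

test_that("sites merge below 50 km and stay separate above", {
  t0 <- utc("2016-04-10 00:00")
  mk <- function(eastKm, n, tOff) {
    sc <- scatterLocs(n, 35, 121, 0, t0 + tOff * 3600)
    sc$lon <- sc$lon + eastKm / (111.1951 * cos(35 * pi / 180))
    sc
  }
  pairCase <- function(sep) {
    locs <- rbind(mk(0, 5, 0), mk(sep, 5, 24))
    locs$fixIdx <- seq_len(nrow(locs))
    sites <- siteFidelity:::.sitesFromLabels(locs, rep(1:2, each = 5))
    mergeCloseSites(sites, locs, cfg)
  }
  expect_equal(length(pairCase(49)), 1L)
  expect_equal(length(pairCase(51)), 2L)
  ## chain A-B 40 km, B-C 40 km, A-C 80 km: closest pair merges first,
  ## the merged centroid (20 km) is then 60 km from C -> two sites remain
  locs <- rbind(mk(0, 5, 0), mk(40, 5, 24), mk(80, 5, 48))
  locs$fixIdx <- seq_len(nrow(locs))
  sites <- siteFidelity:::.sitesFromLabels(locs, rep(1:3, each = 5))
  merged <- mergeCloseSites(sites, locs, cfg)
  expect_equal(length(merged), 2L)
  lat <- vapply(merged, `[[`, numeric(1), "centroidLat")
  lon <- vapply(merged, `[[`, numeric(1), "centroidLon")
  expect_true(all(siteFidelity:::.distMatrixKm(lat, lon)[1, 2] >=
                    cfg$mergeKm))
  ## member-weighted centroid of the merged A+B pair sits midway (~20 km)
  expect_equal(sort(round(vapply(merged, function(s) length(s$members),
                                 numeric(1)))), c(5, 10))
})

test_that("undersized and short-lived sites are discarded", {
  t0 <- utc("2016-04-10 00:00")
  locs <- scatterLocs(10, 35, 121, 1, t0)
  mkSite <- function(members, spanH) {
    locs2 <- locs
    locs2$timestamp <- t0 + seq(0, spanH, length.out = 10) * 3600
    siteFidelity:::.sitesFromLabels(locs2[members, , drop = FALSE],
                                    rep(1L, length(members)))[[1]]
  }
  expect_equal(length(filterSites(list(mkSite(1:2, 5)), cfg)), 0L)
  expect_equal(length(filterSites(list(mkSite(1:5, 1.9)), cfg)), 0L)
  s3 <- siteFidelity:::.sitesFromLabels(
    data.frame(fixIdx = 1:3, timestamp = t0 + c(0, 1.5, 3) * 3600,
               lat = 35, lon = 121, speedKmh = 0), rep(1L, 3))
  expect_equal(length(filterSites(s3, cfg)), 1L)
})

test_that("arrival/departure extrapolation crosses the 25 km radius", {
  t0 <- utc("2016-04-10 00:00")
  ## three member fixes at the centroid, next fix 100 km away 4 h later
  coords <- data.frame(timestamp = t0 + c(0, 1, 2, 6) * 3600,
                       lat = 35,
                       lon = 121 + c(0, 0, 0, 100) /
                         (111.1951 * cos(35 * pi / 180)))
  locs <- data.frame(fixIdx = 1:3, timestamp = coords$timestamp[1:3],
                     lat = coords$lat[1:3], lon = coords$lon[1:3],
                     speedKmh = 0)
  site <- siteFidelity:::.sitesFromLabels(locs, rep(1L, 3))[[1]]
  tm <- estimateTimes(site, coords, locs, cfg)
  ## departure = t_last + (25/100) * 4 h = t_last + 1 h
  expect_equal(as.numeric(tm$departureTime - coords$timestamp[3],
                          units = "hours"), 1, tolerance = 1e-4)
  ## no fix before the first member: arrival = first fix time
  expect_equal(tm$arrivalTime, coords$timestamp[1])
  ## next fix exactly on the 25 km circle -> departure = next fix time
  coords25 <- coords
  coords25$lon[4] <- 121 + 25 / (111.1951 * cos(35 * pi / 180))
  tm25 <- estimateTimes(site, coords25, locs, cfg)
  expect_lt(abs(as.numeric(tm25$departureTime) -
                  as.numeric(coords25$timestamp[4])), 60)
  ## no fix after the last member -> departure = last member time
  tmEnd <- estimateTimes(site, coords[1:3, ], locs, cfg)
  expect_equal(tmEnd$departureTime, coords$timestamp[3])
})

test_that("a track never entering the region yields an empty itinerary", {
  tr <- kmTrack(hours = 0:20, eastKm = rnorm(21), northKm = rnorm(21),
                baseLat = -18, baseLon = 122)
  sites <- buildItinerary(tr, cfg)
  expect_equal(nrow(sites), 0L)
})

test_that("two well-separated true sites are recovered with accurate centroids", {
  set.seed(56)
  sc <- simConfig(nIndividuals = c(GK = 1),
                  classProbs = c("3" = 0, "2" = 0, "1" = 1, "0" = 0,
                                 A = 0, B = 0, Z = 0),
                  nSitesProbs = list(GK = c("2" = 1)),
                  siteSepKm = c(350, 450), stayDaysYs = c(12, 16),
                  spikeRate = 0, fixesPerOnHour = 0.6)
  it <- simulateItinerary(sc, "GK", "g1")
  tr <- simulateTrack(it, sc)
  sites <- buildItinerary(hybridFilter(tr, cfg)$retained, cfg)
  north <- sites[sites$season == "northward", ]
  expect_equal(nrow(north), 2L)
  trueSites <- it$stays[it$stays$phase == "northward", ]
  for (i in seq_len(2)) {
    dmin <- min(gcDistKm(north$centroidLat, north$centroidLon,
                         trueSites$lat[i], trueSites$lon[i]))
    expect_lt(dmin, 10)
  }
})
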