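cfg <- pipelineConfig()

test_that("the non-breeding window ends a week before first departure", {
  rel <- utc("2015-10-01 00:00")
  expect_equal(nonbreedingWindow("GK", rel, cfg)$end, utc("2016-03-15"))
  expect_equal(nonbreedingWindow("BTG", rel, cfg)$end, utc("2016-03-28"))
  ## release in January still ends the same non-breeding season
  expect_equal(nonbreedingWindow("GK", utc("2016-01-10"), cfg)$end,
               utc("2016-03-15"))
  expect_error(nonbreedingWindow("XX", rel, cfg), "first-departure")
})

test_that("a bird never leaving a 25 km area used a single site, not moved", {
  set.seed(61)
  n <- 120
  tr <- kmTrack(id = "gk1", hours = cumsum(runif(n, 2, 6)),
                eastKm = rnorm(n, 0, 3), northKm = rnorm(n, 0, 3),
                t0 = utc("2015-10-05 00:00"), baseLat = -18.07,
                baseLon = 122.33)
  us <- nonbreedingUsage(tr, cfg)
  expect_equal(us$nSitesUsed, 1L)
  expect_false(us$moved)
})

test_that("a 170 km mid-window excursion flags the bird as a mover", {
  set.seed(62)
  sc <- simConfig(nIndividuals = c(GK = 1), moverDistKm = 170,
                  moverStayDays = c(20, 30), includeMigration = FALSE,
                  spikeRate = 0)
  it <- simulateItinerary(sc, "GK", "gk2", mover = TRUE)
  tr <- simulateTrack(it, sc)
  us <- nonbreedingUsage(hybridFilter(tr, cfg)$retained, cfg)
  expect_true(us$moved)
  expect_gte(us$nSitesUsed, 2L)
})

test_that("seasonal revisit proportions follow stay durations", {
  t0 <- utc("2016-04-10 00:00")
  mkSites <- function(lats, lons, stayDays, season) {
    arr <- t0 + cumsum(c(0, rep(20, length(lats) - 1))) * 86400
    data.frame(siteId = paste0(season, seq_along(lats)),
               centroidLat = lats, centroidLon = lons,
               arrivalTime = arr,
               departureTime = arr + stayDays * 86400,
               season = season)
  }
  ## identical single site both seasons
  no <- mkSites(35, 121, 10, "northward")
  so <- mkSites(35, 121, 8, "southward")
  rv <- seasonalRevisit(no, so, cfg)
  expect_true(rv$revisited)
  expect_equal(rv$propTimeRevisited, 1)
  ## disjoint sites >= 60 km apart
  so2 <- mkSites(35 + 60 / 111.1951, 121, 8, "southward")
  rv2 <- seasonalRevisit(no, so2, cfg)
  expect_false(rv2$revisited)
  expect_equal(rv2$propTimeRevisited, 0)
  ## 12 d at a matched site + 4 d elsewhere -> 0.75
  so3 <- mkSites(c(35, 37), c(121, 123), c(12, 4), "southward")
  rv3 <- seasonalRevisit(no, so3, cfg)
  expect_equal(rv3$propTimeRevisited, 0.75)
  ## empty southward itinerary is excluded
  expect_null(seasonalRevisit(no, so3[0, ], cfg))
})

test_that("the time proportion is invariant to splitting a stay", {
  t0 <- utc("2016-08-01 00:00")
  no <- data.frame(centroidLat = 35, centroidLon = 121,
                   arrivalTime = t0 - 90 * 86400,
                   departureTime = t0 - 80 * 86400)
  whole <- data.frame(centroidLat = c(35, 37), centroidLon = c(121, 124),
                      arrivalTime = t0 + c(0, 15) * 86400,
                      departureTime = t0 + c(12, 19) * 86400)
  half1 <- whole[c(1, 1, 2), ]
  half1$arrivalTime <- t0 + c(0, 5, 15) * 86400
  half1$departureTime <- t0 + c(5, 12, 19) * 86400
  expect_equal(seasonalRevisit(no, whole, cfg)$propTimeRevisited,
               seasonalRevisit(no, half1, cfg)$propTimeRevisited)
})

test_that("round-trip outcomes classify return, displacement and tag loss", {
  mkRoundTrip <- function(endEast) {
    hours <- c(seq(0, 240, by = 6),                 # origin residency
               seq(246, 330, by = 6),               # northward transit
               seq(336, 1200, by = 8),              # breeding
               seq(1206, 1290, by = 6),             # southward transit
               seq(1296, 1896, by = 8))             # post-migration
    n1 <- length(seq(0, 240, by = 6))
    n2 <- length(seq(246, 330, by = 6))
    n3 <- length(seq(336, 1200, by = 8))
    n4 <- length(seq(1206, 1290, by = 6))
    n5 <- length(seq(1296, 1896, by = 8))
    north <- c(rep(0, n1), seq(0, 9300, length.out = n2),
               9300 + rnorm(n3, 0, 1),
               seq(9300, 0, length.out = n4), rep(0, n5))
    east <- c(rep(0, n1 + n2 + n3 + n4), rep(endEast, n5))
    kmTrack(id = "rt", hours = hours, eastKm = east + rnorm(length(east)),
            northKm = north, t0 = utc("2015-10-01 00:00"),
            baseLat = -18.07, baseLon = 122.33)
  }
  origin <- c(lat = -18.07, lon = 122.33)
  set.seed(63)
  expect_true(returnedAfterMigration(mkRoundTrip(0), origin, cfg))
  ## ending ~920 km away
  expect_false(returnedAfterMigration(mkRoundTrip(920), origin, cfg))
  ## tag stops at the breeding grounds
  full <- mkRoundTrip(0)
  cut <- fixes(full)[fixes(full)$lat > 50, , drop = FALSE]
  truncated <- Track("rt", "GK", cut)
  expect_true(is.na(suppressMessages(
    returnedAfterMigration(truncated, origin, cfg))))
})

test_that("species summaries rebuild the contingency tables exactly", {
  usages <- data.frame(
    individualId = c(sprintf("b%02d", 1:24), sprintf("g%02d", 1:41)),
    species = rep(c("BTG", "GK"), c(24, 41)),
    nSitesUsed = 1L,
    moved = c(rep(FALSE, 24), rep(TRUE, 7), rep(FALSE, 34)))
  ss <- speciesSummary(usages = usages)
  expect_equal(unname(ss$nonbreedingStay$table),
               matrix(c(24, 34, 0, 7), 2))
  expect_equal(unname(ss$nonbreedingStay$percentStayed),
               c(100, 100 * 34 / 41))
  expect_equal(round(ss$nonbreedingStay$fisher$pTwoSided, 2), 0.04)
  ## seasonal revisit block: 16/20 vs 8/12 with stay-time proportions
  set.seed(64)
  revisits <- data.frame(
    individualId = c(sprintf("b%02d", 1:20), sprintf("g%02d", 1:12)),
    species = rep(c("BTG", "GK"), c(20, 12)),
    revisited = c(rep(c(TRUE, FALSE), c(16, 4)),
                  rep(c(TRUE, FALSE), c(8, 4))),
    propTimeRevisited = pmin(1, pmax(0, c(rnorm(20, 0.9, 0.05),
                                          rnorm(12, 0.25, 0.1)))),
    nSitesNorth = 2L, nSitesSouth = 2L)
  ss2 <- speciesSummary(revisits = revisits)
  expect_equal(unname(ss2$seasonalRevisit$table),
               matrix(c(16, 8, 4, 4), 2))
  expect_equal(round(ss2$seasonalRevisit$fisher$pTwoSided, 2), 0.43)
  expect_lt(ss2$seasonalRevisit$fractional$pValue, 0.05)
})

test_that("estimated mover fractions are consistent with the programmed rate", {
  ## cohorts with mover probability p: the pipeline's estimated fraction
  ## should be statistically indistinguishable from p (exact binomial test
  ## at the 5% level) in at least 93% of replicates
  p <- 0.25
  sc <- simConfig(nIndividuals = c(GK = 12), moverProb = c(GK = p),
                  includeMigration = FALSE, moverStayDays = c(20, 50))
  ok <- vapply(seq_len(100), function(i) {
    b <- makeBenchmark(sc, seed = 400000 + i)
    us <- suppressMessages(analyzeNonbreeding(b$tracks))
    stats::binom.test(sum(us$moved), nrow(us), p)$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.93)
})
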