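cfg <- pipelineConfig()

test_that("the benchmark is byte-identical under the same seed", {
  sc <- simConfig(nIndividuals = c(GK = 3, BTG = 2))
  b1 <- makeBenchmark(sc, seed = 9)
  b2 <- makeBenchmark(sc, seed = 9)
  expect_identical(b1$truth, b2$truth)
  expect_identical(lapply(trackList(b1$tracks), fixes),
                   lapply(trackList(b2$tracks), fixes))
  expect_identical(b1$resightings, b2$resightings)
  ## requested cohort sizes are honoured
  expect_equal(as.integer(table(b1$truth$species)[c("BTG", "GK")]),
               c(2L, 3L))
})

test_that("mover probability zero yields only single-site itineraries", {
  sc <- simConfig(nIndividuals = c(GK = 8), moverProb = c(GK = 0),
                  includeMigration = FALSE)
  b <- makeBenchmark(sc, seed = 10)
  expect_false(any(b$truth$mover))
  for (it in b$itineraries)
    expect_equal(unique(it$stays$siteKey), "origin")
  ## exact mover counts are honoured when fixed
  sc2 <- simConfig(nIndividuals = c(GK = 10), nMovers = c(GK = 4),
                   includeMigration = FALSE)
  b2 <- makeBenchmark(sc2, seed = 10)
  expect_equal(sum(b2$truth$mover), 4L)
})

test_that("revisit probability one reuses every northward site southward", {
  sc <- simConfig(nIndividuals = c(BTG = 6), revisitProb = c(BTG = 1))
  b <- makeBenchmark(sc, seed = 11)
  for (it in b$itineraries) {
    no <- it$stays[it$stays$phase == "northward", ]
    so <- it$stays[it$stays$phase == "southward", ]
    expect_equal(nrow(so), nrow(no))
    for (i in seq_len(nrow(so)))
      expect_lte(min(gcDistKm(so$lat[i], so$lon[i], no$lat, no$lon)), 50)
  }
})

test_that("a degenerate site-count distribution is honoured", {
  sc <- simConfig(nIndividuals = c(GK = 5),
                  nSitesProbs = list(GK = c("3" = 1)))
  b <- makeBenchmark(sc, seed = 12)
  expect_true(all(b$truth$n_sites_north == 3L))
})

test_that("fixes fall only inside the 8 h-on windows of the duty cycle", {
  sc <- simConfig(nIndividuals = c(GK = 4))
  b <- makeBenchmark(sc, seed = 13)
  for (tr in trackList(b$tracks)) {
    dt <- as.numeric(fixes(tr)$timestamp) -
      as.numeric(releaseTime(tr))
    phase <- dt %% ((sc$dutyOnH + sc$dutyOffH) * 3600)
    expect_true(all(phase <= sc$dutyOnH * 3600))
    ## consequently no gap across an off period is shorter than 25 h
    gaps <- diff(as.numeric(fixes(tr)$timestamp)) / 3600
    crossing <- gaps > sc$dutyOnH
    expect_true(all(gaps[crossing] >= sc$dutyOffH))
  }
})

test_that("class-3 radial error calibrates to its 68th percentile", {
  sc <- simConfig(nIndividuals = c(GK = 1), includeMigration = FALSE,
                  classProbs = c("3" = 1, "2" = 0, "1" = 0, "0" = 0,
                                 A = 0, B = 0, Z = 0),
                  stayJitterKm = 0, spikeRate = 0, fixesPerOnHour = 6)
  set.seed(14)
  it <- simulateItinerary(sc, "GK", "g1", mover = FALSE)
  tr <- simulateTrack(it, sc)
  err <- gcDistKm(fixes(tr)$lat, fixes(tr)$lon,
                  it$origin["lat"], it$origin["lon"])
  expect_gt(length(err), 5000)
  q68 <- unname(quantile(err, 0.68))
  expect_lt(abs(q68 - 0.25) / 0.25, 0.10)
})

test_that("zero error and zero jitter put every fix on the true path", {
  sc <- simConfig(nIndividuals = c(GK = 1), includeMigration = FALSE,
                  classR68Km = c("3" = 0, "2" = 0, "1" = 0, "0" = 0,
                                 A = 0, B = 0, Z = 0),
                  stayJitterKm = 0, spikeRate = 0)
  set.seed(15)
  it <- simulateItinerary(sc, "GK", "g1", mover = FALSE)
  tr <- simulateTrack(it, sc)
  err <- gcDistKm(fixes(tr)$lat, fixes(tr)$lon,
                  it$origin["lat"], it$origin["lon"])
  expect_lt(max(err), 1e-6)
})

test_that("detection extremes give empty or truth-equal resightings", {
  scBase <- list(nIndividuals = c(GK = 6), nMovers = c(GK = 2),
                 moverStayDays = c(30, 60), includeMigration = FALSE,
                 surveyedSiteKeys = "all",
                 surveysPerWeek = 3)
  sc0 <- do.call(simConfig, c(scBase, list(detectionProb = 0)))
  b0 <- makeBenchmark(sc0, seed = 16)
  expect_equal(nrow(b0$resightings), 0L)
  sc1 <- do.call(simConfig, c(scBase, list(detectionProb = 1)))
  b1 <- makeBenchmark(sc1, seed = 16)
  u <- periodUsage(b1$resightings, cfg)
  col <- collapseAcrossYears(u)
  truthSites <- ifelse(b1$truth$mover, 2L, 1L)
  names(truthSites) <- b1$truth$individual_id
  expect_equal(unname(truthSites[col$individual_id]), col$maxSites)
  ## with the alternative site unsurveyed, movers appear single-site
  sc2 <- do.call(simConfig, c(scBase[setdiff(names(scBase),
                                             "surveyedSiteKeys")],
                              list(detectionProb = 1,
                                   surveyedSiteKeys = "origin")))
  b2 <- makeBenchmark(sc2, seed = 16)
  u2 <- collapseAcrossYears(periodUsage(
    b2$resightings, cfg))
  expect_true(all(u2$maxSites == 1L))
})
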