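cfg <- pipelineConfig()

rec <- function(id, species, date, site, lat, lon) {
  data.frame(individual_id = id, species = species, date = as.Date(date),
             site_id = site, site_lat = lat, site_lon = lon)
}
RB <- c(-18.07, 122.33)   # Roebuck Bay
EMB <- c(-19.4, 121.3)    # Eighty Mile Beach
YJ <- c(39.8, 123.9)      # Yalu Jiang
BH <- c(39.1, 118.2)      # Bohai Bay

test_that("records are assigned to the correct analysis periods", {
  r <- rbind(rec("a", "GK", "2016-01-15", "RB", RB[1], RB[2]),
             rec("a", "GK", "2016-03-20", "RB", RB[1], RB[2]),
             rec("a", "GK", "2016-05-01", "YJ", YJ[1], YJ[2]),
             rec("a", "BTG", "2016-03-20", "RB", RB[1], RB[2]),
             rec("a", "GK", "2015-11-01", "RB", RB[1], RB[2]),
             rec("a", "GK", "2016-08-10", "YJ", YJ[1], YJ[2]))
  p <- assignPeriod(r, cfg)
  ## mid-January at Roebuck Bay: non-breeding, year of the preceding 1 Nov
  expect_equal(p$periodType[1], "nonbreeding")
  expect_equal(p$periodYear[1], 2015L)
  ## 20 March is past the Great Knot cutoff (22 Mar - 7 d = 15 Mar)
  expect_true(is.na(p$periodType[2]))
  ## but within the Bar-tailed Godwit window (4 Apr - 7 d = 28 Mar)
  expect_equal(p$periodType[4], "nonbreeding")
  ## 1 May at a Yellow Sea site: northward migration
  expect_equal(p$periodType[3], "northward")
  expect_equal(p$periodYear[3], 2016L)
  ## 1 November opens the non-breeding window
  expect_equal(p$periodType[5], "nonbreeding")
  expect_equal(p$periodYear[5], 2015L)
  ## August at a Yellow Sea site: southward
  expect_equal(p$periodType[6], "southward")
})

test_that("period usage counts sightings and sites, dropping sparse periods", {
  r <- rbind(rec("a", "GK", "2015-12-01", "RB", RB[1], RB[2]),
             rec("a", "GK", "2015-12-15", "RB", RB[1], RB[2]),
             rec("a", "GK", "2016-01-10", "RB", RB[1], RB[2]),
             rec("b", "GK", "2015-12-01", "RB", RB[1], RB[2]),
             rec("b", "GK", "2016-02-01", "EMB", EMB[1], EMB[2]),
             rec("c", "GK", "2015-12-01", "RB", RB[1], RB[2]))
  u <- periodUsage(r, cfg)
  expect_equal(u$nSites[u$individual_id == "a"], 1L)
  expect_equal(u$nSightings[u$individual_id == "a"], 3L)
  ## Roebuck Bay and Eighty Mile Beach in one period -> 2 sites
  expect_equal(u$nSites[u$individual_id == "b"], 2L)
  ## single sighting -> dropped
  expect_false("c" %in% u$individual_id)
})

test_that("multi-year usages collapse to the maximum site count", {
  u <- data.frame(individual_id = "a", species = "GK",
                  periodType = "nonbreeding",
                  periodYear = c(2013L, 2014L, 2015L),
                  nSightings = 2L, nSites = c(1L, 1L, 2L))
  col <- collapseAcrossYears(u)
  expect_equal(col$maxSites, 2L)
  expect_equal(nrow(col), 1L)
  ## single year passes through; no qualifying rows excluded entirely
  expect_equal(collapseAcrossYears(u[1, ])$maxSites, 1L)
  expect_equal(nrow(collapseAcrossYears(u[0, ])), 0L)
})

test_that("seasonal matching pools years and respects the 50 km rule", {
  sameBoth <- rbind(rec("a", "BTG", "2016-05-01", "YJ", YJ[1], YJ[2]),
                    rec("a", "BTG", "2016-08-10", "YJ", YJ[1], YJ[2]))
  expect_true(seasonalMatch(sameBoth, cfg)$matched)
  farApart <- rbind(rec("b", "BTG", "2016-05-01", "YJ", YJ[1], YJ[2]),
                    rec("b", "BTG", "2016-08-10", "BH", BH[1], BH[2]))
  expect_false(seasonalMatch(farApart, cfg)$matched)
  ## different ids but centroids within 50 km still match
  near <- rbind(rec("c", "BTG", "2016-05-01", "YJ", YJ[1], YJ[2]),
                rec("c", "BTG", "2016-08-10", "YJ2", YJ[1] + 0.2, YJ[2]))
  expect_true(seasonalMatch(near, cfg)$matched)
  ## an individual with only northward records is not eligible
  northOnly <- rec("d", "BTG", "2016-05-01", "YJ", YJ[1], YJ[2])
  expect_equal(nrow(seasonalMatch(northOnly, cfg)), 0L)
  ## a 10-of-11 cohort reproduces the matched fraction
  cohort <- do.call(rbind, lapply(1:11, function(i) {
    south <- if (i <= 10) c("YJ", YJ) else c("BH", BH)
    rbind(rec(paste0("m", i), "BTG", "2016-05-01", "YJ", YJ[1], YJ[2]),
          rec(paste0("m", i), "BTG", "2016-08-10", south[1],
              as.numeric(south[2]), as.numeric(south[3])))
  }))
  sm <- seasonalMatch(cohort, cfg)
  expect_equal(sum(sm$matched), 10L)
  expect_equal(nrow(sm), 11L)
})

test_that("between-year matching requires two northward years", {
  twoYears <- rbind(rec("a", "GK", "2010-05-01", "BH", BH[1], BH[2]),
                    rec("a", "GK", "2012-05-05", "BH", BH[1], BH[2]))
  expect_true(betweenYearMatch(twoYears, cfg)$matched)
  diffSites <- rbind(rec("b", "GK", "2010-05-01", "BH", BH[1], BH[2]),
                     rec("b", "GK", "2012-05-05", "YJ", YJ[1], YJ[2]))
  expect_false(betweenYearMatch(diffSites, cfg)$matched)
  oneYear <- rbind(rec("c", "GK", "2010-05-01", "BH", BH[1], BH[2]),
                   rec("c", "GK", "2010-05-20", "BH", BH[1], BH[2]))
  expect_equal(nrow(betweenYearMatch(oneYear, cfg)), 0L)
})

test_that("every individual contributes at most one datapoint per summary", {
  set.seed(71)
  years <- 2012:2016
  cohort <- do.call(rbind, lapply(1:30, function(i) {
    do.call(rbind, lapply(sample(years, sample(3, 1)), function(y) {
      rbind(rec(paste0("i", i), "GK", sprintf("%d-12-01", y), "RB",
                RB[1], RB[2]),
            rec(paste0("i", i), "GK", sprintf("%d-12-15", y), "RB",
                RB[1], RB[2]))
    }))
  }))
  u <- periodUsage(cohort, cfg)
  col <- collapseAcrossYears(u)
  expect_equal(nrow(col), length(unique(col$individual_id)))
  expect_equal(sort(unique(cohort$individual_id)),
               sort(col$individual_id))
})

test_that("summary percentages equal the count ratios exactly", {
  mk <- function(n1, n2, sp, prefix) {
    do.call(rbind, lapply(seq_len(n1 + n2), function(i) {
      sites <- if (i <= n1) list(c("RB", RB), c("RB", RB)) else
        list(c("RB", RB), c("EMB", EMB))
      rbind(rec(paste0(prefix, i), sp, "2015-12-01", sites[[1]][1],
                as.numeric(sites[[1]][2]), as.numeric(sites[[1]][3])),
            rec(paste0(prefix, i), sp, "2016-01-05", sites[[2]][1],
                as.numeric(sites[[2]][2]), as.numeric(sites[[2]][3])))
    }))
  }
  records <- rbind(mk(624, 17, "BTG", "bt"), mk(727, 48, "GK", "gk"))
  rs <- resightSummary(records, cfg)
  expect_equal(unname(rs$nonbreedingSites$table),
               matrix(c(624, 727, 17, 48), 2))
  expect_equal(round(unname(rs$nonbreedingSites$percent), 1),
               c(97.3, 93.8))
  expect_equal(round(rs$nonbreedingSites$fisher$pTwoSided, 3), 0.001)
})
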