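## Resighting-based fidelity metrics. A record enters the non-breeding
## analysis when dated between 1 November and one week before the species'
## first tracked departure; Yellow Sea records inside the seasonal calendar
## windows enter the northward/southward migration analyses. Individuals
## need two or more sightings within a period to qualify, and each
## individual contributes at most one datapoint per summary.

#' Assign resighting records to analysis periods
#'
#' Yellow Sea records dated inside the northward (southward) calendar
#' window are assigned to the northward (southward) migration of that
#' calendar year. Other records dated between
#' \code{cfg$nonbreedingResightStart} (1 November) and one week before the
#' species first departure are assigned to the non-breeding period, whose
#' year is the year containing the 1 November. Everything else gets NA.
#'
#' @param records resighting data.frame (see \code{\link{readResightings}}).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return the records with \code{periodType} and \code{periodYear} columns
#'   appended.
#' @export
assignPeriod <- function(records, cfg = pipelineConfig()) {
  n <- nrow(records)
  periodType <- rep(NA_character_, n)
  periodYear <- rep(NA_integer_, n)
  if (n) {
    mdn <- .dateMdNum(records$date)
    yr <- as.integer(format(records$date, "%Y"))
    inYs <- pointInRegion(records$site_lat, records$site_lon,
                          cfg$regions$yellowSea)
    nw <- .mdNum(cfg$northWindow); sw <- .mdNum(cfg$southWindow)
    north <- inYs & mdn >= nw[1] & mdn <= nw[2]
    south <- inYs & mdn >= sw[1] & mdn <= sw[2]
    periodType[north] <- "northward"
    periodType[south] <- "southward"
    periodYear[north | south] <- yr[north | south]
    startMd <- .mdNum(cfg$nonbreedingResightStart)
    cutMd <- .mdNum(vapply(records$species, .departureCutoffMd,
                           character(1), cfg = cfg))
    nb <- !inYs & is.na(periodType) & (mdn >= startMd | mdn <= cutMd)
    periodType[nb] <- "nonbreeding"
    periodYear[nb] <- ifelse(mdn[nb] >= startMd, yr[nb], yr[nb] - 1L)
  }
  records$periodType <- periodType
  records$periodYear <- periodYear
  records
}

#' Sightings and distinct sites per individual-period
#'
#' Counts sightings and distinct sites for every (individual, period type,
#' period year) combination and drops those with fewer than
#' \code{cfg$minSightings} sightings.
#'
#' @param records resighting data.frame; period columns are added with
#'   \code{\link{assignPeriod}} if absent.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return data.frame with \code{individual_id}, \code{species},
#'   \code{periodType}, \code{periodYear}, \code{nSightings},
#'   \code{nSites}.
#' @export
periodUsage <- function(records, cfg = pipelineConfig()) {
  if (is.null(records$periodType)) records <- assignPeriod(records, cfg)
  records <- records[!is.na(records$periodType), , drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(individual_id = character(), species = character(),
                      periodType = character(), periodYear = integer(),
                      nSightings = integer(), nSites = integer()))
  key <- interaction(records$individual_id, records$periodType,
                     records$periodYear, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    sub <- records[ix, , drop = FALSE]
    data.frame(individual_id = sub$individual_id[1],
               species = sub$species[1],
               periodType = sub$periodType[1],
               periodYear = sub$periodYear[1],
               nSightings = nrow(sub),
               nSites = length(unique(sub$site_id)))
  })
  out <- .rbindRows(rows)
  out <- out[out$nSightings >= cfg$minSightings, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse multi-year usages to one value per individual
#'
#' Takes the maximum number of sites an individual was observed at within a
#' single qualifying period of the given type (guards against
#' pseudo-replication across years).
#'
#' @param usages output of \code{\link{periodUsage}}.
#' @param periodType which period type to collapse (default nonbreeding).
#' @return data.frame with one row per individual: \code{individual_id},
#'   \code{species}, \code{maxSites}, \code{nPeriods}.
#' @export
collapseAcrossYears <- function(usages, periodType = "nonbreeding") {
  usages <- usages[usages$periodType == periodType, , drop = FALSE]
  if (nrow(usages) == 0)
    return(data.frame(individual_id = character(), species = character(),
                      maxSites = integer(), nPeriods = integer()))
  rows <- lapply(split(seq_len(nrow(usages)), usages$individual_id),
                 function(ix) {
    sub <- usages[ix, , drop = FALSE]
    data.frame(individual_id = sub$individual_id[1],
               species = sub$species[1],
               maxSites = max(sub$nSites), nPeriods = nrow(sub))
  })
  out <- .rbindRows(rows)
  rownames(out) <- NULL
  out
}

## same-site test: identical id, or centroids within cfg$revisitKm
.sameSite <- function(idA, latA, lonA, idB, latB, lonB, cfg) {
  idA == idB | gcDistKm(latA, lonA, latB, lonB) <= cfg$revisitKm
}

#' Seasonal site match from resightings
#'
#' For each individual with at least one northward and one southward
#' Yellow Sea record in the same calendar year, reports whether some site
#' (same id, or sites within \code{cfg$revisitKm}) was used in both
#' seasons. Years are pooled: an individual matches when any year matches.
#'
#' @param records resighting data.frame (periods are assigned if absent).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return data.frame with one row per eligible individual:
#'   \code{individual_id}, \code{species}, \code{matched}.
#' @export
seasonalMatch <- function(records, cfg = pipelineConfig()) {
  if (is.null(records$periodType)) records <- assignPeriod(records, cfg)
  rec <- records[!is.na(records$periodType) &
                   records$periodType %in% c("northward", "southward"), ,
                 drop = FALSE]
  empty <- data.frame(individual_id = character(), species = character(),
                      matched = logical())
  if (nrow(rec) == 0) return(empty)
  rows <- lapply(split(seq_len(nrow(rec)), rec$individual_id),
                 function(ix) {
    sub <- rec[ix, , drop = FALSE]
    matched <- NA
    for (yr in unique(sub$periodYear)) {
      no <- sub[sub$periodYear == yr & sub$periodType == "northward", ]
      so <- sub[sub$periodYear == yr & sub$periodType == "southward", ]
      if (nrow(no) == 0 || nrow(so) == 0) next
      if (is.na(matched)) matched <- FALSE
      for (i in seq_len(nrow(no)))
        if (any(.sameSite(no$site_id[i], no$site_lat[i], no$site_lon[i],
                          so$site_id, so$site_lat, so$site_lon, cfg)))
          matched <- TRUE
    }
    if (is.na(matched)) return(NULL)  # never both seasons in one year
    data.frame(individual_id = sub$individual_id[1],
               species = sub$species[1], matched = matched)
  })
  out <- .rbindRows(rows)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Between-year northward site match from resightings
#'
#' For each individual resighted in at least two distinct northward
#' migration years in the Yellow Sea, reports whether some site (same id or
#' within \code{cfg$revisitKm}) was used in two or more different years.
#'
#' @param records resighting data.frame (periods are assigned if absent).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return data.frame with one row per eligible individual:
#'   \code{individual_id}, \code{species}, \code{matched}.
#' @export
betweenYearMatch <- function(records, cfg = pipelineConfig()) {
  if (is.null(records$periodType)) records <- assignPeriod(records, cfg)
  rec <- records[!is.na(records$periodType) &
                   records$periodType == "northward", , drop = FALSE]
  empty <- data.frame(individual_id = character(), species = character(),
                      matched = logical())
  if (nrow(rec) == 0) return(empty)
  rows <- lapply(split(seq_len(nrow(rec)), rec$individual_id),
                 function(ix) {
    sub <- rec[ix, , drop = FALSE]
    yrs <- unique(sub$periodYear)
    if (length(yrs) < 2) return(NULL)
    matched <- FALSE
    for (i in seq_len(nrow(sub))) {
      other <- sub$periodYear != sub$periodYear[i]
      if (any(other) &&
          any(.sameSite(sub$site_id[i], sub$site_lat[i], sub$site_lon[i],
                        sub$site_id[other], sub$site_lat[other],
                        sub$site_lon[other], cfg))) {
        matched <- TRUE
        break
      }
    }
    data.frame(individual_id = sub$individual_id[1],
               species = sub$species[1], matched = matched)
  })
  out <- .rbindRows(rows)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Species-level summary of resighting-based fidelity with exact tests
#'
#' Builds the 2x2 contingency tables (one site vs two or more sites in a
#' non-breeding period; seasonal match vs not; between-year match vs not)
#' with exact percentages, and runs the exact Fisher test on each.
#'
#' @param records resighting data.frame.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param speciesOrder order of the two species in tables (rows).
#' @return list of summary blocks, each with the table, percentages, n and
#'   the Fisher result; blocks are omitted when no individual qualifies.
#' @export
resightSummary <- function(records, cfg = pipelineConfig(),
                           speciesOrder = c("BTG", "GK")) {
  records <- assignPeriod(records, cfg)
  usages <- periodUsage(records, cfg)
  out <- list()
  block <- function(df, okCol, okName, badName) {
    tab <- t(vapply(speciesOrder, function(sp) {
      ok <- df[[okCol]][df$species == sp]
      c(sum(ok), sum(!ok))
    }, numeric(2)))
    colnames(tab) <- c(okName, badName)
    list(table = tab, percent = 100 * tab[, 1] / rowSums(tab),
         n = rowSums(tab), fisher = fisherExact2x2(tab))
  }
  nb <- collapseAcrossYears(usages, "nonbreeding")
  if (nrow(nb)) {
    nb$oneSite <- nb$maxSites == 1
    out$nonbreedingSites <- block(nb, "oneSite", "oneSite", "multiSite")
  }
  nwu <- collapseAcrossYears(usages, "northward")
  if (nrow(nwu)) {
    nwu$oneSite <- nwu$maxSites == 1
    out$northwardSites <- block(nwu, "oneSite", "oneSite", "multiSite")
  }
  sm <- seasonalMatch(records, cfg)
  if (nrow(sm))
    out$seasonalMatch <- block(sm, "matched", "matched", "notMatched")
  by <- betweenYearMatch(records, cfg)
  if (nrow(by))
    out$betweenYearMatch <- block(by, "matched", "matched", "notMatched")
  out
}
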