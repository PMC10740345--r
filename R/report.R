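## End-to-end orchestration: filter every track, compute the per-individual
## metrics, and assemble the species comparison report (the shape of the
## study's Tables 1 and 2).

#' Non-breeding usage for every track in a set
#'
#' Applies the hybrid Argos filter and \code{\link{nonbreedingUsage}} to
#' each track.
#'
#' @param tracks a \code{\link{TrackSet}} (raw; filtering is applied here).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param smooth run the state-space smoother before site detection.
#' @return data.frame of per-individual usages (excluded birds dropped).
#' @export
analyzeNonbreeding <- function(tracks, cfg = pipelineConfig(),
                               smooth = FALSE) {
  rows <- lapply(trackList(tracks), function(tr) {
    ft <- hybridFilter(tr, cfg)$retained
    if (smooth && nFixes(ft) >= 4) ft <- fitRwSsm(ft, cfg)$track
    nonbreedingUsage(ft, cfg)
  })
  out <- .rbindRows(rows)
  if (is.null(out))
    out <- data.frame(individualId = character(), species = character(),
                      nSitesUsed = integer(), moved = logical())
  out
}

#' Seasonal Yellow Sea revisitation for every track in a set
#'
#' Filters each track, builds its per-season Yellow Sea itinerary, takes
#' the first tracked migration (earliest year with any Yellow Sea site)
#' and computes \code{\link{seasonalRevisit}}.
#'
#' @param tracks a \code{\link{TrackSet}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param smooth run the state-space smoother before site detection.
#' @return list with \code{revisits} (per-individual data.frame) and
#'   \code{sites} (all itinerary sites, row-bound).
#' @export
analyzeSeasonal <- function(tracks, cfg = pipelineConfig(),
                            smooth = FALSE) {
  revRows <- list(); siteRows <- list()
  for (tr in trackList(tracks)) {
    ft <- hybridFilter(tr, cfg)$retained
    if (smooth && nFixes(ft) >= 4) ft <- fitRwSsm(ft, cfg)$track
    sites <- buildItinerary(ft, cfg)
    if (nrow(sites)) siteRows[[length(siteRows) + 1]] <- sites
    if (nrow(sites) == 0) next
    yr <- min(sites$year)
    no <- sites[sites$year == yr & sites$season == "northward", ,
                drop = FALSE]
    so <- sites[sites$year == yr & sites$season == "southward", ,
                drop = FALSE]
    rv <- seasonalRevisit(no, so, cfg)
    if (!is.null(rv)) {
      rv$individualId <- individualId(tr)
      rv$species <- speciesOf(tr)
      revRows[[length(revRows) + 1]] <- rv
    }
  }
  revisits <- .rbindRows(revRows)
  if (is.null(revisits))
    revisits <- data.frame(revisited = logical(),
                           propTimeRevisited = numeric(),
                           nSitesNorth = integer(), nSitesSouth = integer(),
                           individualId = character(),
                           species = character())
  sites <- .rbindRows(siteRows)
  list(revisits = revisits, sites = sites)
}

#' Full fidelity report from tracking and/or resighting data
#'
#' Runs the tracking pipeline (non-breeding usage and, when migration data
#' are present, seasonal revisitation) and the resighting metrics, and
#' assembles species comparisons with exact Fisher tests and fractional
#' regression.
#'
#' @param tracks optional \code{\link{TrackSet}}.
#' @param resightings optional resighting data.frame.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param smooth run the state-space smoother before site detection.
#' @return list of class \code{"fidelityReport"} with components
#'   \code{tracking} (from \code{\link{speciesSummary}}) and
#'   \code{resighting} (from \code{\link{resightSummary}}).
#' @export
fidelityReport <- function(tracks = NULL, resightings = NULL,
                           cfg = pipelineConfig(), smooth = FALSE) {
  if (is.null(tracks) && is.null(resightings))
    stop("at least one of tracks or resightings is required")
  tracking <- NULL
  if (!is.null(tracks)) {
    usages <- analyzeNonbreeding(tracks, cfg, smooth = smooth)
    seas <- analyzeSeasonal(tracks, cfg, smooth = smooth)
    tracking <- speciesSummary(usages = usages, revisits = seas$revisits)
  }
  resighting <- NULL
  if (!is.null(resightings) && nrow(resightings))
    resighting <- resightSummary(resightings, cfg)
  structure(list(tracking = tracking, resighting = resighting),
            class = "fidelityReport")
}

#' @export
print.fidelityReport <- function(x, ...) {
  fmtPct <- function(v) sprintf("%.1f%%", v)
  if (!is.null(x$tracking)) {
    cat("== Tracking-based site fidelity ==\n")
    tb <- x$tracking
    if (!is.null(tb$nonbreedingStay)) {
      b <- tb$nonbreedingStay
      cat("Remained at one site during the non-breeding period:\n")
      for (sp in rownames(b$table))
        cat(sprintf("  %-4s %s (n = %d)\n", sp,
                    fmtPct(b$percentStayed[sp]), b$n[sp]))
      cat(sprintf("  Fisher exact p = %.3f\n", b$fisher$pTwoSided))
    }
    if (!is.null(tb$postMigrationReturn)) {
      b <- tb$postMigrationReturn
      cat("Returned to the same non-breeding site after migration:\n")
      for (sp in rownames(b$table))
        cat(sprintf("  %-4s %s (n = %d)\n", sp,
                    fmtPct(b$percentReturned[sp]), b$n[sp]))
      cat(sprintf("  Fisher exact p = %.3f\n", b$fisher$pTwoSided))
    }
    if (!is.null(tb$seasonalRevisit)) {
      b <- tb$seasonalRevisit
      cat("Revisited the same Yellow Sea site(s) in both seasons:\n")
      for (sp in rownames(b$table))
        cat(sprintf("  %-4s %s (n = %d); median sites N %s (%s), S %s (%s)\n",
                    sp, fmtPct(b$percentRevisited[sp]), b$n[sp],
                    b$medianSitesNorth[sp], b$rangeSitesNorth[sp],
                    b$medianSitesSouth[sp], b$rangeSitesSouth[sp]))
      cat(sprintf("  Fisher exact p = %.3f\n", b$fisher$pTwoSided))
      if (!is.null(b$fractional))
        cat(sprintf(
          "  Proportion of time at revisited sites: medians %s; fractional regression p = %.3f\n",
          paste(fmtPct(100 * b$medianPropTime), collapse = " vs "),
          b$fractional$pValue))
    }
  }
  if (!is.null(x$resighting)) {
    cat("== Resighting-based site fidelity ==\n")
    lbl <- c(nonbreedingSites = "One non-breeding site",
             northwardSites = "One Yellow Sea site within northward migration",
             seasonalMatch = "Same Yellow Sea site in both seasons",
             betweenYearMatch = "Same Yellow Sea site across northward years")
    for (nm in names(x$resighting)) {
      b <- x$resighting[[nm]]
      cat(lbl[nm], ":\n", sep = "")
      for (sp in rownames(b$table))
        cat(sprintf("  %-4s %s (n = %d)\n", sp, fmtPct(b$percent[sp]),
                    b$n[sp]))
      cat(sprintf("  Fisher exact p = %.3f\n", b$fisher$pTwoSided))
    }
  }
  invisible(x)
}

#' Flatten a fidelity report into a tidy data.frame
#'
#' One row per species per comparison, with counts, percentage and the
#' test p-value; convenient for CSV export.
#'
#' @param report a \code{\link{fidelityReport}} result.
#' @return data.frame.
#' @export
reportTable <- function(report) {
  rows <- list()
  add <- function(metric, source, blk, pct) {
    for (sp in rownames(blk$table))
      rows[[length(rows) + 1]] <<- data.frame(
        source = source, metric = metric, species = sp,
        n = unname(blk$n[sp]), count_yes = unname(blk$table[sp, 1]),
        count_no = unname(blk$table[sp, 2]),
        percent = unname(pct[sp]),
        fisher_p = blk$fisher$pTwoSided)
  }
  tb <- report$tracking
  if (!is.null(tb$nonbreedingStay))
    add("stayed_one_site", "tracking", tb$nonbreedingStay,
        tb$nonbreedingStay$percentStayed)
  if (!is.null(tb$postMigrationReturn))
    add("returned_after_migration", "tracking", tb$postMigrationReturn,
        tb$postMigrationReturn$percentReturned)
  if (!is.null(tb$seasonalRevisit))
    add("seasonal_revisit", "tracking", tb$seasonalRevisit,
        tb$seasonalRevisit$percentRevisited)
  rb <- report$resighting
  for (nm in names(rb)) add(nm, "resighting", rb[[nm]], rb[[nm]]$percent)
  .rbindRows(rows)
}
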