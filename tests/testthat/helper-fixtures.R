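## Shared fixture builders: small tracks and CSV files constructed in code.

utc <- function(s) as.POSIXct(s, tz = "UTC")

## a track from offsets (hours) and km east/north displacements from a base
## point, using a locally flat conversion (fine for the few-km fixtures)
kmTrack <- function(id = "b1", species = "GK", t0 = utc("2016-04-10 00:00"),
                    hours, eastKm, northKm, locClass = "3",
                    baseLat = 35, baseLon = 121, ...) {
  lat <- baseLat + northKm / 111.1951
  lon <- baseLon + eastKm / (111.1951 * cos(baseLat * pi / 180))
  n <- length(hours)
  Track(id, species,
        data.frame(timestamp = t0 + hours * 3600, lat = lat, lon = lon,
                   locClass = rep_len(locClass, n), ...))
}

## scatter n points (km displacements) around a centre with given sd
scatterLocs <- function(n, centerLat, centerLon, sdKm, t0, stepH = 3) {
  dx <- rnorm(n, 0, sdKm); dy <- rnorm(n, 0, sdKm)
  data.frame(fixIdx = seq_len(n), timestamp = t0 + (0:(n - 1)) * stepH * 3600,
             lat = centerLat + dy / 111.1951,
             lon = centerLon + dx / (111.1951 * cos(centerLat * pi / 180)),
             speedKmh = 0)
}

telemetryCsv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

## minimal well-formed telemetry rows
telemetryRows <- function(n = 3, id = "b1", species = "GK",
                          ts = NULL, locClass = "3") {
  if (is.null(ts))
    ts <- format(utc("2015-10-01 00:00") + (seq_len(n) - 1) * 3600,
                 "%Y-%m-%dT%H:%M:%SZ")
  data.frame(individual_id = id, species = species, timestamp = ts,
             lat = -18 - 0.01 * seq_len(n), lon = 122.3,
             loc_class = rep_len(locClass, n),
             smaj_m = NA, smin_m = NA, eor_deg = NA)
}
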