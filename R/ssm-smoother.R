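## Random-walk state-space smoother. The state is the true position in a
## local azimuthal-equidistant plane (km east/north of the track's median
## position); between fixes the position diffuses with covariance
## sigma^2 * dt * I, and each Argos fix observes it with the per-fix error
## covariance (from the error ellipse when present, else class defaults).
## A forward Kalman filter plus backward RTS smoother produces fitted
## locations; sigma is estimated by maximising the innovations likelihood.

## radial 68th percentile of a bivariate isotropic normal = sigma * 1.5096
.R68_FACTOR <- sqrt(qchisq(0.68, df = 2))

#' Observation covariance of one Argos fix
#'
#' If the fix carries an error ellipse, the 2x2 covariance (km^2, local
#' east/north axes) is built from the semi-axes (interpreted as 1-sigma,
#' metres) rotated by the ellipse orientation (degrees clockwise from
#' north). Otherwise an isotropic covariance is used whose radial 68th
#' percentile equals the class default in \code{cfg$classR68Km}
#' (3/2/1 -> 0.25/0.5/1.5 km; 0/A/B/Z -> 5/8/15/15 km).
#'
#' @param locClass Argos class of the fix.
#' @param smajM,sminM,eorDeg error-ellipse semi-major/minor (m) and
#'   orientation (deg clockwise from north); may be NA.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return symmetric positive semi-definite 2x2 matrix (km^2).
#' @export
obsCovariance <- function(locClass, smajM = NA, sminM = NA, eorDeg = NA,
                          cfg = pipelineConfig()) {
  if (!is.na(smajM) && !is.na(sminM)) {
    if (sminM > smajM) stop("ellipse semi-minor exceeds semi-major")
    a <- smajM / 1000; b <- sminM / 1000
    th <- (if (is.na(eorDeg)) 0 else eorDeg) * pi / 180
    ## orientation clockwise from north: major axis unit vector (east, north)
    u <- c(sin(th), cos(th)); v <- c(cos(th), -sin(th))
    a^2 * tcrossprod(u) + b^2 * tcrossprod(v)
  } else {
    r68 <- cfg$classR68Km[as.character(locClass)]
    if (is.na(r68)) stop("unknown location class '", locClass, "'")
    sig <- unname(r68) / .R68_FACTOR
    diag(sig^2, 2)
  }
}

## forward Kalman filter; returns filtered/predicted moments and loglik
.kalmanForward <- function(y, Rs, dtH, sigma) {
  n <- nrow(y)
  mF <- matrix(0, n, 2); PF <- vector("list", n)
  mP <- matrix(0, n, 2); PP <- vector("list", n)
  jitter <- diag(1e-9, 2)  # guards singular observation covariances
  ## the first fix initialises the state: posterior = (y1, R1)
  mF[1, ] <- y[1, ]; PF[[1]] <- Rs[[1]] + jitter
  mP[1, ] <- mF[1, ]; PP[[1]] <- PF[[1]]
  ll <- 0
  for (t in seq_len(n)[-1]) {
    mp <- mF[t - 1, ]
    Pp <- PF[[t - 1]] + diag(sigma^2 * dtH[t - 1], 2)
    mP[t, ] <- mp; PP[[t]] <- Pp
    S <- Pp + Rs[[t]] + jitter
    v <- y[t, ] - mp
    detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2) / detS
    ll <- ll - 0.5 * (log(detS) + drop(t(v) %*% Sinv %*% v) +
                        2 * log(2 * pi))
    K <- Pp %*% Sinv
    mF[t, ] <- mp + drop(K %*% v)
    PF[[t]] <- (diag(2) - K) %*% Pp
  }
  list(mF = mF, PF = PF, mP = mP, PP = PP, logLik = ll)
}

#' Fit the random-walk state-space smoother to one track
#'
#' Projects the track into a local azimuthal-equidistant plane centred on
#' its median position, runs a linear-Gaussian random-walk model (process
#' covariance \code{sigma^2 * dt * I}, observation covariance from
#' \code{\link{obsCovariance}}), smooths with the RTS recursion, and
#' re-projects fitted positions to lon/lat. Unless \code{sigma} is supplied,
#' the process-noise scale is estimated by a bounded one-dimensional search
#' over \code{cfg$sigmaBoundsKmSqrtH} (log scale, relative tolerance 1e-4)
#' maximising the innovations likelihood.
#'
#' @param track a filtered \code{\link{Track}} with at least 4 fixes (fewer
#'   fixes: returned unsmoothed with a warning).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param sigma optional fixed process-noise scale (km per sqrt hour).
#' @return list with \code{track} (the input Track gaining fix columns
#'   \code{fittedLat}, \code{fittedLon}, \code{fittedVarKm2} = trace of the
#'   smoothed position covariance), \code{sigmaKmSqrtH} and \code{logLik}.
#' @export
fitRwSsm <- function(track, cfg = pipelineConfig(), sigma = NULL) {
  fx <- fixes(track)
  n <- nrow(fx)
  if (n < 4) {
    warning("track '", individualId(track),
            "' has fewer than 4 fixes; smoothing skipped")
    return(list(track = track, sigmaKmSqrtH = NA_real_,
                logLik = NA_real_))
  }
  ctrLat <- median(fx$lat); ctrLon <- median(fx$lon)
  y <- projectAeqd(fx$lat, fx$lon, ctrLat, ctrLon)
  Rs <- lapply(seq_len(n), function(i)
    obsCovariance(fx$locClass[i], fx$smajM[i], fx$sminM[i], fx$eorDeg[i],
                  cfg))
  dtH <- diff(as.numeric(fx$timestamp)) / 3600
  if (is.null(sigma)) {
    nll <- function(logSig)
      -.kalmanForward(y, Rs, dtH, exp(logSig))$logLik
    opt <- optimize(nll, interval = log(cfg$sigmaBoundsKmSqrtH),
                    tol = 1e-4)
    sigma <- exp(opt$minimum)
  }
  kf <- .kalmanForward(y, Rs, dtH, sigma)
  ## backward RTS smoother
  mS <- kf$mF; PS <- kf$PF
  for (t in seq(n - 1, 1)) {
    Pp <- kf$PP[[t + 1]]
    detP <- Pp[1, 1] * Pp[2, 2] - Pp[1, 2] * Pp[2, 1]
    Pinv <- matrix(c(Pp[2, 2], -Pp[2, 1], -Pp[1, 2], Pp[1, 1]), 2) / detP
    C <- kf$PF[[t]] %*% Pinv
    mS[t, ] <- kf$mF[t, ] + drop(C %*% (mS[t + 1, ] - kf$mP[t + 1, ]))
    PS[[t]] <- kf$PF[[t]] + C %*% (PS[[t + 1]] - Pp) %*% t(C)
  }
  ll <- unprojectAeqd(mS, ctrLat, ctrLon)
  fx$fittedLat <- ll[, "lat"]
  fx$fittedLon <- ll[, "lon"]
  fx$fittedVarKm2 <- vapply(PS, function(P) P[1, 1] + P[2, 2], numeric(1))
  out <- Track(individualId(track), speciesOf(track), fx,
               releaseTime = releaseTime(track))
  list(track = out, sigmaKmSqrtH = sigma, logLik = kf$logLik)
}
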