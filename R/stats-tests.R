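## The two inferential procedures used throughout: the exact two-sided
## Fisher test (probability-mass convention) and fractional logit
## regression for proportion responses.

## log hypergeometric point probabilities over the full support of the
## upper-left cell, given margins (r1, r2 rows; c1 first column)
.logHyperProbs <- function(r1, r2, c1) {
  n <- r1 + r2
  aMin <- max(0, c1 - r2); aMax <- min(r1, c1)
  a <- aMin:aMax
  lp <- (lgamma(r1 + 1) - lgamma(a + 1) - lgamma(r1 - a + 1)) +
    (lgamma(r2 + 1) - lgamma(c1 - a + 1) - lgamma(r2 - (c1 - a) + 1)) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  list(a = a, lp = lp)
}

## two-sided p-values for every feasible upper-left cell given the margins;
## used by fisherExact2x2 and by the exhaustive-agreement tests
.fisherPvalsForMargins <- function(r1, r2, c1, tieTol = 1e-7) {
  h <- .logHyperProbs(r1, r2, c1)
  p <- exp(h$lp)
  vapply(seq_along(h$a), function(i)
    min(1, sum(p[p <= p[i] * (1 + tieTol)])), numeric(1))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' With both margins fixed, enumerates every feasible table, computes its
#' hypergeometric point probability via log-gamma, and sums the
#' probabilities of all tables as or less probable than the observed one
#' (relative tie tolerance 1e-7) — the probability-mass two-sided
#' convention. A table with a zero margin is degenerate and returns p = 1.
#'
#' @param a,b,c,d cell counts (row 1: a, b; row 2: c, d), or a 2x2 matrix
#'   as \code{a}.
#' @return list of class \code{"fisherResult"}: \code{pTwoSided},
#'   \code{oddsRatio} (sample cross-product ratio) and \code{table}.
#' @examples
#' fisherExact2x2(24, 0, 34, 7)$pTwoSided  # 0.041
#' @export
fisherExact2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (sum(tab) <= 0) stop("table total must be positive")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0) {
    message("degenerate table (zero margin); p = 1")
    p <- 1
  } else {
    pv <- .fisherPvalsForMargins(r1, r2, c1)
    h <- .logHyperProbs(r1, r2, c1)
    p <- pv[match(tab[1, 1], h$a)]
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(pTwoSided = unname(p), oddsRatio = unname(or),
                 table = tab), class = "fisherResult")
}

#' @export
print.fisherResult <- function(x, ...) {
  cat("Exact two-sided Fisher test\n")
  print(x$table)
  cat(sprintf("p = %.3f, sample odds ratio = %.3g\n",
              x$pTwoSided, x$oddsRatio))
  invisible(x)
}

#' Fractional logit regression for a two-group proportion comparison
#'
#' Quasi-binomial GLM with logit link fitted by iteratively reweighted
#' least squares (via \code{glm}); the response may include exact 0s and
#' 1s. Dispersion is estimated by Pearson chi-square over residual degrees
#' of freedom and the group effect tested by a two-sided Wald test. Perfect
#' separation (the groups' responses occupy opposite boundaries) is
#' flagged, with a two-sided exact rank test (Wilcoxon) as fallback
#' p-value.
#'
#' @param y proportions in [0, 1].
#' @param group two-level factor (or coercible) of group labels.
#' @return list of class \code{"fracRegResult"}: \code{intercept},
#'   \code{groupCoef} (logit scale), \code{se}, \code{pValue},
#'   \code{dispersion}, \code{n}, \code{separation}.
#' @examples
#' set.seed(1)
#' y <- c(rbeta(20, 8, 2), rbeta(20, 2, 8))
#' g <- rep(c("BTG", "GK"), each = 20)
#' fractionalLogit(y, g)$pValue
#' @export
fractionalLogit <- function(y, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  fit <- glm(y ~ g, family = quasibinomial(link = "logit"),
             control = list(epsilon = 1e-8, maxit = 100))
  sm <- summary(fit)  # Pearson chi-square / df dispersion
  co <- sm$coefficients
  sep <- all(y[g == levels(g)[1]] %in% c(0, 1)) &&
    all(y[g == levels(g)[2]] %in% c(0, 1)) &&
    length(unique(round(fit$fitted.values, 8))) == 2 &&
    abs(coef(fit)[2]) > 15
  pValue <- co[2, "Pr(>|t|)"]
  if (sep || !is.finite(pValue)) {
    if (sep) warning("perfect separation; p-value from exact rank test")
    pValue <- suppressWarnings(wilcox.test(y ~ g, exact = TRUE)$p.value)
  }
  structure(list(intercept = unname(coef(fit)[1]),
                 groupCoef = unname(coef(fit)[2]),
                 se = unname(co[2, "Std. Error"]),
                 pValue = unname(pValue),
                 dispersion = sm$dispersion,
                 n = length(y),
                 separation = sep),
            class = "fracRegResult")
}

#' @export
print.fracRegResult <- function(x, ...) {
  cat("Fractional logit regression (quasi-binomial, Pearson dispersion)\n")
  cat(sprintf("  group coefficient = %.3f (SE %.3f), p = %.3g, n = %d\n",
              x$groupCoef, x$se, x$pValue, x$n))
  if (x$separation) cat("  [perfect separation; rank-test fallback]\n")
  invisible(x)
}
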