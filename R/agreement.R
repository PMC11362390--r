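#' Construct a loop midline
#'
#' @param points n x 2 numeric matrix of (row, col) pixel coordinates
#'   tracing the loop midline, in order.
#' @param pixelSize cm per pixel.
#' @param ischemicDirection \code{"end"} (default) if increasing
#'   arclength runs toward ischemic tissue, \code{"start"} otherwise.
#'
#' @return a \linkS4class{MidlinePath}.
#' @export
midlinePath <- function(points, pixelSize = 0.04,
                        ischemicDirection = c("end", "start")) {
  ischemicDirection <- match.arg(ischemicDirection)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  new("MidlinePath", points = points, pixelSize = pixelSize,
      ischemicDirection = ischemicDirection)
}

## Project a point onto the midline polyline: returns the arclength (px)
## of the nearest point and the Euclidean distance (px) to it.
projectOnMidline <- function(midline, point) {
  p <- midline@points
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  segLen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(segLen))
  best <- c(dist = Inf, arc = 0)
  for (i in seq_len(nrow(p) - 1L)) {
    d <- point - p[i, ]
    t <- sum(d * seg[i, ]) / segLen[i]^2
    t <- min(max(t, 0), 1)
    foot <- p[i, ] + t * seg[i, ]
    dd <- sqrt(sum((point - foot)^2))
    if (dd < best["dist"])
      best <- c(dist = dd, arc = cum[i] + t * segLen[i])
  }
  best
}

#' Signed along-midline distance between two ROI placements
#'
#' Projects the reference (operating surgeon) and observed placements
#' onto the loop midline and measures the arclength between the feet, in
#' cm.  The sign follows the study's convention: positive toward ischemic
#' tissue, negative toward well-perfused tissue.
#'
#' @param midline a \linkS4class{MidlinePath}.
#' @param reference,observed numeric length-2 (row, col) pixel positions.
#' @param snapRadius maximum Euclidean distance (px) a point may lie off
#'   the midline; beyond it the placement is rejected as a data error.
#'
#' @return signed distance in cm.
#'
#' @examples
#' ml <- midlinePath(cbind(50, seq(1, 500)), pixelSize = 0.01)
#' signedMidlineDistance(ml, c(50, 300), c(50, 420))  # +1.2 cm
#'
#' @export
signedMidlineDistance <- function(midline, reference, observed,
                                  snapRadius = 50) {
  stopifnot(is(midline, "MidlinePath"))
  pr <- projectOnMidline(midline, as.numeric(reference))
  po <- projectOnMidline(midline, as.numeric(observed))
  if (pr["dist"] > snapRadius || po["dist"] > snapRadius)
    stop(sprintf("placement lies %.1f px off the midline (snap radius %g)",
                 max(pr["dist"], po["dist"]), snapRadius))
  d <- (po["arc"] - pr["arc"]) * midline@pixelSize
  if (midline@ischemicDirection == "start") d <- -d
  unname(d)
}

#' Fraction of placements within a distance limit
#'
#' @param distances signed distances in cm; NA entries (declined
#'   placements) are excluded from the denominator.
#' @param limit distance limit in cm (> 0).
#'
#' @return list with \code{fraction} (share with |d| <= limit among
#'   non-missing), \code{n} (non-missing count) and \code{nMissing}.
#'
#' @examples
#' fractionWithin(c(0.5, -0.8, 1.2, 2.5), 1)$fraction  # 0.5
#'
#' @export
fractionWithin <- function(distances, limit = 1) {
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0)
    stop("'limit' must be a single positive number")
  if (!length(distances)) stop("'distances' must be non-empty")
  miss <- is.na(distances)
  d <- distances[!miss]
  if (!length(d)) stop("all distances are missing")
  list(fraction = mean(abs(d) <= limit), n = length(d),
       nMissing = sum(miss))
}

#' Discretize placement distances into agreement categories
#'
#' Maps signed distances to ordinal categories for the kappa analysis.
#' With the default +/- 1 cm edges the categories are
#' \code{toward_well} (d <= -1), \code{within} (-1 < d <= +1, bins are
#' right-closed) and \code{toward_ischemic} (d > +1).  Missing distances
#' (declined placements) get the dedicated category \code{missing}.
#'
#' @param distances signed distances in cm (NA = declined).
#' @param binEdges strictly increasing edges including -Inf and +Inf.
#' @param labels category labels, one fewer than \code{binEdges}.
#'
#' @return factor of categories with a \code{missing} level appended when
#'   needed.
#' @export
placementCategories <- function(distances,
                                binEdges = c(-Inf, -1, 1, Inf),
                                labels = c("toward_well", "within",
                                           "toward_ischemic")) {
  if (any(diff(binEdges) <= 0))
    stop("'binEdges' must be strictly increasing")
  if (length(labels) != length(binEdges) - 1L)
    stop("need one label per bin")
  f <- cut(distances, breaks = binEdges, labels = labels, right = TRUE)
  if (anyNA(distances)) {
    f <- factor(f, levels = c(labels, "missing"))
    f[is.na(distances)] <- "missing"
  }
  f
}

#' Cohen's kappa with a bootstrap confidence interval
#'
#' Unweighted Cohen's kappa \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two raters' categorical labels, with expected agreement from the
#' marginal products.  The 95\% confidence interval is a seeded
#' percentile bootstrap (default 2000 resamples) stratified by the first
#' rater's label, which preserves the reference marginal; no asymptotic
#' normality is assumed.  Pairs with a missing label in either rater are
#' excluded pairwise and reported via \code{nPairs}.
#'
#' @param a,b equal-length label vectors (character or factor).
#' @param nBoot bootstrap resamples; 0 skips the CI.
#' @param seed seed for the bootstrap.
#'
#' @return a \linkS4class{KappaResult}.  When both raters assign the
#'   single same label throughout, expected agreement is 1 and kappa is
#'   undefined (NA, with a warning).
#'
#' @examples
#' a <- rep(c("x", "y"), c(25, 25))
#' b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
#' kappaValue(cohensKappa(a, b, nBoot = 0))  # 0.4
#'
#' @export
cohensKappa <- function(a, b, nBoot = 2000, seed = 1) {
  if (length(a) != length(b))
    stop("'a' and 'b' must have the same length")
  keep <- !is.na(a) & !is.na(b)
  a <- as.character(a)[keep]; b <- as.character(b)[keep]
  if (length(a) < 2L) stop("need at least 2 complete pairs")
  cats <- sort(unique(c(a, b)))
  kap <- function(aa, bb) {
    n <- length(aa)
    po <- mean(aa == bb)
    pa <- table(factor(aa, levels = cats)) / n
    pb <- table(factor(bb, levels = cats)) / n
    pe <- sum(pa * pb)
    if (pe >= 1) return(c(NA_real_, po, pe))
    c((po - pe) / (1 - pe), po, pe)
  }
  k0 <- kap(a, b)
  if (is.na(k0[1])) {
    warning("both raters constant and identical; kappa undefined")
    return(new("KappaResult", kappa = NA_real_, ciLow = NA_real_,
               ciHigh = NA_real_, nPairs = length(a),
               categories = cats, po = k0[2], pe = k0[3]))
  }
  ciLow <- ciHigh <- NA_real_
  if (nBoot > 0) {
    strata <- split(seq_along(a), a)
    ks <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), replace = TRUE)]), use.names = FALSE)
      kap(a[idx], b[idx])[1]
    }, numeric(1)))
    qs <- stats::quantile(ks, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
    ciLow <- qs[1]; ciHigh <- qs[2]
  }
  new("KappaResult", kappa = k0[1], ciLow = ciLow, ciHigh = ciHigh,
      nPairs = length(a), categories = cats, po = k0[2], pe = k0[3])
}

#' Simulate observer watershed placements
#'
#' Synthetic observer model for the inter-observer pipeline: each
#' observer's placement sits at the surgeon's reference arclength plus a
#' Gaussian drift (cm) along the midline, positive toward ischemic
#' tissue -- emulating the study's finding that about two thirds of
#' observers placed the watershed ROI more toward the ischemic side.  A
#' placement is declined (missing) with probability
#' \code{missingRate}.
#'
#' @param midline a \linkS4class{MidlinePath}.
#' @param referenceArc arclength positions (px) of the surgeon's
#'   reference placements, one per (loop, timepoint, side) item.
#' @param observers data.frame with columns \code{observer_id} and
#'   \code{expertise}, one row per observer.
#' @param driftMean,driftSD drift distribution in cm (defaults 0.6 and
#'   0.8).
#' @param missingRate probability a placement is declined.
#' @param seed integer seed (required).
#'
#' @return data.frame: observer_id, expertise, item, reference_arc,
#'   position (row, col columns), distance_cm (NA when declined).
#' @export
simulateObserverPlacements <- function(midline, referenceArc, observers,
                                       driftMean = 0.6, driftSD = 0.8,
                                       missingRate = 0.03, seed) {
  stopifnot(is(midline, "MidlinePath"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  p <- midline@points
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  segLen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(segLen))
  total <- cum[length(cum)]
  atArc <- function(s) {
    s <- min(max(s, 0), total)
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(i, length(segLen))
    p[i, ] + (s - cum[i]) / segLen[i] * seg[i, ]
  }
  sgn <- if (midline@ischemicDirection == "end") 1 else -1
  withSeed(seed, {
    rows <- list()
    for (o in seq_len(nrow(observers))) {
      for (it in seq_along(referenceArc)) {
        declined <- stats::runif(1) < missingRate
        drift <- stats::rnorm(1, driftMean, driftSD)      # cm
        arc <- referenceArc[it] + sgn * drift / midline@pixelSize
        pos <- atArc(arc)
        rows[[length(rows) + 1L]] <- data.frame(
          observer_id = observers$observer_id[o],
          expertise = observers$expertise[o], item = it,
          reference_arc = referenceArc[it],
          row = if (declined) NA_real_ else pos[1],
          col = if (declined) NA_real_ else pos[2],
          distance_cm = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    ## recompute distances through the projection path so clamping at the
    ## path ends is honored
    for (i in seq_len(nrow(out))) {
      if (is.na(out$row[i])) next
      ref <- atArc(out$reference_arc[i])
      out$distance_cm[i] <- signedMidlineDistance(
        midline, ref, c(out$row[i], out$col[i]))
    }
    out
  })
}
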