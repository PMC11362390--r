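#' Youden index
#'
#' \eqn{J = sensitivity + specificity - 1}, the quantity maximized when
#' choosing a diagnostic cut-off.  J = 1 is a perfect test, J = 0 chance
#' level.
#'
#' @param sensitivity,specificity values in [0, 1]; vectorized.
#' @return numeric Youden index in [-1, 1].
#'
#' @examples
#' youdenIndex(0.94, 0.87)  # 0.81
#' youdenIndex(0.97, 1.00)  # 0.97
#'
#' @export
youdenIndex <- function(sensitivity, specificity) {
  if (any(!is.finite(sensitivity)) || any(sensitivity < 0) ||
      any(sensitivity > 1))
    stop("sensitivity must lie in [0, 1]")
  if (any(!is.finite(specificity)) || any(specificity < 0) ||
      any(specificity > 1))
    stop("specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Youden-optimal diagnostic cut-off
#'
#' Scans every candidate threshold -- the midpoints between consecutive
#' distinct observed values, plus one sentinel below the minimum and one
#' above the maximum -- and returns the threshold with the highest Youden
#' index.  Under \code{below_positive} (the perfusion convention: low
#' values indicate ischemia) sensitivity is the fraction of ischemic
#' values strictly below the threshold and specificity the fraction of
#' well-perfused values at or above it; \code{above_positive} (the
#' lactate convention) mirrors the inequalities.  Ties on J are broken
#' toward the smallest threshold, which labels the least tissue positive
#' at equal discrimination.
#'
#' @param values numeric vector of measurements.
#' @param labels vector with entries \code{"ischemic"} (positive class)
#'   and \code{"well"}; same length as \code{values}.
#' @param direction \code{"below_positive"} or \code{"above_positive"}.
#'
#' @return a \linkS4class{CutoffResult} including the full ROC table.
#'
#' @examples
#' res <- optimalCutoff(c(40, 50, 60, 80, 90, 100),
#'                      rep(c("ischemic", "well"), each = 3))
#' threshold(res)  # 70: perfect separation at the midpoint
#'
#' @export
optimalCutoff <- function(values, labels,
                          direction = c("below_positive",
                                        "above_positive")) {
  direction <- match.arg(direction)
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have the same length")
  if (any(!is.finite(values))) stop("'values' must be finite")
  labels <- as.character(labels)
  if (!all(labels %in% c("ischemic", "well")))
    stop("labels must be 'ischemic' or 'well'")
  pos <- values[labels == "ischemic"]
  neg <- values[labels == "well"]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  sv <- sort(unique(values))
  if (length(sv) < 2L) stop("at least 2 distinct values are required")

  mids <- (sv[-1] + sv[-length(sv)]) / 2
  cand <- c(sv[1] - 1, mids, sv[length(sv)] + 1)

  posSorted <- sort(pos); negSorted <- sort(neg)
  ## candidates never coincide with observed values, so counts below a
  ## candidate equal counts <= candidate
  fPos <- findInterval(cand, posSorted) / length(pos)
  fNeg <- findInterval(cand, negSorted) / length(neg)
  if (direction == "below_positive") {
    sens <- fPos
    spec <- 1 - fNeg
  } else {
    sens <- 1 - fPos
    spec <- fNeg
  }
  j <- sens + spec - 1
  ## ties on J break toward the smallest threshold; compare with a
  ## tolerance so that fp rounding of equal fractions cannot reorder them
  best <- which(j >= max(j) - 1e-12)[1]

  new("CutoffResult", threshold = cand[best], sensitivity = sens[best],
      specificity = spec[best], youdenJ = j[best], direction = direction,
      roc = data.frame(threshold = cand, sensitivity = sens,
                       specificity = spec))
}

#' Classify tissue against a cut-off
#'
#' Under \code{below_positive}, values strictly below the cut-off are
#' ischemic and values at or above it well-perfused (a value exactly at
#' the cut-off is well-perfused); \code{above_positive} mirrors the rule
#' (strictly above is ischemic).
#'
#' @param values numeric vector of measurements (finite).
#' @param cutoff the threshold.
#' @param direction \code{"below_positive"} or \code{"above_positive"}.
#'
#' @return character vector of \code{"ischemic"} / \code{"well"} labels.
#'
#' @examples
#' classifyTissue(c(68, 69, 70), 69)               # ischemic, well, well
#' classifyTissue(4.0, 3.8, "above_positive")      # ischemic
#'
#' @export
classifyTissue <- function(values, cutoff,
                           direction = c("below_positive",
                                         "above_positive")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) stop("'values' must be finite")
  isch <- if (direction == "below_positive") values < cutoff
          else values > cutoff
  ifelse(isch, "ischemic", "well")
}

#' Logarithmic curve estimation
#'
#' Ordinary least squares of y on the natural logarithm of x with an
#' intercept, \eqn{y = b_0 + b_1 \ln x}, the calibration used to relate
#' perfusion units to capillary lactate.  \eqn{R^2 = 1 - SS_{res} /
#' SS_{tot}}.  The log base only rescales the slope, leaving \eqn{R^2}
#' unchanged.
#'
#' @param x positive predictor values.
#' @param y response values.
#'
#' @return a \linkS4class{LogFitResult}.  A zero-variance response leaves
#'   \code{rSquared} undefined (NA, \code{degenerate} flag set).
#'
#' @examples
#' fit <- logCurveFit(c(1, exp(1), exp(2)), c(2, 3, 4))
#' c(fit@b0, fit@b1)  # 2 and 1, exactly
#'
#' @export
logCurveFit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  if (any(x <= 0)) stop("logarithmic estimation needs x > 0")
  fit <- stats::lm(y ~ log(x))
  b <- unname(stats::coef(fit))
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    warning("zero-variance response; R^2 undefined")
    return(new("LogFitResult", b0 = b[1], b1 = b[2],
               rSquared = NA_real_, n = length(x), degenerate = TRUE))
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sstot
  new("LogFitResult", b0 = b[1], b1 = b[2], rSquared = r2,
      n = length(x), degenerate = FALSE)
}
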