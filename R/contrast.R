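#' Windowed spatial speckle contrast
#'
#' Computes the per-pixel speckle contrast \eqn{K = \sigma / \mu}: the
#' population standard deviation of the intensities in a centered
#' \code{window x window} neighborhood divided by their mean.  Only pixels
#' whose full window lies inside the frame are valid; the border of width
#' \code{(window - 1)/2} is masked, as are pixels with a zero window mean.
#' Since K is a ratio, the map is invariant to any positive intensity
#' gain.
#'
#' @param frame numeric matrix of intensities (finite).
#' @param window odd window edge length in pixels; the conventional
#'   choice is 7.
#'
#' @return a \linkS4class{ContrastMap} with the same dimensions as
#'   \code{frame}.
#'
#' @examples
#' f <- matrix(50, 16, 16)
#' km <- contrastMap(f)
#' unique(kValues(km)[validMask(km)])  # 0: no local fluctuation
#'
#' @export
contrastMap <- function(frame, window = 7L) {
  if (is(frame, "SpeckleStack"))
    stop("contrastMap works on a single 2-D frame; index the stack first")
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'frame' must be a numeric matrix")
  if (any(!is.finite(frame)))
    stop("'frame' must be finite")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  if (nrow(frame) < window || ncol(frame) < window)
    stop("'window' larger than the frame")

  n <- window * window
  s1 <- boxSums(frame, window)
  s2 <- boxSums(frame * frame, window)
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)           # population variance
  kin <- matrix(NA_real_, nrow(mu), ncol(mu))
  pos <- mu > 0
  kin[pos] <- sqrt(v[pos]) / mu[pos]

  half <- (window - 1L) %/% 2L
  k <- matrix(NA_real_, nrow(frame), ncol(frame))
  valid <- matrix(FALSE, nrow(frame), ncol(frame))
  rr <- (half + 1L):(nrow(frame) - half)
  cc <- (half + 1L):(ncol(frame) - half)
  k[rr, cc] <- kin
  valid[rr, cc] <- pos
  new("ContrastMap", k = k, validMask = valid, window = window)
}

#' Map speckle contrast to perfusion units
#'
#' Converts a \linkS4class{ContrastMap} to a perfusion map.  The default
#' \code{inverse_square} form uses the flow-index convention
#' \eqn{LSPU = \min(1/K^2, cap)} (with \eqn{K = 0} mapped to the cap), a
#' monotone non-increasing function of contrast so that faster flow reads
#' higher.  \code{raw_contrast} passes K through unchanged for
#' diagnostics.
#'
#' @param contrast a \linkS4class{ContrastMap}.
#' @param form \code{"inverse_square"} or \code{"raw_contrast"}.
#' @param cap maximum perfusion value in AU (inverse-square form only).
#'
#' @return a \linkS4class{PerfusionMap}; the validity mask is carried
#'   over.
#' @export
lspuMap <- function(contrast, form = c("inverse_square", "raw_contrast"),
                    cap = 200) {
  stopifnot(is(contrast, "ContrastMap"))
  form <- match.arg(form)
  k <- kValues(contrast)
  valid <- validMask(contrast)
  lspu <- matrix(NA_real_, nrow(k), ncol(k))
  if (form == "inverse_square") {
    if (!is.numeric(cap) || length(cap) != 1L || cap <= 0)
      stop("'cap' must be a single positive number")
    kk <- k[valid]
    lspu[valid] <- ifelse(kk == 0, cap, pmin(1 / kk^2, cap))
    mapping <- list(form = form, cap = cap)
  } else {
    lspu[valid] <- k[valid]
    mapping <- list(form = form, cap = NULL)
  }
  new("PerfusionMap", lspu = lspu, validMask = valid, mapping = mapping)
}

#' Pixel-wise mean of perfusion maps
#'
#' Aggregates per-frame perfusion maps over time: the per-pixel arithmetic
#' mean over the supplied maps.  All maps must share dimensions and
#' mapping; the result is valid only where every input is valid.
#'
#' @param maps a non-empty list of \linkS4class{PerfusionMap} objects.
#'
#' @return a \linkS4class{PerfusionMap}.
#' @export
meanPerfusionMap <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("'maps' must be a non-empty list of PerfusionMap objects")
  if (!all(vapply(maps, is, logical(1), "PerfusionMap")))
    stop("'maps' must contain only PerfusionMap objects")
  d <- dim(maps[[1]]@lspu)
  m0 <- maps[[1]]@mapping
  for (m in maps) {
    if (!all(dim(m@lspu) == d)) stop("map dimensions differ")
    if (!identical(m@mapping, m0)) stop("map mappings differ")
  }
  mask <- Reduce(`&`, lapply(maps, validMask))
  acc <- Reduce(`+`, lapply(maps, function(m) {
    v <- m@lspu
    v[!mask] <- 0
    v
  }))
  lspu <- matrix(NA_real_, d[1], d[2])
  lspu[mask] <- acc[mask] / length(maps)
  new("PerfusionMap", lspu = lspu, validMask = mask, mapping = m0)
}
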