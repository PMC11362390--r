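#' Construct a FlowPhantom from raw maps
#'
#' Low-level constructor; most users want \code{\link{makeLoopPhantom}}.
#'
#' @param tauMap numeric matrix of decorrelation times (ms, Inf = static).
#' @param zoneMap character matrix of zone labels, same dimensions.
#' @param pixelSize cm per pixel.
#' @param exposure exposure time in ms the phantom is calibrated for.
#' @param zoneTargets optional named vector of target LSPU values.
#'
#' @return a \linkS4class{FlowPhantom}.
#' @export
flowPhantom <- function(tauMap, zoneMap, pixelSize = 0.04, exposure = 5,
                        zoneTargets = numeric(0)) {
  new("FlowPhantom", tauMap = tauMap, zoneMap = zoneMap,
      pixelSize = pixelSize, exposure = exposure,
      zoneTargets = zoneTargets)
}

#' Build a bowel-loop flow phantom
#'
#' Lays out a horizontal band (the extracorporeal bowel loop) across the
#' image over a static background, split left to right into five zones:
#' well-perfused, left watershed, ischemic, right watershed, well-perfused.
#' The per-pixel decorrelation time is set so that \eqn{T/\tau_c} equals
#' the zone's target perfusion value, exploiting the inverse-square
#' perfusion mapping \eqn{LSPU = 1/K^2 \approx T/\tau_c} for
#' \eqn{T/\tau_c \gg 1}.  The watershed zones carry a smooth linear
#' gradient of \eqn{T/\tau_c} between their neighbors, emulating the
#' perfusion transition the surgeon has to judge.
#'
#' @param rows,cols image dimensions in pixels.
#' @param exposure exposure time T in ms.
#' @param zoneTargets named numeric vector with elements \code{well} and
#'   \code{ischemic}: target perfusion values in AU.
#' @param pixelSize cm per pixel (default 0.04: a ~20 cm loop spanning a
#'   512 px image).
#' @param bandHeight height of the loop band in px (default 40\% of
#'   \code{rows}, at least 60).
#' @param minZone minimum zone extent in px; each zone must be at least
#'   \code{minZone} wide and the band at least \code{minZone} high so a
#'   60 x 60 ROI fits.
#'
#' @return a \linkS4class{FlowPhantom} whose zone map contains all five
#'   labels.
#'
#' @examples
#' ph <- makeLoopPhantom(512, 512, zoneTargets = c(well = 95, ischemic = 50))
#' table(zoneMap(ph))
#' range(tauMap(ph)[zoneMap(ph) == "ischemic"])  # 5 ms / 50 AU = 0.1 ms
#'
#' @export
makeLoopPhantom <- function(rows = 512, cols = 512, exposure = 5,
                            zoneTargets = c(well = 95, ischemic = 50),
                            pixelSize = 0.04,
                            bandHeight = max(60L, round(0.4 * rows)),
                            minZone = 60L) {
  if (!all(c("well", "ischemic") %in% names(zoneTargets)))
    stop("zoneTargets must name 'well' and 'ischemic' values")
  if (any(zoneTargets <= 0)) stop("zoneTargets must be positive")
  if (exposure <= 0) stop("exposure must be positive")
  zw <- cols %/% 5L
  if (zw < minZone || bandHeight < minZone || bandHeight > rows)
    stop(sprintf(
      "phantom too small: each of the 5 zones needs >= %d px width and the band >= %d px height",
      minZone, minZone))

  xWell <- unname(zoneTargets["well"])
  xIsch <- unname(zoneTargets["ischemic"])

  ## per-column T/tau profile across the loop band
  xProfile <- numeric(cols)
  lab <- character(cols)
  b <- c(0L, zw, 2L * zw, 3L * zw, 4L * zw, cols)  # zone boundaries
  idx <- function(k) (b[k] + 1L):b[k + 1L]
  xProfile[idx(1)] <- xWell;  lab[idx(1)] <- "well"
  xProfile[idx(3)] <- xIsch;  lab[idx(3)] <- "ischemic"
  xProfile[idx(5)] <- xWell;  lab[idx(5)] <- "well"
  nw <- length(idx(2))
  xProfile[idx(2)] <- xWell + (xIsch - xWell) * seq_len(nw) / (nw + 1)
  lab[idx(2)] <- "watershed_left"
  nw <- length(idx(4))
  xProfile[idx(4)] <- xIsch + (xWell - xIsch) * seq_len(nw) / (nw + 1)
  lab[idx(4)] <- "watershed_right"

  r0 <- (rows - bandHeight) %/% 2L
  bandRows <- (r0 + 1L):(r0 + bandHeight)

  tau <- matrix(Inf, rows, cols)
  zone <- matrix("background", rows, cols)
  tau[bandRows, ] <- rep(exposure / xProfile, each = length(bandRows))
  zone[bandRows, ] <- rep(lab, each = length(bandRows))

  flowPhantom(tau, zone, pixelSize = pixelSize, exposure = exposure,
              zoneTargets = zoneTargets)
}

#' Default 60 x 60 ROI placement on a loop phantom
#'
#' Centers one square ROI in each of the four tissue zones of a
#' \code{\link{makeLoopPhantom}} phantom (well-perfused, both watersheds,
#' ischemic), mirroring the surgeon's pen-marked regions.
#'
#' @param phantom a \linkS4class{FlowPhantom} built by
#'   \code{\link{makeLoopPhantom}}.
#' @param size ROI edge length in pixels.
#'
#' @return a data.frame with columns \code{roi_id}, \code{zone},
#'   \code{row}, \code{col} (1-based top-left corner), \code{height},
#'   \code{width}; one row per ROI.
#' @export
defaultLoopROIs <- function(phantom, size = 60L) {
  zm <- zoneMap(phantom)
  zones <- c("well", "watershed_left", "ischemic", "watershed_right")
  rois <- lapply(zones, function(z) {
    w <- which(zm == z, arr.ind = TRUE)
    if (!nrow(w)) stop("zone '", z, "' absent from phantom")
    ## the well-perfused zone flanks the loop on both sides; use the left
    ## segment (first contiguous run of columns)
    zc <- sort(unique(w[, 2]))
    gap <- which(diff(zc) > 1L)
    if (length(gap)) {
      keep <- zc[seq_len(gap[1])]
      w <- w[w[, 2] %in% keep, , drop = FALSE]
    }
    cr <- round(mean(range(w[, 1]))); cc <- round(mean(range(w[, 2])))
    data.frame(roi_id = z, zone = z,
               row = cr - size %/% 2L, col = cc - size %/% 2L,
               height = size, width = size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rois)
}
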