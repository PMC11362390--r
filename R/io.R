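#' Write and read speckle stacks as multi-page TIFF
#'
#' Stacks are stored as one grayscale page per frame at the stack's bit
#' depth, with a JSON sidecar (same path plus \code{.json}) carrying
#' exposure, frame interval, bit depth and seed so a read round-trips the
#' object bit-identically.
#'
#' @param stack a \linkS4class{SpeckleStack}.
#' @param path output TIFF path; the sidecar goes to
#'   \code{paste0(path, ".json")}.
#'
#' @return \code{writeSpeckleStack} returns \code{path} invisibly;
#'   \code{readSpeckleStack} returns a \linkS4class{SpeckleStack}.
#' @export
writeSpeckleStack <- function(stack, path) {
  stopifnot(is(stack, "SpeckleStack"))
  maxCount <- 2^stack@bitDepth - 1
  pages <- lapply(seq_len(nFrames(stack)),
                  function(f) stack@frames[, , f] / maxCount)
  bits <- if (stack@bitDepth <= 8) 8L else 16L
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(exposure = stack@exposure,
               frameInterval = stack@frameInterval,
               bitDepth = stack@bitDepth, seed = stack@seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSpeckleStack
#' @export
readSpeckleStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  maxCount <- 2^meta$bitDepth - 1
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- round(pages[[f]] * maxCount)
  new("SpeckleStack", frames = arr, exposure = meta$exposure,
      frameInterval = meta$frameInterval,
      bitDepth = as.integer(meta$bitDepth),
      seed = as.integer(meta$seed))
}

#' Write and read perfusion maps as 32-bit float TIFF
#'
#' The map is stored as a two-page float TIFF: page one holds the
#' perfusion values divided by a scale factor (so they fit the [0, 1]
#' range the format guarantees), page two the validity mask.  The scale
#' and the mapping metadata travel in a JSON sidecar; a read restores
#' values, mask and mapping.
#'
#' @param map a \linkS4class{PerfusionMap}.
#' @param path output TIFF path.
#' @return \code{writePerfusionMap} returns \code{path} invisibly;
#'   \code{readPerfusionMap} a \linkS4class{PerfusionMap}.
#' @export
writePerfusionMap <- function(map, path) {
  stopifnot(is(map, "PerfusionMap"))
  v <- lspuValues(map)
  mask <- validMask(map)
  scale <- max(v[mask], 1)
  v[!mask] <- 0
  tiff::writeTIFF(list(v / scale, mask * 1), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(scale = scale, mapping = map@mapping)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writePerfusionMap
#' @export
readPerfusionMap <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  mask <- pages[[2]] > 0.5
  v <- pages[[1]] * meta$scale
  v[!mask] <- NA_real_
  cap <- meta$mapping$cap
  new("PerfusionMap", lspu = v, validMask = mask,
      mapping = list(form = meta$mapping$form, cap = cap))
}

#' Render a perfusion map with the Viridis colormap
#'
#' Produces the display used intraoperatively: perfusion linearly scaled
#' between \code{lo} and \code{hi} (clipped outside) on the Viridis
#' gradient, blue for low flow through yellow for high flow, with a
#' vertical scale bar on the left edge.  Invalid pixels render black.
#' The default range [30, 110] AU spans the values typically observed on
#' the bowel loop maps.
#'
#' @param map a \linkS4class{PerfusionMap}.
#' @param lo,hi display range in AU (lo < hi).
#' @param file optional PNG output path.
#' @param scaleBarWidth width of the scale bar strip in px (0 disables).
#'
#' @return invisibly, the rendered RGB array (rows x cols x 3 in [0,1]);
#'   written to \code{file} when given.
#' @export
renderColormap <- function(map, lo = 30, hi = 110, file = NULL,
                           scaleBarWidth = 16L) {
  stopifnot(is(map, "PerfusionMap"))
  if (lo >= hi) stop("'lo' must be less than 'hi'")
  pal <- grDevices::hcl.colors(256, "viridis")
  rgbPal <- grDevices::col2rgb(pal) / 255

  v <- lspuValues(map)
  idx <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  idx <- round(idx * 255) + 1
  d <- dim(v)
  img <- array(0, dim = c(d[1], d[2], 3))
  ok <- validMask(map)
  for (ch in 1:3) {
    plane <- matrix(0, d[1], d[2])
    plane[ok] <- rgbPal[ch, idx[ok]]
    img[, , ch] <- plane
  }
  if (scaleBarWidth > 0) {
    ramp <- round(seq(255, 0, length.out = d[1])) + 1  # hi at top
    bar <- array(0, dim = c(d[1], scaleBarWidth + 2L, 3))
    for (ch in 1:3)
      bar[, seq_len(scaleBarWidth), ch] <- rgbPal[ch, ramp]
    img2 <- array(0, dim = c(d[1], d[2] + scaleBarWidth + 2L, 3))
    img2[, seq_len(scaleBarWidth + 2L), ] <- bar
    img2[, (scaleBarWidth + 3L):(d[2] + scaleBarWidth + 2L), ] <- img
    img <- img2
  }
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}

#' Write ROI definitions to JSON
#'
#' @param rois ROI data.frame (see \code{\link{roiSeries}}).
#' @param path JSON output path.
#' @return \code{path}, invisibly.
#' @export
writeRoiJSON <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJSON
#' @export
readRoiJSON <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
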