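#' Select the middle frames of a recording
#'
#' Recordings are trimmed to their middle \code{n} frames to equalize
#' sequence length across loops.  With N frames and 1-based indexing, the
#' selection is frames \code{s + 1, ..., s + n} with
#' \code{s = floor((N - n) / 2)}; when \code{N - n} is odd the window sits
#' one frame earlier.  Order is preserved and the selection is
#' deterministic.
#'
#' @param x a \linkS4class{SpeckleStack}, a list (e.g. of perfusion maps),
#'   or a vector of frame indices/objects.
#' @param n number of frames to keep (default 96).
#' @param id identifier used in the error message when the recording is
#'   too short.
#'
#' @return an object of the same kind as \code{x}, trimmed to n frames.
#'   For a \code{SpeckleStack}, a stack with n frames.
#' @export
selectMiddleFrames <- function(x, n = 96L, id = "recording") {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  len <- if (is(x, "SpeckleStack")) dim(frames(x))[3] else length(x)
  if (len < n)
    stop(sprintf("%s has %d frames, fewer than the %d required", id, len,
                 n))
  s <- (len - n) %/% 2L
  idx <- (s + 1L):(s + n)
  if (is(x, "SpeckleStack")) {
    initialize(x, frames = frames(x)[, , idx, drop = FALSE])
  } else {
    x[idx]
  }
}

#' Indices selected by the middle-frame rule
#'
#' @param N total number of frames.
#' @param n frames to keep.
#' @return integer vector of 1-based frame indices.
#' @rdname selectMiddleFrames
#' @export
middleFrameIndices <- function(N, n = 96L) {
  if (N < n) stop("N < n")
  s <- (N - n) %/% 2L
  (s + 1L):(s + n)
}

#' Per-ROI perfusion time series and summaries
#'
#' Applies rectangular ROIs to a sequence of per-frame perfusion maps and
#' returns, per ROI, the mean perfusion of the valid pixels in each frame
#' plus a summary: the mean of the per-frame means, their sample standard
#' deviation (n - 1) across frames, and -- since the SD basis is a
#' reporting choice -- the mean within-frame pixel SD as an alternative.
#'
#' @param maps list of \linkS4class{PerfusionMap} objects, one per frame.
#' @param rois data.frame with columns \code{roi_id}, \code{zone},
#'   \code{row}, \code{col} (1-based top-left), \code{height},
#'   \code{width}, as from \code{\link{defaultLoopROIs}}.
#' @param loopId,timepoint identifiers copied into the output tables.
#' @param excludeFrames optional integer vector of frame indices to drop
#'   (artifact exclusion list).
#'
#' @return list with elements \code{perFrame} (long-format data.frame:
#'   loop_id, roi_id, zone, timepoint, frame, mean) and \code{summary}
#'   (one row per ROI: n_frames, mean, sd, sd_pixels).
#' @export
roiSeries <- function(maps, rois, loopId = "loop1", timepoint = "T0",
                      excludeFrames = integer(0)) {
  if (!is.list(maps) || !length(maps))
    stop("'maps' must be a non-empty list of PerfusionMap objects")
  if (!all(vapply(maps, is, logical(1), "PerfusionMap")))
    stop("'maps' must contain only PerfusionMap objects")
  need <- c("roi_id", "zone", "row", "col", "height", "width")
  if (!all(need %in% names(rois)))
    stop("'rois' must have columns ", paste(need, collapse = ", "))
  keep <- setdiff(seq_along(maps), excludeFrames)
  if (!length(keep)) stop("all frames excluded")

  per <- list()
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    rr <- r$row:(r$row + r$height - 1L)
    cc <- r$col:(r$col + r$width - 1L)
    means <- vapply(keep, function(f) {
      m <- maps[[f]]
      d <- dim(lspuValues(m))
      if (r$row < 1L || r$col < 1L || max(rr) > d[1] || max(cc) > d[2])
        stop(sprintf("ROI '%s' does not fit inside the %d x %d map",
                     r$roi_id, d[1], d[2]))
      sub <- lspuValues(m)[rr, cc]
      ok <- validMask(m)[rr, cc]
      if (!all(ok))
        stop(sprintf(
          "ROI '%s' touches invalid pixels (map border or zero-mean windows)",
          r$roi_id))
      mean(sub)
    }, numeric(1))
    pixSD <- vapply(keep, function(f)
      stats::sd(lspuValues(maps[[f]])[rr, cc]), numeric(1))
    per[[i]] <- list(
      frames = data.frame(loop_id = loopId, roi_id = r$roi_id,
                          zone = r$zone, timepoint = timepoint,
                          frame = keep, mean = means,
                          stringsAsFactors = FALSE),
      summary = data.frame(loop_id = loopId, roi_id = r$roi_id,
                           zone = r$zone, timepoint = timepoint,
                           n_frames = length(keep), mean = mean(means),
                           sd = stats::sd(means),
                           sd_pixels = mean(pixSD),
                           stringsAsFactors = FALSE))
  }
  list(perFrame = do.call(rbind, lapply(per, `[[`, "frames")),
       summary = do.call(rbind, lapply(per, `[[`, "summary")))
}
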