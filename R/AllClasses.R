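#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' FlowPhantom: a per-pixel flow map for speckle simulation
#'
#' A \code{FlowPhantom} describes the ground truth handed to the speckle
#' simulator: a per-pixel speckle decorrelation time \eqn{\tau_c} (ms,
#' \code{Inf} marks a static pixel) together with a categorical zone label
#' per pixel and the physical pixel pitch.  The standard loop phantom
#' depicts a bowel loop with a well-perfused zone at each end, an ischemic
#' zone in the middle and two watershed transition zones in between; see
#' \code{\link{makeLoopPhantom}}.
#'
#' @slot tauMap numeric matrix of decorrelation times \eqn{\tau_c} in ms;
#'   strictly positive, \code{Inf} allowed for static background.
#' @slot zoneMap character matrix (same dimensions) with labels in
#'   \code{"well"}, \code{"watershed_left"}, \code{"watershed_right"},
#'   \code{"ischemic"}, \code{"background"}.
#' @slot pixelSize physical pixel size in cm per pixel.
#' @slot exposure exposure time T in ms that the zone targets were
#'   calibrated against.
#' @slot zoneTargets named numeric vector of target perfusion values (AU)
#'   used to build the phantom (may be empty for hand-built phantoms).
#'
#' @seealso \code{\link{makeLoopPhantom}}, \code{\link{generateSpeckleStack}}
#' @exportClass FlowPhantom
setClass("FlowPhantom",
  representation(
    tauMap      = "matrix",
    zoneMap     = "matrix",
    pixelSize   = "numeric",
    exposure    = "numeric",
    zoneTargets = "numeric"
  )
)

setValidity("FlowPhantom", function(object) {
  msg <- NULL
  if (!all(dim(object@tauMap) == dim(object@zoneMap)))
    msg <- c(msg, "tauMap and zoneMap must have identical dimensions")
  tv <- object@tauMap
  if (any(!is.na(tv) & tv <= 0))
    msg <- c(msg, "tauMap must be strictly positive (Inf allowed)")
  if (any(is.na(tv)))
    msg <- c(msg, "tauMap must not contain NA")
  ok <- c("well", "watershed_left", "watershed_right", "ischemic",
          "background")
  if (!all(object@zoneMap %in% ok))
    msg <- c(msg, sprintf("zoneMap labels must be one of: %s",
                          paste(ok, collapse = ", ")))
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' SpeckleStack: a simulated LSCI recording
#'
#' Holds a stack of time-integrated speckle frames as produced by
#' \code{\link{generateSpeckleStack}}, with the acquisition metadata needed
#' to interpret them.  Frames are stored as an array indexed
#' \code{[row, col, frame]}; intensities are nonnegative integer counts
#' quantized to \code{bitDepth} bits.
#'
#' @slot frames numeric array \code{rows x cols x nFrames} of counts.
#' @slot exposure exposure time T per frame (ms).
#' @slot frameInterval frame-to-frame interval (ms); at least the exposure.
#' @slot bitDepth sensor bit depth used for quantization.
#' @slot seed integer seed the stack was generated from.
#'
#' @exportClass SpeckleStack
setClass("SpeckleStack",
  representation(
    frames        = "array",
    exposure      = "numeric",
    frameInterval = "numeric",
    bitDepth      = "integer",
    seed          = "integer"
  )
)

setValidity("SpeckleStack", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a rows x cols x nFrames array")
  else if (dim(object@frames)[3] < 1L)
    msg <- c(msg, "at least one frame is required")
  if (any(!is.finite(object@frames)) || any(object@frames < 0))
    msg <- c(msg, "intensities must be finite and nonnegative")
  if (object@exposure <= 0)
    msg <- c(msg, "exposure must be positive")
  if (object@frameInterval < object@exposure)
    msg <- c(msg, "frameInterval must be >= exposure")
  if (is.null(msg)) TRUE else msg
})

#' SimulationConfig: controls for the speckle simulator
#'
#' @slot subSteps integer number M of integration sub-steps per exposure,
#'   or \code{NULL} to scale automatically with the fastest flow
#'   (\code{M = max(25, ceiling(3 * max(T / tau_c)))}), which keeps the
#'   rectangle-rule integration bias on contrast below about 2\%.
#' @slot grainRadius speckle grain size control in pixels: the pupil
#'   cut-off frequency is \code{1 / (2 * grainRadius)} cycles/pixel.
#' @slot beta coherence factor \eqn{\beta \in (0, 1]} scaling
#'   \eqn{K^2}.
#' @slot staticFraction fraction of the field amplitude variance carried by
#'   a non-decorrelating (static) speckle field, in \code{[0, 1)}.
#' @slot shotNoise logical; apply Poisson shot noise to the counts.
#' @slot meanLevel mean intensity level in counts.
#'
#' @seealso \code{\link{simulationConfig}}
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    subSteps       = "numericOrNULL",
    grainRadius    = "numeric",
    beta           = "numeric",
    staticFraction = "numeric",
    shotNoise      = "logical",
    meanLevel      = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (!is.null(object@subSteps) &&
      (length(object@subSteps) != 1L || object@subSteps < 1))
    msg <- c(msg, "subSteps must be NULL (auto) or an integer >= 1")
  if (object@beta <= 0 || object@beta > 1)
    msg <- c(msg, "beta must lie in (0, 1]")
  if (object@staticFraction < 0 || object@staticFraction >= 1)
    msg <- c(msg, "staticFraction must lie in [0, 1)")
  if (object@grainRadius <= 0)
    msg <- c(msg, "grainRadius must be positive")
  if (object@meanLevel <= 0)
    msg <- c(msg, "meanLevel must be positive")
  if (is.null(msg)) TRUE else msg
})

#' ContrastMap: windowed spatial speckle contrast
#'
#' Per-pixel speckle contrast \eqn{K = \sigma/\mu} computed over a centered
#' square window (population standard deviation over window mean).  Pixels
#' whose window does not fit inside the frame, or whose window mean is
#' zero, are marked invalid.
#'
#' @slot k numeric matrix of contrast values (NA where invalid).
#' @slot validMask logical matrix, \code{FALSE} on the border of width
#'   \code{(window - 1) / 2} and wherever the window mean is zero.
#' @slot window odd integer window edge length in pixels.
#'
#' @seealso \code{\link{contrastMap}}, \code{\link{lspuMap}}
#' @exportClass ContrastMap
setClass("ContrastMap",
  representation(k = "matrix", validMask = "matrix", window = "integer")
)

setValidity("ContrastMap", function(object) {
  msg <- NULL
  if (!all(dim(object@k) == dim(object@validMask)))
    msg <- c(msg, "k and validMask must have identical dimensions")
  if (object@window < 3L || object@window %% 2L == 0L)
    msg <- c(msg, "window must be an odd integer >= 3")
  kk <- object@k[object@validMask]
  if (any(!is.finite(kk)) || any(kk < 0))
    msg <- c(msg, "valid contrast values must be finite and >= 0")
  if (is.null(msg)) TRUE else msg
})

#' PerfusionMap: per-pixel perfusion (LSPU) values
#'
#' Laser speckle perfusion units (arbitrary units, AU) derived from a
#' \linkS4class{ContrastMap}.  Under the default \code{inverse_square}
#' mapping, \code{LSPU = min(1/K^2, cap)} so that faster flow (lower
#' contrast) gives higher perfusion values; \code{raw_contrast} keeps K
#' itself for diagnostics.
#'
#' @slot lspu numeric matrix of perfusion values (NA where invalid).
#' @slot validMask logical matrix.
#' @slot mapping list with elements \code{form} (\code{"inverse_square"} or
#'   \code{"raw_contrast"}) and \code{cap} (maximum AU).
#'
#' @exportClass PerfusionMap
setClass("PerfusionMap",
  representation(lspu = "matrix", validMask = "matrix", mapping = "list")
)

setValidity("PerfusionMap", function(object) {
  msg <- NULL
  if (!all(dim(object@lspu) == dim(object@validMask)))
    msg <- c(msg, "lspu and validMask must have identical dimensions")
  form <- object@mapping$form
  if (is.null(form) || !form %in% c("inverse_square", "raw_contrast"))
    msg <- c(msg, "mapping$form must be 'inverse_square' or 'raw_contrast'")
  vals <- object@lspu[object@validMask]
  if (any(!is.finite(vals)) || any(vals < 0))
    msg <- c(msg, "valid LSPU values must be finite and >= 0")
  if (identical(form, "inverse_square")) {
    cap <- object@mapping$cap
    if (is.null(cap) || cap <= 0)
      msg <- c(msg, "mapping$cap must be positive")
    else if (length(vals) && max(vals) > cap + 1e-9)
      msg <- c(msg, "LSPU values exceed the configured cap")
  }
  if (is.null(msg)) TRUE else msg
})

#' CutoffResult: a Youden-optimal diagnostic threshold
#'
#' Result of \code{\link{optimalCutoff}}: the threshold maximizing the
#' Youden index J = sensitivity + specificity - 1 over all candidate
#' thresholds (midpoints between consecutive distinct values plus
#' sentinels), the operating point at that threshold, and the full ROC
#' table.
#'
#' @slot threshold numeric cut-off value.
#' @slot sensitivity,specificity operating point at the threshold.
#' @slot youdenJ Youden index at the threshold.
#' @slot direction \code{"below_positive"} (low values are positive, the
#'   LSPU convention) or \code{"above_positive"} (lactate convention).
#' @slot roc data.frame with columns threshold, sensitivity, specificity.
#'
#' @exportClass CutoffResult
setClass("CutoffResult",
  representation(
    threshold   = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    youdenJ     = "numeric",
    direction   = "character",
    roc         = "data.frame"
  )
)

setValidity("CutoffResult", function(object) {
  msg <- NULL
  if (object@sensitivity < 0 || object@sensitivity > 1)
    msg <- c(msg, "sensitivity must lie in [0, 1]")
  if (object@specificity < 0 || object@specificity > 1)
    msg <- c(msg, "specificity must lie in [0, 1]")
  if (abs(object@youdenJ -
          (object@sensitivity + object@specificity - 1)) > 1e-12)
    msg <- c(msg, "youdenJ must equal sensitivity + specificity - 1")
  if (!object@direction %in% c("below_positive", "above_positive"))
    msg <- c(msg, "direction must be 'below_positive' or 'above_positive'")
  if (is.null(msg)) TRUE else msg
})

#' LogFitResult: logarithmic curve estimation
#'
#' Ordinary least squares of y on \code{log(x)} with intercept:
#' \code{y = b0 + b1 * ln(x)}.  \code{rSquared} is \code{NA} (and
#' \code{degenerate} is \code{TRUE}) when y has zero variance.
#'
#' @slot b0,b1 intercept and slope on the natural log of x.
#' @slot rSquared coefficient of determination (NA if undefined).
#' @slot n number of points fitted.
#' @slot degenerate logical flag for a zero-variance response.
#'
#' @exportClass LogFitResult
setClass("LogFitResult",
  representation(b0 = "numeric", b1 = "numeric", rSquared = "numeric",
                 n = "integer", degenerate = "logical")
)

#' GroupTestResult: a two-group comparison
#'
#' Returned by \code{\link{compareGroups}}: a Welch t test when both groups
#' pass a Shapiro-Wilk normality check, otherwise a two-sided
#' Mann-Whitney U test.
#'
#' @slot testUsed \code{"t"}, \code{"mann_whitney"} or \code{"degenerate"}.
#' @slot statistic test statistic (Welch t, or Mann-Whitney U).
#' @slot pValue two-sided p value.
#' @slot normalityP Shapiro-Wilk p values for the two groups (NA when the
#'   check could not run, e.g. zero variance).
#'
#' @exportClass GroupTestResult
setClass("GroupTestResult",
  representation(testUsed = "character", statistic = "numeric",
                 pValue = "numeric", normalityP = "numeric")
)

#' MidlinePath: the bowel-loop midline for observer distances
#'
#' An ordered polyline tracing the loop midline, used to measure signed
#' along-midline distances between ROI placements.  Positive distances run
#' toward the ischemic end of the path.
#'
#' @slot points numeric matrix n x 2 of (row, col) pixel coordinates.
#' @slot pixelSize cm per pixel.
#' @slot ischemicDirection \code{"end"} if increasing arclength points
#'   toward ischemic tissue, \code{"start"} otherwise.
#'
#' @seealso \code{\link{signedMidlineDistance}}
#' @exportClass MidlinePath
setClass("MidlinePath",
  representation(points = "matrix", pixelSize = "numeric",
                 ischemicDirection = "character")
)

setValidity("MidlinePath", function(object) {
  msg <- NULL
  p <- object@points
  if (ncol(p) != 2L || nrow(p) < 2L)
    msg <- c(msg, "points must be an n x 2 matrix with n >= 2")
  else {
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
    if (any(seg <= 0))
      msg <- c(msg, "consecutive midline points must be distinct")
  }
  if (!object@ischemicDirection %in% c("start", "end"))
    msg <- c(msg, "ischemicDirection must be 'start' or 'end'")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' KappaResult: Cohen's kappa with bootstrap confidence interval
#'
#' @slot kappa chance-corrected agreement (NA when expected agreement is 1).
#' @slot ciLow,ciHigh percentile bootstrap 95\% confidence limits (NA when
#'   the CI was not computed).
#' @slot nPairs number of complete rating pairs used.
#' @slot categories category universe used.
#' @slot po,pe observed and chance-expected agreement.
#'
#' @exportClass KappaResult
setClass("KappaResult",
  representation(kappa = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 nPairs = "integer", categories = "character",
                 po = "numeric", pe = "numeric")
)

#' StudyDesign: the bowel-loop study layout
#'
#' Encodes the study design emulated by \code{\link{generateStudy}}:
#' animals, loops per animal, the four ROIs per loop (well-perfused, two
#' watershed, ischemic), the four timepoints, and the capillary-lactate
#' sampling schedule (which loops were sampled per zone and timepoint).
#'
#' @slot loopsPerAnimal integer vector, one entry per animal.
#' @slot timepoints character vector of timepoint labels.
#' @slot rois character vector of per-loop ROI labels.
#' @slot lactateSchedule data.frame with columns \code{timepoint},
#'   \code{zone} (ROI label) and \code{n_loops}: how many loops have a
#'   lactate record for that ROI at that timepoint (the first
#'   \code{n_loops} loops, deterministically).
#'
#' @seealso \code{\link{studyDesign}}, \code{\link{designRecordCount}}
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(loopsPerAnimal = "integer", timepoints = "character",
                 rois = "character", lactateSchedule = "data.frame")
)

setValidity("StudyDesign", function(object) {
  msg <- NULL
  nl <- sum(object@loopsPerAnimal)
  s <- object@lactateSchedule
  need <- c("timepoint", "zone", "n_loops")
  if (!all(need %in% names(s)))
    msg <- c(msg, "lactateSchedule needs columns timepoint, zone, n_loops")
  else {
    if (!all(s$timepoint %in% object@timepoints))
      msg <- c(msg, "lactateSchedule timepoints outside design timepoints")
    if (!all(s$zone %in% object@rois))
      msg <- c(msg, "lactateSchedule zones outside design ROIs")
    if (any(s$n_loops < 0) || any(s$n_loops > nl))
      msg <- c(msg, "lactateSchedule n_loops outside [0, total loops]")
    if (anyDuplicated(s[, c("timepoint", "zone")]))
      msg <- c(msg, "duplicate (timepoint, zone) rows in lactateSchedule")
  }
  if (is.null(msg)) TRUE else msg
})
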