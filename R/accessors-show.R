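#' @rdname FlowPhantom-class
#' @aliases tauMap,FlowPhantom-method
setMethod("tauMap", "FlowPhantom", function(object) object@tauMap)

#' @rdname FlowPhantom-class
#' @aliases zoneMap,FlowPhantom-method
setMethod("zoneMap", "FlowPhantom", function(object) object@zoneMap)

#' @rdname FlowPhantom-class
#' @aliases pixelSize,FlowPhantom-method
setMethod("pixelSize", "FlowPhantom", function(object) object@pixelSize)

#' @rdname MidlinePath-class
#' @aliases pixelSize,MidlinePath-method
#' @param object a \code{MidlinePath}
setMethod("pixelSize", "MidlinePath", function(object) object@pixelSize)

#' @rdname SpeckleStack-class
#' @aliases frames,SpeckleStack-method
setMethod("frames", "SpeckleStack", function(object) object@frames)

#' @rdname SpeckleStack-class
#' @aliases exposure,SpeckleStack-method
setMethod("exposure", "SpeckleStack", function(object) object@exposure)

#' @rdname SpeckleStack-class
#' @aliases nFrames,SpeckleStack-method
setMethod("nFrames", "SpeckleStack",
          function(object) dim(object@frames)[3])

#' @rdname ContrastMap-class
#' @aliases kValues,ContrastMap-method
setMethod("kValues", "ContrastMap", function(object) object@k)

#' @rdname ContrastMap-class
#' @aliases validMask,ContrastMap-method
setMethod("validMask", "ContrastMap", function(object) object@validMask)

#' @rdname PerfusionMap-class
#' @aliases validMask,PerfusionMap-method
setMethod("validMask", "PerfusionMap", function(object) object@validMask)

#' @rdname ContrastMap-class
#' @aliases windowSize,ContrastMap-method
setMethod("windowSize", "ContrastMap", function(object) object@window)

#' @rdname PerfusionMap-class
#' @aliases lspuValues,PerfusionMap-method
setMethod("lspuValues", "PerfusionMap", function(object) object@lspu)

#' @rdname PerfusionMap-class
#' @aliases perfusionMapping,PerfusionMap-method
setMethod("perfusionMapping", "PerfusionMap",
          function(object) object@mapping)

#' @rdname CutoffResult-class
#' @aliases threshold,CutoffResult-method
setMethod("threshold", "CutoffResult", function(object) object@threshold)

#' @rdname CutoffResult-class
#' @aliases sensitivity,CutoffResult-method
setMethod("sensitivity", "CutoffResult",
          function(object) object@sensitivity)

#' @rdname CutoffResult-class
#' @aliases specificity,CutoffResult-method
setMethod("specificity", "CutoffResult",
          function(object) object@specificity)

#' @rdname CutoffResult-class
#' @aliases youdenJ,CutoffResult-method
setMethod("youdenJ", "CutoffResult", function(object) object@youdenJ)

#' @rdname CutoffResult-class
#' @aliases rocPoints,CutoffResult-method
setMethod("rocPoints", "CutoffResult", function(object) object@roc)

#' @rdname KappaResult-class
#' @aliases kappaValue,KappaResult-method
setMethod("kappaValue", "KappaResult", function(object) object@kappa)

#' @rdname KappaResult-class
#' @aliases kappaCI,KappaResult-method
setMethod("kappaCI", "KappaResult",
          function(object) c(low = object@ciLow, high = object@ciHigh))

setMethod("show", "FlowPhantom", function(object) {
  d <- dim(object@tauMap)
  zones <- table(factor(object@zoneMap))
  cat(sprintf("FlowPhantom %d x %d px (%.3g cm/px), exposure %.3g ms\n",
              d[1], d[2], object@pixelSize, object@exposure))
  cat("  zones:", paste(sprintf("%s=%d", names(zones), zones),
                        collapse = ", "), "\n")
  if (length(object@zoneTargets))
    cat("  targets (AU):",
        paste(sprintf("%s=%.4g", names(object@zoneTargets),
                      object@zoneTargets), collapse = ", "), "\n")
})

setMethod("show", "SpeckleStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "SpeckleStack %d frame(s) of %d x %d px, T = %.3g ms, %d-bit, seed %d\n",
    d[3], d[1], d[2], object@exposure, object@bitDepth, object@seed))
  cat(sprintf("  mean intensity %.2f counts\n", mean(object@frames)))
})

setMethod("show", "ContrastMap", function(object) {
  d <- dim(object@k)
  kk <- object@k[object@validMask]
  cat(sprintf("ContrastMap %d x %d px, window %d x %d, %d valid px\n",
              d[1], d[2], object@window, object@window, sum(object@validMask)))
  if (length(kk))
    cat(sprintf("  K: mean %.4f, range [%.4f, %.4f]\n",
                mean(kk), min(kk), max(kk)))
})

setMethod("show", "PerfusionMap", function(object) {
  d <- dim(object@lspu)
  v <- object@lspu[object@validMask]
  cat(sprintf("PerfusionMap %d x %d px, mapping '%s'",
              d[1], d[2], object@mapping$form))
  if (!is.null(object@mapping$cap))
    cat(sprintf(" (cap %.4g AU)", object@mapping$cap))
  cat("\n")
  if (length(v))
    cat(sprintf("  LSPU: mean %.2f, range [%.2f, %.2f]\n",
                mean(v), min(v), max(v)))
})

setMethod("show", "CutoffResult", function(object) {
  cat(sprintf(
    "CutoffResult (%s): threshold %.4g, sens %.3f, spec %.3f, J %.3f\n",
    object@direction, object@threshold, object@sensitivity,
    object@specificity, object@youdenJ))
  cat(sprintf("  ROC: %d candidate thresholds\n", nrow(object@roc)))
})

setMethod("show", "LogFitResult", function(object) {
  cat(sprintf("LogFitResult: y = %.4g %+.4g * ln(x), n = %d\n",
              object@b0, object@b1, object@n))
  if (object@degenerate)
    cat("  R^2 undefined (zero-variance response)\n")
  else
    cat(sprintf("  R^2 = %.4f\n", object@rSquared))
})

setMethod("show", "GroupTestResult", function(object) {
  cat(sprintf("GroupTestResult: %s test, statistic %.4g, p = %.4g\n",
              object@testUsed, object@statistic, object@pValue))
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf("KappaResult: kappa = %.3f (95%% CI %.3f-%.3f), n = %d\n",
              object@kappa, object@ciLow, object@ciHigh, object@nPairs))
  cat(sprintf("  po = %.3f, pe = %.3f; categories: %s\n", object@po,
              object@pe, paste(object@categories, collapse = ", ")))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d animals, %d loops, %d ROIs/loop, %s\n",
              length(object@loopsPerAnimal), sum(object@loopsPerAnimal),
              length(object@rois),
              paste(object@timepoints, collapse = "/")))
  cat(sprintf("  scheduled lactate records: %d\n",
              designRecordCount(object)))
})

setMethod("show", "MidlinePath", function(object) {
  p <- object@points
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                       p[-nrow(p), , drop = FALSE])^2))
  cat(sprintf(
    "MidlinePath: %d points, length %.1f px (%.2f cm), ischemic toward %s\n",
    nrow(p), sum(seg), sum(seg) * object@pixelSize,
    object@ischemicDirection))
})
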