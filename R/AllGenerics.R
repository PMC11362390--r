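## Accessor generics.  Slot access from user code is discouraged; these are
## the supported surface.

#' @rdname FlowPhantom-class
#' @param object,x an object of the documented class
#' @export
setGeneric("tauMap", function(object) standardGeneric("tauMap"))

#' @rdname FlowPhantom-class
#' @export
setGeneric("zoneMap", function(object) standardGeneric("zoneMap"))

#' @rdname FlowPhantom-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname SpeckleStack-class
#' @param object an object of the documented class
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname SpeckleStack-class
#' @export
setGeneric("exposure", function(object) standardGeneric("exposure"))

#' @rdname SpeckleStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname ContrastMap-class
#' @param object an object of the documented class
#' @export
setGeneric("kValues", function(object) standardGeneric("kValues"))

#' @rdname ContrastMap-class
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname ContrastMap-class
#' @export
setGeneric("windowSize", function(object) standardGeneric("windowSize"))

#' @rdname PerfusionMap-class
#' @param object an object of the documented class
#' @export
setGeneric("lspuValues", function(object) standardGeneric("lspuValues"))

#' @rdname PerfusionMap-class
#' @export
setGeneric("perfusionMapping",
           function(object) standardGeneric("perfusionMapping"))

#' @rdname CutoffResult-class
#' @param object an object of the documented class
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))

#' @rdname CutoffResult-class
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname CutoffResult-class
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname CutoffResult-class
#' @export
setGeneric("youdenJ", function(object) standardGeneric("youdenJ"))

#' @rdname CutoffResult-class
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname KappaResult-class
#' @param object an object of the documented class
#' @export
setGeneric("kappaValue", function(object) standardGeneric("kappaValue"))

#' @rdname KappaResult-class
#' @export
setGeneric("kappaCI", function(object) standardGeneric("kappaCI"))
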