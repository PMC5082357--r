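#' @rdname PDFParameters-class
#' @param object,x an object.
#' @export
setGeneric("viscoelasticity", function(object) standardGeneric("viscoelasticity"))
#' @rdname PDFParameters-class
#' @export
setGeneric("stiffness", function(object) standardGeneric("stiffness"))
#' @rdname PDFParameters-class
#' @export
setGeneric("initialLoad", function(object) standardGeneric("initialLoad"))
#' @rdname PDFParameters-class
#' @param tol relative tolerance on the discriminant used to call a wave
#'   critically damped.
#' @export
setGeneric("regime", function(object, tol = 1e-9) standardGeneric("regime"))

#' @rdname DopplerStrip-class
#' @param object,x an object.
#' @export
setGeneric("pixelMatrix", function(object) standardGeneric("pixelMatrix"))
#' @rdname DopplerStrip-class
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))
#' @rdname DopplerStrip-class
#' @export
setGeneric("velocityStep", function(object) standardGeneric("velocityStep"))
#' @rdname DopplerStrip-class
#' @export
setGeneric("baselineRow", function(object) standardGeneric("baselineRow"))
#' @rdname DopplerStrip-class
#' @export
setGeneric("flowSign", function(object) standardGeneric("flowSign"))
#' @rdname DopplerStrip-class
#' @export
setGeneric("stripTimes", function(object) standardGeneric("stripTimes"))

#' @rdname VelocityTrace-class
#' @param object an object.
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname VelocityTrace-class
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))
#' @rdname VelocityTrace-class
#' @export
setGeneric("acceptedFlags", function(object) standardGeneric("acceptedFlags"))

#' @rdname EwaveFit-class
#' @param object an object.
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname EwaveFit-class
#' @export
setGeneric("fitIndices", function(object) standardGeneric("fitIndices"))
#' @rdname EwaveFit-class
#' @export
setGeneric("fitTrace", function(object) standardGeneric("fitTrace"))
#' @rdname EwaveFit-class
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))
#' @rdname EwaveFit-class
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))

#' @rdname AutoFitReport-class
#' @param object an object.
#' @export
setGeneric("acceptedFits", function(object) standardGeneric("acceptedFits"))
#' @rdname AutoFitReport-class
#' @export
setGeneric("discardedBeats", function(object) standardGeneric("discardedBeats"))

#' @rdname StudyResult-class
#' @param object an object.
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))
#' @rdname StudyResult-class
#' @export
setGeneric("studyFits", function(object) standardGeneric("studyFits"))
#' @rdname StudyResult-class
#' @export
setGeneric("beatTable", function(object) standardGeneric("beatTable"))
#' @rdname StudyResult-class
#' @export
setGeneric("studySummary", function(object) standardGeneric("studySummary"))
#' @rdname StudyResult-class
#' @export
setGeneric("loadIndex", function(object) standardGeneric("loadIndex"))
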