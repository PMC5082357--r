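# Accessors and show() methods for the core classes.

#' @rdname PDFParameters-class
#' @export
setMethod("viscoelasticity", "PDFParameters", function(object) object@c)
#' @rdname PDFParameters-class
#' @export
setMethod("stiffness", "PDFParameters", function(object) object@k)
#' @rdname PDFParameters-class
#' @export
setMethod("initialLoad", "PDFParameters", function(object) object@x0)

#' @rdname PDFParameters-class
#' @export
setMethod("regime", "PDFParameters", function(object, tol = 1e-9) {
  disc <- object@k - object@c^2 / 4
  if (abs(disc) <= tol * max(1, object@k)) "critical"
  else if (disc > 0) "underdamped"
  else "overdamped"
})

setMethod("show", "PDFParameters", function(object) {
  cat(sprintf("PDFParameters: c = %.4g g/s, k = %.5g g/s^2, x0 = %.4g cm (%s)\n",
              object@c, object@k, object@x0, regime(object)))
})

setMethod("show", "Triad", function(object) {
  cat(sprintf("Triad: AT = %.4g s, DT = %.4g s, Vmax = %.4g cm/s\n",
              object@at, object@dt, object@vmax))
})

#' @rdname DopplerStrip-class
#' @export
setMethod("pixelMatrix", "DopplerStrip", function(object) object@pixels)
#' @rdname DopplerStrip-class
#' @export
setMethod("timeStep", "DopplerStrip", function(object) object@dtPerCol)
#' @rdname DopplerStrip-class
#' @export
setMethod("velocityStep", "DopplerStrip", function(object) object@dvPerRow)
#' @rdname DopplerStrip-class
#' @export
setMethod("baselineRow", "DopplerStrip", function(object) object@baselineRow)
#' @rdname DopplerStrip-class
#' @export
setMethod("flowSign", "DopplerStrip", function(object) object@flowSign)

#' @rdname DopplerStrip-class
#' @export
setMethod("stripTimes", "DopplerStrip", function(object) {
  (seq_len(ncol(object@pixels)) - 0.5) * object@dtPerCol
})

#' @rdname DopplerStrip-class
#' @export
setMethod("dim", "DopplerStrip", function(x) dim(x@pixels))

setMethod("show", "DopplerStrip", function(object) {
  cat(sprintf(paste0("DopplerStrip '%s': %d x %d px, %.4g ms/col, ",
                     "%.3g (cm/s)/row, baseline row %d, span %.3g s\n"),
              object@sourceId, nrow(object@pixels), ncol(object@pixels),
              1000 * object@dtPerCol, object@dvPerRow, object@baselineRow,
              ncol(object@pixels) * object@dtPerCol))
  if (!is.na(object@heartRate))
    cat(sprintf("  heart rate: %.4g bpm\n", object@heartRate))
})

#' @rdname VelocityTrace-class
#' @export
setMethod("sampleTimes", "VelocityTrace", function(object) object@times)
#' @rdname VelocityTrace-class
#' @export
setMethod("velocities", "VelocityTrace", function(object) object@velocities)
#' @rdname VelocityTrace-class
#' @export
setMethod("acceptedFlags", "VelocityTrace", function(object) object@accepted)
#' @rdname VelocityTrace-class
#' @export
setMethod("length", "VelocityTrace", function(x) length(x@times))

setMethod("show", "VelocityTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("VelocityTrace: %d samples (%d accepted), t in [%.4g, %.4g] s, peak %.4g cm/s\n",
              n, sum(object@accepted),
              if (n) min(object@times) else NA, if (n) max(object@times) else NA,
              if (any(object@accepted)) max(object@velocities[object@accepted]) else NA))
})

#' @rdname EwaveFit-class
#' @export
setMethod("fitParams", "EwaveFit", function(object) object@params)
#' @rdname EwaveFit-class
#' @export
setMethod("fitIndices", "EwaveFit", function(object) object@indices)
#' @rdname EwaveFit-class
#' @export
setMethod("fitTrace", "EwaveFit", function(object) object@trace)
#' @rdname EwaveFit-class
#' @export
setMethod("residualNorm", "EwaveFit", function(object) object@residualNorm)
#' @rdname EwaveFit-class
#' @export
setMethod("hasConverged", "EwaveFit", function(object) object@converged)

setMethod("show", "EwaveFit", function(object) {
  cat(sprintf("EwaveFit (%s%s): ", object@method,
              if (object@converged) "" else ", NOT converged"))
  show(object@params)
  ix <- object@indices
  cat(sprintf("  Vmax %.4g cm/s | Edec %.4g ms | VTI %.4g cm | KFEI %.3g%% | kx0 %.4g mN\n",
              ix[["vmax"]], ix[["edec"]], ix[["vti"]], ix[["kfei"]], ix[["kx0"]]))
})

#' @rdname AutoFitReport-class
#' @export
setMethod("acceptedFits", "AutoFitReport", function(object) object@fits)
#' @rdname AutoFitReport-class
#' @export
setMethod("discardedBeats", "AutoFitReport", function(object) object@discarded)

setMethod("show", "AutoFitReport", function(object) {
  cat(sprintf("AutoFitReport: %d accepted, %d discarded\n",
              length(object@fits), nrow(object@discarded)))
  if (nrow(object@discarded)) print(object@discarded)
})

setMethod("show", "LoadIndependentIndex", function(object) {
  cat(sprintf("Load-independence regression (%d beats): M = %.4g, B = %.4g mN\n",
              object@nBeats, object@m, object@b))
})

#' @rdname StudyResult-class
#' @export
setMethod("caseId", "StudyResult", function(object) object@caseId)
#' @rdname StudyResult-class
#' @export
setMethod("studyFits", "StudyResult", function(object) object@fits)
#' @rdname StudyResult-class
#' @export
setMethod("loadIndex", "StudyResult", function(object) object@loadIndex)

setMethod("show", "StudyResult", function(object) {
  cat(sprintf("StudyResult '%s': %d beats (%s)\n", object@caseId,
              length(object@fits), object@timestamp))
  if (!is.null(object@loadIndex)) show(object@loadIndex)
})

setMethod("show", "PairedMeasurements", function(object) {
  cat(sprintf("PairedMeasurements '%s' [%s]: %d cases\n", object@parameter,
              object@units, length(object@a)))
})

setMethod("show", "DicomDopplerSource", function(object) {
  cat(sprintf("DICOM Doppler source: %s (%s), %d frame(s), dt %.4g ms, dv %.3g cm/s%s\n",
              if (object@anonymized) "<anonymized>" else object@path,
              object@vendor, object@frameCount, 1000 * object@dtPerCol,
              object@dvPerRow, if (is.na(object@heartRate)) ""
              else sprintf(", HR %.4g bpm", object@heartRate)))
})
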