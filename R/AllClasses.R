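#' @import methods
NULL

.scalarOK <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' The kinematic model constants of one E-wave
#'
#' The three constants of the damped-spring (parameterized diastolic
#' filling) model of early transmitral flow: viscoelastic damping
#' \code{c} (g/s), chamber stiffness \code{k} (g/s^2) and load \code{x0}
#' (cm).  Inertial mass is fixed at 1 g by convention, so all three carry
#' the units above and \code{k} has dimensions of 1/s^2.
#'
#' @slot c viscoelasticity (damping) constant, g/s; non-negative.
#' @slot k stiffness constant, g/s^2; strictly positive.
#' @slot x0 load (initial spring displacement), cm; strictly positive.
#' @seealso [pdfParameters()], [modelVelocity()], [derivedIndices()]
#' @exportClass PDFParameters
setClass("PDFParameters",
  representation(c = "numeric", k = "numeric", x0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarOK(object@c) || object@c < 0)
      msg <- c(msg, "c must be a finite scalar >= 0")
    if (!.scalarOK(object@k) || object@k <= 0)
      msg <- c(msg, "k must be a finite scalar > 0")
    if (!.scalarOK(object@x0) || object@x0 <= 0)
      msg <- c(msg, "x0 must be a finite scalar > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct PDF model constants
#'
#' @param c viscoelasticity, g/s (>= 0).
#' @param k stiffness, g/s^2 (> 0).
#' @param x0 load, cm (> 0).
#' @return A [PDFParameters-class] object.
#' @examples
#' pdfParameters(c = 17.3, k = 135, x0 = 11.4)
#' @export
pdfParameters <- function(c, k, x0) new("PDFParameters", c = c, k = k, x0 = x0)

#' Triad parameterization of an E-wave
#'
#' An E-wave is equivalently described by its acceleration time (onset to
#' peak), deceleration time (peak to terminus) and peak velocity; each
#' valid triad corresponds to exactly one set of model constants.
#'
#' @slot at acceleration time, s.
#' @slot dt deceleration time, s.
#' @slot vmax peak velocity, cm/s.
#' @seealso [paramsFromTriad()], [triadFromParams()]
#' @exportClass Triad
setClass("Triad",
  representation(at = "numeric", dt = "numeric", vmax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.scalarOK(object@at) || object@at <= 0) msg <- c(msg, "at must be > 0")
    if (!.scalarOK(object@dt) || object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (!.scalarOK(object@vmax) || object@vmax <= 0) msg <- c(msg, "vmax must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname Triad-class
#' @param at,dt,vmax triad components (s, s, cm/s).
#' @export
triad <- function(at, dt, vmax) new("Triad", at = at, dt = dt, vmax = vmax)

#' A calibrated spectral-Doppler pixel strip
#'
#' One (or several concatenated) cardiac cycles of pulsed-wave spectral
#' Doppler.  Columns are time, rows are velocity; the physical value of
#' pixel (r, j) is \code{flowSign * (baselineRow - r) * dvPerRow} cm/s at
#' time \code{(j - 0.5) * dtPerCol} s (pixel-center convention, columns
#' numbered from 1).
#'
#' @slot pixels integer-valued brightness matrix, 0-255.
#' @slot dtPerCol seconds per pixel column (> 0).
#' @slot dvPerRow (cm/s) per pixel row (> 0).
#' @slot baselineRow row index (1-based) of zero velocity.
#' @slot flowSign +1 when the E-wave lies above the baseline, -1 below.
#' @slot sourceId provenance string.
#' @slot heartRate beats per minute, NA when unknown.
#' @exportClass DopplerStrip
setClass("DopplerStrip",
  representation(pixels = "matrix", dtPerCol = "numeric", dvPerRow = "numeric",
                 baselineRow = "integer", flowSign = "numeric",
                 sourceId = "character", heartRate = "numeric"),
  prototype(heartRate = NA_real_, sourceId = "unknown", flowSign = 1),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@pixels) || any(!is.finite(object@pixels)))
      msg <- c(msg, "pixels must be a finite numeric matrix")
    if (!.scalarOK(object@dtPerCol) || object@dtPerCol <= 0)
      msg <- c(msg, "dtPerCol must be > 0")
    if (!.scalarOK(object@dvPerRow) || object@dvPerRow <= 0)
      msg <- c(msg, "dvPerRow must be > 0")
    if (length(object@baselineRow) != 1L || is.na(object@baselineRow) ||
        object@baselineRow < 1L || object@baselineRow > nrow(object@pixels))
      msg <- c(msg, "baselineRow must index a pixel row")
    if (!object@flowSign %in% c(-1, 1))
      msg <- c(msg, "flowSign must be +1 or -1")
    if (length(msg)) msg else TRUE
  })

#' @rdname DopplerStrip-class
#' @param pixels,dtPerCol,dvPerRow,baselineRow,flowSign,sourceId,heartRate
#'   see slot documentation.
#' @export
dopplerStrip <- function(pixels, dtPerCol, dvPerRow, baselineRow,
                         flowSign = 1, sourceId = "unknown",
                         heartRate = NA_real_) {
  new("DopplerStrip", pixels = pixels, dtPerCol = dtPerCol,
      dvPerRow = dvPerRow, baselineRow = as.integer(baselineRow),
      flowSign = flowSign, sourceId = sourceId, heartRate = as.numeric(heartRate))
}

#' Settings for envelope detection
#'
#' @slot tStart,tEnd detection window, s.  \code{tEnd = NA} triggers the
#'   default heuristic (75\% of the estimated E-wave duration).
#' @slot threshold brightness threshold 0-255; NA selects Otsu's threshold
#'   of the detection window.
#' @slot maxJump largest accepted velocity change (cm/s) between a
#'   candidate and the last accepted sample; NA defaults to 25\% of the
#'   strip's velocity span.
#' @slot zeroTail,tangentShorten the two deceleration-shortening
#'   procedures; both default on.
#' @exportClass DetectionSettings
setClass("DetectionSettings",
  representation(tStart = "numeric", tEnd = "numeric", threshold = "numeric",
                 maxJump = "numeric", zeroTail = "logical",
                 tangentShorten = "logical"),
  prototype(tStart = 0, tEnd = NA_real_, threshold = NA_real_,
            maxJump = NA_real_, zeroTail = TRUE, tangentShorten = TRUE),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@tEnd) && object@tEnd <= object@tStart)
      msg <- c(msg, "tStart must precede tEnd")
    if (!is.na(object@threshold) &&
        (object@threshold < 0 || object@threshold > 255))
      msg <- c(msg, "threshold must lie in [0, 255]")
    if (!is.na(object@maxJump) && object@maxJump < 0)
      msg <- c(msg, "maxJump must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname DetectionSettings-class
#' @param tStart,tEnd,threshold,maxJump,zeroTail,tangentShorten see slots.
#' @export
detectionSettings <- function(tStart = 0, tEnd = NA_real_,
                              threshold = NA_real_, maxJump = NA_real_,
                              zeroTail = TRUE, tangentShorten = TRUE) {
  new("DetectionSettings", tStart = tStart, tEnd = as.numeric(tEnd),
      threshold = as.numeric(threshold), maxJump = as.numeric(maxJump),
      zeroTail = zeroTail, tangentShorten = tangentShorten)
}

#' A detected time-velocity envelope
#'
#' One velocity sample per analyzed column.  Samples rejected by the
#' detector (no suprathreshold pixel, or a jump larger than
#' \code{maxJump} from the last accepted velocity) are retained with
#' \code{accepted = FALSE} so the detector's behavior stays inspectable.
#'
#' @slot times sample times, s, strictly increasing.
#' @slot velocities velocities, cm/s (NA allowed only where not accepted).
#' @slot accepted per-sample acceptance flag.
#' @slot settings the [DetectionSettings-class] used (resolved defaults).
#' @exportClass VelocityTrace
setClass("VelocityTrace",
  representation(times = "numeric", velocities = "numeric",
                 accepted = "logical", settings = "DetectionSettings"),
  prototype(settings = new("DetectionSettings")),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (length(object@velocities) != n || length(object@accepted) != n)
      msg <- c(msg, "times, velocities and accepted must have equal length")
    if (n > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(is.na(object@velocities) & object@accepted))
      msg <- c(msg, "accepted samples must have finite velocities")
    if (length(msg)) msg else TRUE
  })

#' @rdname VelocityTrace-class
#' @param times,velocities,accepted,settings see slot documentation.
#' @export
velocityTrace <- function(times, velocities,
                          accepted = rep(TRUE, length(times)),
                          settings = detectionSettings()) {
  new("VelocityTrace", times = as.numeric(times),
      velocities = as.numeric(velocities), accepted = accepted,
      settings = settings)
}

#' Result of fitting the kinematic model to one E-wave
#'
#' @slot params the fitted [PDFParameters-class].
#' @slot indices named numeric vector of derived indices, see
#'   [derivedIndices()].
#' @slot trace the [VelocityTrace-class] the fit used.
#' @slot method "full-fit" (least squares on all accepted samples) or
#'   "triad" (closed-form inversion of three landmarks).
#' @slot residualNorm L2 norm of the velocity residuals, cm/s.  Recorded
#'   for diagnostics; no goodness-of-fit verdict is attached to it.
#' @slot converged optimizer convergence flag.
#' @exportClass EwaveFit
setClass("EwaveFit",
  representation(params = "PDFParameters", indices = "numeric",
                 trace = "VelocityTrace", method = "character",
                 residualNorm = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("full-fit", "triad"))
      msg <- c(msg, "method must be 'full-fit' or 'triad'")
    if (length(object@residualNorm) != 1L || is.na(object@residualNorm) ||
        object@residualNorm < 0)
      msg <- c(msg, "residualNorm must be a scalar >= 0")
    if (length(msg)) msg else TRUE
  })

#' A start-of-E-wave image template for multi-beat matching
#'
#' @slot patch pixel patch centered on the onset column.
#' @slot onsetOffset 0-based column offset of the onset within the patch.
#' @slot dtPerCol seconds per column of the source strip.
#' @slot clipped TRUE when the onset was too close to the strip edge and
#'   the patch was truncated.
#' @exportClass StartTemplate
setClass("StartTemplate",
  representation(patch = "matrix", onsetOffset = "integer",
                 dtPerCol = "numeric", clipped = "logical"))

#' Report of the semi-automatic multi-beat fitting loop
#'
#' Every input beat lands either in \code{fits} or in \code{discarded};
#' the two partitions are disjoint and exhaustive.
#'
#' @slot fits accepted [EwaveFit-class] objects, in beat order.
#' @slot discarded data.frame with columns \code{beat} and \code{reason}
#'   ("no-template-match", "parameter-deviation" or "fit-failure").
#' @slot templateMeta list describing the start template geometry.
#' @exportClass AutoFitReport
setClass("AutoFitReport",
  representation(fits = "list", discarded = "data.frame",
                 templateMeta = "list"))

#' Slope and intercept of the driving-vs-resistive force relation
#'
#' Ordinary least-squares fit of peak driving force k*x0 on peak
#' resistive force c*Vmax across beats acquired under varying load.  The
#' slope M is the load-independent index of diastolic filling; B is the
#' intercept in mN.
#'
#' @slot m slope, dimensionless.
#' @slot b intercept, mN.
#' @slot nBeats number of beats entering the regression.
#' @slot forcePairs data.frame with columns \code{cvmax} and \code{kx0}, mN.
#' @exportClass LoadIndependentIndex
setClass("LoadIndependentIndex",
  representation(m = "numeric", b = "numeric", nBeats = "integer",
                 forcePairs = "data.frame"))

#' Per-case study container
#'
#' All fits of one case plus the load-independence regression, provenance
#' and (optionally) the source strips, ready for export or session
#' persistence.
#'
#' @slot caseId case identifier.
#' @slot fits list of [EwaveFit-class], one per accepted beat.
#' @slot strips list of [DopplerStrip-class] (may be empty).
#' @slot loadIndex [LoadIndependentIndex-class] or NULL.
#' @slot provenance list: source files, settings, software version.
#' @slot timestamp ISO-8601 creation time.
#' @exportClass StudyResult
setClass("StudyResult",
  representation(caseId = "character", fits = "list", strips = "list",
                 loadIndex = "ANY", provenance = "list",
                 timestamp = "character"),
  validity = function(object) {
    if (!all(vapply(object@fits, is, TRUE, "EwaveFit")))
      return("fits must all be EwaveFit objects")
    if (!(is.null(object@loadIndex) || is(object@loadIndex, "LoadIndependentIndex")))
      return("loadIndex must be NULL or a LoadIndependentIndex")
    TRUE
  })

#' Source metadata of a DICOM spectral-Doppler file
#'
#' @slot path file path (empty when anonymized).
#' @slot vendor Manufacturer string from the file.
#' @slot frameCount number of frames.
#' @slot heartRate bpm, NA when absent.
#' @slot dtPerCol,dvPerRow physical calibration of the selected region.
#' @slot baselineRow baseline row within the cropped region.
#' @slot anonymized flag.
#' @exportClass DicomDopplerSource
setClass("DicomDopplerSource",
  representation(path = "character", vendor = "character",
                 frameCount = "integer", heartRate = "numeric",
                 dtPerCol = "numeric", dvPerRow = "numeric",
                 baselineRow = "integer", anonymized = "logical"))

#' Paired per-case measurements from two analyses
#'
#' The unit of analysis is the per-case (per-patient) mean; pairing is by
#' case label.
#'
#' @slot labels case identifiers.
#' @slot a,b values from analysis 1 and analysis 2.
#' @slot parameter,units descriptive strings.
#' @exportClass PairedMeasurements
setClass("PairedMeasurements",
  representation(labels = "character", a = "numeric", b = "numeric",
                 parameter = "character", units = "character"),
  validity = function(object) {
    n <- length(object@a)
    msg <- character()
    if (n < 2) msg <- c(msg, "at least 2 paired cases are required")
    if (length(object@b) != n || length(object@labels) != n)
      msg <- c(msg, "labels, a and b must have equal length")
    if (any(!is.finite(object@a)) || any(!is.finite(object@b)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' @rdname PairedMeasurements-class
#' @param labels,a,b,parameter,units see slot documentation.
#' @export
pairedMeasurements <- function(labels, a, b, parameter = "", units = "") {
  new("PairedMeasurements", labels = as.character(labels), a = as.numeric(a),
      b = as.numeric(b), parameter = parameter, units = units)
}

#' Specification of a synthetic Doppler acquisition
#'
#' Defines everything the synthetic generator renders: model constants
#' (per beat), geometry and calibration, fill/noise intensity model,
#' deceleration-phase artifacts, an optional A-wave, and the seed.  The
#' seed fully determines the output.
#'
#' @slot params list of [PDFParameters-class], one per beat.
#' @slot cycleLength cardiac cycle length, s.
#' @slot dtPerCol s per column (default 0.004 s: 100 mm/s sweep at a
#'   0.4 mm pixel pitch).
#' @slot dvPerRow (cm/s) per row.
#' @slot nRows image height, px.
#' @slot baselineRow baseline row.
#' @slot fillRange brightness range of the filled spectral band.
#' @slot noiseLevel sd of background speckle brightness (0 = clean).
#' @slot envelopeJitterSd velocity noise on the rendered envelope, cm/s
#'   (the ground truth stays the clean model envelope).
#' @slot artifactProb per-column probability of a bright supra-envelope
#'   artifact during the deceleration phase.
#' @slot artifactAmp largest artifact velocity excess above the true
#'   envelope, cm/s.
#' @slot aWave render a late-diastolic A-wave.
#' @slot aWaveScale A-wave peak as a fraction of the E-wave peak.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(params = "list", cycleLength = "numeric",
                 dtPerCol = "numeric", dvPerRow = "numeric",
                 nRows = "integer", baselineRow = "integer",
                 fillRange = "numeric", noiseLevel = "numeric",
                 envelopeJitterSd = "numeric",
                 artifactProb = "numeric", artifactAmp = "numeric",
                 aWave = "logical", aWaveScale = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!length(object@params) ||
        !all(vapply(object@params, is, TRUE, "PDFParameters")))
      msg <- c(msg, "params must be a non-empty list of PDFParameters")
    for (s in c("cycleLength", "dtPerCol", "dvPerRow", "noiseLevel",
                "envelopeJitterSd", "artifactProb", "artifactAmp",
                "aWaveScale"))
      if (!.scalarOK(slot(object, s)) || slot(object, s) < 0)
        msg <- c(msg, paste(s, "must be a finite scalar >= 0"))
    if (object@cycleLength <= 0 || object@dtPerCol <= 0 || object@dvPerRow <= 0)
      msg <- c(msg, "geometry must be strictly positive")
    if (object@baselineRow < 1L || object@baselineRow > object@nRows)
      msg <- c(msg, "baselineRow must lie within the image")
    if (length(msg)) msg else TRUE
  })

#' @rdname SyntheticSpec-class
#' @param params a [PDFParameters-class] object or list of them (per beat).
#' @param cycleLength,dtPerCol,dvPerRow,nRows,baselineRow,fillRange,noiseLevel
#'   see slot documentation.
#' @param artifactProb,artifactAmp,aWave,aWaveScale,seed see slots.
#' @export
syntheticSpec <- function(params, cycleLength = 0.8, dtPerCol = 0.004,
                          dvPerRow = 1, nRows = 170L, baselineRow = 160L,
                          fillRange = c(190, 255), noiseLevel = 0,
                          envelopeJitterSd = 0, artifactProb = 0,
                          artifactAmp = 30, aWave = FALSE, aWaveScale = 0.5,
                          seed = 1L) {
  if (is(params, "PDFParameters")) params <- list(params)
  new("SyntheticSpec", params = params, cycleLength = cycleLength,
      dtPerCol = dtPerCol, dvPerRow = dvPerRow, nRows = as.integer(nRows),
      baselineRow = as.integer(baselineRow), fillRange = fillRange,
      noiseLevel = noiseLevel, envelopeJitterSd = envelopeJitterSd,
      artifactProb = artifactProb,
      artifactAmp = artifactAmp, aWave = aWave, aWaveScale = aWaveScale,
      seed = as.integer(seed))
}
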