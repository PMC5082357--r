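# Envelope detection: extraction of the E-wave time-velocity profile
# from a calibrated spectral-Doppler strip, plus the two
# deceleration-shortening procedures applied before the final fit.

#' Normalize strip orientation
#'
#' Returns a strip with the E-wave above the baseline (flowSign = +1),
#' vertically flipping the pixel matrix when needed.  The physical
#' velocity of every pixel is preserved, and the operation is idempotent.
#'
#' @param strip a [DopplerStrip-class].
#' @return an oriented [DopplerStrip-class].
#' @export
orientStrip <- function(strip) {
  stopifnot(is(strip, "DopplerStrip"))
  if (strip@flowSign == 1) return(strip)
  n <- nrow(strip@pixels)
  dopplerStrip(strip@pixels[n:1, , drop = FALSE], strip@dtPerCol,
               strip@dvPerRow, n - strip@baselineRow + 1L, flowSign = 1,
               sourceId = strip@sourceId, heartRate = strip@heartRate)
}

#' Percentile-based contrast stretch
#'
#' Linearly rescales intensities so that the \code{lowPct} percentile
#' maps to 0 and the \code{highPct} percentile to 255, clipping outside.
#' Geometry and calibration are untouched.  A constant image cannot be
#' stretched and is returned unchanged with a warning.
#'
#' @param strip a [DopplerStrip-class].
#' @param lowPct,highPct percentiles in [0, 100], lowPct < highPct.
#' @return the stretched [DopplerStrip-class].
#' @export
contrastStretch <- function(strip, lowPct = 1, highPct = 99) {
  stopifnot(is(strip, "DopplerStrip"),
            lowPct >= 0, highPct <= 100, lowPct < highPct)
  q <- stats::quantile(strip@pixels, c(lowPct, highPct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: contrast stretch is a no-op")
    return(strip)
  }
  px <- strip@pixels
  px[] <- pmin(255, pmax(0, (px - q[1]) * 255 / (q[2] - q[1])))
  methods::initialize(strip, pixels = px)
}

# The onset of flow for time re-referencing: the user-set detection
# start when available (fitted constants are sensitive to onset
# placement, so the marked start is authoritative), else the first
# accepted sample.
.onsetTime <- function(trace) {
  tS <- trace@settings@tStart
  first <- trace@times[which(trace@accepted)[1]]
  if (is.finite(tS) && tS <= first) tS else first
}

# Resolve NA settings against a concrete strip: Otsu threshold, 25%-span
# jump limit, 75%-of-duration end point.
.resolveSettings <- function(strip, settings) {
  times <- stripTimes(strip)
  tEnd <- if (is.na(settings@tEnd)) times[length(times)] + strip@dtPerCol
          else settings@tEnd
  cols <- which(times >= settings@tStart & times <= tEnd)
  if (!length(cols)) stop("detection window contains no columns")
  thr <- settings@threshold
  if (is.na(thr)) {
    win <- strip@pixels[, cols, drop = FALSE]
    thr <- 255 * EBImage::otsu(EBImage::Image(win / 255), range = c(0, 1))
  }
  mj <- settings@maxJump
  if (is.na(mj)) mj <- 0.25 * (strip@baselineRow - 1L) * strip@dvPerRow
  detectionSettings(settings@tStart, tEnd, thr, mj,
                    settings@zeroTail, settings@tangentShorten)
}

# One top-down detection pass over resolved settings.
.detectPass <- function(strip, settings) {
  times <- stripTimes(strip)
  cols <- which(times >= settings@tStart & times <= settings@tEnd)
  if (!length(cols)) stop("detection window contains no columns")
  nc <- length(cols)
  v <- rep(NA_real_, nc)
  acc <- rep(FALSE, nc)
  ref <- 0  # flow is about to begin: reference velocity is zero
  for (i in seq_len(nc)) {
    col <- strip@pixels[seq_len(strip@baselineRow), cols[i]]
    r <- which(col >= settings@threshold)[1]
    if (is.na(r)) next
    v[i] <- (strip@baselineRow - r) * strip@dvPerRow
    if (abs(v[i] - ref) <= settings@maxJump) {
      acc[i] <- TRUE
      ref <- v[i]
    }
  }
  velocityTrace(times[cols], v, acc, settings)
}

#' Detect the E-wave velocity envelope
#'
#' Searches each pixel column of the detection window from the top down
#' for the first pixel at or above the brightness threshold, converting
#' its row to a velocity.  A candidate whose velocity differs from the
#' last accepted velocity by more than \code{maxJump} is retained but
#' flagged \code{accepted = FALSE}, as are columns with no suprathreshold
#' pixel; the reference for the first sample is zero velocity (flow is
#' about to begin).  Comparing against the last accepted sample rather
#' than the previous column keeps isolated noise pixels from poisoning
#' the rest of the trace.
#'
#' Unset settings are resolved against the strip: the threshold defaults
#' to Otsu's threshold of the window, the jump limit to 25\% of the
#' strip's velocity span, and the end point to 75\% of the estimated
#' E-wave duration (estimated from a full-width first pass).
#'
#' @param strip a [DopplerStrip-class] (any orientation).
#' @param settings a [DetectionSettings-class].
#' @return a [VelocityTrace-class].
#' @export
detectEnvelope <- function(strip, settings = detectionSettings()) {
  stopifnot(is(strip, "DopplerStrip"), is(settings, "DetectionSettings"))
  strip <- orientStrip(strip)
  times <- stripTimes(strip)
  if (settings@tStart > times[length(times)])
    stop("detection window lies outside the strip")
  if (!is.na(settings@tEnd) && settings@tEnd < times[1])
    stop("detection window lies outside the strip")
  needHeuristicEnd <- is.na(settings@tEnd)
  res <- .resolveSettings(strip, settings)
  trace <- .detectPass(strip, res)
  if (needHeuristicEnd) {
    # first pass ran to the strip end; trim to 75% of estimated duration
    acc <- which(trace@accepted)
    if (length(acc) >= 3) {
      va <- trace@velocities[acc]
      ipk <- which.max(va)
      after <- acc[-seq_len(ipk)]
      lowIdx <- after[trace@velocities[after] <= 0.05 * va[ipk]][1]
      terminus <- if (!is.na(lowIdx)) trace@times[lowIdx]
                  else trace@times[acc[length(acc)]]
      tEnd <- res@tStart + 0.75 * (terminus - res@tStart)
      res <- detectionSettings(res@tStart, tEnd, res@threshold, res@maxJump,
                               res@zeroTail, res@tangentShorten)
      trace <- .detectPass(strip, res)
    }
  }
  trace
}

#' Zero the tail of a detected trace
#'
#' Replaces the velocities of the final two accepted samples with zero:
#' if the E-wave ends, its terminal velocity must be zero, and artifacts
#' during deceleration otherwise drag the fitted deceleration time out.
#' Times and acceptance flags are untouched; the operation is idempotent.
#'
#' @param trace a [VelocityTrace-class] with at least 3 accepted samples.
#' @return the modified [VelocityTrace-class].
#' @export
zeroTail <- function(trace) {
  stopifnot(is(trace, "VelocityTrace"))
  acc <- which(trace@accepted)
  if (length(acc) < 3)
    stop("zeroTail needs at least 3 accepted samples")
  v <- trace@velocities
  v[utils::tail(acc, 2)] <- 0
  methods::initialize(trace, velocities = v)
}

#' Shorten the deceleration limb along its 70%-of-peak tangent
#'
#' Given a first model fit, computes the tangent to the fitted curve at
#' the time on the deceleration limb where velocity has fallen to 70\% of
#' the peak, and extrapolates it to the velocity baseline — the straight
#' line drawn in clinical echocardiography to mark the deceleration time.
#' The returned trace equals the fitted curve up to that time and follows
#' the tangent from there to its baseline intercept (clamped at zero
#' speed beyond, with those padding samples flagged not accepted).
#' Refitting this trace yields a final curve with a shorter deceleration
#' time.
#'
#' @param trace the detected [VelocityTrace-class] (supplies the time grid
#'   and the onset reference).
#' @param firstFit [PDFParameters-class] from the initial fit.
#' @return a resampled [VelocityTrace-class] ready for refitting.
#' @export
tangentShorten <- function(trace, firstFit) {
  stopifnot(is(trace, "VelocityTrace"), is(firstFit, "PDFParameters"))
  if (!any(trace@accepted)) stop("trace has no accepted samples")
  onset <- .onsetTime(trace)
  pk <- peakCharacteristics(firstFit)
  dur <- ewaveDuration(firstFit)
  t70 <- stats::uniroot(function(t) modelVelocity(firstFit, t) - 0.7 * pk[["vmax"]],
                        c(pk[["tPeak"]], dur), tol = 1e-12)$root
  slope <- .modelAccel(firstFit, t70)
  if (slope >= 0)
    stop("tangent is not decelerating at 70% of peak velocity")
  v70 <- modelVelocity(firstFit, t70)
  tIntercept <- t70 - v70 / slope
  rel <- trace@times - onset
  keep <- rel >= 0
  rel <- rel[keep]
  v <- modelVelocity(firstFit, rel)
  onTangent <- rel >= t70 & rel <= tIntercept
  v[onTangent] <- v70 + slope * (rel[onTangent] - t70)
  v[rel > tIntercept] <- 0
  velocityTrace(trace@times[keep], v,
                accepted = rel <= tIntercept, settings = trace@settings)
}

#' Read / write a plain time-velocity trace
#'
#' Two-column delimited text (\code{time_s}, \code{velocity_cm_s}) with a
#' header row, the pipeline entry point when no DICOM file is available.
#' An optional third column \code{accepted} round-trips the acceptance
#' flags.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return [readVelocityTrace()] returns a [VelocityTrace-class].
#' @export
readVelocityTrace <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "velocity_cm_s") %in% names(d)))
    stop("trace file must have columns time_s and velocity_cm_s")
  acc <- if ("accepted" %in% names(d)) as.logical(d$accepted)
         else rep(TRUE, nrow(d))
  velocityTrace(d$time_s, d$velocity_cm_s, acc)
}

#' @rdname readVelocityTrace
#' @param trace a [VelocityTrace-class].
#' @export
writeVelocityTrace <- function(trace, path, sep = "\t") {
  stopifnot(is(trace, "VelocityTrace"))
  utils::write.table(
    data.frame(time_s = trace@times, velocity_cm_s = trace@velocities,
               accepted = trace@accepted),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
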