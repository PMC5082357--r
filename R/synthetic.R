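# Seeded ground-truth generators: velocity traces, spectral strips,
# multi-beat cines, and DICOM files with known model constants.
#
# The intensity model is phenomenological: a filled bright spectral band
# from the baseline up to the envelope (pulsed-wave Doppler appearance),
# background speckle, optional supra-envelope artifacts during the
# deceleration phase (the failure mode the shortening procedures target)
# and an optional A-wave.  All generators are pure functions of
# (spec, seed).

#' Synthetic velocity trace
#'
#' Samples the model speed on a regular grid over [0, duration] and adds
#' seeded Gaussian noise, clipped at zero speed.  \code{noiseSd = 0}
#' reproduces the closed form exactly.
#'
#' @param params a [PDFParameters-class].
#' @param dt sampling interval, s.
#' @param noiseSd velocity noise standard deviation, cm/s.
#' @param seed RNG seed (only used when noiseSd > 0).
#' @return a [VelocityTrace-class].
#' @export
synthTrace <- function(params, dt = 0.004, noiseSd = 0, seed = 1L) {
  stopifnot(dt > 0, noiseSd >= 0)
  t <- seq(0, ewaveDuration(params), by = dt)
  v <- modelVelocity(params, t)
  if (noiseSd > 0)
    v <- withr::with_seed(seed, pmax(0, v + stats::rnorm(length(v), 0, noiseSd)))
  velocityTrace(t, v)
}

# render one beat (column intensities + exact envelope) into a matrix
.renderBeat <- function(spec, params) {
  nc <- as.integer(round(spec@cycleLength / spec@dtPerCol))
  t <- (seq_len(nc) - 0.5) * spec@dtPerCol
  v <- modelVelocity(params, t)
  if (spec@aWave) {
    # late-diastolic wave: same shape, scaled peak, starting at 55% cycle
    tA <- t - 0.55 * spec@cycleLength
    vA <- numeric(nc)
    ok <- tA >= 0
    vA[ok] <- spec@aWaveScale * modelVelocity(params, tA[ok])
    v <- pmax(v, vA)
  }
  vDrawn <- if (spec@envelopeJitterSd > 0)
    pmax(0, v + stats::rnorm(nc, 0, spec@envelopeJitterSd)) else v
  envRow <- spec@baselineRow - as.integer(round(vDrawn / spec@dvPerRow))
  if (any(envRow < 1L))
    stop("envelope exceeds image height; increase dvPerRow or nRows")
  px <- matrix(0, spec@nRows, nc)
  if (spec@noiseLevel > 0)
    px[] <- round(pmin(255, abs(stats::rnorm(length(px), 0, spec@noiseLevel))))
  for (j in seq_len(nc)) {
    rows <- envRow[j]:spec@baselineRow
    px[rows, j] <- round(stats::runif(length(rows), spec@fillRange[1],
                                      spec@fillRange[2]))
  }
  if (spec@artifactProb > 0) {
    pk <- peakCharacteristics(params)
    dur <- ewaveDuration(params)
    inDecel <- t > pk[["tPeak"]] + 0.2 * (dur - pk[["tPeak"]]) & t < dur
    for (j in which(inDecel)) {
      if (stats::runif(1) < spec@artifactProb) {
        excess <- stats::runif(1, 5, max(5, spec@artifactAmp))
        aRow <- envRow[j] - as.integer(round(excess / spec@dvPerRow))
        if (aRow >= 1L) {
          rows <- max(1L, aRow - 1L):envRow[j]
          px[rows, j] <- round(stats::runif(length(rows), spec@fillRange[1],
                                            spec@fillRange[2]))
        }
      }
    }
  }
  storage.mode(px) <- "integer"
  list(pixels = px, envelope = v, times = t)
}

#' Synthetic spectral-Doppler strip with known ground truth
#'
#' Renders one cardiac cycle from the first parameter set of the spec.
#' The E-wave starts at the beginning of the cycle; the spectral band is
#' filled from the baseline up to the envelope.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with \code{strip} (a [DopplerStrip-class]), \code{truth}
#'   (the exact generating envelope as a [VelocityTrace-class]) and
#'   \code{params}.
#' @examples
#' s <- synthStrip(syntheticSpec(pdfParameters(17.3, 135, 11.4), seed = 7))
#' dim(s$strip)
#' @export
synthStrip <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  withr::with_seed(spec@seed, {
    beat <- .renderBeat(spec, spec@params[[1]])
    list(strip = dopplerStrip(beat$pixels, spec@dtPerCol, spec@dvPerRow,
                              spec@baselineRow, flowSign = 1,
                              sourceId = sprintf("synthetic-seed%d", spec@seed),
                              heartRate = 60 / spec@cycleLength),
         truth = velocityTrace(beat$times, beat$envelope),
         params = spec@params[[1]])
  })
}

#' Synthetic multi-beat cine strip
#'
#' Concatenates one rendered cycle per parameter set in
#' \code{spec@params} (load variation across beats drives the M/B
#' machinery).  Beat boundaries and per-beat envelopes are returned as
#' ground truth.
#'
#' @param spec a [SyntheticSpec-class] whose \code{params} list has one
#'   entry per beat.
#' @return list with \code{strip}, \code{boundaries} (first column of
#'   each beat, 1-based), \code{truths} (per-beat envelope traces) and
#'   \code{params} (per-beat list).
#' @export
synthCine <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  withr::with_seed(spec@seed, {
    beats <- lapply(spec@params, function(p) .renderBeat(spec, p))
    px <- do.call(cbind, lapply(beats, `[[`, "pixels"))
    ncPer <- vapply(beats, function(b) ncol(b$pixels), 0L)
    list(strip = dopplerStrip(px, spec@dtPerCol, spec@dvPerRow,
                              spec@baselineRow, flowSign = 1,
                              sourceId = sprintf("synthetic-cine-seed%d", spec@seed),
                              heartRate = 60 / spec@cycleLength),
         boundaries = cumsum(c(1L, ncPer[-length(ncPer)])),
         truths = lapply(beats, function(b) velocityTrace(b$times, b$envelope)),
         params = spec@params)
  })
}

#' Write a synthetic Doppler acquisition as a DICOM file
#'
#' Renders the spec (one frame per beat when \code{multiframe}, otherwise
#' a single concatenated frame) and writes a standards-conformant
#' ultrasound DICOM whose spectral-Doppler region calibration encodes the
#' spec geometry; [readDopplerDicom()] reads it back identically.
#'
#' @param spec a [SyntheticSpec-class].
#' @param path output file path.
#' @param multiframe write one frame per beat instead of one wide frame.
#' @param withCalibration set FALSE to omit the physical-delta attributes
#'   (an error-path fixture).
#' @return invisibly, the ground truth as returned by [synthCine()].
#' @export
synthDicom <- function(spec, path, multiframe = FALSE, withCalibration = TRUE) {
  cine <- synthCine(spec)
  frames <- if (multiframe) {
    bounds <- c(cine$boundaries, ncol(cine$strip@pixels) + 1L)
    lapply(seq_along(cine$params), function(i)
      cine$strip@pixels[, bounds[i]:(bounds[i + 1] - 1L), drop = FALSE])
  } else list(cine$strip@pixels)
  writeDopplerDicom(frames, path, dtPerCol = spec@dtPerCol,
                    dvPerRow = spec@dvPerRow, baselineRow = spec@baselineRow,
                    heartRate = 60 / spec@cycleLength,
                    withCalibration = withCalibration)
  invisible(cine)
}
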