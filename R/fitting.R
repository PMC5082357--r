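# Nonlinear least-squares estimation of the model constants from a
# detected trace, and the semi-automatic multi-beat loop.
#
# Bounds (c >= 0, k > 0, x0 > 0) are enforced by optimizing over
# unconstrained coordinates (softplus for c, log for k and x0) so the
# Levenberg-Marquardt residual stays smooth at the boundary.

.softplus <- function(a) ifelse(a > 30, a, log1p(exp(a)))
.softplusInv <- function(c.) {
  if (c. <= 0) return(-12)           # c = 0 maps to a tiny positive damping
  if (c. > 30) return(c.)
  log(expm1(c.))
}

.thetaToParams <- function(theta) {
  pdfParameters(c = .softplus(theta[1]), k = exp(theta[2]), x0 = exp(theta[3]))
}

# fallback LM start when the empirical triad is unusable (mid-range of
# typical adult values)
.defaultInit <- pdfParameters(c = 15, k = 170, x0 = 11)

# empirical triad of a trace: peak sample, onset and last accepted sample
.empiricalInit <- function(t, v) {
  ipk <- which.max(v)
  at <- t[ipk]
  dt <- t[length(t)] - t[ipk]
  if (at <= 0) at <- (t[2] - t[1]) / 2
  if (at > dt || dt <= 0 || max(v) <= 0) return(.defaultInit)
  paramsFromTriad(triad(at = at, dt = dt, vmax = max(v)))
}

#' Fit the kinematic model to a detected trace
#'
#' Levenberg-Marquardt least squares of the model speed against the
#' accepted samples of a trace, minimizing
#' \eqn{\sum_i (v(p, t_i) - v_i)^2} with the parameter bounds c >= 0,
#' k > 0, x0 > 0.  Times are re-referenced so the first accepted sample
#' is the onset (t = 0).  When no starting value is given the optimizer
#' is initialized from the closed-form triad inversion of the trace's
#' empirical acceleration time, deceleration time and peak velocity,
#' falling back to mid-range adult values when the empirical triad is
#' non-physical.
#'
#' No goodness-of-fit verdict is attached: the residual norm is recorded
#' for diagnostics only, and the convergence flag reflects the optimizer
#' status.
#'
#' @param trace a [VelocityTrace-class] with >= 5 accepted samples.
#' @param init optional [PDFParameters-class] starting value.
#' @return an [EwaveFit-class].
#' @examples
#' tr <- synthTrace(pdfParameters(17.3, 135, 11.4), dt = 0.004)
#' fitParams(fitPDF(tr))
#' @export
fitPDF <- function(trace, init = NULL) {
  stopifnot(is(trace, "VelocityTrace"))
  acc <- trace@accepted & is.finite(trace@velocities)
  if (sum(acc) < 5)
    stop("fitPDF needs at least 5 accepted samples")
  t <- trace@times[acc] - .onsetTime(trace)
  v <- trace@velocities[acc]
  p0 <- if (is.null(init)) .empiricalInit(t, v) else init
  theta0 <- c(.softplusInv(p0@c), log(p0@k), log(p0@x0))
  resFn <- function(theta) modelVelocity(.thetaToParams(theta), t) - v
  out <- tryCatch(
    minpack.lm::nls.lm(theta0, fn = resFn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(out)) {
    params <- p0
    converged <- FALSE
    rn <- sqrt(sum(resFn(theta0)^2))
  } else {
    params <- .thetaToParams(out$par)
    converged <- out$info %in% 1:4
    rn <- sqrt(sum(out$fvec^2))
  }
  new("EwaveFit", params = params, indices = derivedIndices(params),
      trace = trace, method = "full-fit", residualNorm = rn,
      converged = converged)
}

# prefix errors with the pipeline stage that raised them
.atStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Detect and fit one strip, with the shortening procedures
#'
#' The full single-beat pipeline: envelope detection, optional zero-tail,
#' a first model fit, and (optionally) tangent shortening followed by a
#' refit.  The two shortening flags are honored independently from the
#' settings; with both off the result is identical to
#' \code{fitPDF(detectEnvelope(strip, settings))}.  Errors carry the
#' stage that raised them.
#'
#' @param strip a [DopplerStrip-class].
#' @param settings a [DetectionSettings-class]; the \code{zeroTail} and
#'   \code{tangentShorten} flags select the shortening procedures.
#' @return an [EwaveFit-class] (from the refit when tangent shortening is
#'   enabled).
#' @export
fitWithShortening <- function(strip, settings = detectionSettings()) {
  trace <- .atStage("detect", detectEnvelope(strip, settings))
  if (settings@zeroTail)
    trace <- .atStage("zero-tail", zeroTail(trace))
  fit <- .atStage("fit", fitPDF(trace))
  if (settings@tangentShorten) {
    short <- .atStage("tangent", tangentShorten(trace, fit@params))
    fit <- .atStage("refit", fitPDF(short, init = fit@params))
  }
  fit
}

#' Build a start-of-E-wave template
#'
#' Stores the image patch around the onset column of a fitted E-wave
#' (full strip height, \code{halfWidthS} seconds to each side) for
#' matching the onset on subsequent beats by normalized cross
#' correlation.  A patch reaching past the strip edge is clipped and
#' flagged.
#'
#' @param strip the oriented [DopplerStrip-class] the fit was produced on.
#' @param fit the seed [EwaveFit-class] (its trace supplies the onset).
#' @param halfWidthS template half-width in seconds.
#' @return a [StartTemplate-class].
#' @export
buildStartTemplate <- function(strip, fit, halfWidthS = 0.03) {
  stopifnot(is(strip, "DopplerStrip"), is(fit, "EwaveFit"))
  strip <- orientStrip(strip)
  acc <- which(fit@trace@accepted)
  if (!length(acc)) stop("seed fit has no accepted samples")
  onsetT <- fit@trace@times[acc[1]]
  onsetCol <- max(1L, min(ncol(strip@pixels),
                          as.integer(ceiling(onsetT / strip@dtPerCol))))
  hw <- max(1L, as.integer(round(halfWidthS / strip@dtPerCol)))
  lo <- onsetCol - hw
  hi <- onsetCol + hw
  clipped <- lo < 1L || hi > ncol(strip@pixels)
  lo <- max(1L, lo); hi <- min(ncol(strip@pixels), hi)
  new("StartTemplate", patch = strip@pixels[, lo:hi, drop = FALSE],
      onsetOffset = onsetCol - lo, dtPerCol = strip@dtPerCol,
      clipped = clipped)
}

#' Locate the E-wave onset by normalized cross correlation
#'
#' Slides the start template across the strip and returns the onset time
#' at the correlation maximum.  A peak correlation below \code{floor}
#' means the beat cannot be matched and raises a no-match error (the
#' multi-beat loop turns this into a discarded beat).
#'
#' @param template a [StartTemplate-class].
#' @param strip a [DopplerStrip-class] with the same pixel height.
#' @param floor minimum acceptable peak correlation.
#' @return list with \code{onset} (s), \code{correlation} and
#'   \code{column}.
#' @export
locateStart <- function(template, strip, floor = 0.6) {
  stopifnot(is(template, "StartTemplate"), is(strip, "DopplerStrip"))
  strip <- orientStrip(strip)
  if (nrow(template@patch) != nrow(strip@pixels))
    stop("template and strip heights differ")
  w <- ncol(template@patch)
  if (w > ncol(strip@pixels)) stop("template is wider than the strip")
  tv <- as.vector(template@patch)
  nPos <- ncol(strip@pixels) - w + 1L
  ncc <- vapply(seq_len(nPos), function(j) {
    win <- as.vector(strip@pixels[, j:(j + w - 1L)])
    if (stats::sd(win) == 0 || stats::sd(tv) == 0) return(-Inf)
    stats::cor(tv, win)
  }, 0)
  best <- which.max(ncc)
  if (!is.finite(ncc[best]) || ncc[best] < floor)
    stop(sprintf("no template match: peak correlation %.3f below floor %.2f",
                 max(ncc[is.finite(ncc)], -1), floor))
  onsetCol <- best + template@onsetOffset
  list(onset = (onsetCol - 0.5) * strip@dtPerCol,
       correlation = ncc[best], column = onsetCol)
}

#' Semi-automatic fitting of a beat sequence
#'
#' Propagates a user-accepted seed fit across subsequent beats: the onset
#' of each beat is located with the start template by normalized cross
#' correlation; detection runs from the onset to the earlier of 1/3 of a
#' cardiac cycle and the time where velocity has fallen below 35\% of
#' that beat's peak; the trace is fitted through the same shortening
#' pipeline as the seed; and the fit is kept only if each of c, k and x0
#' deviates by no more than 40\% (relative) from the mean over all
#' previously accepted beats, seed included.  Beats failing template
#' matching, fitting, or the deviation test are discarded with a reason;
#' every beat lands in exactly one of the two partitions.
#'
#' The cycle length for the 1/3-cycle stop comes from (in order)
#' \code{options$cycleLength}, the strip's heart-rate metadata, or the
#' strip's own temporal extent.
#'
#' @param beats list of [DopplerStrip-class]; the first is the seed beat.
#' @param seedFit the user-accepted [EwaveFit-class] of the first beat.
#' @param options list: \code{nccFloor} (0.6), \code{discardFrac} (0.40),
#'   \code{stopFrac} (0.35), \code{cycleFrac} (1/3), \code{cycleLength}
#'   (s, optional), \code{halfWidthS} (0.03).
#' @return an [AutoFitReport-class] whose \code{fits} include the seed.
#' @export
autofitSequence <- function(beats, seedFit, options = list()) {
  stopifnot(length(beats) >= 1, is(seedFit, "EwaveFit"),
            all(vapply(beats, is, TRUE, "DopplerStrip")))
  o <- utils::modifyList(list(nccFloor = 0.6, discardFrac = 0.40,
                              stopFrac = 0.35, cycleFrac = 1 / 3,
                              cycleLength = NULL, halfWidthS = 0.03),
                         options)
  tpl <- buildStartTemplate(beats[[1]], seedFit, o$halfWidthS)
  fits <- list(seedFit)
  disc <- data.frame(beat = integer(), reason = character())
  pvec <- function(f) c(f@params@c, f@params@k, f@params@x0)
  running <- matrix(pvec(seedFit), nrow = 1)
  base <- seedFit@trace@settings
  for (i in seq_along(beats)[-1]) {
    strip <- beats[[i]]
    cyc <- if (!is.null(o$cycleLength)) o$cycleLength
           else if (!is.na(strip@heartRate)) 60 / strip@heartRate
           else ncol(strip@pixels) * strip@dtPerCol
    loc <- tryCatch(locateStart(tpl, strip, o$nccFloor), error = identity)
    if (inherits(loc, "error")) {
      disc <- rbind(disc, data.frame(beat = i, reason = "no-template-match"))
      next
    }
    fit <- tryCatch({
      st <- detectionSettings(loc$onset, loc$onset + cyc * o$cycleFrac,
                              base@threshold, base@maxJump,
                              base@zeroTail, base@tangentShorten)
      trace <- detectEnvelope(strip, st)
      trace <- .truncateAtStopFraction(trace, o$stopFrac)
      if (st@zeroTail) trace <- zeroTail(trace)
      f <- fitPDF(trace)
      if (st@tangentShorten)
        f <- fitPDF(tangentShorten(trace, f@params), init = f@params)
      if (!f@converged) stop("optimizer did not converge")
      f
    }, error = identity)
    if (inherits(fit, "error")) {
      disc <- rbind(disc, data.frame(beat = i, reason = "fit-failure"))
      next
    }
    means <- colMeans(running)
    dev <- abs(pvec(fit) - means) / means
    if (any(dev > o$discardFrac)) {
      disc <- rbind(disc, data.frame(beat = i, reason = "parameter-deviation"))
      next
    }
    fits <- c(fits, list(fit))
    running <- rbind(running, pvec(fit))
  }
  new("AutoFitReport", fits = fits, discarded = disc,
      templateMeta = list(widthCols = ncol(tpl@patch),
                          onsetOffset = tpl@onsetOffset,
                          clipped = tpl@clipped))
}

# drop samples after velocity has fallen below stopFrac * peak
.truncateAtStopFraction <- function(trace, stopFrac) {
  acc <- which(trace@accepted)
  if (length(acc) < 3) return(trace)
  va <- trace@velocities[acc]
  ipk <- which.max(va)
  after <- acc[-seq_len(ipk)]
  low <- after[trace@velocities[after] < stopFrac * va[ipk]][1]
  if (is.na(low)) return(trace)
  keep <- seq_len(length(trace@times)) <= low
  velocityTrace(trace@times[keep], trace@velocities[keep],
                trace@accepted[keep], trace@settings)
}
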