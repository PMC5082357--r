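# The kinematic (PDF) model of early diastolic filling.
#
# Transmitral flow velocity during the E-wave is modeled as the recoil of
# a damped loaded spring: m*x'' + c*x' + k*x = 0 with m = 1 g, x(0) = x0,
# x'(0) = 0.  Measured Doppler velocity is reported as a speed, so all
# model velocities here are magnitudes.

# discriminant k - c^2/4; >0 underdamped, ~0 critical, <0 overdamped
.disc <- function(params) params@k - params@c^2 / 4
.isCritical <- function(params, tol = 1e-9) {
  abs(.disc(params)) <= tol * max(1, params@k)
}

#' Model velocity of the E-wave
#'
#' Evaluates the speed of transmitral flow predicted by the damped-spring
#' model at time \code{t} after the onset of flow.  In the underdamped
#' regime (\code{c^2 < 4k}) the wave terminates at its first zero
#' crossing, t = pi/omega with omega = sqrt(k - c^2/4), and the model
#' speed is zero beyond it; critically damped and overdamped waves decay
#' without a zero crossing.
#'
#' @param params a [PDFParameters-class] object.
#' @param t time(s) since flow onset, s (>= 0); vectorized.
#' @return speed(s) in cm/s; \code{v(0) = 0} and all values are >= 0.
#' @examples
#' p <- pdfParameters(c = 17.3, k = 135, x0 = 11.4)
#' modelVelocity(p, 0.0942)  # near the peak, about 58.6 cm/s
#' @export
modelVelocity <- function(params, t) {
  stopifnot(is(params, "PDFParameters"))
  validObject(params)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  c. <- params@c; k <- params@k; x0 <- params@x0
  disc <- .disc(params)
  if (.isCritical(params)) {
    v <- k * x0 * t * exp(-c. * t / 2)
  } else if (disc > 0) {
    w <- sqrt(disc)
    v <- (k * x0 / w) * exp(-c. * t / 2) * sin(w * t)
    v[t >= pi / w] <- 0
  } else {
    b <- sqrt(-disc)
    v <- (k * x0 / b) * exp(-c. * t / 2) * sinh(b * t)
  }
  pmax(v, 0)
}

# time derivative of the signed model velocity (internal; underdamped /
# critical / overdamped closed forms)
.modelAccel <- function(params, t) {
  c. <- params@c; k <- params@k; x0 <- params@x0
  disc <- .disc(params)
  if (.isCritical(params)) {
    k * x0 * exp(-c. * t / 2) * (1 - c. * t / 2)
  } else if (disc > 0) {
    w <- sqrt(disc)
    (k * x0 / w) * exp(-c. * t / 2) * (w * cos(w * t) - (c. / 2) * sin(w * t))
  } else {
    b <- sqrt(-disc)
    (k * x0 / b) * exp(-c. * t / 2) * (b * cosh(b * t) - (c. / 2) * sinh(b * t))
  }
}

#' Peak of the model E-wave
#'
#' Closed-form time-to-peak and peak velocity: underdamped
#' t_peak = atan(2*omega/c)/omega (reducing to pi/(2*sqrt(k)) at c = 0),
#' critically damped t_peak = 2/c, overdamped t_peak = artanh(2*beta/c)/beta
#' with beta = sqrt(c^2/4 - k).
#'
#' @inheritParams modelVelocity
#' @return named numeric vector \code{c(tPeak = s, vmax = cm/s)}.
#' @examples
#' peakCharacteristics(pdfParameters(0, 100, 10))  # c(pi/20, 100)
#' @export
peakCharacteristics <- function(params) {
  stopifnot(is(params, "PDFParameters"))
  validObject(params)
  disc <- .disc(params)
  tPeak <- if (.isCritical(params)) {
    2 / params@c
  } else if (disc > 0) {
    w <- sqrt(disc)
    atan2(2 * w, params@c) / w
  } else {
    b <- sqrt(-disc)
    atanh(2 * b / params@c) / b
  }
  c(tPeak = tPeak, vmax = modelVelocity(params, tPeak))
}

#' Duration of the model E-wave
#'
#' Underdamped waves end at their first velocity zero, pi/omega.
#' Critically damped and overdamped waves never return to zero; their
#' duration is defined as the time at which speed has decayed to a small
#' fraction of the peak (default 1\%), which keeps the deceleration time
#' and the velocity-time integral finite.
#'
#' @inheritParams modelVelocity
#' @param decayFraction terminus threshold for the non-oscillatory
#'   regimes, as a fraction of peak velocity.
#' @return duration in s.
#' @export
ewaveDuration <- function(params, decayFraction = 0.01) {
  stopifnot(is(params, "PDFParameters"))
  validObject(params)
  disc <- .disc(params)
  if (!.isCritical(params) && disc > 0) return(pi / sqrt(disc))
  pk <- peakCharacteristics(params)
  target <- decayFraction * pk[["vmax"]]
  hi <- 2 * pk[["tPeak"]]
  while (modelVelocity(params, hi) > target) hi <- hi * 2
  stats::uniroot(function(t) modelVelocity(params, t) - target,
                 c(pk[["tPeak"]], hi), tol = 1e-12)$root
}

#' Velocity-time integral of the model E-wave
#'
#' Area under the speed curve over the E-wave duration, in cm.  For
#' underdamped waves the closed form \code{x0 * (1 + exp(-c*pi/(2*omega)))}
#' is used; otherwise adaptive quadrature over [0, duration].
#'
#' @inheritParams ewaveDuration
#' @return VTI in cm.
#' @examples
#' velocityTimeIntegral(pdfParameters(0, 100, 10))  # 2 * x0 = 20 cm
#' @export
velocityTimeIntegral <- function(params, decayFraction = 0.01) {
  stopifnot(is(params, "PDFParameters"))
  validObject(params)
  disc <- .disc(params)
  if (!.isCritical(params) && disc > 0) {
    w <- sqrt(disc)
    return(params@x0 * (1 + exp(-params@c * pi / (2 * w))))
  }
  dur <- ewaveDuration(params, decayFraction)
  stats::integrate(function(t) modelVelocity(params, t), 0, dur,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Relaxation time constant estimated from the model constants
#'
#' Approximates the time constant of isovolumic pressure decay, tau, from
#' the damping-to-stiffness ratio of the fitted spring: tau = c/k
#' (the relaxation time of a viscoelastic element with damping c and
#' stiffness k), reported in ms.  It increases with impaired relaxation
#' (larger c), decreases with a stiffer chamber, and is independent of
#' load.  An undamped wave (c = 0) carries no relaxation information and
#' yields a flagged missing value.
#'
#' @inheritParams modelVelocity
#' @return tau in ms, or NA (with attribute \code{reason}) when c = 0.
#' @export
tauEstimate <- function(params) {
  stopifnot(is(params, "PDFParameters"))
  validObject(params)
  if (params@c <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "tau is undefined for an undamped wave (c = 0)"
    return(out)
  }
  1000 * params@c / params@k
}

#' All derived indices of one fitted E-wave
#'
#' Computes, from the three model constants, every derived physiological
#' index: peak velocity, acceleration and deceleration times, duration,
#' VTI, peak driving force k*x0, peak resistive force c*Vmax, filling
#' energy k*x0^2/2, damping index c^2 - 4k, kinematic filling efficiency
#' index (KFEI), and the tau approximation.  Forces are converted from
#' dyn to mN (1 dyn = 0.01 mN) and energy from erg to mJ (1 erg = 1e-4 mJ).
#'
#' KFEI is the ratio of the wave's VTI to the VTI of an ideal undamped
#' wave (c = 0) with the same k and x0, whose VTI is 2*x0; it depends on
#' (c, k) only.
#'
#' @inheritParams ewaveDuration
#' @return named numeric vector with elements \code{vmax} (cm/s),
#'   \code{vmax_ms} (m/s), \code{at} (s), \code{edec} (ms), \code{duration}
#'   (s), \code{vti} (cm), \code{kx0} (mN), \code{cvmax} (mN),
#'   \code{energy} (mJ), \code{beta} (g^2/s^2), \code{kfei} (%),
#'   \code{tau} (ms).
#' @examples
#' derivedIndices(pdfParameters(17.3, 135, 11.4))
#' @export
derivedIndices <- function(params, decayFraction = 0.01) {
  pk <- peakCharacteristics(params)
  dur <- ewaveDuration(params, decayFraction)
  vti <- velocityTimeIntegral(params, decayFraction)
  c(vmax = pk[["vmax"]],
    vmax_ms = pk[["vmax"]] / 100,
    at = pk[["tPeak"]],
    edec = 1000 * (dur - pk[["tPeak"]]),
    duration = dur,
    vti = vti,
    kx0 = params@k * params@x0 * 0.01,
    cvmax = params@c * pk[["vmax"]] * 0.01,
    energy = 0.5 * params@k * params@x0^2 * 1e-4,
    beta = params@c^2 - 4 * params@k,
    kfei = 100 * vti / (2 * params@x0),
    tau = as.numeric(tauEstimate(params)))
}

#' Triad of a model E-wave
#'
#' The acceleration time, deceleration time and peak velocity implied by
#' a set of model constants.  On the underdamped domain this map is a
#' bijection; [paramsFromTriad()] is its exact inverse.
#'
#' @inheritParams ewaveDuration
#' @return a [Triad-class].
#' @export
triadFromParams <- function(params, decayFraction = 0.01) {
  pk <- peakCharacteristics(params)
  dur <- ewaveDuration(params, decayFraction)
  triad(at = pk[["tPeak"]], dt = dur - pk[["tPeak"]], vmax = pk[["vmax"]])
}

#' Model constants from a triad
#'
#' Closed-form inversion of the triad parameterization, valid on the
#' underdamped (including undamped) domain:
#' omega = pi/(at + dt), c = 2*omega/tan(omega*at), k = omega^2 + c^2/4,
#' x0 = vmax*omega / (k * exp(-c*at/2) * sin(omega*at)).  Equal
#' acceleration and deceleration times give the undamped wave c = 0.  A
#' triad with at > dt would require negative damping and is rejected.
#'
#' @param tri a [Triad-class].
#' @return a [PDFParameters-class].
#' @examples
#' paramsFromTriad(triad(pi / 20, pi / 20, 100))  # c=0, k=100, x0=10
#' @export
paramsFromTriad <- function(tri) {
  stopifnot(is(tri, "Triad"))
  validObject(tri)
  at <- tri@at; dt <- tri@dt
  if (at > dt)
    stop("non-physical triad: acceleration time exceeds deceleration time")
  w <- pi / (at + dt)
  cc <- if (abs(at - dt) < 1e-12 * (at + dt)) 0 else 2 * w / tan(w * at)
  k <- w^2 + cc^2 / 4
  x0 <- tri@vmax * w / (k * exp(-cc * at / 2) * sin(w * at))
  pdfParameters(c = cc, k = k, x0 = x0)
}

#' Load-independent index of diastolic filling
#'
#' Ordinary least-squares regression of peak driving force k*x0 on peak
#' resistive force c*Vmax over beats acquired under varying loading
#' conditions.  The slope M (ratio of change in driving to change in
#' resistive force) is load independent; the intercept B is in mN.
#'
#' @param fits a list of [EwaveFit-class] objects (>= 2 beats), or a
#'   data.frame with columns \code{cvmax} and \code{kx0} in mN.
#' @return a [LoadIndependentIndex-class].
#' @examples
#' loadIndependence(data.frame(cvmax = c(12, 15, 18), kx0 = c(20, 25, 30)))
#' @export
loadIndependence <- function(fits) {
  pairs <- if (is.data.frame(fits)) {
    stopifnot(all(c("cvmax", "kx0") %in% names(fits)))
    fits[c("cvmax", "kx0")]
  } else {
    stopifnot(all(vapply(fits, is, TRUE, "EwaveFit")))
    data.frame(cvmax = vapply(fits, function(f) f@indices[["cvmax"]], 0),
               kx0 = vapply(fits, function(f) f@indices[["kx0"]], 0))
  }
  if (nrow(pairs) < 2)
    stop("load independence requires at least 2 beats")
  if (stats::var(pairs$cvmax) == 0)
    stop("load independence requires variation in peak resistive force")
  co <- stats::coef(stats::lm(kx0 ~ cvmax, data = pairs))
  new("LoadIndependentIndex", m = unname(co[2]), b = unname(co[1]),
      nBeats = nrow(pairs), forcePairs = pairs)
}
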