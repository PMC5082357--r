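# The kinematic model: closed forms against independent numerics, and
# the algebraic identities the model guarantees.

test_that("model velocity matches the analytic undamped case and the worked example", {
  und <- pdfParameters(0, 100, 10)
  # undamped: v = x0*sqrt(k)*sin(sqrt(k)*t), peak x0*sqrt(k) at pi/(2*sqrt(k))
  expect_equal(modelVelocity(und, pi / 20), 100)
  expect_equal(modelVelocity(und, 0), 0)
  # worked example: frozen value from ODE integration of the oscillator
  expect_equal(modelVelocity(refWaveA(), 0.0942), 58.6205, tolerance = 1e-5)
  # v(0) = 0 in every regime
  for (p in list(refWaveA(), pdfParameters(20, 100, 10), pdfParameters(30, 100, 10)))
    expect_identical(modelVelocity(p, 0), 0)
  expect_error(modelVelocity(refWaveA(), -0.1), "t must be")
  expect_error(pdfParameters(-1, 100, 10), "c must be")
  expect_error(pdfParameters(5, -1, 10), "k must be")
})

test_that("peak characteristics agree with numeric maximization", {
  for (p in list(pdfParameters(0, 100, 10), refWaveA(), refWaveB(),
                 pdfParameters(20, 100, 10), pdfParameters(30, 100, 10))) {
    pk <- peakCharacteristics(p)
    hi <- if (regime(p) == "underdamped") pi / sqrt(stiffness(p) - viscoelasticity(p)^2 / 4)
          else 4 * pk[["tPeak"]]
    opt <- optimize(function(t) modelVelocity(p, t), c(0, hi),
                    maximum = TRUE, tol = 1e-10)
    expect_equal(pk[["tPeak"]], opt$maximum, tolerance = 1e-4)
    expect_equal(pk[["vmax"]], opt$objective, tolerance = 1e-6)
    expect_equal(modelVelocity(p, pk[["tPeak"]]), pk[["vmax"]])
    # non-decreasing on [0, tPeak]
    g <- modelVelocity(p, seq(0, pk[["tPeak"]], length.out = 100))
    expect_true(all(diff(g) >= -1e-9))
  }
  expect_equal(unname(peakCharacteristics(pdfParameters(0, 100, 10))),
               c(pi / 20, 100))
  expect_equal(peakCharacteristics(refWaveA())[["tPeak"]], 0.094239,
               tolerance = 1e-4)
  expect_equal(peakCharacteristics(refWaveA())[["vmax"]], 58.6205,
               tolerance = 1e-5)
})

test_that("duration is the first velocity zero (or decay terminus) in every regime", {
  expect_equal(ewaveDuration(pdfParameters(0, 100, 10)), pi / 10)
  expect_equal(ewaveDuration(refWaveA()), pi / sqrt(135 - 17.3^2 / 4))
  # bisection oracle on the underdamped sign change
  p <- refWaveA()
  root <- uniroot(function(t) {
    w <- sqrt(135 - 17.3^2 / 4)
    sin(w * t)                      # zero of the oscillatory factor
  }, c(0.2, 0.5), tol = 1e-12)$root
  expect_equal(ewaveDuration(p), root, tolerance = 1e-9)
  # critical and overdamped: finite, and speed there is 1% of peak
  for (p in list(pdfParameters(20, 100, 10), pdfParameters(28, 100, 10))) {
    dur <- ewaveDuration(p)
    expect_true(is.finite(dur) && dur > 0)
    expect_equal(modelVelocity(p, dur),
                 0.01 * peakCharacteristics(p)[["vmax"]], tolerance = 1e-6)
  }
})

test_that("VTI closed form agrees with adaptive quadrature and decreases with damping", {
  expect_equal(velocityTimeIntegral(pdfParameters(0, 123, 10)), 20)
  expect_equal(velocityTimeIntegral(refWaveA()), 11.74319, tolerance = 1e-6)
  for (p in randomParams(25, seed = 7)) {
    quad <- integrate(function(t) modelVelocity(p, t), 0, ewaveDuration(p),
                      rel.tol = 1e-10)$value
    expect_equal(velocityTimeIntegral(p), quad, tolerance = 1e-6)
  }
  vtis <- sapply(c(0, 5, 10, 20), function(cc)
    velocityTimeIntegral(pdfParameters(cc, 135, 11.4)))
  expect_true(all(diff(vtis) < 0))
})

test_that("derived indices carry the unit conversions and the worked-example values", {
  ix <- derivedIndices(refWaveA())
  expect_equal(ix[["kx0"]], 15.39)            # 135*11.4 dyn -> mN
  expect_equal(ix[["energy"]], 0.87723)       # erg -> mJ
  expect_equal(ix[["beta"]], -240.71)
  expect_equal(ix[["kfei"]], 51.5052, tolerance = 1e-5)
  expect_equal(ix[["cvmax"]], 17.3 * ix[["vmax"]] * 0.01)
  expect_equal(ix[["edec"]], 1000 * (ix[["duration"]] - ix[["at"]]))
  expect_equal(ix[["vmax_ms"]], ix[["vmax"]] / 100)
  # undamped wave: perfectly efficient filling, no resistive force
  ix0 <- derivedIndices(pdfParameters(0, 150, 9))
  expect_equal(ix0[["kfei"]], 100)
  expect_equal(ix0[["cvmax"]], 0)
  # cohort-median (c, k) give a KFEI close to the reported cohort median
  expect_equal(derivedIndices(pdfParameters(17.4, 177.4, 11.7))[["kfei"]],
               53.3, tolerance = 0.01)
})

test_that("KFEI depends on (c, k) only and matches its closed form", {
  for (p in randomParams(20, seed = 3)) {
    w <- sqrt(stiffness(p) - viscoelasticity(p)^2 / 4)
    closed <- 100 * (1 + exp(-viscoelasticity(p) * pi / (2 * w))) / 2
    expect_equal(derivedIndices(p)[["kfei"]], closed, tolerance = 1e-9)
    # x0 invariance
    p2 <- pdfParameters(viscoelasticity(p), stiffness(p), 2.5 * initialLoad(p))
    expect_equal(derivedIndices(p2)[["kfei"]], closed, tolerance = 1e-9)
  }
})

test_that("tau estimate is positive, rises with damping, and ignores load", {
  expect_gt(tauEstimate(pdfParameters(25, 177, 10)),
            tauEstimate(pdfParameters(10, 177, 10)))
  expect_equal(tauEstimate(pdfParameters(17, 200, 8)),
               tauEstimate(pdfParameters(17, 200, 16)))
  # interquartile-box parameter combinations give plausible values
  for (cc in c(15.5, 20.4)) for (k in c(153.9, 206.9)) {
    tau <- tauEstimate(pdfParameters(cc, k, 11.7))
    expect_true(tau > 40 && tau < 160)
  }
  und <- tauEstimate(pdfParameters(0, 150, 10))
  expect_true(is.na(und))
  expect_match(attr(und, "reason"), "undefined")
})

test_that("triad extraction and inversion are exact inverses on the underdamped domain", {
  tr <- triadFromParams(pdfParameters(0, 100, 10))
  expect_equal(tr@at, pi / 20)
  expect_equal(tr@dt, pi / 20)
  expect_equal(tr@vmax, 100)
  p0 <- paramsFromTriad(triad(pi / 20, pi / 20, 100))
  expect_equal(viscoelasticity(p0), 0)
  expect_equal(stiffness(p0), 100)
  expect_equal(initialLoad(p0), 10)
  tr2 <- triadFromParams(refWaveA())
  expect_equal(tr2@at, 0.09424, tolerance = 1e-4)
  expect_equal(tr2@dt, 0.31074, tolerance = 1e-4)
  for (p in randomParams(200, seed = 11)) {
    back <- paramsFromTriad(triadFromParams(p))
    expect_equal(viscoelasticity(back), viscoelasticity(p), tolerance = 1e-6)
    expect_equal(stiffness(back), stiffness(p), tolerance = 1e-6)
    expect_equal(initialLoad(back), initialLoad(p), tolerance = 1e-6)
  }
  expect_error(paramsFromTriad(triad(0.2, 0.1, 60)), "non-physical")
  expect_error(triad(-0.1, 0.2, 60), "at must be")
})

test_that("velocity is continuous across the damping-regime boundary", {
  k <- 100; x0 <- 10
  tg <- seq(0, 0.35, length.out = 60)
  for (eps in c(1e-4, 1e-6, 1e-8)) {
    vU <- modelVelocity(pdfParameters(sqrt(4 * k - eps), k, x0), tg)
    vO <- modelVelocity(pdfParameters(sqrt(4 * k + eps), k, x0), tg)
    expect_lt(max(abs(vU - vO)), 10 * sqrt(eps))
  }
  # exactly critical evaluates finitely
  expect_true(all(is.finite(modelVelocity(pdfParameters(20, 100, 10), tg))))
})

test_that("scaling the load scales amplitudes linearly and energy quadratically", {
  p <- refWaveA(); s <- 1.7
  ps <- pdfParameters(viscoelasticity(p), stiffness(p), s * initialLoad(p))
  a <- derivedIndices(p); b <- derivedIndices(ps)
  for (f in c("vmax", "vti", "kx0", "cvmax")) expect_equal(b[[f]], s * a[[f]])
  expect_equal(b[["energy"]], s^2 * a[["energy"]])
  for (f in c("at", "edec", "kfei", "beta", "tau")) expect_equal(b[[f]], a[[f]])
})

test_that("load independence recovers exact collinear force pairs and rejects degenerate input", {
  li <- loadIndependence(data.frame(cvmax = c(12, 15, 18), kx0 = c(20, 25, 30)))
  expect_equal(li@m, 5 / 3)
  expect_equal(li@b, 0)
  expect_identical(li@nBeats, 3L)
  # duplicating an on-line point changes nothing
  li2 <- loadIndependence(data.frame(cvmax = c(12, 15, 18, 15),
                                     kx0 = c(20, 25, 30, 25)))
  expect_equal(li2@m, li@m)
  expect_equal(li2@b, li@b)
  expect_error(loadIndependence(data.frame(cvmax = 12, kx0 = 20)), "at least 2")
  expect_error(loadIndependence(data.frame(cvmax = c(12, 12), kx0 = c(20, 21))),
               "variation")
})
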