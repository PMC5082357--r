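# Levenberg-Marquardt parameter recovery, the shortening pipeline, and
# the semi-automatic multi-beat loop.

test_that("noise-free traces are recovered essentially exactly", {
  for (truth in list(refWaveA(), refWaveB())) {
    f <- fitPDF(synthTrace(truth, dt = 0.001))
    expect_lt(paramErrPct(f, truth), 0.5)
    expect_true(hasConverged(f))
    expect_lt(residualNorm(f), 1e-6 * fitIndices(f)[["vmax"]])
  }
  # undamped boundary: the damping estimate collapses onto c = 0
  und <- pdfParameters(0, 100, 10)
  fu <- fitPDF(synthTrace(und, dt = 0.001))
  expect_lte(viscoelasticity(fitParams(fu)), 0.1)
  expect_lt(relErr(stiffness(fitParams(fu)), 100), 0.005)
  expect_error(fitPDF(velocityTrace((1:4) / 100, c(0, 1, 2, 1))), "at least 5")
})

test_that("recovery holds across random underdamped parameter sets", {
  for (truth in randomParams(40, seed = 17)) {
    f <- fitPDF(synthTrace(truth, dt = 0.004))
    expect_lt(paramErrPct(f, truth), 0.5)
  }
})

test_that("the fit is invariant to uniform time shifts of the trace", {
  truth <- refWaveA()
  tr <- synthTrace(truth, dt = 0.004, noiseSd = 1, seed = 2)
  shifted <- velocityTrace(sampleTimes(tr) + 0.35, velocities(tr),
                           acceptedFlags(tr),
                           detectionSettings(tStart = 0.35))
  a <- fitParams(fitPDF(tr))
  b <- fitParams(fitPDF(shifted))
  expect_equal(viscoelasticity(b), viscoelasticity(a), tolerance = 1e-6)
  expect_equal(stiffness(b), stiffness(a), tolerance = 1e-6)
  expect_equal(initialLoad(b), initialLoad(a), tolerance = 1e-6)
})

test_that("noisy fits stay accurate on average (seeded Monte Carlo)", {
  truth <- refWaveA()
  errK <- sapply(1:50, function(i) {
    f <- fitPDF(synthTrace(truth, dt = 0.004, noiseSd = 3, seed = 100 + i))
    relErr(stiffness(fitParams(f)), stiffness(truth))
  })
  expect_lt(mean(errK), 0.05)
})

test_that("the shortening pipeline composes stages and reduces Edec on artifact strips", {
  spec <- syntheticSpec(refWaveA(), seed = 41)
  s <- synthStrip(spec)$strip
  off <- detectionSettings(zeroTail = FALSE, tangentShorten = FALSE)
  # both flags off equals plain detect + fit
  fOff <- fitWithShortening(s, off)
  fRef <- fitPDF(detectEnvelope(s, off))
  expect_equal(fitParams(fOff)@c, fitParams(fRef)@c)
  expect_equal(fitParams(fOff)@k, fitParams(fRef)@k)
  # artifacts during deceleration bias the naive Edec upward; the
  # shortening procedures pull the fitted Edec back toward the truth
  art <- synthStrip(syntheticSpec(refWaveA(), artifactProb = 0.6,
                                  artifactAmp = 30, seed = 43))
  trueEdec <- derivedIndices(refWaveA())[["edec"]]
  eOff <- fitIndices(fitWithShortening(art$strip, off))[["edec"]]
  eOn <- fitIndices(fitWithShortening(art$strip, detectionSettings()))[["edec"]]
  expect_lt(eOn, eOff)
  expect_lt(abs(eOn - trueEdec), abs(eOff - trueEdec))
  # errors carry their stage
  expect_error(fitWithShortening(s, detectionSettings(5, 6)), "\\[detect\\]")
})

test_that("start templates match exactly on the source strip and track translations", {
  spec <- syntheticSpec(refWaveA(), seed = 51)
  s <- synthStrip(spec)$strip
  fit <- fitWithShortening(s, detectionSettings(zeroTail = FALSE,
                                                tangentShorten = FALSE))
  tpl <- buildStartTemplate(s, fit)
  loc <- locateStart(tpl, s)
  expect_equal(loc$correlation, 1, tolerance = 1e-12)
  expect_equal(loc$column, 1L + tpl@onsetOffset)
  # shift the content right by 10 columns
  px <- pixelMatrix(s)
  shifted <- dopplerStrip(cbind(matrix(0L, nrow(px), 10), px),
                          timeStep(s), velocityStep(s), baselineRow(s))
  loc2 <- locateStart(tpl, shifted)
  expect_equal(loc2$onset - loc$onset, 10 * timeStep(s))
  # pure noise never reaches the correlation floor
  noise <- withr::with_seed(99, dopplerStrip(
    matrix(sample(0:255, length(px), replace = TRUE), nrow(px)),
    timeStep(s), velocityStep(s), baselineRow(s)))
  expect_error(locateStart(tpl, noise, floor = 0.6), "no template match")
})

test_that("the multi-beat loop accepts consistent beats and partitions every beat", {
  off <- detectionSettings(zeroTail = FALSE, tangentShorten = FALSE)
  beats <- lapply(1:5, function(i)
    synthStrip(syntheticSpec(refWaveA(), seed = 60 + i))$strip)
  seed <- fitWithShortening(beats[[1]], off)
  rep <- autofitSequence(beats, seed)
  expect_length(acceptedFits(rep), 5)
  expect_identical(nrow(discardedBeats(rep)), 0L)
  expect_identical(length(acceptedFits(rep)) + nrow(discardedBeats(rep)),
                   length(beats))
})

test_that("a 40% parameter deviation from the running mean discards the beat", {
  off <- detectionSettings(zeroTail = FALSE, tangentShorten = FALSE)
  ks <- c(135, 135, 135, 220)   # |220 - 135|/135 = 0.63 > 0.40
  beats <- lapply(seq_along(ks), function(i)
    synthStrip(syntheticSpec(pdfParameters(17.3, ks[i], 11.4),
                             seed = 70 + i))$strip)
  rep <- autofitSequence(beats, fitWithShortening(beats[[1]], off))
  expect_length(acceptedFits(rep), 3)
  expect_equal(discardedBeats(rep)$beat, 4)
  expect_equal(discardedBeats(rep)$reason, "parameter-deviation")
  expect_identical(length(acceptedFits(rep)) + nrow(discardedBeats(rep)),
                   length(beats))
})

test_that("a smooth load drift stays within the deviation rule and tracks the running mean", {
  off <- detectionSettings(zeroTail = FALSE, tangentShorten = FALSE)
  beats <- lapply(0:5, function(i)
    synthStrip(syntheticSpec(pdfParameters(17.3, 135, 11.4 * 1.05^i),
                             seed = 80 + i))$strip)
  rep <- autofitSequence(beats, fitWithShortening(beats[[1]], off))
  expect_length(acceptedFits(rep), 6)
  x0s <- sapply(acceptedFits(rep), function(f) initialLoad(fitParams(f)))
  expect_true(all(diff(x0s) > 0))
})

test_that("detection in the loop stops at 1/3 cycle or 35% of peak, whichever is earlier", {
  off <- detectionSettings(zeroTail = FALSE, tangentShorten = FALSE)
  p <- refWaveA()
  t35 <- uniroot(function(t) modelVelocity(p, t) - 0.35 * 58.6205,
                 c(0.1, 0.4))$root
  mkBeats <- function(cycle) lapply(1:2, function(i)
    synthStrip(syntheticSpec(p, cycleLength = cycle, seed = 90 + i))$strip)
  endOfBeat <- function(rep) {
    tr <- fitTrace(acceptedFits(rep)[[2]])
    max(sampleTimes(tr)[acceptedFlags(tr)])
  }
  # short cycle: the 1/3-cycle stop wins (0.2 s < t35)
  b1 <- mkBeats(0.6)
  e1 <- endOfBeat(autofitSequence(b1, fitWithShortening(b1[[1]], off)))
  expect_lt(e1, 0.6 / 3 + 3 * 0.004)
  # long cycle: the 35%-of-peak stop wins
  b2 <- mkBeats(0.9)
  e2 <- endOfBeat(autofitSequence(b2, fitWithShortening(b2[[1]], off)))
  expect_lt(e2, t35 + 3 * 0.004)
  expect_gt(e2, t35 - 3 * 0.004)
  expect_lt(e2, 0.9 / 3)
})
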