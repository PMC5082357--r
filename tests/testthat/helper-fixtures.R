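# Shared fixtures: the two worked-example parameter sets (underdamped,
# physiological), cohort-style parameter ranges for random draws, and a
# tiny hand-built strip whose envelope is known exactly.

refWaveA <- function() pdfParameters(c = 17.3, k = 135, x0 = 11.4)
refWaveB <- function() pdfParameters(c = 17.7, k = 226, x0 = 16.0)

# random underdamped parameter draws inside cohort-style ranges
randomParams <- function(n, seed = 1) {
  withr::with_seed(seed, {
    out <- vector("list", n)
    i <- 0
    while (i < n) {
      cc <- runif(1, 10.6, 32.8)
      k <- runif(1, 106.5, 294.8)
      if (cc^2 >= 4 * k * 0.95) next   # keep clearly underdamped
      i <- i + 1
      out[[i]] <- pdfParameters(cc, k, runif(1, 7.7, 17.9))
    }
    out
  })
}

# a 5-column strip whose column-wise first suprathreshold rows encode
# known velocities (dv = 10 cm/s per row, baseline row 21 -> v of row r
# is (21 - r) * 10)
tinyStrip <- function(vels = c(0, 20, 40, 30, 10), bright = 200) {
  px <- matrix(0L, 21, length(vels))
  for (j in seq_along(vels)) {
    r <- 21L - as.integer(vels[j] / 10)
    px[r:21L, j] <- bright
  }
  dopplerStrip(px, dtPerCol = 0.004, dvPerRow = 10, baselineRow = 21L,
               sourceId = "tiny")
}

relErr <- function(est, truth) abs(est - truth) / abs(truth)

paramErrPct <- function(fit, truth) {
  p <- fitParams(fit)
  100 * max(relErr(viscoelasticity(p), viscoelasticity(truth)),
            relErr(stiffness(p), stiffness(truth)),
            relErr(initialLoad(p), initialLoad(truth)))
}

# small synthetic study used by export / session tests
syntheticStudy <- function(nBeats = 3, seed = 42, x0Ramp = 0.1) {
  base <- refWaveA()
  fits <- lapply(seq_len(nBeats), function(i) {
    p <- pdfParameters(viscoelasticity(base), stiffness(base),
                       initialLoad(base) * (1 + x0Ramp * (i - 1)))
    fitPDF(synthTrace(p, dt = 0.004, noiseSd = 0.5, seed = seed + i))
  })
  studyResult("case-demo", fits, provenance = list(origin = "synthetic"))
}
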