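# DICOM round trips, region calibration, cine splitting, export and
# session persistence.  All DICOM files are generated at run time.

test_that("synthetic DICOM files round-trip to an identical calibrated strip", {
  spec <- syntheticSpec(refWaveA(), seed = 3)
  path <- withr::local_tempfile(fileext = ".dcm")
  synthDicom(spec, path)
  rd <- readDopplerDicom(path)
  ref <- synthCine(spec)$strip
  expect_length(rd$strips, 1)
  s <- rd$strips[[1]]
  expect_identical(pixelMatrix(s), pixelMatrix(ref))
  expect_equal(timeStep(s), timeStep(ref))
  expect_equal(velocityStep(s), velocityStep(ref))
  expect_identical(baselineRow(s), baselineRow(ref))
  expect_identical(flowSign(s), 1)
  expect_equal(rd$source@heartRate, 75)
  expect_identical(rd$source@frameCount, 1L)
  # write -> read -> write is stable
  path2 <- withr::local_tempfile(fileext = ".dcm")
  writeDopplerDicom(pixelMatrix(s), path2, timeStep(s), velocityStep(s),
                    baselineRow(s), heartRate = 75)
  s2 <- readDopplerDicom(path2)$strips[[1]]
  expect_identical(pixelMatrix(s2), pixelMatrix(s))
})

test_that("the DICOM writer is readable by an independent DICOM implementation", {
  spec <- syntheticSpec(refWaveA(), seed = 13)
  path <- withr::local_tempfile(fileext = ".dcm")
  synthDicom(spec, path)
  script <- paste(
    "import json, sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "r = d.SequenceOfUltrasoundRegions[0]",
    "print(json.dumps({'rows': int(d.Rows), 'cols': int(d.Columns),",
    " 'dx': float(r.PhysicalDeltaX), 'dy': float(r.PhysicalDeltaY),",
    " 'refY': int(r.ReferencePixelY0), 'dtype': int(r.RegionDataType),",
    " 'px0': int(d.pixel_array[169, 0])}))", sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path)),
            stdout = TRUE, stderr = FALSE))
  info <- jsonlite::fromJSON(out[length(out)])
  expect_equal(info$rows, 170)
  expect_equal(info$cols, 200)
  expect_equal(info$dx, 0.004)
  expect_equal(info$dy, -1)
  expect_equal(info$refY, 159)   # 0-based baseline row
  expect_equal(info$dtype, 3)    # PW spectral Doppler
  expect_equal(info$px0, pixelMatrix(synthCine(spec)$strip)[170, 1])
})

test_that("files without region calibration or Doppler regions fail with named errors", {
  spec <- syntheticSpec(refWaveA(), seed = 4)
  bad <- withr::local_tempfile(fileext = ".dcm")
  synthDicom(spec, bad, withCalibration = FALSE)
  expect_error(readDopplerDicom(bad), "PhysicalDeltaX")
  expect_error(readDopplerDicom(withr::local_tempfile(lines = "plainly not dicom")),
               "not a DICOM file")
})

test_that("multi-frame cines yield one strip per frame", {
  p <- refWaveA()
  spec <- syntheticSpec(list(p, p, p), seed = 5)
  path <- withr::local_tempfile(fileext = ".dcm")
  truth <- synthDicom(spec, path, multiframe = TRUE)
  rd <- readDopplerDicom(path)
  expect_length(rd$strips, 3)
  expect_identical(rd$source@frameCount, 3L)
  wide <- do.call(cbind, lapply(rd$strips, pixelMatrix))
  expect_identical(wide, pixelMatrix(truth$strip))
})

test_that("folders mixing single-frame and cine files are rejected", {
  dir <- withr::local_tempdir()
  p <- refWaveA()
  synthDicom(syntheticSpec(p, seed = 6), file.path(dir, "single.dcm"))
  synthDicom(syntheticSpec(list(p, p), seed = 7), file.path(dir, "cine.dcm"),
             multiframe = TRUE)
  expect_error(readDopplerDicom(dir), "mixes single-frame and cine")
})

test_that("cine splitting finds the generated cycle boundaries", {
  p <- refWaveA()
  cine <- synthCine(syntheticSpec(list(p, p, p), seed = 8))
  # metadata (heart-rate) path
  parts <- splitCine(cine$strip)
  expect_length(parts, 3)
  # autocorrelation path: period within 1%, boundaries within 2 columns
  partsA <- splitCine(cine$strip, method = "autocorrelation")
  expect_length(partsA, 3)
  widths <- sapply(partsA, function(s) dim(s)[2])
  truePeriod <- diff(cine$boundaries)[1]
  expect_lt(abs(widths[1] - truePeriod) / truePeriod, 0.01)
  starts <- as.numeric(sub(".*@([0-9.]+)s$", "\\1",
                           sapply(partsA, function(s) s@sourceId)))
  startCols <- round(starts / timeStep(cine$strip)) + 1
  expect_true(all(abs(startCols - cine$boundaries) <= 2))
  # a strip shorter than one cycle comes back whole
  short <- synthStrip(syntheticSpec(p, seed = 9))$strip
  expect_warning(whole <- splitCine(short), "uncut|periodicity")
  expect_length(whole, 1)
})

test_that("exports contain per-beat rows plus a recomputable summary", {
  study <- syntheticStudy()
  path <- withr::local_tempfile(fileext = ".csv")
  exportResults(study, path, format = "csv")
  d <- utils::read.csv(path)
  expect_identical(nrow(d), 5L)         # 3 beats + mean + sd
  beats <- d[grepl("^beat", d$record), ]
  expect_equal(d$k[d$record == "mean"], mean(beats$k), tolerance = 1e-12)
  expect_equal(d$x0[d$record == "sd"], sd(beats$x0), tolerance = 1e-10)
  expect_equal(d$m[d$record == "mean"], loadIndex(study)@m, tolerance = 1e-12)
  # values survive with at least 12 significant digits
  expect_equal(beats$c, sapply(studyFits(study), function(f) f@params@c),
               tolerance = 1e-12)
  expect_error(exportResults(study, path, format = "xlsx"), "not supported")
})

test_that("the study database appends cases and refuses schema drift", {
  db <- withr::local_tempfile(fileext = ".csv")
  appendStudyDatabase(syntheticStudy(seed = 1), db)
  appendStudyDatabase(syntheticStudy(seed = 2), db)
  d <- utils::read.csv(db)
  expect_identical(nrow(d), 2L)
  expect_true(all(c("mean_k", "sd_k", "m", "b") %in% names(d)))
  # corrupt the header and try again
  lines <- readLines(db)
  writeLines(c(sub("mean_k", "mean_q", lines[1]), lines[-1]), db)
  expect_error(appendStudyDatabase(syntheticStudy(seed = 3), db),
               "header does not match")
})

test_that("anonymized exports carry no case or source identification", {
  study <- syntheticStudy()
  path <- withr::local_tempfile(fileext = ".csv")
  exportResults(study, path, anonymize = TRUE)
  txt <- readLines(path)
  expect_false(any(grepl("case-demo", txt)))
  ses <- withr::local_tempfile(fileext = ".ewk.json")
  saveSession(study, ses, anonymize = TRUE)
  stxt <- paste(readLines(ses), collapse = "")
  expect_false(grepl("case-demo", stxt))
  expect_false(grepl("origin", stxt))
  expect_identical(caseId(loadSession(ses)), "anonymous")
})

test_that("sessions round-trip losslessly and reject tampering", {
  spec <- syntheticSpec(refWaveA(), seed = 30)
  gen <- synthStrip(spec)
  fit <- fitWithShortening(gen$strip, detectionSettings())
  study <- studyResult("case-rt", list(fit), strips = list(gen$strip))
  path <- withr::local_tempfile(fileext = ".ewk.json")
  saveSession(study, path)
  back <- loadSession(path)
  expect_identical(caseId(back), "case-rt")
  expect_equal(pixelMatrix(back@strips[[1]]), pixelMatrix(gen$strip),
               ignore_attr = TRUE)
  f2 <- studyFits(back)[[1]]
  expect_equal(f2@params@c, fit@params@c, tolerance = 1e-14)
  expect_equal(f2@params@k, fit@params@k, tolerance = 1e-14)
  expect_equal(velocities(fitTrace(f2)), velocities(fitTrace(fit)),
               tolerance = 1e-14)
  expect_equal(fitIndices(f2)[["edec"]], fitIndices(fit)[["edec"]],
               tolerance = 1e-14)
  # truncation breaks the parse loudly
  raw <- readLines(path)
  trunc <- withr::local_tempfile()
  writeLines(substr(paste(raw, collapse = ""), 1, 500), trunc)
  expect_error(loadSession(trunc))
  # version gate
  v2 <- sub('"version":"1.0"', '"version":"9.9"', paste(raw, collapse = ""))
  vf <- withr::local_tempfile(lines = v2)
  expect_error(loadSession(vf), "version")
})

test_that("coarse temporal sampling triggers the sweep-speed advisory", {
  spec <- syntheticSpec(refWaveA(), dtPerCol = 0.008, seed = 31)
  path <- withr::local_tempfile(fileext = ".dcm")
  synthDicom(spec, path)
  expect_warning(readDopplerDicom(path), "sweep speed")
})
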