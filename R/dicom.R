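# DICOM input/output for spectral-Doppler ultrasound.
#
# A focused implementation of the Explicit VR Little Endian transfer
# syntax (the syntax this package writes): file meta group, flat
# elements, defined-length sequences, 8-bit single- and multi-frame
# pixel data, and the ultrasound-regions sequence that carries the
# physical time/velocity calibration of the spectral region.

.VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_US_SINGLE <- "1.2.840.10008.5.1.4.1.1.6.1"
.UID_US_MULTI <- "1.2.840.10008.5.1.4.1.1.3.1"
.UID_ROOT <- "1.2.826.0.1.3680043.9.7484"

.leBytes <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                       endian = "little")

.dcmPayload <- function(vr, value) {
  switch(vr,
    US = .leBytes(value, 2L),
    UL = .leBytes(value, 4L),
    SL = .leBytes(value, 4L),
    FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
    OB = as.raw(value),
    OW = as.raw(value),
    SQ = value,          # pre-encoded raw
    {                    # string VRs
      r <- charToRaw(paste(value, collapse = "\\"))
      if (length(r) %% 2L) r <- c(r, if (vr == "UI") as.raw(0L)
                                  else charToRaw(" "))
      r
    })
}

.dcmElement <- function(group, element, vr, value) {
  payload <- .dcmPayload(vr, value)
  head <- c(.leBytes(group, 2L), .leBytes(element, 2L), charToRaw(vr))
  if (vr %in% .VR_LONG)
    c(head, as.raw(c(0L, 0L)), .leBytes(length(payload), 4L), payload)
  else
    c(head, .leBytes(length(payload), 2L), payload)
}

.dcmItem <- function(content) {
  c(.leBytes(0xFFFE, 2L), .leBytes(0xE000, 2L),
    .leBytes(length(content), 4L), content)
}

# one spectral-Doppler ultrasound region item (defined lengths)
.regionItem <- function(nRows, nCols, baselineRow, dtPerCol, dvPerRow,
                        withCalibration = TRUE) {
  content <- c(
    .dcmElement(0x0018, 0x6012, "US", 3L),          # spatial format: spectral
    .dcmElement(0x0018, 0x6014, "US", 3L),          # data type: PW Doppler
    .dcmElement(0x0018, 0x6016, "UL", 0L),          # region flags
    .dcmElement(0x0018, 0x6018, "UL", 0L),          # min x0
    .dcmElement(0x0018, 0x601A, "UL", 0L),          # min y0
    .dcmElement(0x0018, 0x601C, "UL", nCols - 1L),  # max x1
    .dcmElement(0x0018, 0x601E, "UL", nRows - 1L),  # max y1
    .dcmElement(0x0018, 0x6020, "SL", 0L),          # reference pixel x0
    .dcmElement(0x0018, 0x6022, "SL", baselineRow - 1L),
    .dcmElement(0x0018, 0x6024, "US", 4L),          # x units: seconds
    .dcmElement(0x0018, 0x6026, "US", 7L),          # y units: cm/s
    .dcmElement(0x0018, 0x6028, "FD", 0),
    .dcmElement(0x0018, 0x602A, "FD", 0))
  if (withCalibration)
    content <- c(content,
      .dcmElement(0x0018, 0x602C, "FD", dtPerCol),
      .dcmElement(0x0018, 0x602E, "FD", -dvPerRow))  # velocity up = row down
  .dcmItem(content)
}

#' Write a spectral-Doppler ultrasound DICOM file
#'
#' Writes an Explicit VR Little Endian ultrasound DICOM with 8-bit
#' MONOCHROME2 pixel data and a SequenceOfUltrasoundRegions carrying one
#' spectral-Doppler region: x calibration in seconds per pixel, y
#' calibration in (cm/s) per pixel (negative delta: velocity increases
#' upward), and the reference pixel on the zero-velocity baseline.
#'
#' @param frames a pixel matrix (rows x cols, 0-255) or list of equally
#'   sized matrices (frames of a multi-frame cine).
#' @param path output path.
#' @param dtPerCol,dvPerRow,baselineRow calibration, see
#'   [DopplerStrip-class].
#' @param heartRate bpm, written when finite.
#' @param patientName,patientId identification strings.
#' @param withCalibration set FALSE to omit the physical deltas (for
#'   exercising error paths).
#' @return invisibly, \code{path}.
#' @export
writeDopplerDicom <- function(frames, path, dtPerCol, dvPerRow, baselineRow,
                              heartRate = NA_real_,
                              patientName = "SYNTHETIC^PHANTOM",
                              patientId = "SYN000",
                              withCalibration = TRUE) {
  if (is.matrix(frames)) frames <- list(frames)
  nR <- nrow(frames[[1]]); nC <- ncol(frames[[1]])
  stopifnot(all(vapply(frames, function(f)
    nrow(f) == nR && ncol(f) == nC, TRUE)))
  nF <- length(frames)
  sopClass <- if (nF > 1) .UID_US_MULTI else .UID_US_SINGLE
  sopInstance <- paste0(.UID_ROOT, ".",
                        format(as.integer(Sys.time()) %% 1e8), ".",
                        sample.int(1e6, 1))
  # pixel bytes, row-major per frame
  pix <- as.raw(unlist(lapply(frames, function(f)
    as.integer(round(pmax(0, pmin(255, t(f))))))))
  if (length(pix) %% 2L) pix <- c(pix, as.raw(0L))

  region <- .regionItem(nR, nC, as.integer(baselineRow), dtPerCol, dvPerRow,
                        withCalibration)
  ds <- c(
    .dcmElement(0x0008, 0x0016, "UI", sopClass),
    .dcmElement(0x0008, 0x0018, "UI", sopInstance),
    .dcmElement(0x0008, 0x0060, "CS", "US"),
    .dcmElement(0x0008, 0x0070, "LO", "ewavekit synthetic"),
    .dcmElement(0x0010, 0x0010, "PN", patientName),
    .dcmElement(0x0010, 0x0020, "LO", patientId),
    if (is.finite(heartRate))
      .dcmElement(0x0018, 0x1088, "IS", sprintf("%d", as.integer(round(heartRate)))),
    .dcmElement(0x0018, 0x6011, "SQ", region),
    .dcmElement(0x0028, 0x0002, "US", 1L),
    .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    if (nF > 1) .dcmElement(0x0028, 0x0008, "IS", sprintf("%d", nF)),
    .dcmElement(0x0028, 0x0010, "US", nR),
    .dcmElement(0x0028, 0x0011, "US", nC),
    .dcmElement(0x0028, 0x0100, "US", 8L),
    .dcmElement(0x0028, 0x0101, "US", 8L),
    .dcmElement(0x0028, 0x0102, "US", 7L),
    .dcmElement(0x0028, 0x0103, "US", 0L),
    .dcmElement(0x7FE0, 0x0010, "OB", pix))

  metaBody <- c(
    .dcmElement(0x0002, 0x0001, "OB", c(0L, 1L)),
    .dcmElement(0x0002, 0x0002, "UI", sopClass),
    .dcmElement(0x0002, 0x0003, "UI", sopInstance),
    .dcmElement(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcmElement(0x0002, 0x0012, "UI", paste0(.UID_ROOT, ".1")))
  meta <- c(.dcmElement(0x0002, 0x0000, "UL", length(metaBody)), metaBody)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# ---- reading ---------------------------------------------------------

.rdU16 <- function(raw, pos) sum(as.integer(raw[pos:(pos + 1L)]) * c(1, 256))
.rdU32 <- function(raw, pos) sum(as.integer(raw[pos:(pos + 3L)]) *
                                 c(1, 256, 65536, 16777216))
.rdI32 <- function(raw, pos) {
  u <- .rdU32(raw, pos)
  if (u >= 2^31) u - 2^32 else u
}
.rdF64 <- function(raw, pos) readBin(raw[pos:(pos + 7L)], "double",
                                     size = 8L, endian = "little")

.decodeValue <- function(vr, payload) {
  n <- length(payload)
  switch(vr,
    US = vapply(seq(1, n, 2), function(p) .rdU16(payload, p), 0),
    UL = vapply(seq(1, n, 4), function(p) .rdU32(payload, p), 0),
    SL = vapply(seq(1, n, 4), function(p) .rdI32(payload, p), 0),
    FD = vapply(seq(1, n, 8), function(p) .rdF64(payload, p), 0),
    OB = payload, OW = payload,
    IS = as.numeric(trimws(strsplit(rawToChar(payload), "\\", fixed = TRUE)[[1]])),
    DS = as.numeric(trimws(strsplit(rawToChar(payload), "\\", fixed = TRUE)[[1]])),
    trimws(rawToChar(payload[payload != as.raw(0L)])))
}

# parse a defined-length explicit-VR element stream into a named list;
# sequences become lists of item datasets
.parseDataset <- function(raw, pos, end) {
  out <- list()
  while (pos + 7L <= end) {
    group <- .rdU16(raw, pos); element <- .rdU16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .VR_LONG) {
      len <- .rdU32(raw, pos + 8L)
      vPos <- pos + 12L
    } else {
      len <- .rdU16(raw, pos + 6L)
      vPos <- pos + 8L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements are not supported ",
           sprintf("(tag %04X,%04X)", group, element))
    key <- sprintf("%04X%04X", group, element)
    if (vr == "SQ") {
      items <- list()
      ip <- vPos
      while (ip < vPos + len) {
        ig <- .rdU16(raw, ip); ie <- .rdU16(raw, ip + 2L)
        il <- .rdU32(raw, ip + 4L)
        if (ig != 0xFFFE || ie != 0xE000)
          stop("malformed sequence item")
        if (il == 4294967295)
          stop("undefined-length sequence items are not supported")
        items <- c(items, list(.parseDataset(raw, ip + 8L, ip + 7L + il)))
        ip <- ip + 8L + il
      }
      out[[key]] <- items
    } else {
      out[[key]] <- .decodeValue(vr, if (len > 0) raw[vPos:(vPos + len - 1L)]
                                     else raw(0))
    }
    pos <- vPos + len
  }
  out
}

.parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  # meta group (always explicit little endian)
  stopifnot(.rdU16(raw, pos) == 0x0002)
  metaLen <- .rdU32(raw, pos + 8L)
  meta <- .parseDataset(raw, pos, pos + 11L + metaLen)
  ts <- meta[["00020010"]]
  if (!identical(ts, .TS_EXPLICIT_LE))
    stop("unsupported transfer syntax '", ts,
         "'; only Explicit VR Little Endian is supported")
  ds <- .parseDataset(raw, pos + 12L + metaLen, length(raw))
  ds
}

.requireAttr <- function(ds, key, name) {
  if (is.null(ds[[key]]))
    stop(sprintf("missing DICOM attribute %s (%s,%s)", name,
                 substr(key, 1, 4), substr(key, 5, 8)))
  ds[[key]]
}

.stripsFromDataset <- function(ds, path) {
  regions <- ds[["00186011"]]
  if (is.null(regions) || !length(regions))
    stop("no Doppler region: the file has no ultrasound-regions sequence")
  isSpectral <- vapply(regions, function(r) {
    dt <- r[["00186014"]]
    !is.null(dt) && dt %in% c(3, 4)
  }, TRUE)
  if (!any(isSpectral))
    stop("no Doppler region: no spectral region among ",
         length(regions), " ultrasound region(s)")
  cand <- regions[isSpectral]
  if (length(cand) > 1) {
    area <- vapply(cand, function(r)
      (r[["0018601C"]] - r[["00186018"]] + 1) *
      (r[["0018601E"]] - r[["0018601A"]] + 1), 0)
    message("multiple spectral regions; selecting the largest")
    cand <- cand[which.max(area)]
  }
  reg <- cand[[1]]
  dx <- .requireAttr(reg, "0018602C", "PhysicalDeltaX")
  dy <- .requireAttr(reg, "0018602E", "PhysicalDeltaY")
  if (dx <= 0) stop("PhysicalDeltaX must be positive")
  x0 <- reg[["00186018"]] %||% 0; y0 <- reg[["0018601A"]] %||% 0
  x1 <- .requireAttr(reg, "0018601C", "RegionLocationMaxX1")
  y1 <- .requireAttr(reg, "0018601E", "RegionLocationMaxY1")
  refY <- reg[["00186022"]] %||% y1

  nR <- .requireAttr(ds, "00280010", "Rows")
  nC <- .requireAttr(ds, "00280011", "Columns")
  if (!is.null(ds[["00280100"]]) && ds[["00280100"]] != 8)
    stop("only 8-bit pixel data is supported")
  nF <- as.integer(ds[["00280008"]] %||% 1)
  pix <- .requireAttr(ds, "7FE00010", "PixelData")
  need <- nR * nC * nF
  if (length(pix) < need) stop("truncated PixelData")
  hr <- as.numeric(ds[["00181088"]] %||% NA_real_)
  rows <- (y0 + 1):(y1 + 1)
  cols <- (x0 + 1):(x1 + 1)
  flowSign <- if (dy < 0) 1 else -1
  strips <- lapply(seq_len(nF), function(f) {
    m <- matrix(as.integer(pix[((f - 1) * nR * nC + 1):(f * nR * nC)]),
                nrow = nR, byrow = TRUE)
    dopplerStrip(m[rows, cols, drop = FALSE], dx, abs(dy),
                 as.integer(refY - y0 + 1), flowSign = flowSign,
                 sourceId = sprintf("%s#frame%d", basename(path), f),
                 heartRate = hr)
  })
  src <- new("DicomDopplerSource", path = path,
             vendor = ds[["00080070"]] %||% "unknown",
             frameCount = nF, heartRate = hr, dtPerCol = dx,
             dvPerRow = abs(dy), baselineRow = as.integer(refY - y0 + 1),
             anonymized = FALSE)
  list(strips = strips, source = src)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read spectral-Doppler data from DICOM
#'
#' Locates the spectral-Doppler ultrasound region by its region-type
#' metadata, crops the pixel data to the region, and maps the physical
#' calibration (seconds per column, cm/s per row, baseline reference
#' row) into [DopplerStrip-class] objects — one per frame for
#' multi-frame cines.  When several spectral regions exist the largest
#' wins.  A folder may be given instead of a file; folders mixing
#' single-frame and cine files are rejected.
#'
#' @param path a DICOM file or a folder of DICOM files.
#' @return list with \code{strips} (list of [DopplerStrip-class]) and
#'   \code{source} (a [DicomDopplerSource-class]; for a folder, a list of
#'   them).
#' @export
readDopplerDicom <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    reads <- lapply(files, function(f)
      tryCatch(readDopplerDicom(f), error = function(e) NULL))
    reads <- Filter(Negate(is.null), reads)
    if (!length(reads)) stop("no readable DICOM files in ", path)
    nFrames <- vapply(reads, function(r) r$source@frameCount, 0L)
    if (any(nFrames == 1L) && any(nFrames > 1L))
      stop("folder mixes single-frame and cine DICOM files; ",
           "load them separately")
    return(list(strips = do.call(c, lapply(reads, `[[`, "strips")),
                source = lapply(reads, `[[`, "source")))
  }
  out <- .stripsFromDataset(.parseDicomFile(path), path)
  .sweepSpeedGuard(out$strips[[1]])
  out
}

# a 100 mm/s sweep at typical display pitch gives <= ~5 ms/column; warn
# on coarser sampling, never fail
.sweepSpeedGuard <- function(strip, pixelPitchMm = 0.4) {
  sweep <- pixelPitchMm / 1000 / strip@dtPerCol  # m/s of screen travel
  if (sweep * 1000 < 99)
    warning(sprintf(paste0("temporal resolution %.1f ms/column suggests a ",
                           "sweep speed below the recommended 100 mm/s"),
                    1000 * strip@dtPerCol), call. = FALSE)
  invisible(strip)
}

#' Split a cine strip into single-cycle strips
#'
#' Estimates the cardiac period from heart-rate metadata when present,
#' otherwise from the autocorrelation of the column intensity sums, then
#' cuts the strip at onset-aligned cycle starts (the rising edge of the
#' cycle-folded activity profile).  A strip without detectable
#' periodicity, or shorter than one cycle, is returned whole with a
#' warning.
#'
#' @param strip a [DopplerStrip-class].
#' @param method "metadata", "autocorrelation", or "auto" (metadata when
#'   available).
#' @return list of [DopplerStrip-class], each carrying its time offset in
#'   its \code{sourceId}.
#' @export
splitCine <- function(strip, method = c("auto", "metadata", "autocorrelation")) {
  stopifnot(is(strip, "DopplerStrip"))
  method <- match.arg(method)
  nc <- ncol(strip@pixels)
  activity <- colSums(strip@pixels)
  periodCols <- NA_integer_
  if (method %in% c("auto", "metadata") && !is.na(strip@heartRate))
    periodCols <- as.integer(round(60 / strip@heartRate / strip@dtPerCol))
  if (is.na(periodCols) && method != "metadata") {
    minLag <- max(10L, as.integer(round(0.25 / strip@dtPerCol)))
    maxLag <- min(nc - 1L, as.integer(round(2 / strip@dtPerCol)))
    if (maxLag > minLag) {
      ac <- stats::acf(activity, lag.max = maxLag, plot = FALSE)$acf[-1]
      lag <- which.max(ac[minLag:maxLag]) + minLag - 1L
      if (ac[lag] > 0.2) periodCols <- lag
    }
  }
  if (is.na(periodCols) || periodCols >= nc) {
    warning("no periodicity found; returning the strip uncut")
    return(list(strip))
  }
  # cycle-folded activity: boundary at the rising edge before the peak
  nCyc <- nc %/% periodCols
  folded <- rowMeans(matrix(activity[seq_len(nCyc * periodCols)],
                            nrow = periodCols))
  thresh <- min(folded) + 0.1 * (max(folded) - min(folded))
  above <- folded > thresh
  rising <- which(above & !above[c(length(above), seq_len(length(above) - 1))])
  onsetPhase <- if (length(rising)) rising[1] else which.max(folded)
  starts <- seq(onsetPhase, nc, by = periodCols)
  starts <- starts[nc - starts + 1L >= periodCols %/% 2L]
  lapply(starts, function(s) {
    cols <- s:(min(nc, s + periodCols - 1L))
    dopplerStrip(strip@pixels[, cols, drop = FALSE], strip@dtPerCol,
                 strip@dvPerRow, strip@baselineRow, strip@flowSign,
                 sourceId = sprintf("%s@%.4fs", strip@sourceId,
                                    (s - 1) * strip@dtPerCol),
                 heartRate = strip@heartRate)
  })
}
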