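# Study assembly, spreadsheet export, study-database append, and the
# portable JSON session container.

.EWK_SESSION_VERSION <- "1.0"

.INDEX_COLS <- c("c", "k", "x0", "vmax", "vmax_ms", "at", "edec", "duration",
                 "vti", "kx0", "cvmax", "energy", "beta", "kfei", "tau")

#' Assemble a per-case study result
#'
#' Bundles the accepted fits of one case with the load-independence
#' regression (computed when >= 2 beats with varying resistive force are
#' present), provenance and a timestamp.
#'
#' @param caseId case identifier.
#' @param fits list of [EwaveFit-class] objects.
#' @param strips optional list of source [DopplerStrip-class] objects.
#' @param provenance optional list (source files, settings, ...).
#' @return a [StudyResult-class].
#' @export
studyResult <- function(caseId, fits, strips = list(), provenance = list()) {
  li <- tryCatch(loadIndependence(fits), error = function(e) NULL)
  prov <- utils::modifyList(
    list(software = paste0("ewavekit ",
                           as.character(utils::packageVersion("ewavekit")))),
    provenance)
  new("StudyResult", caseId = caseId, fits = fits, strips = strips,
      loadIndex = li, provenance = prov,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @rdname StudyResult-class
#' @export
setMethod("beatTable", "StudyResult", function(object) {
  rows <- lapply(seq_along(object@fits), function(i) {
    f <- object@fits[[i]]
    data.frame(beat = i, c = f@params@c, k = f@params@k, x0 = f@params@x0,
               t(f@indices[setdiff(.INDEX_COLS, c("c", "k", "x0"))]),
               residual_norm = f@residualNorm, converged = f@converged,
               method = f@method)
  })
  do.call(rbind, rows)
})

#' @rdname StudyResult-class
#' @export
setMethod("studySummary", "StudyResult", function(object) {
  bt <- beatTable(object)
  num <- bt[.INDEX_COLS]
  data.frame(statistic = c("mean", "sd"),
             rbind(colMeans(num), apply(num, 2, stats::sd)))
})

#' Export a study to a spreadsheet file
#'
#' Writes one row per beat (the constants plus every derived index),
#' followed by mean and SD summary rows and the M/B regression values.
#' The dialect is UTF-8, '.' decimal, header row, comma (csv) or tab
#' (tsv) separated; numbers keep 15 significant digits.  Anonymized
#' exports carry no case identifier or source information.
#'
#' @param study a [StudyResult-class] with >= 1 fit.
#' @param path output path.
#' @param format "csv" or "tsv".
#' @param anonymize drop case id and provenance from the output.
#' @return invisibly, the exported data.frame.
#' @export
exportResults <- function(study, path, format = c("csv", "tsv", "xlsx"),
                          anonymize = FALSE) {
  stopifnot(is(study, "StudyResult"))
  if (!length(study@fits)) stop("study has no fits to export")
  format <- match.arg(format)
  if (format == "xlsx")
    stop("format 'xlsx' is not supported; use 'csv' or 'tsv'")
  sep <- if (format == "csv") "," else "\t"
  bt <- beatTable(study)
  sm <- studySummary(study)
  rows <- data.frame(record = sprintf("beat%d", bt$beat),
                     case = if (anonymize) "" else study@caseId,
                     bt[-1], m = NA_real_, b = NA_real_,
                     check.names = FALSE)
  sumRows <- data.frame(record = sm$statistic,
                        case = if (anonymize) "" else study@caseId,
                        sm[-1], residual_norm = NA_real_, converged = NA,
                        method = "", m = NA_real_, b = NA_real_)
  if (!is.null(study@loadIndex)) {
    sumRows$m[1] <- study@loadIndex@m
    sumRows$b[1] <- study@loadIndex@b
  }
  out <- rbind(rows, sumRows[names(rows)])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = sep, dec = ".", row.names = FALSE,
                     quote = FALSE)
  invisible(out)
}

#' Append a case summary to a cumulative study database
#'
#' Adds one row per case — the per-case mean and SD of every constant
#' and derived index, plus M and B — to a delimited study-database file,
#' creating it when absent.  Appending to a file whose header does not
#' match is an error: the schema never drifts silently.
#'
#' @param study a [StudyResult-class].
#' @param dbPath database file path (.csv or .tsv decides the separator).
#' @param anonymize drop the case identifier.
#' @return invisibly, the appended row.
#' @export
appendStudyDatabase <- function(study, dbPath, anonymize = FALSE) {
  stopifnot(is(study, "StudyResult"))
  if (!length(study@fits)) stop("study has no fits to append")
  sep <- if (grepl("\\.tsv$", dbPath)) "\t" else ","
  sm <- studySummary(study)
  means <- as.numeric(sm[1, -1]); sds <- as.numeric(sm[2, -1])
  row <- data.frame(case = if (anonymize) "anonymous" else study@caseId,
                    n_beats = length(study@fits))
  for (i in seq_along(.INDEX_COLS)) {
    row[[paste0("mean_", .INDEX_COLS[i])]] <- means[i]
    row[[paste0("sd_", .INDEX_COLS[i])]] <- sds[i]
  }
  row$m <- if (is.null(study@loadIndex)) NA_real_ else study@loadIndex@m
  row$b <- if (is.null(study@loadIndex)) NA_real_ else study@loadIndex@b
  if (file.exists(dbPath)) {
    hdr <- strsplit(readLines(dbPath, n = 1), sep, fixed = TRUE)[[1]]
    if (!identical(hdr, names(row)))
      stop("study database header does not match; refusing to append")
    utils::write.table(format(row, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       dbPath, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE, append = TRUE)
  } else {
    utils::write.table(format(row, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       dbPath, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(row)
}

# ---- session container ----------------------------------------------

.traceToList <- function(tr) {
  s <- tr@settings
  list(times = tr@times, velocities = tr@velocities, accepted = tr@accepted,
       settings = list(tStart = s@tStart, tEnd = s@tEnd,
                       threshold = s@threshold, maxJump = s@maxJump,
                       zeroTail = s@zeroTail, tangentShorten = s@tangentShorten))
}

.traceFromList <- function(x) {
  s <- x$settings
  velocityTrace(x$times, x$velocities, x$accepted,
                detectionSettings(s$tStart, s$tEnd %||% NA_real_,
                                  s$threshold %||% NA_real_,
                                  s$maxJump %||% NA_real_,
                                  s$zeroTail, s$tangentShorten))
}

#' Save / load a portable analysis session
#'
#' A self-describing JSON container (schema version 1.0, recorded in the
#' file) holding the Doppler strips, detected traces, settings
#' and fits of one case, so an analysis can be reviewed or edited later.
#' The round trip is lossless to full double precision.  Saving with
#' \code{anonymize = TRUE} strips the case identifier and all source
#' provenance.
#'
#' @param study a [StudyResult-class].
#' @param path session file path (conventionally \code{.ewk.json}).
#' @param anonymize strip identifying fields on save.
#' @return \code{loadSession} returns the restored [StudyResult-class].
#' @export
saveSession <- function(study, path, anonymize = FALSE) {
  stopifnot(is(study, "StudyResult"))
  payload <- list(
    container = "ewavekit-session",
    version = .EWK_SESSION_VERSION,
    caseId = if (anonymize) "anonymous" else study@caseId,
    anonymized = anonymize,
    timestamp = study@timestamp,
    provenance = if (anonymize)
      list(software = study@provenance$software) else study@provenance,
    strips = lapply(study@strips, function(s) list(
      pixels = s@pixels, dtPerCol = s@dtPerCol, dvPerRow = s@dvPerRow,
      baselineRow = s@baselineRow, flowSign = s@flowSign,
      sourceId = if (anonymize) "anonymous" else s@sourceId,
      heartRate = s@heartRate)),
    fits = lapply(study@fits, function(f) list(
      params = list(c = f@params@c, k = f@params@k, x0 = f@params@x0),
      indices = as.list(f@indices), method = f@method,
      residualNorm = f@residualNorm, converged = f@converged,
      trace = .traceToList(f@trace))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = FALSE), path)
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
  if (!identical(x$container, "ewavekit-session"))
    stop("not an ewavekit session file")
  if (!identical(x$version, .EWK_SESSION_VERSION))
    stop("session version ", x$version, " cannot be migrated; expected ",
         .EWK_SESSION_VERSION)
  strips <- lapply(x$strips, function(s)
    dopplerStrip(s$pixels, s$dtPerCol, s$dvPerRow, s$baselineRow,
                 s$flowSign, s$sourceId, s$heartRate %||% NA_real_))
  fits <- lapply(x$fits, function(f) {
    new("EwaveFit",
        params = pdfParameters(f$params$c, f$params$k, f$params$x0),
        indices = vapply(f$indices, function(v)
          if (is.null(v)) NA_real_ else as.numeric(v), 0),
        trace = .traceFromList(f$trace), method = f$method,
        residualNorm = f$residualNorm, converged = f$converged)
  })
  li <- tryCatch(loadIndependence(fits), error = function(e) NULL)
  new("StudyResult", caseId = x$caseId, fits = fits, strips = strips,
      loadIndex = li, provenance = x$provenance,
      timestamp = x$timestamp %||% "")
}
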