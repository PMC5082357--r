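# Reproducibility statistics between two repeated analyses of the same
# cases.  The unit of analysis is the per-case mean.

#' Coefficient of variation of repeated analyses
#'
#' The standard deviation of the paired differences between the two
#' analyses (n-1 denominator) divided by the grand mean of all values,
#' as a percent.  Reported as a positive magnitude even for parameters
#' that are mathematically negative (such as the damping index).
#'
#' @param pairs a [PairedMeasurements-class].
#' @return CV in percent (>= 0).
#' @examples
#' pm <- pairedMeasurements(letters[1:3], c(10, 12, 14), c(11, 11, 15))
#' coefficientOfVariation(pm)
#' @export
coefficientOfVariation <- function(pairs) {
  stopifnot(is(pairs, "PairedMeasurements"))
  gm <- mean(c(pairs@a, pairs@b))
  if (gm == 0) stop("grand mean is zero; CV is undefined")
  abs(100 * stats::sd(pairs@a - pairs@b) / gm)
}

#' Intraclass correlation coefficient of repeated analyses
#'
#' Two-way random-effects, single-measure ICC from the case-by-analysis
#' ANOVA mean squares.  The default form is absolute agreement,
#' ICC(2,1): \deqn{\frac{MS_R - MS_E}{MS_R + MS_E + 2 (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the case, analysis and
#' residual mean squares; the consistency form ICC(3,1) is available via
#' \code{form}.
#'
#' @param pairs a [PairedMeasurements-class].
#' @param form "ICC(2,1)" (absolute agreement, default) or "ICC(3,1)"
#'   (consistency).
#' @return list with \code{icc}, the mean squares in \code{components},
#'   and \code{form}.
#' @export
icc <- function(pairs, form = c("ICC(2,1)", "ICC(3,1)")) {
  stopifnot(is(pairs, "PairedMeasurements"))
  form <- match.arg(form)
  n <- length(pairs@a)
  d <- data.frame(y = c(pairs@a, pairs@b),
                  case = factor(rep(seq_len(n), 2)),
                  analysis = factor(rep(1:2, each = n)))
  if (stats::var(d$y) == 0)
    stop("zero total variance; ICC is undefined")
  ms <- summary(stats::aov(y ~ case + analysis, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  val <- if (form == "ICC(2,1)")
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  else
    (msr - mse) / (msr + mse)
  list(icc = val, components = c(MSR = msr, MSC = msc, MSE = mse),
       form = form)
}

#' Percentage difference between repeated analyses
#'
#' Per case, the absolute difference as a percentage of the pairwise
#' mean, \eqn{100 |a - b| / ((a + b)/2)}; returns its mean and SD.
#' Cases with a zero pairwise mean are excluded with a warning and
#' reported in \code{excluded}.
#'
#' @param pairs a [PairedMeasurements-class].
#' @return list with \code{mean}, \code{sd} (both percent) and
#'   \code{excluded} (labels of dropped cases).
#' @export
percentageDifference <- function(pairs) {
  stopifnot(is(pairs, "PairedMeasurements"))
  denom <- (pairs@a + pairs@b) / 2
  bad <- denom == 0
  if (any(bad))
    warning("excluding ", sum(bad), " case(s) with zero pairwise mean: ",
            paste(pairs@labels[bad], collapse = ", "))
  d <- 100 * abs(pairs@a - pairs@b)[!bad] / denom[!bad]
  if (!length(d)) stop("no cases remain after exclusion")
  list(mean = mean(d), sd = stats::sd(d), excluded = pairs@labels[bad])
}

#' Reproducibility report across parameters
#'
#' Convenience wrapper producing one row per parameter — CV, mean and SD
#' of the percentage difference, and ICC — from two study-database
#' exports (as written by [appendStudyDatabase()]) or two data.frames
#' with matching \code{case} and \code{mean_*} columns.
#'
#' @param fileA,fileB paths to the two study-database files, or
#'   data.frames.
#' @param form ICC form, see [icc()].
#' @return data.frame with columns parameter, n, cv_pct, diff_pct_mean,
#'   diff_pct_sd, icc.
#' @export
reproducibilityReport <- function(fileA, fileB, form = "ICC(2,1)") {
  readDb <- function(x) {
    if (is.data.frame(x)) return(x)
    sep <- if (grepl("\\.tsv$", x)) "\t" else ","
    utils::read.table(x, header = TRUE, sep = sep)
  }
  a <- readDb(fileA); b <- readDb(fileB)
  common <- intersect(a$case, b$case)
  if (length(common) < 2) stop("need at least 2 common cases")
  a <- a[match(common, a$case), ]
  b <- b[match(common, b$case), ]
  pars <- grep("^mean_", names(a), value = TRUE)
  pars <- pars[pars %in% names(b)]
  rows <- lapply(pars, function(p) {
    va <- a[[p]]; vb <- b[[p]]
    if (any(!is.finite(va)) || any(!is.finite(vb))) return(NULL)
    pm <- pairedMeasurements(common, va, vb, parameter = sub("^mean_", "", p))
    pd <- suppressWarnings(percentageDifference(pm))
    data.frame(parameter = sub("^mean_", "", p), n = length(common),
               cv_pct = coefficientOfVariation(pm),
               diff_pct_mean = pd$mean, diff_pct_sd = pd$sd,
               icc = icc(pm, form)$icc)
  })
  do.call(rbind, rows)
}
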