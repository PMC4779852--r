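#' @include AllClasses.R
NULL

## seconds per declared input unit
.timeUnitFactors <- c(s = 1, min = 60, h = 3600, d = 86400)

toSeconds <- function(times, unit) {
  unit <- match.arg(unit, names(.timeUnitFactors))
  times * .timeUnitFactors[[unit]]
}

#' Summary statistics and inverse-variance weights
#'
#' Computes, per time point, the arithmetic mean of the replicates, the
#' sample standard deviation (denominator r_j - 1) and the inverse-variance
#' weight w_j = sigma_j^-2 used by the weighted smoothing spline. Where the
#' weight is undefined (a single replicate, or zero variance) it is set by
#' policy to `kappa` times the largest finite weight of the series, with a
#' warning; if no finite weight exists at all, every weight becomes 1
#' (unweighted fit).
#'
#' @param x a \linkS4class{ReplicateSeries}, or a list of them.
#' @param kappa cap multiplier for degenerate-weight time points
#'   (default 10).
#' @param ... unused.
#' @return The input with `means`, `sds` and `weights` populated.
#'   Idempotent: re-summarizing a summarized series changes nothing.
#' @examples
#' rs <- ReplicateSeries("X", c(0, 10), list(c(1, 2, 3), c(4, 5, 6)))
#' seriesWeights(summarizeReplicates(rs))  # 1/variance = 1 at both points
#' @export
setMethod("summarizeReplicates", "ReplicateSeries",
          function(x, kappa = 10, ...) {
  stopifnot(kappa > 0)
  reps <- x@replicates
  n    <- vapply(reps, length, integer(1))
  m    <- vapply(reps, mean, numeric(1))
  s    <- vapply(reps, function(v)
            if (length(v) >= 2L) stats::sd(v) else NA_real_, numeric(1))
  w    <- ifelse(!is.na(s) & s > 0, s^-2, NA_real_)
  bad  <- !is.finite(w)
  if (any(bad)) {
    if (all(bad)) {
      warning(sprintf(
        "%s: no time point has a finite inverse-variance weight; %s",
        x@metaboliteId, "falling back to unit weights"))
      w[] <- 1
    } else {
      w[bad] <- kappa * max(w[!bad])
      warning(sprintf(
        "%s: %d time point(s) with zero variance or a single replicate; %s",
        x@metaboliteId, sum(bad),
        sprintf("weight capped at %g x the largest finite weight", kappa)))
    }
  }
  initialize(x, means = m, sds = s, weights = unname(w))
})

#' @rdname summarizeReplicates
#' @export
setMethod("summarizeReplicates", "list", function(x, kappa = 10, ...)
  lapply(x, summarizeReplicates, kappa = kappa))

## split a delimited header line, auto-detecting tab vs comma
.detectDelim <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read replicate metabolite time series from a delimited text file
#'
#' Two layouts are supported. Long: columns `metabolite`, `time`, `value`,
#' one row per replicate measurement. Wide: a `time` column plus one column
#' per metabolite and replicate named `metabolite.rep1`, `metabolite.rep2`,
#' ... Delimiter (tab or comma) is auto-detected from the header; the
#' decimal separator is the point. Times are converted to seconds from the
#' declared `timeUnit`. Missing values (`NA` or empty) are dropped,
#' reducing that point's replicate count.
#'
#' @param path file path.
#' @param layout `"long"` or `"wide"`.
#' @param timeUnit input time unit: `"s"`, `"min"`, `"h"` or `"d"`.
#' @param summarize logical; also run [summarizeReplicates()] on each
#'   series.
#' @return Named list of \linkS4class{ReplicateSeries}, one per metabolite,
#'   in first-appearance order.
#' @examples
#' path <- system.file("extdata", "chain4_timeseries_synthetic.tsv",
#'                     package = "omegaflux")
#' series <- readTimeseries(path, layout = "long", summarize = TRUE)
#' seriesMeans(series$A)
#' @seealso [writeTimeseries()], [writeSummary()]
#' @export
readTimeseries <- function(path, layout = c("long", "wide"),
                           timeUnit = "s", summarize = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- .detectDelim(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  out <- if (layout == "long") .seriesFromLong(df, path)
         else .seriesFromWide(df, path)
  out <- lapply(out, function(x)
    ReplicateSeries(x$id, x$times, x$replicates, timeUnit = timeUnit))
  names(out) <- vapply(out, metaboliteId, character(1))
  if (summarize) summarizeReplicates(out) else out
}

.numericOrStop <- function(v, what, path) {
  if (is.numeric(v)) return(v)
  suppress <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(suppress) & !is.na(v) & v != "")
  if (length(bad))
    stop(sprintf("non-numeric %s in '%s' at data row %d: '%s'",
                 what, path, bad[1], v[bad[1]]))
  suppress
}

.seriesFromLong <- function(df, path) {
  need <- c("metabolite", "time", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("long layout requires columns %s; '%s' has: %s",
                 paste(need, collapse = ", "), path,
                 paste(names(df), collapse = ", ")))
  df$time  <- .numericOrStop(df$time, "time", path)
  df$value <- .numericOrStop(df$value, "concentration value", path)
  ids <- unique(df$metabolite)
  lapply(ids, function(id) {
    sub <- df[df$metabolite == id & !is.na(df$value), , drop = FALSE]
    times <- sort(unique(sub$time))
    if (length(times) < 2L)
      stop(sprintf("metabolite '%s' has fewer than 2 distinct time points",
                   id))
    list(id = id, times = times,
         replicates = lapply(times, function(t) sub$value[sub$time == t]))
  })
}

.seriesFromWide <- function(df, path) {
  if (!"time" %in% names(df))
    stop(sprintf("wide layout requires a 'time' column; '%s' has: %s",
                 path, paste(names(df), collapse = ", ")))
  df$time <- .numericOrStop(df$time, "time", path)
  valcols <- setdiff(names(df), "time")
  m <- regmatches(valcols, regexec("^(.*)\\.rep([0-9]+)$", valcols))
  if (any(vapply(m, length, integer(1)) != 3L))
    stop(sprintf("wide layout columns must be named <metabolite>.rep<k>; %s",
                 sprintf("offending column(s) in '%s': %s", path,
                         paste(valcols[vapply(m, length, integer(1)) != 3L],
                               collapse = ", "))))
  ids <- unique(vapply(m, `[`, character(1), 2))
  ord <- order(df$time)
  lapply(ids, function(id) {
    cols <- valcols[vapply(m, `[`, character(1), 2) == id]
    vals <- as.matrix(df[ord, cols, drop = FALSE])
    vals <- matrix(.numericOrStop(as.vector(vals), "concentration value",
                                  path), nrow = nrow(vals))
    times <- df$time[ord]
    if (anyDuplicated(times))
      stop(sprintf("wide layout in '%s' has duplicated time rows", path))
    if (length(times) < 2L)
      stop(sprintf("metabolite '%s' has fewer than 2 distinct time points",
                   id))
    list(id = id, times = times,
         replicates = lapply(seq_along(times), function(j)
           vals[j, ][!is.na(vals[j, ])]))
  })
}

#' Write replicate series to a delimited text file
#'
#' @param series list of \linkS4class{ReplicateSeries}.
#' @param path output path.
#' @param layout `"long"` (metabolite, time, value; one row per replicate)
#'   or `"wide"` (`time` plus `metabolite.repK` columns; requires equal
#'   replicate counts per metabolite).
#' @param sep field delimiter (tab default).
#' @return `path`, invisibly. Times are written in seconds.
#' @export
writeTimeseries <- function(series, path, layout = c("long", "wide"),
                            sep = "\t") {
  layout <- match.arg(layout)
  if (is(series, "ReplicateSeries")) series <- list(series)
  fmt <- function(x) sprintf("%.17g", x)   # lossless numeric round trip
  if (layout == "long") {
    rows <- do.call(rbind, lapply(series, function(x) {
      data.frame(metabolite = x@metaboliteId,
                 time  = fmt(rep(x@times, vapply(x@replicates, length,
                                                 integer(1)))),
                 value = fmt(unlist(x@replicates)))
    }))
    utils::write.table(rows, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  } else {
    times <- series[[1]]@times
    cols <- list(time = fmt(times))
    for (x in series) {
      if (!identical(x@times, times))
        stop("wide layout requires a common time vector across metabolites")
      r <- unique(vapply(x@replicates, length, integer(1)))
      if (length(r) != 1L)
        stop(sprintf("wide layout requires equal replicate counts ('%s')",
                     x@metaboliteId))
      for (k in seq_len(r))
        cols[[sprintf("%s.rep%d", x@metaboliteId, k)]] <-
          fmt(vapply(x@replicates, `[`, numeric(1), k))
    }
    utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                       sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export per-time-point summary statistics
#'
#' Writes a TSV with columns `metabolite`, `time_s`, `mean_mM`, `sd_mM`,
#' `weight` for a collection of summarized series.
#'
#' @param series list of summarized \linkS4class{ReplicateSeries}.
#' @param path output path.
#' @return The exported data.frame, invisibly.
#' @export
writeSummary <- function(series, path) {
  if (is(series, "ReplicateSeries")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(x) {
    if (!isSummarized(x))
      stop("series '", x@metaboliteId, "' is not summarized")
    data.frame(metabolite = x@metaboliteId, time_s = x@times,
               mean_mM = x@means, sd_mM = x@sds, weight = x@weights)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}
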