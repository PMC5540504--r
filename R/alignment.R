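#' @include AllClasses.R
NULL

#' Alignment configuration
#'
#' Settings for correlation-optimized integer-sample alignment: the maximum
#' allowed shift, optional intervals (half-open \code{[start_s, end_s)}
#' windows aligned independently; \code{NULL} means whole-trace mode) and
#' the fill policy for vacated samples (edge replication, so no missing
#' values reach integration).
#'
#' @param max_shift_samples integer >= 0, largest |shift| searched.
#' @param intervals \code{NULL} for whole-trace alignment, or a list of
#'   \code{c(start_s, end_s)} windows, non-overlapping and ordered.
#' @param fill_policy only \code{"edge-replicate"} is supported.
#' @return A validated list of class \code{AlignmentConfig}.
#' @export
alignmentConfig <- function(max_shift_samples, intervals = NULL,
                            fill_policy = "edge-replicate") {
  max_shift_samples <- as.integer(max_shift_samples)
  if (is.na(max_shift_samples) || max_shift_samples < 0L)
    stop("'max_shift_samples' must be an integer >= 0")
  fill_policy <- match.arg(fill_policy, "edge-replicate")
  if (!is.null(intervals)) {
    if (!is.list(intervals) || !length(intervals))
      stop("'intervals' must be NULL or a non-empty list of c(start, end)")
    for (iv in intervals)
      if (length(iv) != 2L || !is.numeric(iv) || iv[1L] >= iv[2L])
        stop("each interval must be numeric c(start_s, end_s) with start < end")
    starts <- vapply(intervals, `[`, numeric(1), 1L)
    ends <- vapply(intervals, `[`, numeric(1), 2L)
    if (is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1L] < ends[-length(ends)]))
      stop("intervals must be ordered and non-overlapping")
  }
  structure(list(max_shift_samples = max_shift_samples,
                 intervals = intervals, fill_policy = fill_policy),
            class = "AlignmentConfig")
}

#' Mean reference chromatogram
#'
#' Elementwise arithmetic mean of all traces in the set; the result is the
#' reference every trace is subsequently aligned to.
#'
#' @param set a non-empty \code{ChromatogramSet} on a common grid.
#' @return A \code{Chromatogram} whose sample_id is \code{"reference"}.
#' @export
buildReference <- function(set) {
  stopifnot(is(set, "ChromatogramSet"))
  if (ncol(set) == 0L) stop("cannot build a reference from an empty set")
  cd <- as.data.frame(SummarizedExperiment::colData(set))
  m <- sampleMeta("reference", 0L, mean(cd$pressure_bar),
                  mean(cd$biomass_gdcw_per_l), FALSE, "mean reference")
  chromatogram(chromTime(set), rowMeans(absorbance(set)), m)
}

#' Correlation-optimal integer shift of a signal against a reference
#'
#' Searches \code{s} in \code{[-max_shift, +max_shift]} for the shift
#' maximizing the Pearson correlation between the edge-replicated shifted
#' signal and the reference. Applying the returned shift aligns the signal
#' to the reference: a signal delayed by \code{d} samples yields
#' \code{-d}. Ties are broken toward the smallest |s|, then the negative
#' one. A zero-variance signal returns shift 0 with a warning.
#'
#' @param signal,reference numeric vectors of equal length.
#' @param max_shift integer, largest |shift| considered; must be smaller
#'   than the signal length.
#' @return Integer shift \code{s*}, with the achieved correlation in
#'   attribute \code{"correlation"}.
#' @export
estimateShift <- function(signal, reference, max_shift) {
  stopifnot(length(signal) == length(reference))
  max_shift <- as.integer(max_shift)
  if (max_shift >= length(signal))
    stop("'max_shift' must be smaller than the signal length")
  if (stats::sd(signal) == 0 || stats::sd(reference) == 0) {
    warning("constant signal: returning shift 0")
    return(structure(0L, correlation = NA_real_))
  }
  cand <- seq.int(-max_shift, max_shift)
  cors <- vapply(cand, function(s)
    stats::cor(shift_vector(signal, s), reference), numeric(1))
  cors[is.na(cors)] <- -Inf
  best <- order(-cors, abs(cand), cand)[1L]
  structure(as.integer(cand[best]), correlation = cors[best])
}

# shift one trace (whole or per interval), edge-replicating within the
# shifted window; returns the new trace and the shift records
align_one <- function(y, ref, idx_list, labels, max_shift) {
  out <- y
  rec <- vector("list", length(idx_list))
  for (k in seq_along(idx_list)) {
    idx <- idx_list[[k]]
    s <- estimateShift(y[idx], ref[idx], max_shift)
    out[idx] <- shift_vector(y[idx], s)
    rec[[k]] <- list(interval = labels[k], shift_samples = as.integer(s),
                     correlation = attr(s, "correlation"))
  }
  list(trace = out, records = rec)
}

#' Align a chromatogram set to its mean reference
#'
#' Builds the mean reference internally, then shifts every trace (whole, or
#' each configured interval independently) by its correlation-optimal
#' integer shift. Vacated samples are filled by edge replication; trace
#' length and grid are never changed.
#'
#' @param set a \code{ChromatogramSet}.
#' @param config an \code{\link{alignmentConfig}}.
#' @return An \code{\link{AlignmentResult}} holding the aligned set, the
#'   per-trace (and per-interval) shifts and achieved correlations.
#' @export
alignSet <- function(set, config) {
  stopifnot(is(set, "ChromatogramSet"), inherits(config, "AlignmentConfig"))
  tm <- chromTime(set)
  ref <- absorbance(buildReference(set))
  if (is.null(config$intervals)) {
    idx_list <- list(seq_along(tm)); labels <- "whole"
  } else {
    idx_list <- lapply(config$intervals, function(iv)
      which(tm >= iv[1L] & tm < iv[2L]))
    labels <- vapply(config$intervals, function(iv)
      sprintf("[%g,%g)", iv[1L], iv[2L]), character(1))
  }
  short <- vapply(idx_list, length, integer(1)) <
    2L * config$max_shift_samples + 1L
  if (any(short))
    stop("interval(s) ", paste(labels[short], collapse = ", "),
         " shorter than 2*max_shift+1 samples")
  mat <- absorbance(set)
  shifts <- list()
  for (j in seq_len(ncol(mat))) {
    res <- align_one(mat[, j], ref, idx_list, labels,
                     config$max_shift_samples)
    mat[, j] <- res$trace
    for (r in res$records)
      shifts[[length(shifts) + 1L]] <- data.frame(
        sample_id = colnames(mat)[j], interval = r$interval,
        shift_samples = r$shift_samples, correlation = r$correlation)
  }
  aligned <- set
  SummarizedExperiment::assay(aligned, "absorbance") <- mat
  new("AlignmentResult", aligned = aligned,
      shifts = DataFrame(do.call(rbind, shifts)), config = unclass(config))
}

#' @rdname alignSet
#' @param result an \code{AlignmentResult}.
#' @export
alignedSet <- function(result) {
  stopifnot(is(result, "AlignmentResult")); result@aligned
}

#' @rdname alignSet
#' @export
shiftTable <- function(result) {
  stopifnot(is(result, "AlignmentResult")); result@shifts
}

#' @rdname alignSet
#' @param path output path for the shift table.
#' @export
writeShiftTable <- function(result, path) {
  utils::write.table(as.data.frame(shiftTable(result)), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
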