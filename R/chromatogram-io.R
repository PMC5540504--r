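#' @include AllClasses.R
NULL

# Autodetect comma vs tab on the first data line.
detect_sep <- function(lines) {
  l <- lines[nzchar(trimws(lines))][1L]
  if (grepl("\t", l)) "\t" else ","
}

#' Read a chromatogram from delimited text
#'
#' Reads a two-column (time in seconds, absorbance in mAU) comma- or
#' tab-delimited file, with or without a header line, validates the time
#' grid (strictly increasing, uniform spacing to a relative tolerance of
#' 1e-6) and attaches the sample metadata.
#'
#' @param path path to the file.
#' @param meta a \code{\link{sampleMeta}} object for this sample.
#' @return A \code{Chromatogram}.
#' @seealso \code{\link{writeChromatogram}}, \code{\link{readSampleMeta}}
#' @export
readChromatogram <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("file has fewer than two data rows: ", path)
  sep <- detect_sep(lines)
  first <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  has_header <- suppressWarnings(anyNA(as.numeric(first[1:2])))
  start <- if (has_header) 2L else 1L
  rows <- strsplit(lines[start:length(lines)], sep, fixed = TRUE)
  tm <- ab <- numeric(length(rows))
  for (k in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[k]][1:2]))
    if (anyNA(v))
      stop("non-numeric values at row ", k + start - 1L, " of ", path)
    tm[k] <- v[1L]; ab[k] <- v[2L]
  }
  d <- diff(tm)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("time not strictly increasing at row ", bad + start - 1L,
         " of ", path)
  }
  check_uniform_grid(tm, what = paste0("time grid of ", path))
  chromatogram(tm, ab, meta)
}

#' Write a chromatogram to delimited text
#'
#' Writes \code{time_s,absorbance_mau} with a header, at full double
#' precision so \code{readChromatogram(writeChromatogram(x))} round-trips
#' numerically.
#'
#' @param chrom a \code{Chromatogram}.
#' @param path output path.
#' @param sep field separator, \code{","} (default) or \code{"\t"}.
#' @return \code{path}, invisibly.
#' @export
writeChromatogram <- function(chrom, path, sep = ",") {
  stopifnot(is(chrom, "Chromatogram"))
  df <- data.frame(time_s = format(chrom@time, digits = 17, trim = TRUE),
                   absorbance_mau = format(chrom@absorbance, digits = 17,
                                           trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' A delimited table with columns \code{sample_id}, \code{cycle},
#' \code{pressure_bar}, \code{biomass_gdcw_per_l}, \code{frozen} and
#' optionally \code{condition_label}; one row per sample.
#'
#' @param path path to the table.
#' @return A named list of \code{SampleMeta}, keyed by sample_id.
#' @export
readSampleMeta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(
    readLines(path, n = 1L)), stringsAsFactors = FALSE)
  need <- c("sample_id", "cycle", "pressure_bar", "biomass_gdcw_per_l",
            "frozen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"condition_label" %in% names(df)) df$condition_label <- NA_character_
  out <- lapply(seq_len(nrow(df)), function(i)
    sampleMeta(df$sample_id[i], df$cycle[i], df$pressure_bar[i],
               df$biomass_gdcw_per_l[i], as.logical(df$frozen[i]),
               df$condition_label[i]))
  names(out) <- df$sample_id
  out
}

#' Write the metadata table of a set
#'
#' @param set a \code{ChromatogramSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMeta <- function(set, path) {
  stopifnot(is(set, "ChromatogramSet"))
  cd <- as.data.frame(SummarizedExperiment::colData(set))
  df <- cbind(sample_id = rownames(cd), cd)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a set onto a common uniform grid
#'
#' Linear interpolation of every trace onto a fresh grid at \code{rate_hz}
#' spanning the shared time range. A trace already on the target grid is
#' returned unchanged (identity); the input set is never modified.
#'
#' @param set a \code{ChromatogramSet}.
#' @param rate_hz target sampling rate in Hz.
#' @return A new \code{ChromatogramSet} on the target grid.
#' @export
resampleToGrid <- function(set, rate_hz) {
  stopifnot(is(set, "ChromatogramSet"), rate_hz > 0)
  tm <- chromTime(set)
  grid <- seq(tm[1L], tm[length(tm)], by = 1 / rate_hz)
  if (grid[length(grid)] > tm[length(tm)] + 1e-9)
    stop("target grid extends beyond the trace span")
  if (length(grid) == length(tm) && max(abs(grid - tm)) < 1e-12)
    return(set)
  mat <- apply(absorbance(set), 2L, function(y)
    stats::approx(tm, y, xout = grid)$y)
  cd <- SummarizedExperiment::colData(set)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = mat),
    rowData = DataFrame(time_s = grid), colData = cd)
  new("ChromatogramSet", se)
}
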