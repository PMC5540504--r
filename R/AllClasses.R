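#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Sample metadata for one homogenization sample
#'
#' Describes the process state a chromatogram was drawn from: the
#' homogenization cycle (0 means the resuspended, untreated "0 sample"),
#' the valve pressure, the biomass concentration and whether the biomass
#' had been frozen before disruption.
#'
#' @param sample_id single character, unique within a set.
#' @param cycle integer >= 0; homogenization pass count.
#' @param pressure_bar homogenization pressure in bar, in [0, 2000].
#' @param biomass_gdcw_per_l biomass concentration in g dry cell weight per
#'   litre, > 0.
#' @param frozen logical; was the biomass frozen before disruption?
#' @param condition_label optional free-text condition tag.
#' @return A named list of class \code{SampleMeta}.
#' @examples
#' sampleMeta("c0", cycle = 0, pressure_bar = 1500, biomass_gdcw_per_l = 10)
#' @export
sampleMeta <- function(sample_id, cycle, pressure_bar, biomass_gdcw_per_l,
                       frozen = FALSE, condition_label = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  cycle <- as.integer(cycle)
  if (is.na(cycle) || cycle < 0L) stop("'cycle' must be an integer >= 0")
  if (!is.numeric(pressure_bar) || pressure_bar < 0 || pressure_bar > 2000)
    stop("'pressure_bar' must lie in [0, 2000]")
  if (!is.numeric(biomass_gdcw_per_l) || biomass_gdcw_per_l <= 0)
    stop("'biomass_gdcw_per_l' must be > 0")
  structure(list(sample_id = sample_id, cycle = cycle,
                 pressure_bar = as.numeric(pressure_bar),
                 biomass_gdcw_per_l = as.numeric(biomass_gdcw_per_l),
                 frozen = isTRUE(frozen),
                 condition_label = as.character(condition_label)),
            class = "SampleMeta")
}

#' Chromatogram: one UV trace on a uniform time grid
#'
#' A single 280 nm UV-absorbance trace recorded on a strictly increasing,
#' uniformly spaced time grid (seconds from injection), together with its
#' sample metadata. The validity method enforces equal slot lengths, grid
#' uniformity to a relative tolerance of 1e-6 and the absence of missing
#' values.
#'
#' @slot time numeric, seconds from injection, uniform grid.
#' @slot absorbance numeric, mAU at 280 nm, same length as \code{time}.
#' @slot meta a \code{SampleMeta} list.
#' @aliases Chromatogram
#' @exportClass Chromatogram
setClass("Chromatogram",
         slots = c(time = "numeric", absorbance = "numeric", meta = "list"))

setValidity("Chromatogram", function(object) {
  if (length(object@time) != length(object@absorbance))
    return("time and absorbance must have equal length")
  if (anyNA(object@time) || anyNA(object@absorbance))
    return("missing values are not allowed after load")
  ok <- tryCatch({ check_uniform_grid(object@time); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' Construct a Chromatogram
#'
#' @param time numeric uniform grid in seconds from injection.
#' @param absorbance numeric absorbance in mAU, same length.
#' @param meta a \code{\link{sampleMeta}} object.
#' @return A \code{Chromatogram}.
#' @examples
#' tm <- seq(0, 299.8, by = 0.2)
#' chromatogram(tm, rep(0, length(tm)),
#'              sampleMeta("blank", 0, 1500, 10))
#' @export
chromatogram <- function(time, absorbance, meta) {
  if (!inherits(meta, "SampleMeta")) stop("'meta' must be a SampleMeta")
  new("Chromatogram", time = as.numeric(time),
      absorbance = as.numeric(absorbance), meta = unclass(meta))
}

#' ChromatogramSet: aligned collection of traces on one grid
#'
#' Extends \code{SummarizedExperiment}: the single assay \code{"absorbance"}
#' is a time-by-sample matrix, \code{rowData} carries the shared time grid
#' (column \code{time_s}) and \code{colData} the per-sample metadata
#' (\code{cycle}, \code{pressure_bar}, \code{biomass_gdcw_per_l},
#' \code{frozen}, \code{condition_label}).
#'
#' @aliases ChromatogramSet
#' @exportClass ChromatogramSet
#' @import SummarizedExperiment
setClass("ChromatogramSet", contains = "SummarizedExperiment")

setValidity("ChromatogramSet", function(object) {
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'absorbance' is required")
  if (!"time_s" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData column 'time_s' is required")
  if (anyDuplicated(colnames(object)))
    return("sample_ids must be unique")
  tm <- SummarizedExperiment::rowData(object)$time_s
  ok <- tryCatch({ check_uniform_grid(tm); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' Assemble a ChromatogramSet from Chromatogram objects
#'
#' All traces must share one time grid (identical length and spacing) and
#' carry unique sample ids.
#'
#' @param chroms a list of \code{Chromatogram} objects.
#' @return A \code{ChromatogramSet}.
#' @examples
#' tm <- seq(0, 9.8, by = 0.2)
#' c1 <- chromatogram(tm, sin(tm), sampleMeta("a", 0, 1500, 10))
#' c2 <- chromatogram(tm, cos(tm), sampleMeta("b", 1, 1500, 10))
#' chromatogramSet(list(c1, c2))
#' @export
chromatogramSet <- function(chroms) {
  if (!is.list(chroms) || length(chroms) == 0L)
    stop("'chroms' must be a non-empty list of Chromatogram objects")
  if (!all(vapply(chroms, is, logical(1), "Chromatogram")))
    stop("all elements must be Chromatogram objects")
  tm <- chroms[[1L]]@time
  for (ch in chroms[-1L]) {
    if (length(ch@time) != length(tm) ||
        max(abs(ch@time - tm)) > 1e-9 * max(1, abs(tm[length(tm)])))
      stop("all traces must share one time grid")
  }
  ids <- vapply(chroms, function(ch) ch@meta$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample_ids must be unique")
  mat <- vapply(chroms, function(ch) ch@absorbance, numeric(length(tm)))
  colnames(mat) <- ids
  cd <- DataFrame(
    cycle = vapply(chroms, function(ch) ch@meta$cycle, integer(1)),
    pressure_bar = vapply(chroms, function(ch) ch@meta$pressure_bar, numeric(1)),
    biomass_gdcw_per_l = vapply(chroms, function(ch) ch@meta$biomass_gdcw_per_l,
                                numeric(1)),
    frozen = vapply(chroms, function(ch) ch@meta$frozen, logical(1)),
    condition_label = vapply(chroms, function(ch) ch@meta$condition_label,
                             character(1)),
    row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = mat),
    rowData = DataFrame(time_s = tm),
    colData = cd)
  new("ChromatogramSet", se)
}

#' AlignmentResult: an aligned set plus the shifts applied
#'
#' @slot aligned the shifted \code{ChromatogramSet}.
#' @slot shifts a \code{DataFrame} with columns \code{sample_id},
#'   \code{interval}, \code{shift_samples}, \code{correlation}.
#' @slot config the \code{alignmentConfig} list used.
#' @aliases AlignmentResult
#' @exportClass AlignmentResult
setClass("AlignmentResult",
         slots = c(aligned = "ChromatogramSet", shifts = "DataFrame",
                   config = "list"))

#' DoEModel: fitted coded-factor screening model
#'
#' Ordinary least squares on coded factors (intercept, main effects and,
#' optionally, two-factor interactions) with goodness of fit R2, goodness
#' of prediction Q2 from leave-one-out PRESS, and per-coefficient two-sided
#' p-values.
#'
#' @slot coefficients named numeric vector on the coded scale.
#' @slot pValues named numeric vector, same names.
#' @slot r2,q2 numeric scalars; \code{q2 <= r2 <= 1}.
#' @slot press numeric scalar, leave-one-out prediction error sum of squares.
#' @slot coding data.frame mapping each factor to its min/max level.
#' @slot fit the underlying \code{lm} object.
#' @aliases DoEModel
#' @exportClass DoEModel
setClass("DoEModel",
         slots = c(coefficients = "numeric", pValues = "numeric",
                   r2 = "numeric", q2 = "numeric", press = "numeric",
                   coding = "data.frame", fit = "ANY"))

setValidity("DoEModel", function(object) {
  if (length(object@r2) != 1L || object@r2 > 1 + 1e-12)
    return("r2 must be a scalar <= 1")
  if (object@q2 > object@r2 + 1e-12) return("q2 must not exceed r2")
  if (any(object@pValues < -1e-12 | object@pValues > 1 + 1e-12))
    return("p-values must lie in [0, 1]")
  TRUE
})

#' ContourGrid: model predictions over two factors
#'
#' @slot axisNames character(2), factor names of the two axes.
#' @slot axis1,axis2 numeric grids in natural units.
#' @slot fixed named numeric, values of the remaining factors.
#' @slot predicted matrix, \code{length(axis1)} by \code{length(axis2)}.
#' @aliases ContourGrid
#' @exportClass ContourGrid
setClass("ContourGrid",
         slots = c(axisNames = "character", axis1 = "numeric",
                   axis2 = "numeric", fixed = "numeric",
                   predicted = "matrix"))

setValidity("ContourGrid", function(object) {
  d <- dim(object@predicted)
  if (d[1L] != length(object@axis1) || d[2L] != length(object@axis2))
    return("predicted dimensions must match the axis grids")
  TRUE
})
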