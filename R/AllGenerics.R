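#' @include AllClasses.R
NULL

#' Accessors for chromatogram objects
#'
#' \code{chromTime} returns the time grid in seconds, \code{absorbance} the
#' mAU trace (vector) or time-by-sample matrix, \code{samplingRate} the grid
#' rate in Hz, \code{chromMeta} the sample metadata, and \code{nChrom} the
#' number of traces in a set.
#'
#' @param object a \code{Chromatogram} or \code{ChromatogramSet}.
#' @return See the individual descriptions above.
#' @name chromatogram-accessors
#' @aliases chromTime absorbance samplingRate chromMeta nChrom
NULL

#' @rdname chromatogram-accessors
#' @export
setGeneric("chromTime", function(object) standardGeneric("chromTime"))
#' @rdname chromatogram-accessors
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))
#' @rdname chromatogram-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname chromatogram-accessors
#' @export
setGeneric("chromMeta", function(object) standardGeneric("chromMeta"))
#' @rdname chromatogram-accessors
#' @export
setGeneric("nChrom", function(object) standardGeneric("nChrom"))

#' @rdname chromatogram-accessors
setMethod("chromTime", "Chromatogram", function(object) object@time)
#' @rdname chromatogram-accessors
setMethod("chromTime", "ChromatogramSet",
          function(object) SummarizedExperiment::rowData(object)$time_s)
#' @rdname chromatogram-accessors
setMethod("absorbance", "Chromatogram", function(object) object@absorbance)
#' @rdname chromatogram-accessors
setMethod("absorbance", "ChromatogramSet",
          function(object) SummarizedExperiment::assay(object, "absorbance"))
#' @rdname chromatogram-accessors
setMethod("samplingRate", "Chromatogram",
          function(object) 1 / stats::median(diff(object@time)))
#' @rdname chromatogram-accessors
setMethod("samplingRate", "ChromatogramSet",
          function(object) 1 / stats::median(diff(chromTime(object))))
#' @rdname chromatogram-accessors
setMethod("chromMeta", "Chromatogram",
          function(object) structure(object@meta, class = "SampleMeta"))
#' @rdname chromatogram-accessors
setMethod("nChrom", "ChromatogramSet", function(object) ncol(object))

#' Extract one trace of a set as a Chromatogram
#'
#' @param set a \code{ChromatogramSet}.
#' @param i column index or sample id.
#' @return A \code{Chromatogram}.
#' @export
getChromatogram <- function(set, i) {
  stopifnot(is(set, "ChromatogramSet"))
  cd <- as.data.frame(SummarizedExperiment::colData(set))
  if (is.character(i)) i <- match(i, colnames(set))
  if (is.na(i) || i < 1L || i > ncol(set)) stop("no such trace")
  m <- sampleMeta(colnames(set)[i], cd$cycle[i], cd$pressure_bar[i],
                  cd$biomass_gdcw_per_l[i], cd$frozen[i],
                  cd$condition_label[i])
  chromatogram(chromTime(set), absorbance(set)[, i], m)
}

setMethod("show", "Chromatogram", function(object) {
  tm <- object@time
  cat("Chromatogram '", object@meta$sample_id, "': ",
      length(tm), " points, ", sprintf("%.1f", tm[1L]), "-",
      sprintf("%.1f", tm[length(tm)]), " s at ",
      sprintf("%.3g", 1 / stats::median(diff(tm))), " Hz; cycle ",
      object@meta$cycle, ", ", object@meta$pressure_bar, " bar, ",
      object@meta$biomass_gdcw_per_l, " g DCW/L\n", sep = "")
})

setMethod("show", "AlignmentResult", function(object) {
  cat("AlignmentResult: ", ncol(object@aligned), " traces, ",
      nrow(object@shifts), " shift records (max |shift| ",
      max(abs(object@shifts$shift_samples)), " samples)\n", sep = "")
})

setMethod("show", "DoEModel", function(object) {
  cat("DoEModel (coded factors)\n")
  tab <- data.frame(coefficient = signif(object@coefficients, 6),
                    p_value = signif(object@pValues, 4))
  print(tab)
  cat(sprintf("R2 = %.3f, Q2 = %.3f (LOO-PRESS)\n", object@r2, object@q2))
})

setMethod("show", "ContourGrid", function(object) {
  cat("ContourGrid: ", object@axisNames[1L], " (", length(object@axis1),
      ") x ", object@axisNames[2L], " (", length(object@axis2), "), fixed: ",
      paste(names(object@fixed), "=", object@fixed, collapse = ", "),
      "\n", sep = "")
})
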