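#' @include AllClasses.R
NULL

#' Region of interest on the chromatogram time axis
#'
#' Half-open window \code{[start_s, end_s)} in seconds from injection,
#' named for the peak it brackets: \code{"FT"} (flowthrough, unbound
#' material) or \code{"EL"} (salt-eluted material).
#'
#' @param name \code{"FT"} or \code{"EL"}.
#' @param start_s,end_s window bounds in seconds, \code{start_s < end_s}.
#' @return A list of class \code{RegionOfInterest}.
#' @export
roi <- function(name, start_s, end_s) {
  name <- match.arg(name, c("FT", "EL"))
  if (!is.numeric(start_s) || !is.numeric(end_s) || start_s >= end_s)
    stop("'start_s' must be smaller than 'end_s'")
  structure(list(name = name, start_s = as.numeric(start_s),
                 end_s = as.numeric(end_s)), class = "RegionOfInterest")
}

#' Trapezoidal AUC over a region of interest
#'
#' Composite trapezoid rule over the samples inside \code{[start_s,
#' end_s)}; partial intervals at the window bounds are handled by linear
#' interpolation of the trace at the bound, so the integral covers the
#' window exactly. Units: mAU·s.
#'
#' @param chrom a \code{Chromatogram}.
#' @param region a \code{\link{roi}} lying within the trace span.
#' @return AUC in mAU·s.
#' @export
integrateRoi <- function(chrom, region) {
  stopifnot(is(chrom, "Chromatogram"), inherits(region, "RegionOfInterest"))
  tm <- chrom@time; y <- chrom@absorbance
  a <- region$start_s; b <- region$end_s
  if (a < tm[1L] - 1e-9 || b > tm[length(tm)] + 1e-9)
    stop("ROI [", a, ", ", b, ") lies outside the trace span")
  b <- min(b, tm[length(tm)]); a <- max(a, tm[1L])
  inner <- tm > a & tm < b
  xs <- c(a, tm[inner], b)
  vs <- c(stats::approx(tm, y, xout = a)$y, y[inner],
          stats::approx(tm, y, xout = b)$y)
  dx <- diff(xs)
  sum(dx * (vs[-length(vs)] + vs[-1L]) / 2)
}

#' Flowthrough and elution peak areas of one trace
#'
#' Integrates the FT and EL windows (optionally after subtracting, per
#' window, the straight line through the trace values at the window
#' bounds), clips negative areas to zero with a warning, and reports their
#' sum as the total AUC.
#'
#' @param chrom a \code{Chromatogram}.
#' @param ft,el disjoint \code{\link{roi}} windows.
#' @param baseline logical; subtract the per-window linear baseline?
#'   Off by default.
#' @return A one-row data.frame: \code{sample_id}, \code{cycle},
#'   \code{auc_ft}, \code{auc_el}, \code{auc_total} (mAU·s).
#' @export
peakAreas <- function(chrom, ft, el, baseline = FALSE) {
  stopifnot(is(chrom, "Chromatogram"))
  if (!(ft$end_s <= el$start_s || el$end_s <= ft$start_s))
    stop("FT and EL windows must be disjoint")
  one <- function(region) {
    a <- integrateRoi(chrom, region)
    if (baseline) {
      tm <- chrom@time; y <- chrom@absorbance
      ya <- stats::approx(tm, y, xout = region$start_s)$y
      yb <- stats::approx(tm, y, xout = min(region$end_s, tm[length(tm)]))$y
      a <- a - (ya + yb) / 2 *
        (min(region$end_s, tm[length(tm)]) - region$start_s)
    }
    if (a < 0) {
      warning("negative ", region$name, " area clipped to 0 for sample ",
              chrom@meta$sample_id)
      a <- 0
    }
    a
  }
  auc_ft <- one(ft); auc_el <- one(el)
  data.frame(sample_id = chrom@meta$sample_id, cycle = chrom@meta$cycle,
             auc_ft = auc_ft, auc_el = auc_el,
             auc_total = auc_ft + auc_el)
}

#' Peak areas for every trace of a set
#'
#' @param set a \code{ChromatogramSet}.
#' @inheritParams peakAreas
#' @return A data.frame with one row per trace, ordered by cycle.
#' @export
peakAreaTable <- function(set, ft, el, baseline = FALSE) {
  stopifnot(is(set, "ChromatogramSet"))
  out <- do.call(rbind, lapply(seq_len(ncol(set)), function(j)
    peakAreas(getChromatogram(set, j), ft, el, baseline)))
  out[order(out$cycle), , drop = FALSE]
}

#' Relative protein recovery (start/end-anchored ratio)
#'
#' The recovery statistic
#' \deqn{100 (AUC_i - AUC_{Start}) / (AUC_{End} - AUC_{Start})}
#' where Start and End are the first and last cycle of the series: 0\% at
#' the first cycle, 100\% at the last, and invariant under positive affine
#' transforms of the AUC series.
#'
#' @param auc numeric vector of total AUC values in cycle order, length
#'   >= 2.
#' @return Percent recovery per cycle.
#' @export
relativeRecoveryEq2 <- function(auc) {
  if (length(auc) < 2L) stop("need at least two cycles")
  denom <- auc[length(auc)] - auc[1L]
  if (denom == 0)
    stop("recovery undefined: AUC_End equals AUC_Start")
  (auc - auc[1L]) / denom * 100
}

#' End-anchored normalization (protein convention)
#'
#' \code{value_i / value_last * 100}: the final cycle is taken as 100\%,
#' the convention used for total-protein columns in multi-method
#' comparison tables.
#'
#' @param x numeric vector in cycle order; last element must be nonzero.
#' @return Percent of the final value.
#' @export
normalizeEndAnchored <- function(x) {
  if (!length(x)) stop("empty series")
  if (x[length(x)] == 0) stop("final value is zero; cannot end-anchor")
  x / x[length(x)] * 100
}

#' Start-anchored normalization (viability convention)
#'
#' \code{value_i / value_first * 100}: the untreated "0 sample" is taken as
#' 100\%, the convention for viability signals (plate counts, flow
#' cytometry, delta capacitance).
#'
#' @param x numeric vector in cycle order; first element must be nonzero.
#' @return Percent of the initial value.
#' @export
normalizeStartAnchored <- function(x) {
  if (!length(x)) stop("empty series")
  if (x[1L] == 0) stop("first value is zero; cannot start-anchor")
  x / x[1L] * 100
}

#' Biomass normalization of an AUC signal
#'
#' @param auc AUC in mAU·s.
#' @param biomass biomass concentration in g DCW/L, > 0.
#' @return AUC per unit biomass, mAU·s per (g DCW/L).
#' @export
normalizePerBiomass <- function(auc, biomass) {
  if (any(biomass <= 0)) stop("'biomass' must be > 0")
  auc / biomass
}

#' OD600 to dry-cell-weight conversion
#'
#' Linear correlation \eqn{y = 0.451 x} between the optical density at
#' 600 nm and the biomass concentration in g DCW/L;
#' \code{dcwToOd} inverts it to give the OD required for a target biomass.
#'
#' @param od600 optical density, >= 0.
#' @return Biomass concentration in g DCW/L.
#' @examples
#' odToDcw(1.0)      # 0.451
#' dcwToOd(10)       # ~22.17
#' @export
odToDcw <- function(od600) {
  if (any(od600 < 0)) stop("'od600' must be >= 0")
  0.451 * od600
}

#' @rdname odToDcw
#' @param dcw target biomass in g DCW/L, >= 0.
#' @export
dcwToOd <- function(dcw) {
  if (any(dcw < 0)) stop("'dcw' must be >= 0")
  dcw / 0.451
}

#' Cycle-indexed recovery table under both conventions
#'
#' Assembles the per-cycle total AUC with the start/end-ratio recovery
#' (0\% at cycle 0, 100\% at the final cycle) and the end-anchored percent
#' (final cycle = 100\%).
#'
#' @param areas a peak-area table from \code{\link{peakAreaTable}}.
#' @return A data.frame: \code{cycle}, \code{auc_total},
#'   \code{recovery_pct} (ratio convention), \code{end_anchored_pct}.
#' @export
recoveryTable <- function(areas) {
  stopifnot(all(c("cycle", "auc_total") %in% names(areas)))
  areas <- areas[order(areas$cycle), , drop = FALSE]
  if (anyDuplicated(areas$cycle)) stop("cycles must be unique")
  data.frame(cycle = areas$cycle, auc_total = areas$auc_total,
             recovery_pct = relativeRecoveryEq2(areas$auc_total),
             end_anchored_pct = normalizeEndAnchored(areas$auc_total))
}

#' Propose FT/EL window bounds from a reference trace
#'
#' Heuristic for unconfigured runs: the two largest local maxima of the
#' reference are taken as the FT and EL apexes and the deepest valley
#' between them as the split point; FT spans from the trace start to the
#' valley, EL from the valley to the trace end.
#'
#' @param reference a \code{Chromatogram} (typically from
#'   \code{\link{buildReference}}).
#' @return A list with elements \code{ft} and \code{el} (\code{\link{roi}}).
#' @export
proposeRoi <- function(reference) {
  stopifnot(is(reference, "Chromatogram"))
  tm <- reference@time; y <- reference@absorbance
  n <- length(y)
  ismax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
               y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(ismax)
  if (length(peaks) < 2L) stop("fewer than two peaks in the reference")
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1L] + which.min(y[top2[1L]:top2[2L]]) - 1L
  list(ft = roi("FT", tm[1L], tm[valley]),
       el = roi("EL", tm[valley], tm[n]))
}
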