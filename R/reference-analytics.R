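#' @include AllClasses.R
NULL

#' Colony count to CFU/mL
#'
#' Back-calculates the viable titre from one plate of a 1:10 serial
#' dilution series: \code{colonies / plated_volume_ml * 10^(-dilution_exp)}.
#'
#' @param colonies integer >= 0, colonies counted on the plate.
#' @param dilution_exp integer <= 0, log10 of the plated dilution (e.g. -6
#'   for the 10^-6 plate).
#' @param plated_volume_ml plated volume in mL (default 0.1, i.e. 100 uL).
#' @return CFU per mL of the undiluted suspension.
#' @examples
#' cfuPerMl(50, -6)   # 5e8
#' @export
cfuPerMl <- function(colonies, dilution_exp, plated_volume_ml = 0.1) {
  if (any(colonies < 0)) stop("'colonies' must be >= 0")
  if (any(dilution_exp > 0)) stop("'dilution_exp' must be <= 0")
  if (any(plated_volume_ml <= 0)) stop("'plated_volume_ml' must be > 0")
  colonies / plated_volume_ml * 10^(-dilution_exp)
}

#' Select the countable plate of a dilution series
#'
#' Standard 30-300 countable-range rule: among plates whose colony count
#' falls in \code{range}, pick the one closest to \code{target} colonies;
#' if none is in range, pick the plate nearest the range. Ties go to the
#' higher dilution (more negative \code{dilution_exp}).
#'
#' @param plates data.frame with columns \code{dilution_exp} and
#'   \code{colonies} (one row per plate of one sample).
#' @param range countable-range bounds, default \code{c(30, 300)}.
#' @param target preferred count within range, default 100.
#' @return The selected row of \code{plates}.
#' @export
selectCountablePlate <- function(plates, range = c(30, 300), target = 100) {
  stopifnot(is.data.frame(plates),
            all(c("dilution_exp", "colonies") %in% names(plates)))
  if (!nrow(plates)) stop("no plates supplied")
  inr <- plates$colonies >= range[1L] & plates$colonies <= range[2L]
  if (any(inr)) {
    cand <- plates[inr, , drop = FALSE]
    key <- abs(cand$colonies - target)
  } else {
    cand <- plates
    key <- pmax(range[1L] - cand$colonies, cand$colonies - range[2L], 0)
  }
  # ties -> higher dilution = more negative exponent
  cand[order(key, cand$dilution_exp), , drop = FALSE][1L, , drop = FALSE]
}

#' Viable-cell count from dual-dye flow cytometry
#'
#' RH414 stains all cells; DiBAC4(3) stains membrane-compromised (dead)
#' cells. Viable = total - dead.
#'
#' @param total_rh414 total event count (RH414 positive), >= 0.
#' @param dead_dibac dead event count (DiBAC4(3) positive), <=
#'   \code{total_rh414}.
#' @return Viable event count.
#' @export
fcViable <- function(total_rh414, dead_dibac) {
  if (any(total_rh414 < 0) || any(dead_dibac < 0))
    stop("counts must be >= 0")
  if (any(dead_dibac > total_rh414))
    stop("dead count exceeds total count")
  total_rh414 - dead_dibac
}

#' Delta-capacitance signal from a dual-frequency trace
#'
#' Mean over the logged trace of (low-frequency minus high-frequency)
#' capacitance; the low frequency (~1 MHz) polarizes viable cells, the
#' high frequency (~10 MHz) reads the non-cellular background.
#'
#' @param cap_low_freq,cap_high_freq numeric traces of equal length.
#' @return Mean delta capacitance.
#' @export
dsSignal <- function(cap_low_freq, cap_high_freq) {
  if (!length(cap_low_freq)) stop("empty capacitance trace")
  if (length(cap_low_freq) != length(cap_high_freq))
    stop("capacitance traces must have equal length")
  mean(cap_low_freq - cap_high_freq)
}

#' Five-method comparison table
#'
#' Normalizes each method's per-cycle series onto a common percent scale:
#' total-protein methods (e.g. Bradford, HPLC) are end-anchored (final
#' cycle = 100\%), viability methods (e.g. DS, CfUs, FC) are
#' start-anchored (cycle 0 = 100\%), then assembled into one table with
#' rows = cycles, columns = methods.
#'
#' @param protein named list of numeric per-cycle series for
#'   protein-release methods.
#' @param viability named list of numeric per-cycle series for viability
#'   methods.
#' @param cycles integer vector of cycles, shared by every series.
#' @return A data.frame: \code{cycle} plus one percent column per method.
#' @export
buildComparison <- function(protein, viability, cycles) {
  series <- c(protein, viability)
  if (!length(series)) stop("no method series supplied")
  lens <- vapply(series, length, integer(1))
  if (any(lens != length(cycles)))
    stop("method series ", paste(names(series)[lens != length(cycles)],
                                 collapse = ", "),
         " do not cover the cycle set")
  out <- data.frame(cycle = cycles)
  for (nm in names(protein)) out[[nm]] <- normalizeEndAnchored(protein[[nm]])
  for (nm in names(viability))
    out[[nm]] <- normalizeStartAnchored(viability[[nm]])
  out
}
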