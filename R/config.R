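#' @include AllClasses.R
NULL

# allowed keys of the run-config file, by section
.config_schema <- list(
  seed = NULL,
  n_cycles = NULL,
  efficiency = NULL,
  baseline_frac = NULL,
  baseline_subtract = NULL,
  convention = NULL,
  sim = c("run_length_s", "sampling_rate_hz", "noise_sd", "baseline_drift",
          "shift_jitter_max", "ft_peak", "el_peak"),
  align = c("max_shift_samples", "intervals"),
  roi = c("ft", "el"),
  doe = c("interactions")
)
.peak_keys <- c("center_s", "width_s", "area")
.roi_keys <- c("start_s", "end_s")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads the YAML run configuration used by the command-line interface.
#' Unknown keys are rejected by name; omitted keys fall back to the
#' package defaults (5-cycle run at 1500 bar with the default simulator
#' settings, whole-trace alignment with a 10-sample search window, FT
#' window [30, 120) s and EL window [160, 280) s).
#'
#' @param path path to a YAML file, or \code{NULL} for all defaults.
#' @return A validated list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, names(.config_schema), "top level")
  for (sec in c("sim", "align", "roi", "doe"))
    if (!is.null(raw[[sec]]))
      check_keys(raw[[sec]], .config_schema[[sec]], sec)
  for (pk in c("ft_peak", "el_peak"))
    if (!is.null(raw$sim[[pk]]))
      check_keys(raw$sim[[pk]], .peak_keys, paste0("sim/", pk))
  for (rk in c("ft", "el"))
    if (!is.null(raw$roi[[rk]]))
      check_keys(raw$roi[[rk]], .roi_keys, paste0("roi/", rk))

  simargs <- raw$sim %||% list()
  for (pk in c("ft_peak", "el_peak"))
    if (!is.null(simargs[[pk]]))
      simargs[[pk]] <- do.call(peakSpec, simargs[[pk]])
  cfg <- list(
    seed = as.integer(raw$seed %||% 1L),
    n_cycles = as.integer(raw$n_cycles %||% 5L),
    efficiency = raw$efficiency %||% 0.85,
    baseline_frac = raw$baseline_frac %||% 0,
    baseline_subtract = isTRUE(raw$baseline_subtract %||% FALSE),
    convention = match.arg(raw$convention %||% "end-anchored",
                           c("end-anchored", "eq2")),
    sim = do.call(simConfig, simargs),
    align = alignmentConfig(
      max_shift_samples = raw$align$max_shift_samples %||% 10L,
      intervals = if (!is.null(raw$align$intervals))
        lapply(raw$align$intervals, function(iv) as.numeric(unlist(iv)))),
    roi_ft = roi("FT", raw$roi$ft$start_s %||% 30,
                 raw$roi$ft$end_s %||% 120),
    roi_el = roi("EL", raw$roi$el$start_s %||% 160,
                 raw$roi$el$end_s %||% 280),
    doe_interactions = isTRUE(raw$doe$interactions %||% TRUE)
  )
  structure(cfg, class = "RunConfig")
}

#' End-to-end recovery pipeline
#'
#' The at-line workflow on a loaded set: align every trace to the mean
#' reference, integrate the FT and EL windows, and tabulate per-cycle
#' recovery under both normalization conventions. The cycle-0 "0 sample"
#' must be present as the anchor.
#'
#' @param set a \code{ChromatogramSet} (one trace per cycle).
#' @param config a \code{\link{readRunConfig}} result (defaults if NULL).
#' @return A list: \code{recovery} (see \code{\link{recoveryTable}}),
#'   \code{areas}, \code{alignment} (the \code{AlignmentResult}).
#' @export
runRecovery <- function(set, config = NULL) {
  if (is.null(config)) config <- readRunConfig()
  stopifnot(is(set, "ChromatogramSet"))
  cyc <- SummarizedExperiment::colData(set)$cycle
  if (!0L %in% cyc)
    stop("missing cycle 0: the untreated '0 sample' is required as anchor")
  al <- alignSet(set, config$align)
  areas <- peakAreaTable(alignedSet(al), config$roi_ft, config$roi_el,
                         baseline = config$baseline_subtract)
  list(recovery = recoveryTable(areas), areas = areas, alignment = al)
}
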