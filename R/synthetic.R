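#' @include AllClasses.R
NULL

#' Gaussian peak specification
#'
#' @param center_s apex position in seconds.
#' @param width_s Gaussian sigma in seconds, > 0.
#' @param area peak area in mAU·s, >= 0.
#' @return A list of class \code{PeakSpec}.
#' @export
peakSpec <- function(center_s, width_s, area) {
  if (width_s <= 0) stop("'width_s' must be > 0")
  if (area < 0) stop("'area' must be >= 0")
  structure(list(center_s = center_s, width_s = width_s, area = area),
            class = "PeakSpec")
}

#' Simulation configuration for two-peak chromatograms
#'
#' Emulates a 5-minute anion-exchange run recorded at 5 Hz: an early
#' flowthrough peak, a later elution peak, a linear baseline drift, white
#' detector noise and integer retention-time jitter. The defaults describe
#' a 10 g DCW/L homogenate run: FT apex at 60 s (sigma 6 s, 2000 mAU·s at
#' full release), EL apex at 210 s (sigma 8 s, 3000 mAU·s), 0.5 mAU noise,
#' 2 mAU drift across the run and up to 3 samples of jitter.
#'
#' @param run_length_s run duration in seconds (default 300).
#' @param sampling_rate_hz detector rate in Hz (default 5).
#' @param ft_peak,el_peak \code{\link{peakSpec}} objects for the
#'   flowthrough and elution peaks at full protein release.
#' @param noise_sd white-noise standard deviation in mAU, >= 0.
#' @param baseline_drift linear baseline rise across the run in mAU.
#' @param shift_jitter_max maximum |retention jitter| in samples, >= 0.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(run_length_s = 300, sampling_rate_hz = 5,
                      ft_peak = peakSpec(60, 6, 2000),
                      el_peak = peakSpec(210, 8, 3000),
                      noise_sd = 0.5, baseline_drift = 2,
                      shift_jitter_max = 3L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  shift_jitter_max <- as.integer(shift_jitter_max)
  if (is.na(shift_jitter_max) || shift_jitter_max < 0L)
    stop("'shift_jitter_max' must be an integer >= 0")
  stopifnot(inherits(ft_peak, "PeakSpec"), inherits(el_peak, "PeakSpec"),
            run_length_s > 0, sampling_rate_hz > 0)
  structure(list(run_length_s = run_length_s,
                 sampling_rate_hz = sampling_rate_hz,
                 ft_peak = ft_peak, el_peak = el_peak,
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 shift_jitter_max = shift_jitter_max),
            class = "SimConfig")
}

gauss_peak <- function(t, spec, scale) {
  spec$area * scale / (spec$width_s * sqrt(2 * pi)) *
    exp(-(t - spec$center_s)^2 / (2 * spec$width_s^2))
}

#' Simulate one chromatogram
#'
#' Baseline drift plus the two Gaussian peaks, their areas scaled by
#' \code{protein_load}, plus white noise; both peak centers are displaced
#' by one uniformly drawn integer-sample retention jitter. The same seed
#' always yields a bit-identical trace.
#'
#' @param config a \code{\link{simConfig}}.
#' @param protein_load fraction of full protein release in [0, 1] scaling
#'   both peak areas.
#' @param seed integer seed for this trace.
#' @param meta optional \code{\link{sampleMeta}}; a generic one is built
#'   from the seed if omitted.
#' @return A \code{Chromatogram}.
#' @export
simulateChromatogram <- function(config, protein_load, seed, meta = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (protein_load < 0 || protein_load > 1)
    stop("'protein_load' must lie in [0, 1]")
  dt <- 1 / config$sampling_rate_hz
  tm <- seq(0, by = dt, length.out =
              round(config$run_length_s * config$sampling_rate_hz))
  with_seed(seed, {
    jit <- if (config$shift_jitter_max > 0L)
      sample.int(2L * config$shift_jitter_max + 1L, 1L) -
        config$shift_jitter_max - 1L else 0L
    ft <- config$ft_peak; el <- config$el_peak
    ft$center_s <- ft$center_s + jit * dt
    el$center_s <- el$center_s + jit * dt
    y <- config$baseline_drift * tm / tm[length(tm)] +
      gauss_peak(tm, ft, protein_load) +
      gauss_peak(tm, el, protein_load) +
      stats::rnorm(length(tm), 0, config$noise_sd)
    if (is.null(meta))
      meta <- sampleMeta(paste0("sim_", seed), 0L, 1500, 10)
    chromatogram(tm, y, meta)
  })
}

#' Cell-disruption kinetics (geometric survival per pass)
#'
#' Each homogenization pass disrupts the fraction \code{efficiency} of the
#' still-intact cells, so the cumulative released protein fraction after
#' \code{n} cycles is
#' \deqn{f(n) = f_0 + (1 - f_0)(1 - (1 - e)^n),}
#' nondecreasing and bounded by 1. \code{baseline_frac} \eqn{f_0} is the
#' protein already free at cycle 0 (e.g. freeze-thaw pre-lysis).
#'
#' @param efficiency per-cycle disruption efficiency e in (0, 1].
#' @param baseline_frac released fraction at cycle 0, in [0, 1).
#' @param total_protein total releasable protein in arbitrary units.
#' @return A list of class \code{DisruptionKinetics}.
#' @export
disruptionKinetics <- function(efficiency, baseline_frac = 0,
                               total_protein = 1) {
  if (efficiency <= 0 || efficiency > 1)
    stop("'efficiency' must lie in (0, 1]")
  if (baseline_frac < 0 || baseline_frac >= 1)
    stop("'baseline_frac' must lie in [0, 1)")
  structure(list(efficiency = efficiency, baseline_frac = baseline_frac,
                 total_protein = total_protein),
            class = "DisruptionKinetics")
}

#' @rdname disruptionKinetics
#' @param kinetics a \code{DisruptionKinetics}.
#' @param cycles integer vector of cycle numbers >= 0.
#' @return \code{releasedFraction}: cumulative released fraction f(n) per
#'   cycle.
#' @export
releasedFraction <- function(kinetics, cycles) {
  stopifnot(inherits(kinetics, "DisruptionKinetics"), all(cycles >= 0))
  f0 <- kinetics$baseline_frac
  f0 + (1 - f0) * (1 - (1 - kinetics$efficiency)^cycles)
}

#' Simulate a multi-cycle disruption experiment
#'
#' One chromatogram per cycle 0..\code{n_cycles}, the protein load at
#' cycle n set to the kinetics' released fraction f(n); the true fractions
#' are returned alongside for closed-loop testing.
#'
#' @param kinetics a \code{\link{disruptionKinetics}}.
#' @param n_cycles number of homogenization cycles >= 1 (default 5).
#' @param config a \code{\link{simConfig}}.
#' @param seed integer master seed; per-cycle seeds are derived from it.
#' @param pressure_bar,biomass_gdcw_per_l,frozen metadata for the run
#'   (defaults: 1500 bar, 10 g DCW/L, fresh).
#' @return A list: \code{set} (a \code{ChromatogramSet}, cycles 0..n) and
#'   \code{truth} (data.frame \code{cycle}, \code{released_frac}).
#' @export
simulateDisruptionExperiment <- function(kinetics, n_cycles = 5,
                                         config = simConfig(), seed = 1L,
                                         pressure_bar = 1500,
                                         biomass_gdcw_per_l = 10,
                                         frozen = FALSE) {
  stopifnot(inherits(kinetics, "DisruptionKinetics"), n_cycles >= 1)
  cycles <- 0:n_cycles
  f <- releasedFraction(kinetics, cycles)
  chroms <- lapply(seq_along(cycles), function(k) {
    m <- sampleMeta(sprintf("cycle%02d", cycles[k]), cycles[k],
                    pressure_bar, biomass_gdcw_per_l, frozen)
    simulateChromatogram(config, f[k], seed + 7919L * cycles[k], meta = m)
  })
  list(set = chromatogramSet(chroms),
       truth = data.frame(cycle = cycles, released_frac = f))
}

#' Estimate disruption kinetics from a recovery series
#'
#' Least-squares fit of \code{A * f(n)} (with f the geometric-survival
#' release curve) to a per-cycle AUC or percent series, over the
#' efficiency e, the cycle-0 baseline fraction f0 and the scale A.
#'
#' @param cycles integer vector of cycles (must include 0).
#' @param values per-cycle totals (AUC or normalized percent; the scale is
#'   absorbed by A).
#' @return A list: \code{efficiency}, \code{baseline_frac}, \code{scale},
#'   \code{sse}.
#' @export
estimateEfficiency <- function(cycles, values) {
  stopifnot(length(cycles) == length(values), length(cycles) >= 3L)
  sse <- function(p) {
    f <- p[2L] + (1 - p[2L]) * (1 - (1 - p[1L])^cycles)
    sum((values - p[3L] * f)^2)
  }
  a0 <- max(values)
  start <- c(e = 0.8, f0 = max(min(values[cycles == 0] / a0, 0.9), 0),
             A = a0)
  opt <- stats::optim(start, sse, method = "L-BFGS-B",
                      lower = c(1e-6, 0, 1e-9 * a0),
                      upper = c(1 - 1e-9, 0.999, 10 * a0))
  list(efficiency = unname(opt$par[1L]), baseline_frac = unname(opt$par[2L]),
       scale = unname(opt$par[3L]), sse = opt$value)
}

#' Simulate a DoE run table
#'
#' Generates the response of each design run from the coded screening
#' model (intercept, main effects, two-factor interactions) with given
#' coefficients plus seeded Gaussian noise.
#'
#' @param design a design data.frame from \code{\link{fullFactorial}}.
#' @param coefficients named numeric vector over the model terms (names as
#'   produced by \code{\link{fitScreeningModel}}, e.g. \code{"(Intercept)"},
#'   \code{"pressure_bar"}, \code{"pressure_bar:cycles"}). Terms omitted
#'   from the model family are an error.
#' @param noise_sd response noise standard deviation (default 0).
#' @param seed integer seed.
#' @param interactions must match the fitter's term set (default TRUE).
#' @return The design with a \code{response} column appended.
#' @export
simulateDoeDataset <- function(design, coefficients, noise_sd = 0,
                               seed = 1L, interactions = TRUE) {
  coded <- codeFactors(design)
  fn <- attr(coded, "coding")$factor
  X <- stats::model.matrix(
    stats::as.formula(paste("~", if (interactions && length(fn) > 1L)
      paste0("(", paste(fn, collapse = " + "), ")^2")
      else paste(fn, collapse = " + "))),
    data = coded[, fn, drop = FALSE])
  extra <- setdiff(names(coefficients), colnames(X))
  if (length(extra))
    stop("coefficients name terms outside the model family: ",
         paste(extra, collapse = ", "))
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[names(coefficients)] <- coefficients
  mu <- as.numeric(X %*% beta)
  out <- design
  out$response <- with_seed(seed,
    mu + stats::rnorm(length(mu), 0, noise_sd))
  out
}
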