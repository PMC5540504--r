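# shared in-code fixtures

grid_5hz <- function(len_s = 300) seq(0, by = 0.2, length.out = len_s * 5)

gauss_trace <- function(tm, center, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-(tm - center)^2 / (2 * sigma^2))
}

make_chrom <- function(y, tm = NULL, id = "s1", cycle = 0) {
  if (is.null(tm)) tm <- seq(0, by = 0.2, length.out = length(y))
  chromatogram(tm, y, sampleMeta(id, cycle, 1500, 10))
}

# two-peak trace like the simulator's, but deterministic
two_peak_trace <- function(tm, load = 1, ft_area = 2000, el_area = 3000) {
  gauss_trace(tm, 60, 6, ft_area * load) + gauss_trace(tm, 210, 8, el_area * load)
}

# very fine midpoint Riemann sum, the integration oracle
riemann_oracle <- function(f, a, b, n = 2e5) {
  x <- seq(a, b, length.out = n + 1L)
  mid <- (x[-1L] + x[-length(x)]) / 2
  sum(f(mid)) * (b - a) / n
}

wp3_factors <- function() list(
  factorSpec("pressure_bar", c(500, 1000, 1500)),
  factorSpec("biomass_gdcw_per_l", c(10, 55, 100)),
  factorSpec("cycles", 0:3, "quantitative-multilevel"))
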