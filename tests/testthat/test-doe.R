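test_that("the full factorial enumerates every level combination", {
  d <- fullFactorial(wp3_factors())
  expect_equal(nrow(d), 36)
  expect_false(anyDuplicated(d[, -1]) > 0)
  # the design-space corner is present
  expect_true(any(d$pressure_bar == 500 & d$biomass_gdcw_per_l == 10 &
                    d$cycles == 0))
  # lexicographic: first factor varies slowest
  expect_equal(d$pressure_bar[1:12], rep(500, 12))
  expect_equal(d$cycles[1:4], 0:3)

  expect_equal(nrow(fullFactorial(list(factorSpec("a", c(0, 1))))), 2)
  expect_error(fullFactorial(list()), "empty")
  expect_error(factorSpec("a", 5), ">= 2")
})

test_that("coding maps min/max to -1/+1 and multilevels affinely", {
  d <- fullFactorial(wp3_factors())
  cd <- codeFactors(d)
  expect_setequal(unique(cd$pressure_bar), c(-1, 0, 1))
  expect_setequal(unique(cd$biomass_gdcw_per_l), c(-1, 0, 1))
  expect_equal(sort(unique(cd$cycles)), (0:3 - 1.5) / 1.5)
  expect_error(codeFactors(data.frame(a = c(2, 2)), "a"), "constant")
})

test_that("coded main-effect columns of the symmetric factors are orthogonal", {
  cd <- codeFactors(fullFactorial(wp3_factors()))
  expect_equal(sum(cd$pressure_bar * cd$biomass_gdcw_per_l), 0)
  expect_equal(sum(cd$pressure_bar * cd$cycles), 0)
  expect_equal(sum(cd$pressure_bar), 0)
  expect_equal(sum(cd$biomass_gdcw_per_l), 0)
})

test_that("a noise-free linear response is recovered exactly", {
  d <- fullFactorial(wp3_factors())
  truth <- c("(Intercept)" = 50, pressure_bar = 0.5,
             biomass_gdcw_per_l = -12, cycles = 20,
             "biomass_gdcw_per_l:cycles" = -4)
  tab <- simulateDoeDataset(d, truth, noise_sd = 0, seed = 1)
  m <- fitScreeningModel(tab, tab$response)
  cf <- modelCoefficients(m)
  expect_equal(cf[names(truth)], truth, tolerance = 1e-9)
  expect_equal(unname(cf[setdiff(names(cf), names(truth))]),
               rep(0, length(cf) - length(truth)), tolerance = 1e-9)
  expect_equal(modelR2(m), 1, tolerance = 1e-9)
  expect_lte(modelQ2(m), modelR2(m))
})

test_that("Q2 <= R2 holds across seeded noisy fits", {
  d <- fullFactorial(wp3_factors())
  truth <- c("(Intercept)" = 50, cycles = 20, biomass_gdcw_per_l = -12)
  for (s in 1:20) {
    tab <- simulateDoeDataset(d, truth, noise_sd = 5, seed = s)
    m <- fitScreeningModel(tab, tab$response)
    expect_lte(modelQ2(m), modelR2(m))
    expect_true(all(modelPValues(m) >= 0 & modelPValues(m) <= 1))
  }
})

test_that("Q2 matches a literal leave-one-out refit loop", {
  d <- fullFactorial(wp3_factors())
  tab <- simulateDoeDataset(d, c("(Intercept)" = 10, cycles = 5),
                            noise_sd = 2, seed = 4)
  m <- fitScreeningModel(tab, tab$response)
  cd <- codeFactors(tab)
  dat <- cd[, c("pressure_bar", "biomass_gdcw_per_l", "cycles")]
  dat$.response <- tab$response
  press <- sum(vapply(seq_len(nrow(dat)), function(i) {
    fit <- lm(.response ~ (pressure_bar + biomass_gdcw_per_l + cycles)^2,
              data = dat[-i, ])
    (dat$.response[i] - predict(fit, newdata = dat[i, ]))^2
  }, numeric(1)))
  sstot <- sum((tab$response - mean(tab$response))^2)
  expect_equal(modelQ2(m), 1 - press / sstot, tolerance = 1e-9)
})

test_that("a pressure-null response keeps the pressure effect near zero", {
  d <- fullFactorial(wp3_factors())
  truth <- c("(Intercept)" = 50, biomass_gdcw_per_l = -12, cycles = 20)
  coefs <- vapply(1:20, function(s) {
    tab <- simulateDoeDataset(d, truth, noise_sd = 4, seed = 1000 + s)
    modelCoefficients(fitScreeningModel(tab, tab$response))[["pressure_bar"]]
  }, numeric(1))
  # OLS on the orthogonal coded column: sd of the estimate is
  # noise_sd / sqrt(sum(x^2)) = 4 / sqrt(24)
  expect_lt(abs(mean(coefs)), 3 * 4 / sqrt(24) / sqrt(20))
  expect_lt(max(abs(coefs)), 4 * 4 / sqrt(24))
})

test_that("rank deficiency and degenerate inputs are diagnosed by name", {
  d <- fullFactorial(wp3_factors())
  d2 <- d; d2$dup <- d2$cycles  # aliased factor
  expect_error(
    fitScreeningModel(d2, seq_len(nrow(d2)),
                      factor_names = c("pressure_bar", "cycles", "dup"),
                      interactions = FALSE),
    "aliased.*dup")
  expect_error(fitScreeningModel(d, rep(1, nrow(d))), "constant response")
  expect_error(fitScreeningModel(d, c(NA, rep(1, nrow(d) - 1))), "finite")
})

test_that("surface prediction equals a per-point loop and honors null factors", {
  d <- fullFactorial(wp3_factors())
  truth <- c("(Intercept)" = 40, biomass_gdcw_per_l = -10, cycles = 15,
             "biomass_gdcw_per_l:cycles" = -3)
  tab <- simulateDoeDataset(d, truth, noise_sd = 0, seed = 2)
  m <- fitScreeningModel(tab, tab$response)
  g <- predictSurface(m, axis1 = list(name = "cycles", grid = 0:3),
                      axis2 = list(name = "biomass_gdcw_per_l",
                                   grid = c(10, 55, 100)),
                      fixed = c(pressure_bar = 1500))
  # pointwise oracle from the generating coefficients
  for (i in 1:4) for (j in 1:3) {
    cc <- (0:3)[i]; bb <- c(10, 55, 100)[j]
    cyc <- (cc - 1.5) / 1.5; bio <- (bb - 55) / 45
    expect_equal(g@predicted[i, j],
                 40 - 10 * bio + 15 * cyc - 3 * bio * cyc,
                 tolerance = 1e-9)
  }
  # zero pressure terms: surfaces at 500 and 1500 bar coincide
  g2 <- predictSurface(m, axis1 = list(name = "cycles", grid = 0:3),
                       axis2 = list(name = "biomass_gdcw_per_l",
                                    grid = c(10, 55, 100)),
                       fixed = c(pressure_bar = 500))
  expect_equal(g@predicted, g2@predicted, tolerance = 1e-9)
  # prediction at a design corner equals the fitted value there
  corner <- which(tab$pressure_bar == 1500 & tab$biomass_gdcw_per_l == 10 &
                    tab$cycles == 0)
  expect_equal(g@predicted[1, 1], tab$response[corner], tolerance = 1e-9)
  expect_error(predictSurface(m, list(name = "nope", grid = 1:2),
                              list(name = "cycles", grid = 0:3),
                              c(pressure_bar = 1500)), "exactly once")
  expect_warning(predictSurface(m, list(name = "cycles", grid = 0:5),
                                list(name = "biomass_gdcw_per_l",
                                     grid = c(10, 100)),
                                c(pressure_bar = 1500)), "extrapolat")
})

test_that("coefficient estimates converge as noise shrinks", {
  d <- fullFactorial(wp3_factors())
  truth <- c("(Intercept)" = 50, biomass_gdcw_per_l = -12, cycles = 20)
  err <- vapply(c(4, 1, 0.25), function(sd) {
    e <- 0
    for (s in 1:5) {
      tab <- simulateDoeDataset(d, truth, noise_sd = sd, seed = 200 + s)
      m <- fitScreeningModel(tab, tab$response)
      e <- e + max(abs(modelCoefficients(m)[names(truth)] - truth))
    }
    e / 5
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
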