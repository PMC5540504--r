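test_that("trapezoid integration is exact on flats and triangles", {
  tm <- grid_5hz(60)
  const <- make_chrom(rep(1, length(tm)), tm)
  expect_equal(integrateRoi(const, roi("FT", 20, 30)), 10, tolerance = 1e-12)

  # symmetric triangle of height 4 over width 20, apex on a grid point
  tri <- make_chrom(pmax(0, 4 * (1 - abs(tm - 30) / 10)), tm)
  expect_equal(integrateRoi(tri, roi("FT", 20, 40)), 40, tolerance = 1e-12)
})

test_that("partial boundary intervals are interpolated", {
  tm <- seq(0, 10, by = 1)
  lin <- make_chrom(tm, tm)  # y = t, integral of [a,b) = (b^2-a^2)/2
  expect_equal(integrateRoi(lin, roi("FT", 0.5, 9.5)),
               (9.5^2 - 0.5^2) / 2, tolerance = 1e-12)
})

test_that("trapezoid AUC matches the fine Riemann oracle on Gaussians", {
  tm <- grid_5hz(300)
  set.seed(21)
  for (i in 1:10) {
    c0 <- runif(1, 60, 240); s0 <- runif(1, 2, 12); a0 <- runif(1, 10, 500)
    ch <- make_chrom(gauss_trace(tm, c0, s0, a0), tm)
    win <- roi("FT", max(0, c0 - 8 * s0), min(299, c0 + 8 * s0))
    oracle <- riemann_oracle(function(x) gauss_trace(x, c0, s0, a0),
                             win$start_s, win$end_s)
    expect_equal(integrateRoi(ch, win), oracle, tolerance = 1e-3)
  }
})

test_that("integration agrees with pracma's trapezoid on full-sample windows", {
  skip_if_not_installed("pracma")
  tm <- grid_5hz(100)
  y <- gauss_trace(tm, 50, 5, 100) + 0.3
  ch <- make_chrom(y, tm)
  idx <- tm >= 20 & tm <= 80
  expect_equal(integrateRoi(ch, roi("FT", 20, 80)),
               pracma::trapz(tm[idx], y[idx]), tolerance = 1e-9)
})

test_that("ROI validation errors fire", {
  ch <- make_chrom(rep(1, 100))
  expect_error(integrateRoi(ch, roi("FT", -5, 10)), "outside")
  expect_error(roi("FT", 10, 10), "smaller")
  expect_error(peakAreas(ch, roi("FT", 0, 10), roi("EL", 5, 15)), "disjoint")
})

test_that("peak areas recover two constructed unit peaks and a total", {
  tm <- grid_5hz(300)
  ch <- make_chrom(gauss_trace(tm, 60, 4, 1) + gauss_trace(tm, 210, 5, 1), tm)
  pa <- peakAreas(ch, roi("FT", 20, 120), roi("EL", 160, 280))
  expect_equal(pa$auc_ft, 1, tolerance = 1e-3)
  expect_equal(pa$auc_el, 1, tolerance = 1e-3)
  expect_equal(pa$auc_total, pa$auc_ft + pa$auc_el, tolerance = 1e-12)

  flat <- make_chrom(rep(0, length(tm)), tm)
  pf <- peakAreas(flat, roi("FT", 20, 120), roi("EL", 160, 280))
  expect_equal(unlist(pf[c("auc_ft", "auc_el", "auc_total")]),
               c(auc_ft = 0, auc_el = 0, auc_total = 0))
})

test_that("linear baseline subtraction removes a constant offset", {
  tm <- grid_5hz(300)
  y <- gauss_trace(tm, 60, 4, 100) + gauss_trace(tm, 210, 5, 150)
  ft <- roi("FT", 20, 120); el <- roi("EL", 160, 280)
  clean <- peakAreas(make_chrom(y, tm), ft, el)
  offset <- peakAreas(make_chrom(y + 5, tm), ft, el, baseline = TRUE)
  expect_equal(offset$auc_ft, clean$auc_ft, tolerance = 1e-6)
  expect_equal(offset$auc_el, clean$auc_el, tolerance = 1e-6)
})

test_that("negative areas are clipped to zero with a warning", {
  ch <- make_chrom(rep(-1, 100))
  expect_warning(pa <- peakAreas(ch, roi("FT", 0, 5), roi("EL", 10, 15)),
                 "clipped")
  expect_equal(pa$auc_total, 0)
})

test_that("FT + EL equals the union when the windows tile it", {
  tm <- grid_5hz(300)
  ch <- make_chrom(two_peak_trace(tm) + 1, tm)
  a <- integrateRoi(ch, roi("FT", 10, 150)) +
    integrateRoi(ch, roi("EL", 150, 290))
  expect_equal(a, integrateRoi(ch, roi("FT", 10, 290)), tolerance = 1e-9)
})

test_that("the start/end-ratio recovery is pinned at 0 and 100", {
  auc <- c(10, 55, 100)
  r <- relativeRecoveryEq2(auc)
  expect_equal(r, c(0, 50, 100))
  expect_error(relativeRecoveryEq2(c(5, 7, 5)), "undefined")
  expect_error(relativeRecoveryEq2(7), "two cycles")
})

test_that("ratio recovery is affine-invariant; end-anchored is scale-invariant", {
  set.seed(33)
  for (i in 1:20) {
    auc <- sort(runif(6, 10, 1000))
    a <- runif(1, 0.1, 5); b <- runif(1, -50, 50)
    expect_equal(relativeRecoveryEq2(a * auc + b), relativeRecoveryEq2(auc),
                 tolerance = 1e-9)
    expect_equal(normalizeEndAnchored(a * auc), normalizeEndAnchored(auc),
                 tolerance = 1e-9)
    # end-anchored is NOT invariant under shifts
    expect_false(isTRUE(all.equal(normalizeEndAnchored(auc + 100),
                                  normalizeEndAnchored(auc))))
  }
})

test_that("normalization anchors and errors behave per convention", {
  expect_equal(normalizeEndAnchored(c(2, 16, 20)), c(10, 80, 100))
  expect_equal(normalizeEndAnchored(c(3, 3, 3)), c(100, 100, 100))
  expect_error(normalizeEndAnchored(c(1, 0)), "zero")
  expect_equal(normalizeStartAnchored(c(200, 30)), c(100, 15))
  expect_equal(normalizeStartAnchored(c(4, 4)), c(100, 100))
  expect_error(normalizeStartAnchored(c(0, 1)), "zero")
})

test_that("biomass normalization is a guarded ratio", {
  expect_equal(normalizePerBiomass(500, 10), 50)
  expect_equal(normalizePerBiomass(0, 10), 0)
  expect_equal(normalizePerBiomass(3 * 500, 3 * 10),
               normalizePerBiomass(500, 10))
  expect_error(normalizePerBiomass(500, 0), "> 0")
})

test_that("OD600 converts to dry cell weight by the linear correlation", {
  expect_identical(odToDcw(1.0), 0.451)
  expect_identical(odToDcw(0), 0)
  expect_equal(dcwToOd(10), 10 / 0.451, tolerance = 1e-12)
  expect_equal(odToDcw(dcwToOd(7.3)), 7.3, tolerance = 1e-12)
  expect_error(odToDcw(-1), ">= 0")
})

test_that("the ROI proposal splits at the valley between the two peaks", {
  tm <- grid_5hz(300)
  ref <- make_chrom(two_peak_trace(tm), tm)
  prop <- proposeRoi(ref)
  expect_lt(prop$ft$end_s, 210)
  expect_gt(prop$ft$end_s, 60)
  expect_identical(prop$ft$end_s, prop$el$start_s)
  # proposed windows capture essentially the full two-peak area
  pa <- peakAreas(ref, prop$ft, prop$el)
  expect_equal(pa$auc_ft, 2000, tolerance = 1e-3)
  expect_equal(pa$auc_el, 3000, tolerance = 1e-3)
})
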