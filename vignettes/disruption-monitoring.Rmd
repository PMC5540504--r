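---
title: "Monitoring cell disruption from UV chromatograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring cell disruption from UV chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChromDisrupt)
```

## The measurement problem

High-pressure homogenization disrupts microbial cells by forcing the
suspension through a valve at 500–1500 bar; each pass (cycle) breaks a
fraction of the still-intact cells and releases intracellular protein
into the supernatant. Disruption efficiency is classically judged by
total-protein assays (Bradford) or viability assays (plate counts, flow
cytometry), all of which are slow and manual. The at-line alternative
modelled here injects the supernatant onto a small anion-exchange
monolith and records the 280 nm UV trace at 5 Hz over a 5-minute run:
unbound material passes through early (the flowthrough peak, FT), bound
protein and nucleic acids elute later in a salt step (the elution peak,
EL). The summed area under both peaks tracks the released protein, so
the per-cycle AUC series is a disruption-efficiency readout that needs
no calibration — only consistent normalization.

## Processing model and assumptions

The pipeline is: import → mean reference → alignment → ROI integration →
normalization.

**Uniform grid.** All traces of one experiment must share a uniform time
grid (relative spacing tolerance 1e-6, enforced at load). This is what
makes integer-sample shifting well-defined and keeps the alignment
oracle exact. Traces from instruments with slightly different grids can
be brought onto a common one by `resampleToGrid()` (linear
interpolation, exact on piecewise-linear signals).

**Mean reference.** The alignment target is the elementwise arithmetic
mean of all imported traces. This assumes the majority of traces share
the true retention times; a single outlier pulls the reference only by
1/n.

**Correlation-optimized shifting.** Each trace (whole, or each
configured interval independently) is shifted by the integer number of
samples in [−max_shift, +max_shift] that maximizes its Pearson
correlation with the reference. Design choices, each made deliberately:

* *Integer shifts only* — no sub-sample interpolation. This matches the
  interval-correlation-shifting family of algorithms, never distorts
  peak areas, and lets tests verify recovery exactly against
  constructed delays.
* *Pearson correlation, mean-subtracted* — insensitive to constant
  baseline offsets between trace and reference.
* *Tie-break*: smallest |s| first, then the negative candidate. Any rule
  would do; this one is deterministic and least-interventionist.
* *Edge replication* for vacated samples, so no missing values reach
  integration. For realistic shifts (a few samples) against a 1500-point
  trace the bias is negligible; tests that check exact equality exclude
  the replicated edges.
* *Zero-variance traces* (e.g. a blank) get shift 0 with a warning
  rather than an error — a flat trace cannot be misaligned.

Whole-trace alignment is the default; interval mode is available when FT
and EL drift independently. The algorithm's original publication leaves
mode, window and fill choices to the user, and so do we (config keys
`align/max_shift_samples`, `align/intervals`).

**Integration.** Composite trapezoid rule over the half-open ROI
[start, end), with the trace linearly interpolated at the window bounds
so partial sampling intervals are covered exactly. The trapezoid rule is
exact on piecewise-linear signals and, for smooth peaks sampled at 5 Hz,
agrees with a 1000× finer Riemann sum to better than 1e-3 relative (a
test asserts this across 100 random Gaussian shapes). Baseline handling
is off by default; when enabled it subtracts, per window, the straight
line through the trace values at the window bounds. Negative areas
(noise below baseline) are non-physical for totals and are clipped to
zero with a warning.

**ROI choice.** FT/EL windows are user configuration (defaults
[30, 120) s and [160, 280) s, matching the simulator's peak positions);
`proposeRoi()` offers a data-driven split at the deepest valley between
the two largest reference peaks for unconfigured runs.

## Normalization conventions: why there are two

Two percent scales coexist in practice and both are implemented
explicitly:

* `relativeRecoveryEq2()` — the start/end ratio
  100·(AUC_i − AUC_Start)/(AUC_End − AUC_Start). By construction 0 % at
  cycle 0 and 100 % at the final cycle, and invariant under *affine*
  transforms of the AUC series (so a constant background cancels).
* `normalizeEndAnchored()` — 100·value_i/value_last, the "final cycle is
  100 %" convention used for total-protein columns in comparison tables.
  Only scale-invariant; a cycle-0 sample with pre-released protein shows
  a nonzero percentage here (and values before the last cycle may exceed
  100 %, because the anchor is the final cycle, not the maximum).
* `normalizeStartAnchored()` — 100·value_i/value_first, for viability
  signals that *decline* from an untreated 100 % (plate counts,
  flow-cytometry viable counts, delta capacitance).

`buildComparison()` applies end-anchoring to the protein methods and
start-anchoring to the viability methods, which is the convention of the
published five-method comparison tables this layout mirrors.

## Reference-analytics reductions

Only the computational reductions are modelled, not the assay chemistry:
CFU/mL from a serial-dilution plate count (`colonies / plated_volume ·
10^(−dilution_exp)`), viable flow-cytometry events as total (RH414)
minus dead (DiBAC4(3)), and the dielectric-spectroscopy signal as the
mean of the low-frequency minus high-frequency capacitance trace. The
countable-plate rule (30–300 colonies, prefer ~100, ties to the higher
dilution) is standard microbiological practice adopted here as an
explicit, configurable selection rule since plating protocols rarely
state one.

## DoE module

`fullFactorial()` enumerates all level combinations (the 3 × 3 × 4
pressure/biomass/cycles screening design has 36 runs). Factors are coded
affinely to −1…+1 (`codeFactors()`); for the symmetric 3-level factors
the coded main-effect columns are mutually orthogonal, which makes the
null-pressure simulation a clean test. The model family is intercept +
main effects + two-factor interactions — the usual screening default; no
quadratic terms, because a screening design cannot resolve them
(interactions can be disabled by a switch). Model quality:

* R² = 1 − SSE/SStot.
* Q² = 1 − PRESS/SStot, with PRESS from the leave-one-out shortcut
  e_i/(1 − h_i) using the hat values — algebraically identical to
  refitting without each run (a test verifies this against a literal
  refit loop). Q² ≤ R² always, since |1 − h_i| ≤ 1.
* Two-sided coefficient p-values from the t distribution on the
  residual degrees of freedom.

The response for disruption studies is the total AUC normalized per
biomass (`normalizePerBiomass()`), so runs at different cell densities
are comparable. Whether to apply the same normalization to Bradford
responses is left configurable. Rank deficiency is reported as an error
naming the aliased terms rather than silently dropping them.

## What the simulator emulates — and what it does not

`simulateChromatogram()` generates: a linear baseline drift (default
2 mAU across the run), two Gaussian peaks (FT apex 60 s, σ 6 s,
2000 mAU·s at full release; EL apex 210 s, σ 8 s, 3000 mAU·s), white
noise (σ 0.5 mAU) and a uniform integer retention jitter of up to ±3
samples applied to both peaks jointly. These defaults describe a
realistic 10 g DCW/L homogenate run at a 0.1 mL monolith: peak heights
of ~130–150 mAU against sub-mAU noise, and sub-second retention
reproducibility. All randomness flows from one explicit per-call seed;
the caller's RNG stream is untouched.

The disruption trajectory follows geometric survival: each cycle
disrupts fraction *e* of the remaining intact cells, so the cumulative
released fraction is f(n) = f₀ + (1 − f₀)(1 − (1 − e)ⁿ), with f₀ the
protein already free at cycle 0 (freeze–thaw pre-lysis doubles the
cycle-0 signal when f₀ doubles). This is the minimal mechanism that
reproduces the saturating trajectories seen in practice — ~80–90 %
release after one 1500-bar pass, small gains after cycle 2.

Deliberately **not** modelled: peak tailing (exponentially modified
shapes), detector saturation and nonlinearity, carry-over between
injections, column fouling drift across a campaign, and
temperature-dependent release. Passing tests on synthetic data therefore
demonstrate the correctness of the *computations* (alignment,
integration, normalization, model fitting), not the adequacy of a
Gaussian peak model for any particular instrument — on real data the
ROI windows and alignment settings still need to be chosen by
inspection.

## Numerical choices and degenerate inputs

* Grid tolerance 1e-6 (relative) at load; round-trips through the text
  writer are tested to 1e-9.
* Recovery is undefined when AUC_End = AUC_Start (ratio convention) or
  the anchor value is zero — both are errors, not NaNs.
* `estimateEfficiency()` fits A·f(n) to a per-cycle series by bounded
  L-BFGS-B over (e, f₀, A); the scale A absorbs units, so raw AUCs and
  percent series give the same efficiency. On noise-free series the
  estimate is within 0.02 of the generating e across e ∈ [0.5, 0.95]
  (tested).
* The kinetics fit needs at least 3 cycles; with 2 the three-parameter
  model is unidentifiable.

## Problem sizes

The test suite simulates 1500-point traces (5 min at 5 Hz), experiments
of 5 cycles, 36-run designs, 200-replicate null-pressure simulations and
100-shape integration sweeps; the full suite runs in about a minute.
These sizes were chosen as the smallest that exercise every code path at
realistic signal-to-noise, not as statements about instrument limits.

## Known limitations

* Integer-sample alignment cannot correct sub-sample drift; at 5 Hz this
  bounds the residual misalignment at 0.1 s, which is negligible for
  30–120 s wide ROIs but would matter for narrow-bore columns.
* The end-anchored convention depends on the final cycle truly being
  near-complete disruption; anchoring a short run (e.g. 2 cycles at low
  pressure) overstates recovery.
* AUC is a *relative* protein measure; no absolute mg/mL calibration is
  attempted.
* The comparison table assumes every method covers the identical cycle
  set; missing cycles must be handled upstream.
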