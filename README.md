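# ChromDisrupt

Automated, at-line monitoring of microbial **cell disruption efficiency**
from HPLC UV chromatograms.

When intracellular products (e.g. recombinant proteins in *E. coli*) are
recovered by high-pressure homogenization, each pass ("cycle") through the
homogenizer releases a further fraction of the intracellular protein.
The classic ways to track this — Bradford assays, plate counts, flow
cytometry — are slow and manual. A fast alternative injects the homogenate
supernatant onto a small anion-exchange monolith and records the 280 nm UV
trace: the areas under the flowthrough (FT) and elution (EL) peaks track
the total released protein, and a 5-minute run can be evaluated
automatically. ChromDisrupt is the data-analysis side of that workflow,
for bioprocess engineers developing disruption steps.

## What it computes

- **Import & validation** of chromatograms as two-column delimited text
  (time in s, absorbance in mAU) on a uniform grid (nominally 5 Hz), with
  per-sample metadata (cycle, pressure, biomass, fresh/frozen).
- **Alignment**: every trace is shifted by the integer number of samples
  *s* ∈ [−*s*max, +*s*max] that maximizes its Pearson correlation with the
  elementwise **mean reference** chromatogram — whole-trace or per
  interval, with edge replication for vacated samples.
- **Integration**: composite trapezoid AUC over the configured FT and EL
  windows (optional per-window linear baseline subtraction), giving
  AUC_total = AUC_FT + AUC_EL in mAU·s.
- **Recovery statistics** per cycle *i*:
  - ratio convention: 100 · (AUC_i − AUC_Start) / (AUC_End − AUC_Start),
    pinned to 0 % at the first and 100 % at the last cycle;
  - end-anchored convention: 100 · value_i / value_last (protein columns);
  - start-anchored convention: 100 · value_i / value_first (viability
    columns: plate counts, flow-cytometry viable counts = RH414 − DiBAC4(3),
    dielectric delta capacitance).
  `buildComparison()` assembles the five-method comparison table with the
  proper convention per method. `odToDcw()` applies the linear OD600→DCW
  correlation y = 0.451·x.
- **DoE evaluation**: full-factorial designs over pressure, biomass and
  cycle count; OLS screening model on coded (−1…+1) factors with
  two-factor interactions; R² = 1 − SSE/SStot, Q² = 1 − PRESS/SStot with
  leave-one-out PRESS from the hat values; coefficient p-values; response
  contour surfaces.
- **Simulators** (seeded, deterministic) for two-peak chromatograms with
  baseline drift, noise and retention jitter, and for multi-cycle
  disruption experiments following geometric-survival release kinetics
  f(n) = f₀ + (1 − f₀)(1 − (1 − e)ⁿ).

## Worked example

Simulate a 5-cycle homogenization at 1500 bar (per-cycle efficiency
e = 0.85), then run the full align → integrate → normalize pipeline:

```r
library(ChromDisrupt)

kin <- disruptionKinetics(efficiency = 0.85)
sim <- simulateDisruptionExperiment(kin, n_cycles = 5, seed = 42)
res <- runRecovery(sim$set)
round(res$recovery, 2)
#>   cycle auc_total recovery_pct end_anchored_pct
#> 1     0    222.28         0.00             4.25
#> 2     1   4470.48        84.87            85.51
#> 3     2   5108.71        97.61            97.72
#> 4     3   5204.31        99.52            99.54
#> 5     4   5216.97        99.78            99.79
#> 6     5   5228.12       100.00           100.00
```

Cycle 1 recovers ~85 % of the final protein signal — one pass at 1500 bar
does most of the disruption, later cycles add little (the e = 0.85 truth
trajectory is 85.0 / 97.8 / 99.7 / 100 %). `res$areas` holds the per-ROI
AUCs and `shiftTable(res$alignment)` the applied shifts.

Fit a screening model to a simulated 36-run full factorial (3 pressures ×
3 biomass levels × 4 cycle counts) whose generating model has no pressure
effect:

```r
d <- fullFactorial(list(
  factorSpec("pressure_bar", c(500, 1000, 1500)),
  factorSpec("biomass_gdcw_per_l", c(10, 55, 100)),
  factorSpec("cycles", 0:3, "quantitative-multilevel")))
tab <- simulateDoeDataset(d, c("(Intercept)" = 50, biomass_gdcw_per_l = -12,
  cycles = 20, "biomass_gdcw_per_l:cycles" = -4), noise_sd = 3, seed = 42)
fitScreeningModel(tab, tab$response)
#> DoEModel (coded factors)
#>                                 coefficient   p_value
#> (Intercept)                       50.202700 5.717e-36
#> pressure_bar                      -1.178210 1.244e-01
#> biomass_gdcw_per_l               -11.545700 1.423e-15
#> cycles                            20.115700 5.238e-21
#> pressure_bar:biomass_gdcw_per_l   -0.745339 4.204e-01
#> pressure_bar:cycles               -1.284100 2.088e-01
#> biomass_gdcw_per_l:cycles         -3.469630 1.636e-03
#> R2 = 0.968, Q2 = 0.947 (LOO-PRESS)
```

Cycles and biomass come out strongly significant, pressure does not —
the generating truth. `predictSurface()` turns the model into a
cycles × biomass contour at fixed pressure.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/chromdisrupt` (after installation:
`system.file("scripts", "chromdisrupt", package = "ChromDisrupt")`):

```sh
chromdisrupt simulate --out runs/ --seed 4          # write a synthetic experiment
chromdisrupt recover  --in runs/ --out results/     # align + integrate + normalize
chromdisrupt doe      --table runs.csv --out doe/   # screening model + contour
```

All settings (ROI windows, alignment search width, simulator parameters)
come from a YAML config (`--config`); unknown keys are rejected by name.

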