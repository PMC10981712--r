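# soilhmrisk

Soil heavy-metal pollution indices, Monte Carlo probabilistic human-health
risk, and PMF source apportionment — the full risk-analysis chain that
environmental soil surveys run, as one tested R package.

It is aimed at environmental scientists and risk assessors working with
per-sample heavy-metal concentration tables (mg/kg dry soil). The packaged
reference values emulate a published 84-sample survey of topsoil around a
large chrysotile-asbestos mine in an arid-plateau region of northwestern
China, whose serpentinite host rock makes Cr and Ni the dominant
contaminants; every reference table is user-overridable.

## What it computes

* **Pollution indices** — geo-accumulation index
  `I_geo = log2(C / (1.5 C0))` with its five-class grading, and Hakanson
  potential ecological risk `Er = Tr·C/C0`, `RI = Σ Er`, with RI grading
  thresholds re-scaled to the panel's toxicity-coefficient total
  (`150/133 × ΣTr`, rounded: 111 / 222 / 444 for the default eight-element
  panel).
* **Probabilistic health risk** — USEPA three-pathway model (ingestion,
  dermal, inhalation) for child and adult receptors; exposure parameters as
  point / uniform / triangular / lognormal distributions; Monte Carlo
  propagation to HQ/HI (non-carcinogenic) and CR/TCR (carcinogenic) with
  mean and 5th/50th/95th percentile summaries.
* **PMF source apportionment** — uncertainty-weighted positive matrix
  factorization with multi-restart optimization, robust outlier
  re-weighting (`Q_robust`/`Q_true`), scaled-residual and R² diagnostics,
  and per-element / overall source-contribution percentages.
* **Synthetic surveys** — a calibrated three-source generator (asbestos,
  natural background, coal combustion) with known ground truth, used to
  validate the whole chain end to end.
* **Non-detect handling** — censored cells are substituted at 5/6 of the
  detection limit before index and PMF stages.

## Worked example

```r
library(soilhmrisk)

# A synthetic 84-sample survey with known source structure
sim   <- generate_panel(default_source_model())
panel <- substitute_nondetects(sim$panel)
refs  <- default_reference_set()

summarize_panel(panel, refs)[, c("element", "mean", "cv", "exceedance_factor")]
#>   element     mean    cv exceedance_factor
#> 1      As 2.11e+01 0.473            1.6539
#> 5      Cr 5.94e+02 0.735           13.6558
#> 8      Ni 6.58e+02 0.855           34.5320    (survey: 1.74, 13.31, 33.37)

eco <- compute_ri(compute_er(panel, refs))
round(mean(eco$ri), 1)
#> [1] 272.3        # mean comprehensive ecological risk: "high" (222 <= RI < 444)
derive_ri_thresholds(refs)
#> <ri_grading> sum(T_r) = 98; thresholds 111 / 222 / 444 (unit value 1.1278)

rs <- run_monte_carlo(panel, default_exposure_model("child"),
                      default_toxicity_reference(), iterations = 10000,
                      seed = 1)
rs
#> <risk_summary> receptor = child, 10000 iterations, seed 1
#>  quantity         mean           p5          p50          p95 classification
#>        HI 4.4162076696 2.845117e-01 2.8759562649 1.351342e+01        concern
#>       TCR 0.0002300758 1.797988e-05 0.0001705525 6.531761e-04    intolerable

unc <- build_uncertainty(panel)                    # EPA-style uncertainties
sol <- fit_pmf(panel, unc, k = 3, restarts = 20, seed = 1)
round(contribution_percentages(sol)$overall_share, 1)
#> factor1 factor2 factor3
#>    82.4    10.2     7.4
round(match_factors(sol, sim$f)$cosine, 3)
#> asbestos  natural     coal
#>    0.986    1.000    0.925
```

Reading the output: the simulated survey reproduces the emulated study's
headline pattern — Ni and Cr means tens of times above background, a mean
RI in the "high" ecological-risk band, child health risks above both the
HQ = 1 and CR = 1e-4 thresholds (driven by Cr and As), and a dominant
Cr/Ni-rich source recovered by PMF with ~80% overall contribution, with the
fitted profiles matching the generator's ground truth.

## Layout

* `R/` — implementation (panel I/O and non-detects, indices, Monte Carlo
  engine, PMF, synthetic generator, pipeline orchestration)
* `vignettes/soil-heavy-metal-risk.Rmd` — the methods vignette: models,
  assumptions, parameter conventions, numerical choices, limitations
* `tests/testthat/` — unit, property and end-to-end acceptance tests
* `inst/extdata/reference_default.yaml` — editable default reference values
* `inst/cli/soilrisk.R` — command-line front end
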