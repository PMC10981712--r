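---
title: "Methods: pollution indices, probabilistic health risk and PMF source apportionment for soil heavy metals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollution indices, probabilistic health risk and PMF source apportionment for soil heavy metals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilhmrisk)
```

soilhmrisk implements the analysis chain that environmental surveys of
heavy-metal-contaminated soils conventionally run: descriptive statistics
and pollution indices, a probabilistic (Monte Carlo) human-health risk
assessment, and receptor-model source apportionment by positive matrix
factorization (PMF). Its packaged defaults emulate a published 84-sample
survey of topsoil around a large chrysotile-asbestos mine on an arid
plateau in northwestern China, where the asbestos host rock (serpentinite)
carries very high Cr and Ni. All reference tables are replaceable, so the
chain applies to any survey of the eight-element panel As, Hg, Cd, Pb, Cr,
Cu, Zn, Ni — or, for the index and PMF stages, any panel at all.

## Data model and non-detects

A `sample_panel` is a samples-by-elements concentration matrix (mg/kg dry
soil) plus censoring metadata. Cells below the detection limit stay `NA`
until `substitute_nondetects()` replaces them with 5/6 of the detection
limit — the substitution convention of the emulated survey — while keeping
the censoring flag so the PMF uncertainty rule can still recognize them.
The substitution is idempotent and happens before any index is computed
(the geo-accumulation index needs strictly positive concentrations).

CSV input accepts a wide layout (one column per element) or a long one
(`sample_id`, `element`, `value`), with non-detects written either as
`"<0.5"` sentinels or as paired `<element>_cens` flag columns.
`write_sample_table()` and `read_sample_table()` round-trip a panel at full
precision.

## Pollution indices

The geo-accumulation index is
$$I_{geo} = \log_2\!\left[\frac{C_i}{k \cdot C_0}\right],$$
with background $C_0$ and the conventional correction $k = 1.5$ absorbing
lithogenic background variation. Grades: $I_{geo} \le 0$ none; $(0,1]$
slight; $(1,2]$ moderate; $(2,3]$ severe; $>3$ extremely severe. Upper
bounds are inclusive. (Survey reports sometimes attach different labels to
the same numeric classes; the labels are a `compute_igeo()` argument.)

Hakanson's single-element potential ecological risk is
$E_r = T_r \, C_i / C_0$ with toxicity coefficients
Hg 40, Cd 30, As 10, Pb 5, Cu 5, Ni 5, Cr 2, Zn 1, and the comprehensive
index $RI = \sum_i E_r^i$ is the exact per-sample sum. $E_r$/RI grade
boundaries are lower-inclusive (an $E_r$ of exactly 40 is "moderate").

Hakanson's first-level RI threshold (150) was calibrated for a pollutant
set with $\sum T_r = 133$, so `derive_ri_thresholds()` re-scales it to the
panel in use: the per-unit-toxicity value $150/133$ times the panel's
$\sum T_r$, rounded half-up to an integer, with each further level doubling
the previous rounded value. For the default panel ($\sum T_r = 98$) this
gives 111 / 222 / 444. Rounding before doubling matches how the re-scaled
thresholds are quoted in practice (111, 222, 444 rather than 110.5, 221,
442).

The packaged backgrounds are the survey area's non-agricultural-land
values. The printed Hg background (11.48 mg/kg) is geochemically
implausible, but it is the value the survey's own $E_r$ arithmetic uses
(its reported mean Hg risk of 0.03 equals $40 \times 0.010 / 11.48$), so
the package ships it as-is and lets users override it.

## Probabilistic health risk

The USEPA residential-soil model is used with three pathways. With
concentration $C$ (mg/kg):

$$ADD_{ingest} = \frac{C \cdot R_{ingest} \cdot EF \cdot ED}{BW \cdot AT} \cdot 10^{-6},
\qquad
ADD_{dermal} = \frac{C \cdot SA \cdot AF \cdot ABF \cdot EF \cdot ED}{BW \cdot AT} \cdot 10^{-6},
\qquad
ADD_{inhal} = \frac{C \cdot R_{inhal} \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}.$$

Unit bridging: $EF$ (d/y) times $ED$ (y) is the total number of exposure
days, divided directly by the averaging time $AT$ in days. No additional
factor of 365 is introduced; the packaged $AT$ values (2190 d child,
9125 d adult) are exactly the $ED$-range midpoints in years times 365,
which is the internally consistent reading of the parameter table. The same
$AT$ serves the carcinogenic and non-carcinogenic endpoints — common USEPA
practice would use a 70-year lifetime $AT$ for carcinogens, and we document
this deviation rather than silently "correcting" the study design.

Non-carcinogenic risk: $HQ = \sum_j ADD_j / RfD_j$ per element over
pathways with an established reference dose, $HI = \sum HQ$; concern above
1. Carcinogenic risk: $CR = \sum_j ADD_j \cdot SF_j$ over pathways with a
slope factor, $TCR = \sum CR$; at most $10^{-6}$ negligible, up to
$10^{-4}$ tolerable, above that intolerable. Missing RfD/SF entries (the
dashes of published compilations) simply drop that pathway from the sum;
Cu, Hg and Zn therefore contribute 0 to TCR.

`run_monte_carlo()` draws, per iteration, one survey row uniformly at
random (elements co-vary as observed; a fitted-lognormal per-element mode
is also available, since how the original study fed its 84 concentrations
to the simulator is not documented) and independent draws of every exposure
parameter, then summarizes HQ/HI/CR/TCR and the pathway doses by mean and
5th/50th/95th percentiles. 10,000 iterations take well under a second for
the default panel; all runs are bitwise reproducible under a seed.

Distribution parameterization deserves care. Lognormal pairs such as body
weight (57.03, 1.18) are geometric mean / geometric SD — values like 1.18
are implausible as arithmetic SDs in kg and are canonical GSDs in the
exposure literature. The adult skin-adherence pair (0.49, 0.54) cannot be a
GM/GSD (a GSD below 1 is impossible), so it is read as an arithmetic
mean/SD and modelled as a zero-truncated normal by default (a
moment-matched lognormal is selectable). Exposure-duration draws use the
half-open interval $(0, b]$: a draw of exactly zero is measure-zero and
excluded. The adult soil-ingestion triangular is (14, 30, 52) mg/d; the
printed table runs the child and adult columns together, and this split is
the one whose mean (32 mg/d) matches standard adult central tendencies.

Because the original per-sample concentrations are unpublished, the printed
mean CR/HI values cannot be reproduced exactly by anyone; the package's
tests therefore pin the model down by its structural properties instead:
degenerate (all-point) runs equal an independent hand-computed closed form
exactly; doses and risks are linear in concentration; child doses per kg
body weight exceed adult doses under the default parameters; summaries are
seed-stable.

## PMF source apportionment

The receptor model decomposes $X \approx GF$ ($G \ge 0$ contributions,
$F \ge 0$ profiles) by minimizing the uncertainty-weighted objective
$$Q = \sum_{ij}\left(\frac{x_{ij} - \sum_k g_{ik}f_{kj}}{u_{ij}}\right)^2 .$$

The survey this package emulates does not publish its uncertainty equation,
so `build_uncertainty()` adopts the standard concentration-based rule of
receptor-modelling practice: $u = \sqrt{(ef \cdot c)^2 + (0.5 \cdot MDL)^2}$
with error fraction $ef = 0.10$ by default, and censored cells at value
$= u = \tfrac{5}{6} MDL$. This is a documented assumption, not a reproduced
fact.

Optimization is by alternating weighted multiplicative updates (the
weighted Lee–Seung scheme), which preserve nonnegativity and decrease $Q$
monotonically; convergence is declared when the relative $Q$ change falls
below $10^{-8}$ (at most 5000 iterations per pass), and 20 random restarts
(matching the 20 random-seed runs of the emulated study) guard against
local minima. Robust mode re-weights outliers iteratively: cells with
scaled residual magnitude above 4 get their uncertainty inflated by
$\sqrt{|e/u|/4}$, and both $Q_{true}$ and $Q_{robust}$ are reported
($Q_{robust} \le Q_{true}$ by construction). Diagnostics follow the usual
acceptance conventions: at least 95.5% of scaled residuals in $[-3, 3]$ and
overall $R^2 \ge 0.98$ (thresholds configurable).

Fitted contributions are normalized to mean 1, so profile rows are mg/kg
per unit contribution; per-element factor shares are each factor's mean
reconstructed mass as a percentage of the element's mean reconstructed
concentration, and overall source shares are the mass-weighted average.

`select_factor_count()` scans a k-range and, besides random restarts,
warm-starts each k from the best $(k-1)$ solution with a near-zero extra
factor. Since the update steps never increase $Q$, the best objective is
non-increasing in k by construction, which makes the Q-versus-k table a
clean screeplot-style instrument; the choice of k remains the analyst's.

Factor identity (asbestos / natural / coal in the emulated setting) is
analyst metadata: `match_factors()` resolves permutation ambiguity against
a reference profile set. Profiles are compared in element-scaled space —
each element divided by its mean working concentration — because the raw
panel spans five orders of magnitude (Hg ~0.01 vs Ni ~640 mg/kg) and a raw
cosine would see only Cr and Ni. A raw-space comparison is available via
`scale = 1`.

## The synthetic survey generator

`default_source_model()` builds a three-factor generative model calibrated
to the published survey summary:

* **asbestos** — the published source-material mean profile (Cr 1339.17,
  Ni 1788.33 mg/kg, other elements low), scaled so that at mean
  contribution it supplies the survey's entire mean Ni excess over
  background;
* **natural** — anchored to the local background composition (As and Ni
  exactly at background) with the other elements rebalanced so that the
  three-source expectation equals the published survey means. A natural
  profile strictly proportional to the background vector cannot reproduce
  the survey (the printed Hg background exceeds the survey's mean Hg
  concentration a thousandfold), so the rebalancing, with Cr absorbing the
  excess the asbestos profile leaves unexplained, is the package's design
  choice;
* **coal** — an As-only profile carrying the As excess, mimicking
  combustion deposition.

Contribution laws are lognormal with mean 1 and log-scale SDs 0.85
(asbestos), 0.35 (natural) and 1.0 (coal), chosen once so the generated
heterogeneity echoes the survey's pattern: CVs near 1 for the
asbestos-driven Cr and Ni, and around 0.3–0.5 for the background-dominated
elements. Elements whose survey CV reflects a few extreme hotspots (As
especially, printed CV 1.45) come out smoother here — the generator has no
spatial hotspot mechanism, and no attempt is made to inflate its tails to
match. Measurement noise is multiplicative lognormal
($\sigma = 0.1$ on the log scale) — concentrations are positive and
right-skewed, so additive Gaussian noise would be the wrong error model.
Default detection limits (Hg 0.0037, Cd 0.047 mg/kg) censor roughly 5% of
Hg and Cd cells and nothing else, exercising the non-detect path without
dominating it. An 84-sample draw under the default seed lands within a few
percent of every published element mean (the calibration requirement is
±25%).

What the generator does *not* emulate: spatial autocorrelation and
zone-specific contamination gradients (zones are assigned at random),
between-element noise correlation, and analytical bias. Passing recovery
tests on this generator therefore shows the estimators are correct under
the stated mixture-with-lognormal-noise model, not that three sources are
identifiable in any real survey.

## Numerical choices and degenerate inputs

* RI is an exact `rowSums`; no tolerance is involved in the additivity
  invariant.
* Grade assignment is total: every finite index value falls in exactly one
  class, with the boundary conventions stated above.
* The multiplicative PMF updates use a $10^{-12}$ additive guard in
  denominators; zero columns in $G$ are left unnormalized rather than
  divided by zero. `fit_pmf()` flags non-convergence in the result instead
  of raising.
* Uniform sampling rejects draws exactly at the lower bound; zero-truncated
  normal sampling is by rejection (acceptance ~82% for the adult AF
  parameters).
* Panels with censored cells must pass through `substitute_nondetects()`
  before the index stages; `compute_igeo()` refuses zero or negative
  concentrations with a pointer to that function.
* Problem sizes in the test suite (n = 84–200 panels, 10,000 Monte Carlo
  iterations, 5–20 PMF restarts, k up to 6) were chosen as the smallest
  sizes at which the statistical assertions are stable across seeds.

## Known limitations

* The probabilistic engine treats exposure parameters as independent;
  correlated draws (e.g. BW with SA) are not supported.
* PMF standard-error machinery (bootstrap, displacement, Fpeak rotation) is
  out of scope; only point factorizations with restart-based stability.
* The re-scaled RI thresholds assume Hakanson's unit-toxicity grading value
  transfers linearly to other panels, which is the convention of the
  emulated survey rather than a law of nature.
* Printed survey risk means (e.g. adult As CR of 1.56e-05) are
  order-of-magnitude anchors only; without the raw 84-sample data no
  implementation can reproduce them exactly, and this package does not
  pretend to.
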