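---
title: "Estimating germination responses to temperature and water potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating germination responses to temperature and water potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germresp)
```

germresp characterises how seed lots respond to temperature and water
potential: it turns replicated cumulative germination counts into per-species
cardinal temperatures (minimum $T_0$, optimum $T_{opt}$, maximum $T_{max}$),
a base temperature $T_b$, and a base water potential $\Psi_b$, and then
groups species with similar germination envelopes by Ward clustering. This
vignette explains the models, the estimation conventions, the choices that
were genuinely open, and what the synthetic-data generator does and does not
emulate.

## The model chain

**Dynamics.** Each species x condition time course (cumulative percentage of
sown seeds germinated) is fitted with the Gompertz curve

$$G(t) = G_{max}\, \exp\!\left[\left(-\tfrac{b}{c}\right) e^{-c t}\right],$$

where $G_{max} \in (0, 100]$ is the final germination percentage and
$b, c > 0$ are shape parameters ($c$ in 1/h sets the time scale). The fit is
bounded nonlinear least squares on the replicate-mean percentage curve: one
dynamics curve per species and condition, which is the convention in this
literature (per-replicate fitting is available behind a flag). Observations
before the first germination are retained — the zeros are informative for
$b$ and $c$.

**Percentile rates.** The germination rate for a percentile $G$ *of sown
seeds* is $1/t(G)$, with the time obtained by the closed-form inversion

$$t(G) = -\tfrac{1}{c} \ln\!\left[-\tfrac{c}{b}\ln\left(G/G_{max}\right)\right].$$

Percentiles are percentages of the sown population, not of $G_{max}$:
when final germination is below 50%, the 40th and 50th percentiles are
simply unreachable and are omitted (never zero-filled). This is the only
convention under which "use only the 20th and 30th percentiles when final
germination is low" is coherent.

**Thermal response.** For each percentile, the rates across the pure-water
temperature series are fitted with the beta-function (Yin) model

$$1/t(G) = e^{\mu} (T - T_0)^{\alpha} (T_{max} - T)^{\beta},$$

zero outside $(T_0, T_{max})$. The optimum is the analytic argmax,

$$T_{opt} = \frac{\alpha T_{max} + \beta T_0}{\alpha + \beta},$$

which always lies strictly inside the thermal window. A variant of this
formula with $\alpha$ and $\beta$ interchanged circulates in print; only the
form above maximises the rate equation as written (the package tests verify
it against a dense grid search), so that is the form used. Cardinal
temperatures are estimated once per percentile and then averaged, with the
SD across percentiles reported as the uncertainty.

**Base temperature.** Over the sub-optimal range the rate rises nearly
linearly with temperature. $T_b$ is the x-intercept of an ordinary
least-squares line fitted per percentile over a *linear-phase window*, then
averaged across percentiles. No standard algorithm exists for choosing that
window, so the package defines one: among all contiguous windows of at
least three tested temperatures strictly below the optimum with positive
rates, take the window maximising the linear $R^2$; break ties in favour of
the longer window, then the lower starting temperature. The window is
selected once per species from the highest available percentile's rates and
shared across percentiles. $T_b$ is deliberately not clamped at zero —
slightly negative base temperatures are reported in the literature — which
is intentionally asymmetric with the Yin fit, whose $T_0$ is bounded below
by 0 °C by default (several species are conventionally reported at exactly
0.0; `t0_lower` relaxes the bound). Because the fitted rate curve is convex
near its base, the extrapolated $T_b$ can sit well above $T_0$; both
estimands are reported.

**Base water potential.** The same x-intercept method applied to rates
across water potentials at a fixed 20 °C assay: rate regressed on $\Psi$
per percentile, with $\Psi_b$ the potential at which the extrapolated rate
is null. Only the 20th and 30th percentiles are used by default because
final germination often falls below 50% under water stress; the pure-water
rate is included as a regression point. The linear form is an assumption —
the source procedure is described only as "the same method" as for
$T_b$ — and it is exact on the generator's ground-truth hydro model, where
the rate scales with $1 - \Psi/\Psi_b$.

**PEG-8000 solutions.** Water potentials are imposed with PEG-8000.
The package converts between potential and concentration by monotone
piecewise-linear interpolation through the five published anchor pairs
(0 MPa = 0 g/L, −0.1 = 73.7, −0.5 = 195, −0.75 = 250, −1.5 = 376),
refusing to extrapolate. The temperature-dependent Michel relation is not
implemented: the anchors are calibration points at 20 °C, the only assay
temperature used here.

**Functional grouping.** Species profiles $(T_0, T_{opt}, T_{max}, \Psi_b)$
are clustered agglomeratively under the Ward criterion with squared
Euclidean distances; merge heights are reported as the increase in total
within-cluster sum of squares, and the tree is cut at $k = 5$ groups by
default. $T_0$ is used rather than $T_b$ because it is generally the more
precisely estimated minimum-temperature trait. Features enter on raw scales
(°C and MPa) by default, matching how group means are conventionally
tabulated; mixing units without scaling is statistically questionable, so
`standardize = TRUE` z-scores the features first. For correlation claims of
one trait against several others, both the pairwise Pearson correlations
and the multiple $R^2$ are available (`trait_correlation()`,
`trait_multiple_r2()`), since either may be meant by such statements.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `percentiles` | 20, 30, 40, 50 | percentages of sown seeds defining rates |
| `hydro_percentiles` | 20, 30 | percentiles used for $\Psi_b$ |
| `t0_lower` | 0 °C | lower bound of the Yin $T_0$ (set −5 to relax) |
| `tmax_upper` | 50 °C | upper bound of the Yin $T_{max}$ |
| `min_points` (window) | 3 | minimum linear-phase window length |
| `k` | 5 | number of functional groups |
| `standardize` | FALSE | z-score clustering features |

## The synthetic experiment generator

Every pipeline stage is testable against known ground truth because the
package ships a generator emulating the reference experimental design:

- 25 seeds x 4 replicates per condition; a temperature series
  (default grid 4.5, 11.5, 15, 20, 26.7, 31, 36, 39.5, 43 °C — the
  mid-range values interpolate a partially published grid and are
  configurable) in pure water, observed 2-hourly on the imaging-table
  range (11.5–36 °C) and 8-hourly at incubator extremes; and a
  water-potential series (0, −0.1, −0.5, −0.75 MPa) at 20 °C observed
  8-hourly, with its own pure-water control kept as a separate assay.
- Each seed germinates with probability $g_{max}(T)/100$ (binomial count
  noise), and germinating seeds draw times from a Gompertz-shaped
  distribution whose median is $1/\text{rate}$ and whose dispersion is a
  log-scale `spread` about the median (default 0.2; no within-seed-lot
  variance information exists to calibrate it, so it is an
  order-of-magnitude choice).
- Ground-truth rates compose a Yin thermal response, a linear hydro factor
  $\max(0, 1 - \Psi/\Psi_b)$, and a percentile scaling with $f(50) = 1$ so
  earlier fractions germinate faster.
- Final-germination profiles follow two qualitative shapes seen in real
  species: a plateau that collapses only near $T_{max}$
  (`plateau_drop_high`, linear drop from $0.9\,T_{max}$), or additionally a
  ramp from half the plateau at $T_0$ (`drop_both_ends`). The shapes and
  knee positions are stylised inventions, configurable.
- Species draws span the observed trait ranges ($T_0 \in [0, 11]$,
  $T_{max} \in [28, 43]$ °C, $\Psi_b \in [-2.6, -0.1]$ MPa, plateau
  75–100%). $T_{max}$ is drawn coupled to $T_0$ so every species has a
  thermal window of roughly 26–34 °C, as all observed taxa do;
  independent draws would create windows narrower than any real species
  and leave too few usable grid temperatures for a five-parameter fit.
  Shape magnitudes ($\alpha \approx 1\!-\!3.6$, $\alpha/\beta \approx
  2.5\!-\!4.5$) keep the sub-optimal limb near-linear, as observed, with
  the optimum in the upper part of the window; peak rates correspond to
  median germination times of roughly 17–50 h near the optimum.
- The default horizon is 1008 h (6 weeks), long enough for slow
  sub-optimal conditions to approach their plateau, since the design
  measures *final* germination percentages.
- Reproducibility: one root seed; each time course gets a private RNG
  stream derived by a stable hash of (species, condition, replicate), so
  any subset of a design reproduces the identical counts.

```{r, eval = FALSE}
species <- draw_true_species(20, seed = 1)
sim <- simulate_experiment(species, seed = 1)
profiles <- estimate_species_profiles(sim$data)
```

**What passing tests do and do not show.** The generator reproduces the
statistical structure the estimators assume: binomial seed counts,
Gompertz-shaped dynamics, Yin-shaped thermal response, linear hydro
reduction. Real data add everything the generator omits: dormancy and
hard-seededness (low plateaus in some legumes), seed-lot aging, spatial
effects on the germination table, imaging artifacts, temperature
fluctuation in incubators, and model misspecification (real dynamics are
not exactly Gompertz, real thermal responses not exactly beta-shaped).
Recovery results on simulated data are therefore a correctness check of
the estimation chain, not a field-accuracy claim; the near-unity $R^2$ of
Yin refits on simulated rates is likewise optimistic relative to what real
seed lots give.

## Numerical choices

- Nonlinear fits use bounded Levenberg–Marquardt least squares
  (minpack.lm) with deterministic multi-starts: five time-scale starts for
  the Gompertz fit ($c$ seeded from the observed rise interval, $b = c$,
  $G_{max}$ from the observed maximum), five shape-pair starts for the Yin
  fit. Convergence tolerance is tight (`ftol` 1e-12/1e-14); the best
  converged start by RSS wins.
- Yin bounds follow the data: $T_0 \in [0, \min T^+)$,
  $T_{max} \in (\max T^+, 50]$ where $T^+$ are temperatures with positive
  rates; $\alpha, \beta \in (0, 20]$. Fits at a shape bound are flagged
  `boundary` and treated as non-converged rather than silently used.
- Time courses with fewer than three distinct percentage levels are
  under-determined for three parameters and are returned flagged, never
  dropped silently; all-zero curves raise a typed error that the pipeline
  records per condition.
- Replicates are averaged on the union of their observation grids with
  last-observation-carried-forward interpolation, the natural reading of
  cumulative step data.
- Ward clustering is delegated to `stats::hclust(method = "ward.D")` on
  squared Euclidean distances, whose Lance–Williams heights equal exactly
  twice the within-cluster SS increase (halved for reporting); the test
  suite checks the full linkage against a brute-force greedy oracle for
  small n. Equal-cost merges follow hclust's deterministic ordering.
- Degenerate inputs: rates constant across temperature are unidentifiable
  and flagged; regressions with non-positive slope (rate falling with
  temperature, or rising with drought) exclude that percentile with a
  warning, and error only if no percentile survives.

## Known limitations

- Species whose usable grid temperatures number fewer than five (a high
  $T_0$ combined with the final-germination drop zone swallowing the top
  grid point) cannot support a five-parameter thermal fit; the pipeline
  reports the failure per species and recovery summaries count such
  species as failures rather than dropping them. About one draw in ten
  falls in this tail at the default grid.
- $\Psi_b$ far below the tested range (e.g. −2.6 MPa from points no lower
  than −0.75 MPa) rests on a long linear extrapolation; it is exact when
  the linear hydro model holds and sensitive to slope noise when it does
  not.
- The PEG calibration is valid at 20 °C only.
- Full five-group memberships of real datasets are sensitive to the
  $\Psi_b$ estimates entering the feature matrix; only robustly separated
  groups (e.g. the two thermophilic outliers) should be over-interpreted.

## Problem sizes in the test suite

The suite fits about 1,300 Gompertz curves end to end: the recovery checks
use 20 simulated species at the full factorial design (both noisy and
noise-free modes), smaller fixtures use 1–3 species, and the exhaustive
Ward oracle runs at $n \le 7$ where enumeration is exact. These sizes were
chosen so the whole suite completes in well under a minute while every
stage is exercised at the design's real replicate structure.
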