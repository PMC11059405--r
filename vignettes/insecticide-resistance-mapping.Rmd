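---
title: "Modelling and mapping climate-driven insecticide resistance risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and mapping climate-driven insecticide resistance risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(irmap)
library(dplyr)
```

## The problem

Insecticide resistance in *Anopheles gambiae*, the principal African
malaria vector, spreads through mosquito populations under selection
pressure from pyrethroid-based interventions (treated nets, indoor
residual spraying). Because mosquito demography is strongly driven by
temperature and rainfall, the *potential* for resistance to persist and
spread varies across the landscape and through the year. `irmap`
implements a compartmental model of resistance transmission, a basic
reproduction number for resistance whose birth and death rates respond to
climate, sensitivity analyses of that reproduction number, and a raster
pipeline that classifies a landscape into low / moderate / high resistance
risk and validates the map against observation points.

## The compartmental model

The population is split into susceptible mosquitoes $S$, resistant
mosquitoes $R$, and non-resistant offspring of resistant mosquitoes $M$.
Model 1 (imperfect vertical transmission) is

$$
\begin{aligned}
\frac{dS}{dt} &= r - (\mu + \mu_i)S - \frac{\beta}{N}SR - \gamma SM + \alpha MS\\
\frac{dR}{dt} &= \frac{\beta}{N}SR - \mu R\\
\frac{dM}{dt} &= \gamma SM - \alpha MS - \mu M
\end{aligned}
$$

with birth rate $r$ (day$^{-1}$), natural mortality $\mu$ and
insecticide-induced mortality $\mu_i$ (day$^{-1}$), transmission
probability $\beta$, probability $\gamma$ that a resistant mosquito
produces non-resistant offspring, reversion rate $\alpha$ (day$^{-1}$) of
such offspring to the susceptible pool, and total population $N$. Model 2
(perfect vertical transmission) is model 1 with $\alpha = 0$; the model
choice is always an explicit argument, never inferred from $\alpha$.

One structural peculiarity is worth naming: the $-\gamma SM + \alpha MS$
terms make susceptibles interact with $M$ by mass action rather than
receiving a simple outflow from $M$. The package implements the system
exactly as written above; the biological reading ("offspring become
susceptible again") would suggest a $+\alpha M$ inflow instead, but we do
not second-guess the model definition.

The resistance-free equilibrium (RFE) is
$E^0 = \left(\tfrac{r}{\mu + \mu_i},\, 0,\, 0\right)$. Linearising at the
RFE decouples $R$ and $M$, giving two invasion ratios,
$\beta S_0 / (N\mu)$ and $(\gamma - \alpha)S_0/\mu$: a small seed of the
corresponding compartment grows when its ratio exceeds 1 and dies out
otherwise. `simulate_model()` exists to exercise exactly these claims at
desk scale (the mapping pipeline never integrates the ODEs), and the test
suite checks decay and growth on both sides of the threshold.

```{r simulate}
p <- model_parameters()          # calibrated "table1" preset
invasion_conditions(p)

rfe <- resistance_free_equilibrium(p)
traj <- simulate_model(p, rfe + c(S = 0, R = 1, M = 0), t_end = 60)
glance(traj)
```

## The reproduction number and its climate drivers

The transmission potential of resistance is summarised by

$$
R_0 = \frac{1}{\mu + \mu_i + \alpha}\sqrt{\frac{\beta\,(r + \gamma)}{N}},
$$

interpreted as the average number of resistant mosquitoes that one
resistant mosquito gives rise to in its lifetime. Two caveats are
documented rather than hidden. First, this closed form is **not** what the
standard next-generation-matrix construction yields for the system above:
`ngm_standard()` computes the conventional $FV^{-1}$ spectral radius on
the infected compartments $\{R, M\}$ (which equals the larger invasion
ratio) so the disagreement is measurable; the closed form remains the
authoritative quantity for maps and sensitivity because it is what the
published risk surfaces are built from. Second, because of that
disagreement, the package's stability statements rest on the
Jacobian-derived invasion ratios, not on the closed form crossing 1.

Climate enters through two response functions:

* **Mortality** $\mu(T) = 1/(aT^2 + bT + c)$, the reciprocal of a
  quadratic adult lifespan in days. Where the lifespan is non-positive
  the rate is undefined and the package returns `NA` — invalidity is a
  value, not an exception, so raster maps simply carry nodata cells.
* **Birth rate**
  $r(R,T) = B_E\theta_E\theta_L\theta_P
  \left(\frac{4R(R_L-R)}{R_L^2}\right)^3
  \frac{(k_1T+k_2)e^{-(k_1T+k_2)}}{2(k_1T+k_2)+1}$:
  fecundity times immature survival, a cubed rainfall parabola that peaks
  at half the rainfall limit $R_L$ and collapses at $R_L$ (clamped to 0
  beyond it — flooding washout), and a temperature-dependent emergence
  term, floored at 0 at cold temperatures.

```{r climate}
lh <- life_history_parameters()      # "parham2010" preset
tibble::tibble(T = c(18, 25, 32), rain = c(10, 25, 60)) |>
  climate_rates(lh) |>
  r0_table(p, lh)
```

### Parameter presets and the mortality coefficient

The shipped dynamical preset (`"table1"`) carries the calibrated values
$\beta = 1$, $\gamma = 0.75$, $\alpha = 0.01$, $\mu_i = 0.01$, $N = 50$,
plus desk-scale defaults $r = 0.75$ and $\mu = 0.04$ for
constant-parameter work (in climate-driven runs $r$ and $\mu$ are replaced
by the response functions, so those two defaults never touch a map).

The life-history constants come in two presets. The published table lists
the mortality coefficient as $a = -0.3$; with that value the lifespan
quadratic is negative at every temperature (its discriminant
$b^2 - 4ac = 1.31^2 - 5.28 < 0$ with $a < 0$), so $\mu(T)$ would be
undefined everywhere and no map could exist. We therefore ship both: the
default `"parham2010"` preset uses $a = -0.03$, the standard
Martens/Parham-style coefficient under which $\mu(20\,°C) = 1/9.8 =
0.102$ day$^{-1}$, and `"table1_as_printed"` keeps $-0.3$ verbatim so the
discrepancy is visible and testable rather than silently corrected. Which
value produced the published maps cannot be determined from the text.

The denominator constant of the birth-rate emergence term is read as
$k_1$ (the source prints an undefined symbol $c_1$ there); this is the
only typographic repair made, and the equivalence test between the
composed and fully-substituted forms of the climate $R_0$ pins it down.

## Sensitivity analysis

Two complementary analyses are provided.

**Local:** `perturb_r0()` multiplies one parameter by $(1+\delta)$ and
reports the percent change in $R_0$. For $\beta$ and $N$ these are pure
scaling laws, $\sqrt{1.1}$ and $1/\sqrt{1.1}$ for a 10% increase
(+4.88% and −4.65%), independent of the baseline; for $r$ and $\gamma$
at the calibrated baseline ($r=\gamma$) a 10% increase gives
$\sqrt{1.05}$, i.e. +2.47%.

```{r perturb}
perturb_r0(p, delta = 0.1) |>
  mutate(pct_change = round(pct_change, 2))
```

**Global:** `r0_prcc()` draws a Latin hypercube over all seven
parameters, evaluates $R_0$, and computes partial rank correlation
coefficients — the rank correlation between a parameter and the output
after regressing both on the remaining parameters' ranks, with p-values
from the t statistic on $n - 2 - k$ degrees of freedom. The sampling
distribution is uniform, $\pm 20\%$ around the active preset by default;
that band is a package choice (no range is published), chosen because it
robustly recovers the analytic sign structure of the closed form
(positive for $\beta, r, \gamma$; negative for $N, \mu, \mu_i, \alpha$).
Published PRCC magnitudes cannot be reproduced without the original
sampling ranges, and the published *positive* coefficient for $\mu$
contradicts the closed form's strict monotone decrease in $\mu$ (and the
same report's own −6.9% perturbation result); the package asserts
sign-consistency with the closed form instead. Every stochastic entry
point requires an explicit seed, which is echoed in the result.

```{r prcc}
res <- r0_prcc(p, n = 1000, seed = 42)
tidy(res)
```

## The raster pipeline

Monthly mean-temperature and rainfall grids go in; per-pixel $R_0$ maps,
risk-class maps, annual aggregates, confidence-interval layers and
overlay statistics come out. The canonical exchange format is the ESRI
ASCII grid (6-line header, north-first rows, nodata sentinel), which the
package reads and writes losslessly.

* `r0_map()` applies the climate $R_0$ per pixel; a cell is nodata when
  either input is nodata or $\mu(T)$ is undefined there.
* `classify_map()` applies the legend thresholds: low ($R_0 < 1$),
  moderate ($1 \le R_0 \le 1.1$, both ends inclusive — the deterministic
  reading of the "1–1.1" band), high ($R_0 > 1.1$).
* `annual_aggregate()` reduces 12 monthly maps to one. The published
  description of the annual combination ("50% annual contribution") does
  not determine a weighting, so the neutral pixel-wise mean over valid
  months is the default, with median as an option; the choice is recorded
  in the output metadata.
* `ci_rasters()` computes per-pixel mean and sample standard deviation
  (divisor $n-1$) across the months and the normal bounds
  $\text{mean} \pm 1.96\,\text{sd}$; the width identity
  $\text{upper} - \text{lower} = 2 \times 1.96 \times \text{sd}$ is
  assertable raster-wide.
* `overlay_accuracy()` scores confirmed-resistant observation points
  against a class map: the fraction of scored points whose containing
  pixel is high-class. Cells are half-open
  $[x, x+\text{cell}) \times [y, y+\text{cell})$, so points exactly on
  the top or right grid edge fall off-grid; susceptible-status points are
  never scored, and points on nodata pixels are dropped and counted.

## Synthetic study conditions

Real TerraClimate rasters and WHO threat-map points are deliberately out
of scope; `synth_climate()` and `synth_points()` generate stand-ins with
the statistical structure the pipeline assumes, so that every stage runs
end-to-end from code alone.

The default synthetic landscape is a 40 × 40 grid at 0.5° resolution with
lower-left corner (−20, −35) — an Africa-like extent at toy resolution,
sized so the full 12-month pipeline runs in seconds. Temperature is a
latitudinal gradient around 25 °C with a ±4 °C seasonal sinusoid and
truncated Gaussian noise, clamped to [0, 45] °C; rainfall is a seasonal
bump peaking at 25 mm (half the 50 mm rainfall limit, so the oviposition
factor attains its maximum) in month 7 at the central latitude band,
floored at 0. All randomness sits behind one integer seed and identical
seeds give bit-identical grids.

`synth_points()` emulates a 295-point ground-truthing set: a chosen
fraction of points is forced into high-class pixels and the rest are
scattered uniformly over all valid pixels. Because a scattered point can
land in a high pixel by chance, the generator counts, at construction
time, how many points actually sit in high-class pixels; that count is an
exact oracle for `overlay_accuracy()`, and the end-to-end test asserts
the two agree exactly.

```{r pipeline}
clim <- synth_climate(seed = 11)
maps <- purrr::map2(clim$temperature, clim$rainfall, r0_map,
                    params = p, lh = lh)
annual <- annual_aggregate(maps)
cls <- classify_map(annual)
pts <- synth_points(cls, n = 295, frac_high = 0.92, seed = 11)
overlay_accuracy(pts, cls)
```

```{r riskmap, fig.cap = "Annual risk classification of the synthetic landscape."}
plot_risk_map(cls)
```

What passing these tests does and does not show: the synthetic fields
exercise seasonality, nodata handling, class mixing and point placement,
but they are smooth, unimodal and spatially uncorrelated in their noise —
they do not emulate real African climatology, orography, coastlines, or
the strongly clustered spatial sampling of real resistance bioassays. A
high overlay accuracy on synthetic data validates the *plumbing*, not the
epidemiological claim; validation against real data requires the real
rasters and points, which the package deliberately does not download.

## Numerical choices

* Integration: adaptive `lsoda` with relative tolerance $10^{-8}$ and
  absolute tolerance $10^{-10}$ — the system is non-stiff at the shipped
  parameter magnitudes and tight tolerances make equilibrium tests crisp.
  Compartments are counts: undershoot within $-10^{-9}$ is clipped to
  zero with a warning, anything worse is an error.
* The climate $R_0$ is computed by composing the two verified response
  functions through the closed form; the fully-substituted algebraic
  expression is kept as `r0_climate_direct()` and the two are held equal
  to $10^{-12}$ over a 50 × 50 temperature–rainfall grid in the tests.
* Class boundaries are inclusive on both ends of the moderate band;
  ties are therefore deterministic.
* Problem sizes in the shipped tests — 40 × 40 × 12 synthetic rasters,
  $n = 1000$–2000 hypercube samples, 50-point property sweeps — were
  chosen so the whole suite completes in seconds while leaving each
  statistical check adequately powered.

## Limitations

Beyond the synthetic-data caveats above: genotype structure (e.g. *kdr*
homozygote/heterozygote bookkeeping), human-host malaria dynamics,
humidity and land-use covariates, stochastic or agent-based variants, and
Sobol/eFAST sensitivity schemes are all out of scope. Monthly climate
means are treated as the representative daily forcing for their month.
The mapping pipeline performs no spatial interpolation or smoothing:
classification operates on the computed grid directly, and cartographic
styling is left to the user.
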