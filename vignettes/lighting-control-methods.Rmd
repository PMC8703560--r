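---
title: "Methods: optimal and predictive supplemental lighting control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal and predictive supplemental lighting control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenlight)
```

## The control problem

Greenhouse crops need a daily dose of photochemistry, not a fixed light
level. The package works with the daily photochemical integral (DPI): the
24-h integral of the electron transport rate (ETR), which saturates with
instantaneous photon flux (PPFD) as `ETR = a(1 − e^{−k·PPFD})`. Because of
this saturation the DPI — unlike the daily light integral (DLI) — accounts
for the diminishing photochemical value of bright light, and two days with
the same DLI but different photoperiods yield different DPIs. The shipped
crop preset ("Green Towers" lettuce: `a = 121` µmol m⁻² s⁻¹,
`k = 0.00277`, DPI target 3 mol m⁻² d⁻¹) is the parameterisation the
package's defaults are built around; any `light_response_params()` works.

The controller minimises the electricity bill of meeting the DPI target
within a photoperiod of `T` steps of `m` seconds:

$$\min_{\bar x}\; \sum_{t=1}^{T} C_t\left[\frac1k
\ln\frac{a}{a-\bar x_t-\bar s_t}-s_t\right]
\quad\text{s.t.}\quad \sum_t(\bar x_t+\bar s_t)\ \ge\ \frac{\bar D}{m\cdot
10^{-6}},\qquad 0\le\bar x_t\le \bar U_{LED}.$$

Two identities make this interpretable. First, since
$\bar s_t = a(1-e^{-k s_t})$, the bracket equals the *supplemental PPFD*
required to lift the step's combined ETR from $\bar s_t$ to
$\bar x_t+\bar s_t$; the objective is therefore the price-weighted photon
purchase, and it vanishes when no supplemental light is used. Second, the
constraint is the DPI requirement expressed in summed-ETR units; the
µmol→mol factor `1e-6` is applied in exactly one place in the package
(`integral_over_day()`), so no quantity is ever double-scaled.

### Receding horizon

In closed loop the day's sunlight is unknown. At step *i* the controller

1. observes the measured PPFD $s_i$;
2. forecasts $s_{i+1},\dots,s_T$ with the Markov model (below);
3. re-solves the program over steps $i..T$ with the requirement reduced by
   the credit $\sum_{t<i}(\bar x_t+\bar s_t)$ of light already delivered —
   realized sunlight, not the morning's forecast of it;
4. commits only $\bar x_i$.

The final re-solve (at step `T`) faces a fully known requirement, which is
what carries the DPI guarantee whenever remaining LED capacity permits. Fed
the true future instead of forecasts, the loop is time-consistent and
reproduces the single full-horizon solution — this oracle-equivalence is a
test, since it exercises the credit bookkeeping end to end.

## Solving the program

The objective is separable and strictly convex on $\bar x_t+\bar s_t<a$ and
the coupling constraint is linear, so the KKT conditions are solved
directly rather than through a general NLP routine: for multiplier
$\lambda$ on the light constraint, the per-step optimum is the closed form

$$\bar x_t(\lambda)=\mathrm{clip}\!\left(a-\bar s_t-\frac{C_t}{k\lambda},\;
0,\; \mathrm{cap}_t\right),$$

monotone non-decreasing in $\lambda$; $\lambda$ is found by bisection (200
iterations on a verified bracket) until the constraint binds. Zero-price
steps are filled first — their marginal cost is zero — but only up to the
requirement, so the plan never overshoots the target gratuitously.
Numerical choices:

* **Saturation guard.** Each step's cap is
  $\min(\bar U_{LED},\,a-\varepsilon-\bar s_t)$ with
  $\varepsilon=10^{-6}a$, keeping the log objective's argument bounded away
  from its pole.
* **Infeasibility.** If even the all-cap plan cannot cover the remaining
  requirement, that plan is returned flagged `feasible = FALSE` with the
  shortfall in ETR-sum units. A closed-loop controller must act every step,
  so this is a reporting state, not an error.
* **Verification.** Global optimality is asserted against an exhaustive
  grid-search oracle (independent objective evaluation over all grid
  plans) on 4-step instances, and by monotonicity properties of the optimal
  cost in the requirement and in sunlight.

## Sunlight prediction

The predictor is a first-order Markov chain on discretized PPFD:

* **State space** — 10 equal-width bins over `[0, training max]`
  (configurable). Out-of-range measurements on evaluation days are clamped
  into the boundary bin with a warning.
* **Time-inhomogeneity** — one transition matrix per step-of-day when at
  least 10 training days are available (sunlight dynamics are strongly
  time-of-day dependent), otherwise a single pooled matrix.
* **Smoothing** — add-α counting with default `α = 1/n_bins`. The intent of
  smoothing is only to keep unseen transitions from becoming absorbing
  zeros; a full Laplace `α = 1` adds `n_bins` pseudo-counts per row, which
  against per-step matrices fitted on a month of data (≈ 0.5 observed
  transitions per row) drowns the signal and measurably destroys the
  predictive controller's cost advantage. The default keeps the total
  pseudo-mass at one observation per row regardless of bin count. Rows of
  states never observed leaving fall back to self-persistence; they are
  unreachable from the data but can still be entered by a fresh
  measurement.
* **Representative values** — bin midpoints (unbiased under within-bin
  uniformity), optionally training-data bin means.
* **Forecast** — the *expected* PPFD: a probability vector initialised as
  the indicator of the current measurement's bin and propagated through
  the transition matrices, then dotted with the bin values at each horizon.
  The optimizer consumes expectations, not sample paths. Before sunrise,
  with no measurement yet, the forecast for every step is the per-step
  historical mean — which is also the model's known weak point on
  unusually dark mornings. Expectation propagation is tested against
  exhaustive enumeration of all bin paths on small chains.

## Synthetic weather

The generator replaces unavailable sensor/database irradiance with a
process that has the two features the controllers care about: a diurnal
envelope and persistent, multi-scale variability. A day is

    PPFD(t) = peak · transmission · amplitude_day · halfsine(t) · att(t)

sampled every 3 minutes and averaged in blocks of five to the 15-min
control step (mirroring a sensor polled every three minutes). `att(t)`
follows a 3-state (clear / partly / overcast) first-order chain with
tridiagonal transitions and stationary distribution (¼, ½, ¼);
`amplitude_day` is a mean-one lognormal factor carrying the slow
weather-system variability that a fast-mixing chain cannot produce alone.
The greenhouse transmission fraction defaults to 0.40.

Two presets were calibrated by 1000-day Monte Carlo
(`scratch/calibrate_weather.R`, frozen before any acceptance run) to match
seasonal under-shade DLI statistics: `winter_athens` targets
2.22 ± 0.6 mol m⁻² d⁻¹ (achieved 2.21 ± 0.55) with a 10 h day in the
04:30–20:30 photoperiod, and `spring_athens` targets 7.45 ± 3.11 (achieved
7.57 ± 3.35) with a 13 h day in the 05:00–21:00 photoperiod. The peak
values are *effective* constants absorbing shade-cloth and glazing losses,
not astronomical clear-sky irradiance. What the generator deliberately does
not model: solar geometry by site, spectral composition, within-day
transmission changes (shade screens), and autocorrelation between
consecutive days. Passing tests therefore demonstrate controller behaviour
under realistic *statistics* of light, not under any particular recorded
season; cost percentages quoted for real greenhouses depend on the measured
irradiance of those experiments and are reproduced here only qualitatively
(ordering and separation, not exact values).

## Pricing and units

Electricity prices are per-step vectors in cents/kWh: a fixed tariff
(default 13.19 cents/kWh) or an hourly time-of-use profile held constant
across the four 15-min steps of each hour. The shipped 24-h variable
profile is a synthetic shape (off-peak low, midday and early-evening
peaks, mean near the fixed tariff) — generated data standing in for a
market profile that exists only in graphical form. The optimizer objective
`f` has units cents/kWh × µmol m⁻² s⁻¹; with LED efficacy 2.9 µmol/J,
a supplemental PPFD `p` draws `p/2900` kW m⁻², so
`q = step_hours/(efficacy·10³)` converts `f` to cents/m², and `q·f` equals
the summed per-step costs to numerical precision (a tested identity).

## Benchmarks and their defaults

The heuristic threshold default is the minimal constant PPFD whose
photoperiod-long application meets the DPI target exactly — obtained by
inverting the light response at the required mean ETR (203.2 µmol m⁻² s⁻¹
for the lettuce preset). It is the least favourable threshold choice *for
the heuristic's cost* that still guarantees the dose, making cost
comparisons conservative; practitioners may override it. The heuristic runs
on the same steps, LED cap and duty-cycle model (linear PPFD→PWM mapping)
as the optimizers, so cost differences are attributable to strategy alone.

## Problem sizes

Simulation studies in the tests and documentation use 12–30 training days
and up to 50 evaluation days per regime, chosen as representative of one
crop cycle per season; the solver handles a full 64-step day in
milliseconds, so longer studies scale linearly.

## Known limitations

* The expectation forecast systematically overestimates sunlight on rare
  very dark days (regression toward the historical mean), which inflates
  early-day supplemental light; the final re-solves recover the DPI but at
  above-baseline cost.
* The LED bound is imposed on supplemental *ETR* as in the program above;
  because of response-curve concavity the implied physical PPFD bound is
  step-dependent. `ppfd_max_led()` reports the zero-sun equivalent used for
  duty-cycle scaling.
* Daily problems are independent: no carry-over of photochemical debt
  between days, no heating-interaction modelling, no discrete (on/off)
  lamp variant.
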