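---
title: "Mutation accumulation in a two-phase stem-cell pool and multistage cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation accumulation in a two-phase stem-cell pool and multistage cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutstage)
```

## The model

`mutstage` models somatic mutation accumulation in the stem-cell pool of a
tissue and maps the accumulated burden to an age-dependent cumulative cancer
risk. The pool has two phases:

* **Growth phase.** Starting from `N0` founding cells, every stem cell
  divides at rate `r` per cell per time unit, so the pool grows
  exponentially until it first reaches the capacity `NL`.
* **Stable phase.** At capacity, division stops. Cells are removed (death or
  differentiation, not distinguished) at rate `b` per cell; whenever the
  pool is below capacity the remaining cells divide at rate `a_d` per cell
  until the vacancy is refilled. Homeostasis therefore couples divisions to
  removals one-for-one.

Mutations come from two sources:

* **Replication errors**: at each division the daughter acquires
  `k ~ Poisson(lambda1)` new errors.
* **Lesions**: mutagen-induced mutations that arise independently of
  division. Each cell experiences lesion events at rate one per time unit,
  with `l ~ Poisson(lambda2)` lesions per event (so the lesion yield per
  cell per time unit is `lambda2`; events with `l = 0` are recorded null
  events, a bookkeeping convention that keeps the total event rate of the
  process in the simple closed form `(r + 1) N` during growth and
  `(a + b + 1) N` in the stable phase below capacity). A chronic exposure
  has `lambda2_onset = 0`; setting an onset age gates the lesion yield to
  zero before that time, e.g. an exposure that starts in adulthood.

Division and removal rates are taken independent of a cell's mutation count;
mutation-dependent rates, stem-cell competition, and age-dependent division
rates are out of scope.

### Exact simulation

`simulate_pool()` runs the process exactly with the Gillespie algorithm on
an occupancy grid `n[i, j]` of cells carrying `i` errors and `j` lesions.
The caps `I`, `J` of the grid are sized by default to roughly ten times the
expected terminal counts, so clamping at the boundary is vanishingly rare
(the run report tallies clamp events so this can be audited). Waiting times
are exponential in the grand total rate; the event class is chosen in
proportion to its class total; the affected cell is chosen uniformly by
occupancy. Each division appends one daughter at `(min(i + k, I), j)` and
leaves the parent entry untouched, which is the convention that all `k` new
errors go to one daughter.

The trajectory columns `E` and `W` count the mutation *events* generated
(new errors and lesions entering the pool), which are non-decreasing and
satisfy `E[E(d)] = lambda1 * d` exactly at every division count `d`. The
occupancy-grid sums `sum(i * n[i, j])` and `sum(j * n[i, j])` are also
available (`pool_totals()$grid_E`, `grid_W`) but they are *not* the same
quantity: the division bookkeeping copies the parent's mutations into the
daughter's label, so the grid sum inflates during growth (analytically, by
the factor `(N0 + d) log((N0 + d)/N0) / d` relative to `lambda1 d`), and
removals delete the mutations carried by the removed cell. The closed-form
approximations below describe the cumulative event counts, and the
simulator reports those as its primary outputs.

### Closed-form approximations

With `t'` the growth-phase end `log(NL/N0)/r`:

* divisions: `d(t) = N0 (exp(rt) - 1)` in growth;
  `d(t) = NL - N0 + (t - t') / tau` in the stable phase, where
  `tau = 1/(b NL) + 1/(a_d (NL - 1))` is the renewal waiting time per
  stable division;
* errors: `E = lambda1 d` in both phases;
* lesions: `W = (lambda2 / r) d` in growth and
  `W = NL lambda2 (t - t') + (lambda2 / r)(NL - N0)` in the stable phase.
  With an exposure onset, lesion accrual is `lambda2` times the integral of
  `N(s)` over the exposed interval, which reduces to the chronic forms when
  the onset is zero and handles an onset inside the growth phase as well.

`expected_totals()` evaluates the piecewise curves; all four outputs are
continuous at `t'` and monotone in `t` (property-tested over random
parameter draws).

### A known limitation of the stable-phase waiting time

The renewal form `tau = 1/(b NL) + 1/(a_d (NL - 1))` serialises the wait for
a removal and the wait for the refilling division, i.e. it assumes each
vacancy is refilled before the next removal. In the exact process the clock
toward the next removal keeps running while a vacancy refills, so for
moderate `a_d / b` the pool divides *faster* than the renewal form predicts.
At the reference small-tissue parameters (`a_d = 0.16`, `b = 0.01`,
`NL = 100`, so `a_d/b = 16`) the measured mean time to the 300th division is
about 6% shorter than the closed form, and the lesion count at a given
division count is correspondingly below the approximation. The discrepancy
vanishes as `a_d >> b` (the regime the registry fitting uses, where
`tau -> 1/(b NL)`); a dedicated test asserts both the bias at moderate
`a_d/b` and the agreement at large `a_d/b`. For this reason the
simulation-versus-approximation comparisons in the test suite use a division
grid whose stable-phase extent keeps the accumulated bias well inside the
Monte-Carlo 3-SE band (15–150 divisions at the reference parameters, 50
replicates); on much longer grids the linearly accumulating bias dominates
the shrinking standard error and the 3-SE comparison fails by construction,
a property of the printed approximation rather than of the simulator.

Statistical note: at the reference mutation rates the per-replicate error
and lesion counts at early grid points are near-zero integers, so a sample
standard error over 50 replicates can collapse to almost zero. The 3-SE
comparisons therefore floor the standard error at the Poisson sampling SE
implied by the comparison value, `sqrt(theory / n)` — a robust estimate of
the same band, not a wider tolerance.

## From burden to risk

Carcinogenesis is modelled as multistage: each mutation hits a cancer
driver gene with probability `p`, and `g` driver-gene mutations transform
the tissue. With burden `m`, the cumulative risk is the binomial tail
(`risk_binomial()`), approximated for large `m` and small `p` by the
Poisson tail with mean `p m` (`risk_poisson()`, the package default; it is
evaluated through the regularised incomplete gamma function, so tiny tails
retain full relative precision and large burdens do not overflow).

### Burden conventions

Two burden conventions are implemented, and the choice matters:

* `per_cell` (default): `m(t) = (E(t) + W(t)) / N(t)`, the average burden
  per stem cell. Under the registry convention this gives
  `p m(t) = lambda1p (1 + b (t - 18))` (up to a factor `(NL-1)/NL`) after
  age 18 — burdens of order 1–10 over a lifetime, which is the scale on
  which registry cumulative risks of a few percent arise and on which the
  turnover rates `b` ("divisions of each stem cell per year") are quoted.
* `total`: `m(t) = E(t) + W(t)`, the tissue-wide mutation count. For
  registry-sized pools (`NL` of order 1e8–1e10) the total division count is
  astronomically large and any realistic per-division driver rate saturates
  the risk at 1 within the first decades of life, so this convention is not
  usable for registry-scale fitting. It is retained because the per-cell
  and total readings both appear in the literature on burden definitions,
  and for small simulated tissues either can be sensible.

The package defaults to `per_cell` everywhere a registry-scale workflow is
involved; this is the package's resolution of a genuine ambiguity between
the per-cell definition of the burden and shorthand notation that treats
the division count as the burden scale directly.

## Registry fitting

The registry convention assumes each tissue grows from one stem cell to its
pool size `NL` by age 18 (`r = log(NL)/18` per year) and that a removed stem
cell is replaced essentially immediately (`a_d >> b`, realised numerically
with `a_d = 1e4 * b`; the fitting path uses the exact limit formula
`d(t) = NL - 1 + b NL (t - 18)` so the ratio only matters for simulation
comparisons). `registry_tissue_table()` carries turnover rates and pool
sizes for nine tissues from published stem-cell estimates.

`fit_error_only()` estimates `(g, lambda1p)` from an age versus
cumulative-risk curve by ordinary least squares: `g` is profiled over an
integer range (default 1–20, covering published estimates of 2–10 with
margin), and for each `g` the SSE is minimised over `lambda1p` on a bounded
log10 scale (coarse grid with 0.1-decade steps over [-8, 2], then
golden-section refinement; the grid pass guards against local minima since
unimodality in `lambda1p` is observed but unproven). The full per-`g` SSE
profile is returned for diagnostics, and ties resolve deterministically to
the smallest `g`. Least squares is unweighted by default — the classical
choice for these curves, with optional per-point weights exposed — and the
default age grid is the 5-year registry binning 5, 10, ..., 85.

`fit_with_lesions()` adds a mutagen term gated at an onset age (default 20),
so the per-cell burden becomes
`lambda1p * d(t)/N(t) + lambda2p * max(0, t - onset)`. The SSE is minimised
jointly over `(lambda1p, lambda2p) >= 0` per candidate `g`: an outer search
over `lambda2p` (explicit zero candidate, half-decade log grid over
[1e-16, 1e4], golden-section refinement) with the inner `lambda1p` profile
solved as above, then a Nelder-Mead polish of the best interior point on
the log scale. All stages are deterministic. A fit that lands on the
`lambda2p = 0` boundary coincides with the error-only fit (the models are
nested) and is flagged as adding no explanatory power.

Noiseless self-consistency — generating a curve from the model and
recovering its parameters — holds exactly for `g` and to better than 0.1%
for `lambda1p` across all nine tissues, `g` in 2–8 and `lambda1p` over four
decades; the acceptance script recomputes this grid. Fitting *real*
registry data is a separate matter: those fits depend on an external data
download, and the published point estimates also reflect that data's cohort
structure, so they are not reproduced here. The CSV reader ingests such
data when the user supplies it (percent scales are auto-detected when
several values exceed 1; a lone value above 1 is treated as an out-of-range
error rather than silently rescaled).

## Mutagen influence: risk difference

`risk_difference()` quantifies the influence of a mutagen as
`RD(t) = G1(t) - G0(t)`, the cumulative risk with the lesion rate minus the
risk with `lambda2 = 0` and everything else equal. Risk ratios are avoided
because the baseline `G0` can be exactly zero. `RD` starts at zero (no
mutations yet), peaks at intermediate ages and returns to zero once
replication errors alone saturate the risk. The peak is located on a dense
age grid (default resolution 0.1 years, recorded in the output) with local
golden-section refinement inside the bracketing grid cells.

Three single-parameter scans around the base setting `N0 = 1`, `NL = 1e9`,
`r = log(NL)/18`, `lambda1 = 0.5`, `p = 0.2` reproduce the qualitative
behaviour of the model (property-tested):

* larger `lambda2` — higher and earlier peak;
* smaller turnover `b` — later and higher peak (errors accumulate slowly,
  so fewer cancers arise without the mutagen, but also later);
* smaller `g` — earlier and lower peak (fewer hits suffice, so the mutagen
  tips the balance sooner, but the baseline is higher).

The scanned grids (one decade apart, bracketing the fixed values:
`lambda2` in 1e-3–1e-1, `b` in 0.01–1, `g` in 2–6) are the package's
choice; the fixed values in each scan are the reference ones above.

## The synthetic-data generator

`generate_registry_curve()` produces registry-style curves with known
ground truth for testing the whole pipeline without any download. The
default conditions mirror the registry workflow: the 5–85 year five-year
age grid, tissues from the registry table, and error-only or
error-plus-lesion model curves under the `per_cell` convention. Noise is
binomial by default conceptually — registry cumulative risks are
proportions from finite cohorts — with a default cohort of 1e6 per age
point (the scale of single-year national birth cohorts); additive gaussian
noise is available for the least-squares noise model. Noisy cumulative
curves are restored to monotonicity by a running maximum (raw output is
available behind `monotonize = FALSE` for stress-testing the fitter).
What the generator does not emulate: birth-cohort effects, coding changes,
competing mortality, and population structure — so a pipeline that passes
on synthetic curves is validated for the model's own assumptions, not for
those registry artifacts.

## Numerical choices

* Risk tails are computed with `lower.tail = FALSE` so that curves with
  tiny risks keep ~15 significant digits; this is what makes noiseless
  parameter recovery exact even where every risk value is below 1e-16.
* The simulator draws the lesion count before selecting the affected cell
  and skips the cell draw for null events; RNG use is documented and runs
  are reproducible from a single integer seed (replicate `r` of a
  summary uses `seed + r`).
* `optimize()` tolerances: 1e-12 on the log10 rate scale (fit), 1e-10 on
  the log10 lesion-rate scale, peak refinement at 1e-4 of the grid
  resolution.
* Degenerate inputs: all-zero risk curves are rejected as unfittable; an
  absorbing simulation state (empty pool) ends the run early with a flag;
  `r = 0` with `NL > N0` is a growth phase that never ends and is handled
  piecewise.
* Problem sizes in the test suite: 50 replicates on a 15–150 division grid
  for the simulation/approximation comparison, the full 9 x 7 x 4 recovery
  grid, and 100-draw randomized grids for the distributional identities.

## Limitations

* The stable-phase closed forms are a renewal approximation (see above);
  the simulator is the reference for exactness.
* Eq-level inconsistency between the occupancy-sum and event-count readings
  of `E`, `W` is resolved in favour of event counts (see "Exact
  simulation"); the occupancy sums remain inspectable.
* Published fitted values for real registry data are not desk-reproducible
  (external data); the fitting pipeline is validated by synthetic-recovery
  and end-to-end CSV ingestion instead.
* No confidence intervals on fitted parameters (point estimates only), no
  competing mortality, no polyclonality, no mutation-dependent rates.
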