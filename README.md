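# mutstage

Stem-cell mutation accumulation and multistage cancer risk.

Age-dependent cancer risk tracks the number of stem-cell divisions a tissue
has undergone, but mutagens (radiation, smoking) add mutations on top of the
replication-error baseline, and their influence — especially at low dose —
is hard to see against that baseline. `mutstage` is for modellers and
radiation-protection / cancer-epidemiology researchers who want to compute
that baseline explicitly and measure how a mutagen perturbs it.

The model: a tissue's stem-cell pool grows exponentially at rate *r* from
*N₀* founding cells to its capacity *N_L* (growth phase), after which cells
divide (rate *a_d* per cell) only to replace removed cells (removal rate *b*
per cell, stable phase). Replication **errors** arrive at division,
Poisson(*λ₁*) per division; mutagen-induced **lesions** arrive independently
of division, Poisson(*λ₂*) per cell per time unit, optionally gated to start
at an exposure onset age. Carcinogenesis is multistage: each mutation hits a
cancer driver gene with probability *p*, and the cumulative risk of having
accumulated at least *g* driver hits by age *t* is the Poisson tail

> G(t) = 1 − Σ_{k<g} (p·m(t))^k e^{−p·m(t)} / k!

with *m(t)* the mutation burden per stem cell (binomial form also
available). Under the registry convention (single founding cell, capacity
reached at age 18, immediate replacement of removed cells) the burden has a
closed form, and the two free parameters — the driver mutation rate per
division *λ₁p* and the driver-gene count *g* — can be fitted to registry
curves of age versus cumulative cancer risk by least squares, with an
optional lesion term *λ₂p* to represent a mutagen.

The package provides:

* `simulate_pool()`, `sim_step()`, `replicate_summary()` — exact Gillespie
  simulation of the two-phase process on an (errors × lesions) occupancy
  grid;
* `expected_totals()`, `divisions_growth()`, `lesions_stable()`, ... —
  the closed-form approximations for divisions, errors and lesions;
* `risk_poisson()`, `risk_binomial()`, `risk_curve()` — the multistage risk
  functions;
* `fit_error_only()`, `fit_with_lesions()`, `registry_tissue_table()` —
  least-squares estimation of (*g*, *λ₁p*[, *λ₂p*]) from cumulative-risk
  curves for nine reference tissues or custom ones;
* `risk_difference()` — the mutagen-influence measure RD(t) = G₁(t) − G₀(t)
  with peak localisation;
* `synthetic_curve_spec()`, `generate_registry_curve()` — registry-style
  synthetic curves with known ground truth and binomial or gaussian noise;
* `read_risk_curve_csv()`, `write_outputs()` and a command-line wrapper
  (`exec/mutstage`) with subcommands
  `simulate | approx | risk | riskdiff | fit | synth`.

## Worked example

Generate a registry-style synthetic curve for colonic stem cells (turnover
73 divisions per stem cell per year, pool size 2×10⁸) with known ground
truth *g* = 5, *λ₁p* = 4×10⁻⁴, binomial sampling noise from a cohort of 10⁶
per age point — then recover the parameters:

```r
library(mutstage)

tis <- registry_tissue("colon")
tis
#> Tissue parameters
#>   N0 = 1, NL = 2e+08 (cells)
#>   r = 1.06188 (growth), a_d = 730000, b = 73 (stable, per cell per time)

spec <- synthetic_curve_spec("colon", true_g = 5, true_lambda1p = 4e-4,
                             noise = "binomial", cohort_size = 1e6, seed = 42)
curve <- generate_registry_curve(spec)
tail(curve, 3)
#>    age     risk
#> 15  75 0.027276
#> 16  80 0.037563
#> 17  85 0.048734

fit <- fit_error_only(curve, tis, g_range = 1:12)
fit
#> Least-squares fit of the multistage risk curve
#>   g_hat = 5, lambda1p_hat = 0.000400112
#>   SSE = 2.2328e-07 over 12 candidate g
```

The fitted curve reaches ~4.9% cumulative risk by age 85 (the registry
scale for colon cancer), and the true driver count (5) and rate (recovered
as 0.000400, 0.03% off under sampling noise) come back from the noisy data.

How strongly would a chronic mutagen perturb such a tissue? The risk
difference peaks where the mutagen matters most:

```r
rd <- risk_difference(seq(0, 800, 2), make_tissue_from_registry(1e9, b = 0.1),
                      mutation_params(0.5, 0.01), risk_params(0.2, 6))
rd
#> Risk difference curve (401 ages, per_cell convention)
#>   peak RD = 0.1717 at t = 557.2 (resolution 0.1)
```

A slowly cycling tissue (*b* = 0.1) shows a large but very late mutagen
influence; raising the turnover moves the peak earlier and lowers it.

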