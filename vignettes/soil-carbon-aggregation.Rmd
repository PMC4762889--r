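---
title: "Methods: five-pool soil carbon dynamics and climate-input aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five-pool soil carbon dynamics and climate-input aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awenh)
```

## The decomposition model

Soil organic carbon is represented by five chemical pools: four labile
compound groups into which fresh litter is partitioned — A
(acid-hydrolyzeable), W (water-soluble), E (soluble in a non-polar
solvent), N (neither soluble nor hydrolyzeable) — and humus H, a more
recalcitrant end product formed from a fixed fraction of all decomposed
labile mass. Each pool loses mass by first-order kinetics; a part of the
decomposed mass of pool $i$ is routed to pool $j$ (mass-flow fraction
$p_{ij}$) or to humus ($p_H$), and the remainder leaves the system as
heterotrophic respiration. Writing the pool vector $x$ (kg C m$^{-2}$)
and the annual litter input $b$, the system is linear:

$$\frac{dx}{dt} = M\,x + b, \qquad
M_{ii} = -k_i,\quad M_{ji} = p_{ij}\,k_i .$$

The climate dependence of the labile rates is

$$k_i = \alpha_i\,
  \exp(\beta_1 T + \beta_2 T^2)\,\bigl(1 - e^{\gamma P}\bigr)\, h(d),$$

with $T$ the mean annual temperature (°C), $P$ the annual precipitation
(m; the user-facing interface takes mm and converts internally), and
$h(d)$ a woody-size modifier. The humus rate is $k_H = \alpha_H$ times
the same climate factor; woody-size features do not apply to humus. The
dimensionless *climate dependence factor*
$\exp(\beta_1 T + \beta_2 T^2)(1 - e^{\gamma P})$ is the central
diagnostic of the package: it rises steeply with precipitation when dry,
saturates beyond roughly 1500 mm yr$^{-1}$ (with the shipped $\gamma$ the
relative sensitivity per mm at 2000 mm is under 3 % of that at 200 mm),
and rises with temperature over the boreal range. Because the factor is
concave in precipitation in the dry regime and steady-state stocks scale
as $1/k$, spatial averaging of climate before the nonlinearity biases
stocks — the Jensen mechanism the aggregation experiment quantifies.

An optional sinusoid mode averages the temperature term over twelve
monthly temperatures $T_m = T + A\sin(2\pi m/12)$ with amplitude
$A = (t_{\max}-t_{\min})/2$ reconstructed from the lowest and highest
monthly means. The default is the annual-mean mode: with the shipped
parameters it reproduces the reference worked value of the dependence
factor at 3.5 °C and 1150 mm (1.033, against a published 1.031), which a
sinusoid correction would not. Both modes are exposed via
`use_sinusoid`.

### Parameters

The shipped constants (`inst/extdata/yasso07_map.txt`, loaded by
`yasso07_params()`) are the published maximum-a-posteriori Yasso07
estimate (Tuomi et al. 2011): labile rates $\alpha_{A,W,E,N}$ = 0.73,
5.8, 0.29, 0.031 yr$^{-1}$, humus rate $\alpha_H$ = 0.0017 yr$^{-1}$,
twelve mass-flow fractions, humus share $p_H$ = 0.0045, climate
coefficients $\beta_1$ = 0.096 °C$^{-1}$, $\beta_2$ = −0.0014 °C$^{-2}$,
$\gamma$ = −1.21 m$^{-1}$, and woody-size coefficients $\phi_1$ = −1.71,
$\phi_2$ = 0.86 (per cm) with exponent $r$ = −0.306 in
$h(d) = \min\{1, (1+\phi_1 d+\phi_2 d^2)^r\}$. The functional form of
$h$ is the published woody-litter parameterization; $h(0) = 1$ encodes
that non-woody litter has no woody-specific behaviour, and $h$ decreases
with diameter so 10 cm material outlives 2 cm material. Every function
accepts an alternative `awenh_params` object, and `read_params()` /
`write_params()` round-trip the flat key = value format, so the
parameter file is configuration, not code.

### Numerics

The forcing is piecewise constant over calendar years, so the package
integrates exactly rather than by time-stepping error-prone schemes:

* one year advances as
  $x(t{+}1) = e^{M}x + M^{-1}(e^{M}-I)\,b$, with a truncated
  $\varphi$-series fallback when `rcond(M)` < 10$^{-12}$ (this also covers
  the zero matrix, pure accumulation);
* steady states solve $Mx + b = 0$ directly and fail loudly on numerically
  singular matrices (condition number above 10$^{12}$) or a zero climate
  factor, which has no finite equilibrium;
* the landscape runner exploits that every rate matrix for a given
  parameter set and size class is $c\,B_d$ with $c$ the climate factor:
  $B_d$ is diagonalized once and the annual step for all plots becomes a
  handful of 5-row matrix products
  ($e^{cB} = V\,\mathrm{diag}(e^{c\lambda})\,V^{-1}$, input term via
  $\varphi_1(z) = (e^z-1)/z$). Equivalence with the reference
  `Matrix::expm()` path is asserted to 10$^{-9}$ in the tests. $M$ is a
  Metzler matrix, so the exact exponential preserves non-negativity by
  construction.

Carbon balance is auditable at every step: `step_annual_fluxes()`
integrates $\int_0^1 x(t)\,dt$ independently of the state update and
reports the atmospheric export, and the identity
$\Delta(\text{total}) = \text{input} - \text{export}$ closes to
10$^{-10}$ relative in the tests.

### Spin-up and the humus timescale

`spin_up()` iterates the annual step for 5000 years under constant
climate (the 1961–1990 normal) and constant litter, checks the final
per-step relative change against 10$^{-6}$, and warns with diagnostics
when unconverged. A caveat worth stating explicitly: starting from empty
pools, the humus gap to equilibrium decays as $e^{-5000\,k_H}$, which
with $\alpha_H = 0.0017$ yr$^{-1}$ is $\approx 2\times10^{-4}$ at climate
factor 1 and far larger in cold-dry climates — 5000 years is *not* enough
to equilibrate humus to high precision, in this or any implementation of
the same constants. The labile pools do equilibrate to well below
10$^{-6}$. For this reason the experiment runner initializes pools at the
*analytic* steady state, which is exact, and the iterative spin-up serves
as a cross-check of the dynamics rather than as the production
initializer.

## Litter bookkeeping

Annual litter input per plot is the sum of:

* **living vegetation turnover** — biomass component × annual turnover
  rate; species-specific tree rates (e.g. foliage 0.143 / 0.33 / 1
  yr$^{-1}$ for spruce / pine / deciduous; branches and coarse roots
  0.0125 / 0.027 / 0.025; fine roots 0.6 for all) and ground-vegetation
  class rates above/below ground. Fine-root biomass is 0.3 × foliage;
  below-ground ground vegetation is twice above-ground (mosses and
  lichens, having no roots, contribute above-ground litter only);
* **natural mortality** — an annual fraction of the stand transfers every
  component to litter in its size class;
* **harvest residues** — a harvested fraction transfers everything except
  the commercially extracted stems (stumps, branches, foliage, roots);
  non-commercial extraction can leave stems on site.

Size classes are 0 cm (foliage, fine roots, bark, ground vegetation),
2 cm (branches, coarse roots) and 10 cm (stems, stumps); living trees
shed stems and stumps only through mortality or harvest. Chemical quality
attaches per species × component from an editable table
(`inst/extdata/awen_chemistry.tsv`); the shipped values are rounded
defaults in the range of published boreal litter-chemistry compilations
and are deliberately configuration, not ground truth — published
applications differ in their sources for these fractions. Birch stumps
follow the pine rule, expressed simply as shared table rows for woody
components. Litter input is held constant within each 5-year inventory
cycle; harvest pulses are spread evenly over the cycle's five years.

## Initialization and the historical series

Simulations need pools that reflect stand history, not just the first
inventory. Each plot is initialized at steady state under its climate
normal and the *group-mean* litter of its species × site-productivity
class at first inventory, then driven through a deterministic historical
litter series (default 1956 up to the first inventory year — a common
start for all plots, since the rules fill whatever span is asked of
them) built by `back_cast_litter()` from first-inventory attributes
alone. Rule classes: stands older than 34 years are back-projected
geometrically by a per-cycle change rate ($b_{t-5} = b_t/(1+r)$, default
$r$ = 0.10 per cycle); young unproductive stands are held constant; young
productive stands are traced to age zero with the previous rotation
standing at a configured mature biomass (by species and site class) until
its harvest releases a residue pulse; after land-use change a configured
prior biomass scale applies; northern low-productivity plots are traced
to age zero and carry only ground vegetation further back. All rule
parameters live in `inst/extdata/backcast_rules.yaml`. The back-cast is a
pure function — no randomness — and the tests assert that pools are
steady at the pre-simulation start and drift once trending forcing
begins.

## Aggregation schemes and the experiment

`aggregate_climate()` produces exactly one climate record per plot-year
under a scheme from {plot, district, country} × {longterm, fiveyear,
annual}. Spatial means are unweighted over member plots, computed per
variable per year (per-variable averaging *before* any sinusoid
transformation — the alternative order was considered and rejected as it
would make the aggregate depend on the response mode). The long-term
scheme fixes the 1991–2008 mean for all years; the 5-year scheme averages
over each plot's own inventory interval (windows anchored at its first
inventory year, extended backward over the historical period); annual
uses each year as is. Spin-up climate is always the plot's own 1961–1990
normal regardless of scheme, and litter input is never aggregated.

The five named simulations cross these scales: I = plot × long-term (the
reporting standard), II = district × long-term, III = country ×
long-term, IV = plot × 5-year, V = plot × annual. `run_simulation()` is
deterministic given its inputs; `report()` returns a tidy long table
(country mean stock, district stocks, district 5-year changes, annual
national change series). Reporting windows default to 2008–2012 for
stocks and 2000–2012 for changes, with the national series available for
the full span. National totals multiply each plot's change by its
representation area (default 900 ha) and are reported in Gg C. District
stock summaries are unweighted plot means, matching the unweighted
spatial climate means.

Expected magnitudes are data-dependent and are not asserted; only the
two directional hypotheses are: (H1) country-scale climate input lowers
the national mean stock relative to plot-scale input, and (H2) under a
post-1990 warming trend, annual or 5-year climate input lowers the
cumulative national stock change relative to the long-term mean.

## The synthetic landscape generator

The generator exists so the full pipeline runs and is testable without
restricted inventory or climate-grid data. It emulates the *structure* of
a northern national forest inventory: a plot network in 19 districts
across three climatic regions — a warm-wet coastal southwest (baseline
6 °C / 2000 mm), a colder, drier southeast (3 °C / 700 mm) and a cold
north (0 °C / 600 mm); these baselines are plausible defaults chosen
here, not values from any data set — with fixed district/plot offsets, a
linear post-1990 trend (defaults +0.04 °C yr$^{-1}$, +3 mm yr$^{-1}$) and
independent interannual noise; 5-year re-measurement cycles offset across
plots (first inventories 1986–1993); species (spruce/pine/deciduous),
gamma-distributed stand ages kept consistent with the back-cast rule
mixture (default 76 % mature, 3 % young unproductive, 19 % young
productive, 2 % land-use change, with a northern low-productivity
override); organic-layer thickness spanning the 0.4 m upland threshold so
the filter is exercised; and logistic age–biomass curves with fixed
component shares (fine roots tied to foliage by the 0.3 rule), a
plot-level lognormal multiplier, annual mortality 0.005 (a free generator
parameter; the underlying inventory change tables are unpublished) and
occasional clear-cuts past the recommended harvest age. Foliage shares
(13 % spruce, 5 % pine, 4 % deciduous) are realistic for boreal stands
and, combined with the turnover table, yield the expected litter
ordering: spruce stands out-produce pine and deciduous stands of equal
age. The three streams (landscape, climate, biomass) are independently
seeded and restore the caller's RNG state.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial autocorrelation beyond the
region/district hierarchy, real geography or sampling design, biomass
measurement error, species mixtures within a plot, climate
interpolation error, and any calibration of absolute magnitudes. The
directional aggregation results are structural consequences of the
model's nonlinearity and should transfer; the sizes of the effects are
properties of the synthetic configuration only.

## Problem sizes and limitations

The test suite exercises landscapes of tens to hundreds of plots; the
full acceptance run uses 2000 plots over 1956–2012, which completes in
seconds thanks to the eigen-propagator. Known limitations: no vertical
soil structure (the pools are totals over the profile); sub-annual
climate enters only through the optional sinusoid temperature averaging;
parameter uncertainty is out of scope (the constants file is a point
estimate); harvested stems simply leave the system (no product pool); and
the iterative spin-up inherits the humus-timescale caveat discussed
above.
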