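---
title: "Modelling density-dependent facilitation with zones of influence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling density-dependent facilitation with zones of influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoifacil)
```

## The question

Stress-gradient reasoning predicts that plant-plant interactions shift
from net competition towards net facilitation as abiotic stress
intensifies. Most tests compare plants with and without neighbours and
ignore *how many* neighbours there are. `zoifacil` implements a
spatially explicit, individual-based model in which both the benefit a
plant receives from neighbours (stress amelioration) and the cost
(shared resources) emerge from the same geometry, so that the
interaction-density relationship and its change along a stress gradient
can be simulated, summarised and analysed statistically.

## The model

### Zones of influence

Each plant $i$ is a circle of area $A_i = C_0\, m_i^{3/4}$ centred on
its position, where $m_i$ is its biomass; the circle is the zone of
influence (ZOI), the area over which the plant can acquire resources
and, in harsh conditions, the area over which it perceives stress. The
arena is a 200 x 200 grid of unit patches with opposite edges identified
(a torus), so there are no edge effects. A patch belongs to a ZOI when
its centre falls inside the circle; all areas that enter interaction
indices are counted in rasterized patches, which keeps every ratio below
exactly in $[0, 1]$.

Where ZOIs overlap, each contested patch is divided twice, by two
independent rules:

* **Resources.** One patch worth of resource is split among the $k$
  coverers with weights $A_j^p$. The exponent $p$ is the mode of
  competition: $p = 0$ shares equally, $p = 1$ in proportion to size,
  $p = \infty$ gives the whole patch to the largest plant. Summing a
  plant's shares over its patches gives $A_{c,i}$, the resources it
  actually obtains, and the competition index
  $I_{c,i} = A_{c,i} / A_i \in [0, 1]$.

* **Stress.** The patch's stress burden is shared with weights $A_j^q$
  ($q$, the mode of facilitation): plant $i$ bears a fraction
  $w_{q,i}$ of the stress on that patch and is shielded from the rest
  by its neighbours. Its amelioration gain on the patch is
  $(1 - w_{q,i})$, accumulated into $A_{f,i}$, and the realized-stress
  index is $I_{f,i} = 1 - A_{f,i}/A_i \in [0, 1]$.

Two consequences of the stress-sharing rule are worth stating, because
they carry the ecology. First, a small plant whose ZOI lies inside a
large benefactor's ZOI bears almost none of the shared stress: its
$I_f$ approaches 0 and it benefits almost fully, while the same overlap
area does much less for a large plant — the facilitative *response* is
size-dependent (`generate_toy_geometry("fig5-triplet")` packages this
configuration, and `compute_field()` reproduces the inequality).
Second, per-capita relief on a patch grows with the number of coverers
($1 - 1/k$ for equal plants), so more neighbours ameliorate stronger
stress — the mechanism behind the rightward shift of the
facilitation-density peak. At $q = \infty$ the largest coverer bears
the entire shared stress and receives no relief: asymmetric
facilitation is nurse-plant-like sheltering by the big.

### Growth

An isolated plant follows the metabolic-scaling growth form

$$\frac{dm}{dt} = a\, m^{3/4} \left[1 - S - (m/M)^{1/4}\right],$$

where $S \in [0, 1]$ is the stress intensity (the proportional
reduction in incoming energy) and $M$ the theoretical maximum mass. The
isolated equilibrium is $m^\* = M (1 - S)^4$. With neighbours, the rate
is expressed per unit ZOI area through the intrinsic rate
$r$ (mass area$^{-1}$ time$^{-1}$):

$$\frac{dm}{dt} = r A \left[(1 - S\, I_f)\, I_c - (m/M)^{1/4}\right],$$

which reduces *exactly* to the isolated form when $I_c = I_f = 1$ and
$a = r C_0$ (the package enforces this identity by default and tests it
to machine precision). The term $S I_f$ is the stress the plant still
experiences after amelioration; because $I_f$ divides by the plant's
own area, equal amelioration helps small beneficiaries more, with
consistent units (mass time$^{-1}$) on both sides.

The population is advanced synchronously by forward Euler with step
`dt` (default one tick): one interaction field is computed per step and
all masses update from that snapshot, so plant order cannot matter.
Masses are capped at $M$; a plant whose mass falls to zero dies and
never re-enters the field (the minimal mortality hook — stress alone
never kills an isolated plant in this model, a point that matters
below).

## Parameters, defaults, and why

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `M` | 20000 mass units | theoretical maximum mass; sets the scale of all biomasses |
| `C0` | `zoi_c0(40, M)` | allometric constant chosen so a plant at mass `M` has ZOI radius 40 cells — large enough that stressed ZOIs (radius shrinks as $(1-S)^{3/2}$) can still reach neighbours inside the density window, small enough to stay far from the torus half-span limit |
| `a` | 1.5 | intrinsic growth constant; the characteristic time $4 M^{1/4}/a \approx 32$ steps means plants are still growing at the 50-step measurement — an annual harvested mid-growth. This matters: measured at equilibrium, extreme-stress facilitation dwarfs everything else, whereas the time-resolved behaviour of the model (the facilitation-density curve drifts left as plants grow) shows the interesting regime is the transient |
| `r` | `a / C0` | keeps the isolated and neighbourhood growth forms identical |
| `m0` | $M (1-0.85)^4 \approx 10.1$ | seedling mass at the zero-net-growth point of the *extreme* stress level: "extreme" means an isolated seedling cannot grow at all, consistent with defining the top of the gradient as near-complete performance limitation |
| `dt` | 1 | one tick; see numerical notes |
| stress levels | 0, 0.45, 0.75, 0.85 | none, low, high, extreme |
| density levels | 2..8 | the treatment axis and the covariate in all analyses |
| `plants_per_level` | 150 | plants per density level (300..1200 per arena). Density levels are *scaled* counts: with at most 8 plants on a 200 x 200 torus, nearest-neighbour spacing (35-100 cells) exceeds any stressed ZOI's reach for every admissible calibration, so no interaction — let alone its density dependence — could occur at literal counts |
| replicates | 5 | per design cell, measured after 50 steps |
| `p`, `q` | 1, 1 | size-symmetric competition and facilitation (the baseline scenario); robustness runs use $\{0,1\}^2$ |
| patterns | random / regular / aggregated | uniform, centred near-square lattice, Gaussian clusters |
| clusters, `cluster_sd` | 60, 20 | aggregated-pattern constants. A *fixed* cluster count makes within-cluster density scale with the density treatment; tying the count to $N$ would hold local density constant and erase the treatment. Scatter of 20 cells keeps clumps distinct without fusing them into stacks |

The calibration (which the source model publishes only in supplementary
material) was chosen once, by a sweep, to place the system in the
regime the theory describes — stressed ZOIs begin to touch *within* the
density window — and then frozen; every figure and test in the package
runs at these defaults.

## The experiment and its statistics

`run_factorial()` crosses stress with density (5 replicates each),
derives one seed per cell from the master seed so any cell is
reproducible in isolation, and records per replicate the mean survivor
biomass $P_w$, the lone-plant baseline $P_s$ (the same Euler
integration without neighbours, so a plant that never interacts has
RII exactly 0), and

$$\mathrm{RII} = \frac{P_w - P_s}{P_w + P_s} \in [-1, 1],$$

negative under net competition, positive under net facilitation.

Two diagnostics summarise each stress level's RII-density curve.
`peak_density()` is the argmax (ties break to the lower density, which
is conservative when testing for a rightward shift).
`classify_shape()` distinguishes *monotone-decreasing* from
*hump-shaped* with a tolerance expressed in replicate standard errors:
each successive difference of cell means is allowed to deviate by twice
its own standard error $\sqrt{\mathrm{sem}_i^2 + \mathrm{sem}_{i+1}^2}$,
and a hump must additionally rise from the lowest density by more than
one standard error. The hump test runs first so a genuine interior peak
is not absorbed into the monotone band.

The Bayesian layer fits four Gaussian linear models of RII — stress
only, density only, additive, and full interaction on standardized
predictors — with weakly informative priors ($N(0, 10^2)$ coefficients,
half-Gaussian scale 10 on the residual SD; weak on a $[-1,1]$ response).
Sampling is Gibbs (exact conjugate conditional for the coefficients,
slice sampling for the residual scale), 4 chains with 5000 warmup and
5000 kept draws each — 20000 posterior draws in total. Convergence is
checked with split-chain R-hat against 1.05; models are compared by
WAIC, $-2(\mathrm{lppd} - p_\mathrm{waic})$, with Akaike-type weights
$\propto e^{-\Delta/2}$; `model_average()` mixes posterior draws across
models in proportion to those weights, which widens credible sets in
proportion to selection uncertainty. The contract is the posterior, not
the sampler: the test suite checks the Gibbs output against the exact
conjugate posterior at fixed residual scale and against hand-computed
WAIC oracles.

## The synthetic-data generator

`generate_synthetic_rii()` draws replicate RII tables from a *linear*
model on standardized stress, density, and their product, plus Gaussian
noise, clipped to $[-1, 1]$ (clips are reported). It emulates the
*schema and design size* of the experiment — and is the ground-truth
harness for parameter recovery, coverage, and WAIC model-selection
tests — but deliberately not the simulator's nonlinearity: real
factorial output saturates near $-1$ at zero stress and bends around
interior peaks under high stress, which no linear surface reproduces.
Passing the statistical tests therefore certifies the inference
machinery, not the linearity of the ecological response; conversely the
geometric and dynamical tests certify the simulator, not the
statistics. (The same caveat applies to real greenhouse data, which add
germination failure, transplanting, and mortality that the generator
does not model.)

## Numerical choices

* **Rasterization** uses the cell-centre rule (a patch is covered iff
  its centre is strictly inside the circle): cheap, unbiased to first
  order, and convergent — the suite checks rasterized pairwise overlap
  against the closed-form lens area at increasing resolution. A circle
  whose radius reaches half the arena span is rejected (self-overlap on
  a torus is undefined); the calibration keeps all radii well below it.
* **Exact ratios.** $A$, $A_c$, $A_f$ entering $I_c$, $I_f$ are all
  rasterized cell counts, so the $[0,1]$ bounds hold identically, and
  $\sum_i A_{c,i}$ equals the union's rasterized area exactly (tested
  on 1000 random configurations). A plant that rasterizes to zero cells
  (possible at seedling sizes) takes $I_c = I_f = 1$ by convention.
* **Sharing weights** are computed relative to the largest ZOI to avoid
  overflow at large exponents; exact ties at infinite exponents split
  equally; an underflowed weight sum falls back to equal shares.
* **Time discretization** is forward Euler with `dt = 1`. At the
  default growth rate, halving `dt` changes an isolated plant's 50-step
  mass by up to 2.4% (the trajectory is mid-growth, where Euler error
  peaks) but leaves every quantity the package asserts — RII values
  (within 0.01), curve classifications, peak densities — unchanged;
  `dt` is configurable for users who want tighter trajectories.
* **Determinism.** All randomness flows from integer seeds through R's
  RNG (including the C++ samplers, which call R's RNG); factorial cells
  derive their seeds by folding the design coordinates through an LCG,
  so subsets rerun identically.
* The equivalence of the fast C++ interaction field with a plain
  cell-by-cell enumeration is asserted over random configurations,
  including infinite exponents.

## Design choices where the ground was open

* **Amelioration bookkeeping.** The source model defers the exact
  $A_c$/$A_f$ computation to unavailable supplementary material; the
  stress-*sharing* scheme here (bear $w_q$, shed $1 - w_q$) is a
  reconstruction chosen because it is the only simple cell-wise rule
  that simultaneously (i) makes the fully covered small beneficiary
  benefit almost fully, (ii) makes per-capita relief grow with local
  crowding, and (iii) keeps $I_f \in [0,1]$ with exact arithmetic.
  The alternative — splitting an amelioration *budget* by $w_q$ —
  coincides for equal pairs but reverses (i) and (ii).
* **$P_s$ at the measurement step**, not at equilibrium: the baseline
  is the same-step lone integration, which keeps RII exactly zero for
  non-interacting plants and mirrors measuring control pots on harvest
  day.
* **Mean survivor biomass per replicate** is the unit of analysis
  (the replicate, not the plant, is the statistical unit).

## Known limitations

* **Low-density ordering at extreme stress.** In this model the mean
  RII at the *lowest* density increases monotonically with stress:
  sparse-contact events are rare ($\propto (1-S)^3$ through ZOI
  geometry) but their payoff, the biomass ratio of facilitated to lone
  plants, grows like $(1-S)^{-4}$ near the top of the gradient, and
  the product rises with $S$ for every calibration we probed. The
  empirical pattern that facilitation at the lowest densities is
  weaker under extreme than under high stress most plausibly requires
  stress-induced mortality of poorly facilitated individuals, which
  the minimal death rule (death only at zero mass) cannot produce.
  The acceptance suite states this expectation faithfully and reports
  the failure rather than masking it.
* **Regular lattices under extreme stress.** At $S = 0.85$ the largest
  reach an unfacilitated plant can attain is $2 r_\max (0.15)^{3/2}$
  cells; on a maximally even lattice this is below the plant spacing
  at every admissible $r_\max$ (the torus caps radii at half the
  span), so first contact never happens, the RII-density curve is
  identically zero, and the hump cannot appear. Random and aggregated
  patterns, which contain chance clusters, do not have this floor.
* **Saturation at zero stress.** The default calibration drives
  zero-stress competition close to the RII floor of $-1$, which
  flattens the low-stress curves; one statistical consequence is that
  the *linear* stress-by-density interaction adds little over the
  additive model on the factorial's own records (the interaction the
  simulator produces is strongly nonlinear), while the interaction
  model is recovered essentially always on synthetic data generated
  from it.
* One species, one homogeneous stress field, no seed dispersal or
  multi-generation dynamics; fecundity is out of scope.

## Problem sizes used in the checks

The packaged checks run the full factorial (4 stress x 7 density x 5
replicates, 300-1200 plants per arena, 50 steps) once per spatial
pattern or mode variant; statistical calibration uses 20 model-recovery
datasets and 100 coverage replications at the design size (140
observations each); geometric invariants use 1000 random small-arena
configurations. These sizes were chosen so the entire suite documents
the model's behaviour at the study design itself rather than at toy
scale.
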