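# zoifacil

Spatially explicit simulation of density-dependent plant–plant
interactions under stress, for ecologists studying when facilitation
outweighs competition — and in particular how that balance depends on
neighbour *density*, the variable most facilitation experiments leave
out.

## The model in brief

Each plant is a circle (zone of influence, ZOI) of area
`A = C0 · m^(3/4)` on a 200 × 200 wrap-around patch grid. Where ZOIs
overlap, each contested patch is divided twice: its **resources** are
split with weights `A_j^p` (mode of competition *p*: 0 = equal shares,
∞ = winner-takes-all), and its **stress burden** is shared with weights
`A_j^q` (mode of facilitation *q*) — a plant bears its share and is
shielded from the rest by neighbours. This gives each plant a
competition index `I_c = A_c / A` and a realized-stress index
`I_f = 1 − A_f / A`, both in [0, 1], and the growth equation

    dm/dt = r · A · [ (1 − S·I_f) · I_c − (m/M)^(1/4) ],

with stress `S ∈ [0, 1]`. With no neighbours (`I_c = I_f = 1`) this is
the metabolic-scaling growth law with equilibrium `M(1 − S)^4`. Because
`I_f` divides amelioration by the plant's **own** area, equal shelter
helps a small beneficiary more than a large one: the facilitative
response is size-dependent.

Interaction strength is measured by the relative interaction index
`RII = (P_w − P_s)/(P_w + P_s)` against a lone-plant baseline
(negative = net competition, positive = net facilitation), over a full
factorial of stress (0, 0.45, 0.75, 0.85) × density levels (2–8) × 5
replicates. A Bayesian back end (Gibbs sampling, split R-hat, WAIC,
model averaging) relates RII to stress and density through the four
candidate models `S`, `D`, `S+D`, `S+D+S×D`.

## A worked example

Two plants with fully coincident ZOIs split everything evenly:

```r
library(zoifacil)
compute_field(data.frame(x = c(50, 50), y = c(50, 50), A = c(200, 200)),
              arena())
#>   id   A A_rast A_c A_f I_c I_f
#> 1  1 200    208 104 104 0.5 0.5
#> 2  2 200    208 104 104 0.5 0.5
```

The full experiment, and the two headline diagnostics:

```r
records <- run_factorial(seed = 1)      # 140 replicate records, ~20 s
s <- summarize_rii(records)
for (S in unique(s$stress)) {
  ss <- s[s$stress == S, ]
  cat(sprintf("S=%.2f  %s  peak at density %d\n", S,
              classify_shape(ss$mean_rii, ss$sem),
              peak_density(ss$mean_rii, ss$density)))
}
#> S=0.00  monotone-decreasing  peak at density 2
#> S=0.45  monotone-decreasing  peak at density 2
#> S=0.75  hump-shaped  peak at density 3
#> S=0.85  hump-shaped  peak at density 7
```

Read: without stress, more neighbours only means more competition
(mean RII falls from −0.89 at density 2 to −0.97 at density 8). Under
high and extreme stress the curve is hump-shaped — facilitation peaks
at an intermediate density — and the peak moves from density 3 to
density 7 as stress rises from 0.75 to 0.85, because stronger stress
takes more neighbours to ameliorate. At the highest density, mean RII
climbs monotonically with stress (−0.97, −0.80, +0.18, +0.71): the
stress-gradient prediction holds where neighbours are plentiful.

Model comparison on any RII table (simulated or your own CSV with
columns `stress, density, replicate` and `RII` or `P_w, P_s`):

```r
cmp <- compare_models(records, seed = 1)
cmp$table[, c("model", "waic", "delta", "weight")]
model_average(cmp)   # predicted RII with 95% credible sets
```

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/zoisim.R simulate --stress 0.75 --n-plants 300 --seed 1 --out out/
Rscript inst/scripts/zoisim.R reproduce-figures --seed 1 --out out/   # CSVs + PDF figures
```

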