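---
title: "Individual-animal emissions intensity for pasture-based beef finishing"
author: "herdlca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-animal emissions intensity for pasture-based beef finishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdlca)
```

## The problem

Farm-scale life cycle assessment (LCA) of beef systems conventionally builds
one *representative animal* from herd-average performance statistics —
average daily gain (ADG), days on farm, mean feed quality — and reports a
single emissions intensity (EI, kg CO2-eq per kg liveweight gain, LWG).
Because EI is convex in liveweight gain (an animal's burden divided by its
gain), averaging performance *before* computing intensity understates the
mean intensity of the real, heterogeneous herd: a Jensen gap.  Poorly
performing animals emit "empty" maintenance methane while gaining little, so
their intensity rises hyperbolically as gain approaches zero, and a
pre-averaged calculation never sees them.

`herdlca` computes EI for *every* animal from its own weighing record and
the feed quality it actually experienced, then quantifies the bias of the
representative-animal shortcut, with Monte Carlo uncertainty and standard
statistical interpretation.  The setting it models is a three-farmlet
pasture-based finishing trial: cohorts of 30 weaned calves per farmlet
(permanent pasture, PP; white-clover/high-sugar-grass mix, WC;
high-sugar-grass monoculture, HS), housed over winter on silage, finished at
pasture, weighed every two to four weeks, and sold at sex-specific target
weights (ca. 555 kg heifers, 620 kg steers).  The functional unit is 1 kg of
liveweight gain over the finishing stage; the cow-calf stage, land-use
change, soil carbon and farm buildings are outside the boundary.

## The per-period Tier 2 engine

The livestock model is the IPCC (2006) Tier 2 chain, applied *per animal and
per period between consecutive weighings* rather than per year, with
measured digestible energy (DE, % of gross energy) and crude protein (CP, %
of DM) in place of dietary defaults, and with location switching (pasture vs
housing) of the activity allowance, manure methane conversion factor and
N2O emission factors.  These three modifications — temporal resolution,
measured feed quality, location switching — are the only departures from the
standard equation set.

For a period of $d$ days with mean liveweight $W$, gain rate $g$ (kg/d,
possibly $\le 0$), and feed quality $(DE, CP)$:

* **Energy.** $NE_m = Cf_i\,W^{0.75}$ (maintenance, $Cf_i = 0.322$
  MJ d$^{-1}$ kg$^{-0.75}$); $NE_a = C_a\,NE_m$ with $C_a = 0.17$ at pasture
  and 0 housed; $NE_g = 22.02\,(W/(C\,MW))^{0.75} g^{1.097}$ (growth, $C$
  0.8 heifers / 1.0 steers, $MW$ mature weight), floored at zero for
  $g \le 0$.  Gross energy intake is
  $GE = \left[(NE_m + NE_a)/REM + NE_g/REG\right]/(DE/100)$ with the usual
  REM/REG polynomials in DE.
* **Enteric CH4** $ = GE \cdot d \cdot (Y_m/100)/55.65$, with $Y_m$ the
  methane conversion factor (% of GE; default 6.5, assumed — the study does
  not print it) and 55.65 MJ/kg the energy content of methane.
* **Manure CH4.** Volatile solids
  $VS = [GE(1 - DE/100) + 0.04\,GE](1 - 0.08)/18.45$ per day; methane
  $= VS_{tot}\,B_0 \cdot 0.67 \cdot MCF/100$ with $B_0 = 0.17$ m$^3$/kg VS
  and $MCF$ 20 % for housed deep bedding (at 12 °C mean annual temperature)
  vs 1 % for excreta dropped at pasture.  The six-month midden storage of
  farmyard manure is represented by the deep-bedding MCF/EF3 applied to
  housed excreta; no separate storage-phase model is attempted because the
  reporting format carries a single manure-management line per gas.
* **Nitrogen.** Intake $= (GE/18.45)(CP/100)/6.25$ per day; Tier 2
  retention (floored at zero when $g \le 0$, so a non-growing animal
  excretes its full intake); excretion drives four pathways: housed
  direct N2O (EF3 deep bedding 0.01) and volatilisation-indirect
  (FracGas 0.30 × EF4 0.01); grazing direct (EF3 pasture 0.02) and
  leaching-indirect (FracLeach 0.30 × EF5 0.0075); N2O-N × 44/28.

Periods are half-open $[start, end)$ so a day is never counted twice, and
every period-level quantity is additive over any re-partition of time with
unchanged per-day conditions — both properties are tested.  Age-dependent
parameter switching is supported in principle by the same location-switch
mechanism, but the defaults do not differentiate age: the animals are all
post-weaning growers within a single Tier 2 category, and no schedule for
an age split is available to parameterise one honestly.

Feed measurements arrive either as converted values (DE %, CP %) or as raw
laboratory quantities: modified acid detergent fibre (MADF, g/kg DM) maps to
metabolisable energy by an affine calibration per feed type, ME maps to DE
through the DOMD relation ($ME = 0.16 \times DOMD$), and total N maps to CP
by the standard 6.25.  The affine MADF calibrations for UK pastures and
silages are proprietary; the shipped coefficients (pasture
$15.8 - 0.0185\,\mathrm{MADF}$, silage $15.0 - 0.0180\,\mathrm{MADF}$) are
clearly-flagged editable placeholders chosen to land typical forage MADF in
the usual UK ME bands, and every numeric test against them is a hand
evaluation of the same affine form, never a published value.  When both raw
and converted fields are present the measured value wins, with a warning.
Between sampling dates feed quality is a step function (last observation
carried forward): samples were taken to represent the roughage on offer at
that time, and LOCF is the least-assumptive interpolation; `quality_at()`
returns the day-weighted mean of that step function over a period and is
property-tested against a day-by-day brute-force average.

## Farmlet pools, allocation and characterization

Farmlet-level burdens form a pool: soil N2O from fertiliser N, field-applied
farmyard-manure N, crop-residue N (reseeded systems only — the permanent
pasture carries no residue entry at all), sheep excreta N, and leaching from
all of those; lime CO2 by carbonate stoichiometry (0.12 kg C per kg lime);
and upstream production burdens of all purchased inputs and transport
(quantity × factor).  Upstream factors from commercial databases cannot be
redistributed, so the shipped table is an assumed, clearly-flagged default
in the usual range per input class; absolute pool values in any real
assessment should come from licensed factors supplied through the same
structure.  The sheep flock itself is not modelled: its excreta enter as a
configured deposition quantity (default 1350 kg N/farmlet/yr, sized for a
~75-ewe lowland flock), matching the existence of a dedicated ewes line in
the reporting format.  Reseeding operations are annualised by the sowing
interval (default 5 years; the permanent pasture receives none), and the
annualised burden is exactly linear in 1/interval, which is why results are
insensitive to the interval.

Pasture-originating burdens are shared between the cattle and sheep
enterprises that graze the platform in rotation — economic allocation by
default (product values; 78/22 reproduces the reported mean split), mass
allocation by dry-matter intake (72/28) as the sensitivity alternative.
Distribution to animals follows two rules: (a) the cattle share of every
pool burden is split evenly across the 30 cattle; (b) animal-scope records
stay individual, except that cattle excreta deposited on the shared pasture
(urine/dung N2O and its leaching) surrender the sheep-allocated fraction,
because that manure also grows sheep feed.  Enteric and manure-management
emissions are cattle-body processes and are never reallocated.  The design
guarantees exact conservation: per-animal totals plus the sheep share
reproduce the raw ledgers to 1e-9 relative, asserted on every pipeline run.

Characterization uses GWP100 factor sets AR5 (CH4 28, N2O 265) by default
and AR4 (25, 298) for sensitivity; swapping sets reweights gases and touches
nothing else.

## The representative animal and its bias

`representative_ei()` rebuilds the assessment around one synthetic animal
given the herd-mean entry weight, ADG and days on platform: a linear
trajectory weighed on a fixed cadence, housed by the same calendar windows,
fed the *yearly-mean* feed quality per feed type, run through the identical
engine and allocation, and carrying the same per-head pool share.
Yearly-mean (rather than season-resolved) feed quality was chosen because
the representative approach is defined by *pre-averaged, low-temporal-
resolution* inputs; the seasonal series remains available to callers who
want the intermediate variant.  The aggregation bias is then
`mean(individual EI) - representative EI`.  For any herd whose burden does
not vary across animals this is a Jensen gap: non-negative, zero only when
all gains are equal — a property tested over hundreds of random herds.  A
fully degenerate herd (identical animals) reproduces the representative
value exactly.

## The synthetic herd generator

No animal-level records are publicly deposited, so the generator is a
first-class module that emulates the study conditions; its defaults *are*
those conditions and are not tuned per analysis:

* 30 calves per farmlet entering 1 October at 279–284 (SD 29–36) kg;
  housing 1 Oct–30 Apr each winter; weighing gaps uniform on 14–28 days.
* Per-animal lifetime ADG drawn from the per-farmlet mean/SD of the
  performance table (0.76/0.68/0.70, SD 0.08–0.10 kg/d); heifers' expected
  ADG is 0.95 of steers' (normalised so the herd mean is preserved),
  reflecting the reported higher total gain of steers.
* A three-phase piecewise-linear ADG shape (post-weaning dip 0.2, mid-season
  peak 2.4 at 55 % of the trajectory, finishing slowdown 0.3, all relative),
  scaled so the lifetime mean equals the drawn ADG exactly; with the default
  herd means this puts peak gains near 1.4–1.6 kg/d.  Period-level noise is
  a mean-preserving bridge with SD `adg_sd`, so individual periods can lose
  weight without biasing lifetime statistics — the engine must and does
  handle zero and negative period gains.
* Exit at the first weighing at or above the animal's own sale threshold.
  Thresholds average to the sex targets (555/620 kg) but are drawn per
  animal as `entry + ADG × N(sex-mean duration, 35 d)`: sale in practice
  also hinges on conformation and fat class, and empirically time-to-finish
  varies roughly independently of growth rate.  This reproduces the
  reported spreads of finishing weight (SD ≈ 40–50 kg), total growth and
  days on platform simultaneously; a fixed threshold would force finishing
  variance to zero and make days inversely proportional to ADG, neither of
  which the published statistics show.
* Feed quality per farmlet/feed type: spec means from the inventory table,
  a spring-peaking seasonal sinusoid (±3 points pasture, ±1 silage) plus
  Gaussian noise (SD 2/1.5 points pasture DE/CP, 1.5/1 silage), clipped to
  (0, 100); sward samples every 14 days, the weighing weeks.

What the generator does **not** emulate: sward spatial heterogeneity,
supplementary concentrate feeding episodes, second-season management
changes, animal health events, or any correlation between feed quality and
individual intake.  Passing tests therefore demonstrate that the *method*
behaves correctly under realistic heterogeneity — not that the shipped
default factors reproduce the absolute intensities of any particular farm;
absolute levels depend on the upstream factor table, which is an assumed
placeholder here.

## Uncertainty and interpretation

`monte_carlo()` redraws parameter perturbations jointly over iterations
(default 1000) while holding the herd data fixed: livestock heterogeneity
enters through the per-animal engine, parameter uncertainty through the
draws, which is exactly the complementarity the individual-animal approach
provides over distribution-only Monte Carlo.  Defaults (assumed, since the
study's appendix distributions are not in the public record): multiplicative
lognormal with geometric SD 1.10 on Ym, 1.15 on B0, 1.20 on MCF and
upstream factors, 1.30 on N2O emission factors; additive truncated-normal
±2/±1.5 points on DE/CP.  Draws are shared across systems within an
iteration, as in paired LCA comparisons, so pairwise exceedance fractions
respect parameter correlation; the two-sided exceedance p-value is
`2 min(P(A>B), P(B<A))`.  Zero-spread specs reproduce the deterministic run
bit-for-bit, and a median-preserving (lognormal, median 1) perturbation
leaves the empirical median at the deterministic value — both tested.

`interpret()` provides one-way ANOVA across systems on EI and ADG, pairwise
Welch t-tests (group variances differ visibly; the exact Student variant is
selectable), Pearson EI–ADG correlations per system, and steer/heifer
contrasts on EI, total gain and days.  Degenerate groups (n < 2 or zero
variance) skip the affected test with a warning rather than failing the
report.  Distribution summaries use type-7 (linearly interpolated)
quartiles and flag outliers beyond 1.5 interquartile ranges — stated
explicitly so the flags are reproducible.

## Numerical and design notes

* All randomness descends from explicit integer seeds; the pipeline derives
  per-stage substreams from the root seed, and identical config + seed gives
  byte-identical numeric outputs (manifest includes a config hash).
* Non-finishing animals (total gain ≤ 0) have undefined intensity: they are
  excluded from EI distributions with a logged count but retained in system
  totals, so conservation always holds.
* Parameter sets refuse to load without a provenance string per value;
  the shipped defaults label each value "IPCC 2006 default", "paper"
  (the 20 % deep-bedding MCF at 12 °C, six-month storage) or "assumed"
  (Ym, mature weights, FYM nitrogen content).
* Problem sizes in the test-suite and acceptance script: three farmlets × 30
  animals for full runs, 1000 Monte Carlo iterations, 100 seeded replicates
  for the correlation-recovery property, n = 3000 for generator convergence
  checks — sizes at which every statistical tolerance is a 3-standard-error
  band of the quantity under test.

## A worked run

```{r demo, eval = FALSE}
cfg <- demo_config(seed = 1)
run <- run_pipeline(cfg)
run                      # per-system mean EI, representative EI, bias
run$breakdown            # per-source mean (min–max) table
summarize_distributions(run$results)
```

## Known limitations

The engine is demand-side only (silage intake is not capped by measured
yields); there is no lactation/pregnancy energy, no Tier 3 rumen model, no
carcass-level co-product allocation, and no regional upscaling — the bias
finding is a farm-scale statement.  Absolute emission levels inherit the
assumed upstream factor table and feed-conversion calibrations; the
within-package checks that do not depend on those assumptions (conservation,
additivity, Jensen bias, oracle equivalence, correlation structure) are the
ones the test suite enforces quantitatively.
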