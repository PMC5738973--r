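# herdlca

Individual-animal life cycle assessment for pasture-based beef finishing
systems.

## What it does

Farm-scale carbon footprints of beef are usually computed for a single
"representative animal" built from herd-average statistics. Because
emissions intensity — kg CO2-eq per kg liveweight gain (LWG) — is the
quotient of an animal's burden by its gain, it is convex in gain, and
averaging performance *before* dividing understates the herd mean (a Jensen
gap): slow-growing animals emit near-constant maintenance methane while
gaining almost nothing, and their intensity rises hyperbolically as average
daily gain (ADG) approaches zero.

`herdlca` computes emissions intensity for **every animal** in a finishing
herd from its own weighing record and the measured quality of the feed it
ate, then quantifies the bias of the representative-animal shortcut:

* an IPCC (2006) **Tier 2 engine applied per animal and per weighing
  period**: gross energy intake
  `GE = [(NEm + NEa)/REM + NEg/REG] / (DE/100)`, enteric methane
  `GE · d · (Ym/100) / 55.65`, manure methane through volatile solids ×
  B0 × MCF (deep bedding 20 % housed, 1 % at pasture), and the four
  excreted-nitrogen N2O pathways (housed direct + volatilisation, grazed
  direct + leaching), with parameters switched by location and diet;
* **feed-quality conversions**: MADF → ME (affine calibrations per feed
  type), ME → digestible energy via the DOMD relation, total N × 6.25 → CP,
  and step-function (LOCF) time-weighting of samples over each period;
* **farmlet pools**: soil N2O from fertiliser/FYM/residues/sheep excreta
  plus leaching, lime CO2, and upstream production burdens of all purchased
  inputs and transport;
* **co-product allocation** between the cattle and sheep enterprises
  (economic or mass basis), with pool burdens split evenly across the 30
  cattle and cattle pasture-deposition burdens surrendering the sheep
  share — per-animal totals plus the sheep share reproduce the raw ledgers
  to 1e-9 relative, asserted on every run;
* **GWP100 characterization** (AR5: CH4 28, N2O 265; AR4: 25, 298);
* the **representative-animal recalculation** and its aggregation bias,
  seeded **Monte Carlo** uncertainty (1000 iterations, pairwise exceedance
  p-values), and statistical interpretation (one-way ANOVA, Welch t-tests,
  Pearson EI–ADG correlations, sex contrasts);
* a **synthetic herd generator** emulating a three-farmlet finishing trial
  (30 Charolais × Hereford-Friesian calves per farmlet, autumn entry,
  winter housing on silage, weighing every 2–4 weeks, sale around
  555/620 kg for heifers/steers), used for all demonstrations and tests.

The study tables that parameterise the generator (input inventory, herd
performance, per-source intensity breakdown) ship as plain-CSV fixtures
(`load_fixture()`).

## A worked example

```r
library(herdlca)
run <- run_pipeline(demo_config(seed = 1))
run
#> Individual-animal LCA run — 3 system(s), 90 animals
#> Cattle enterprise share: 0.78 | GWP set: AR5_GWP100
#>
#> Mean emissions intensity (kg CO2-eq/kg LWG):
#>    HS    PP    WC
#> 15.32 14.98 13.16
#>
#> Representative-animal comparison:
#>  system mean_individual_ei representative_ei bias
#>      PP              14.98             14.31 0.67
#>      WC              13.16             12.53 0.63
#>      HS              15.32             14.84 0.48
```

Each system's mean intensity is the average over its 30 animals; `bias` is
that mean minus the intensity of a single pre-averaged animal run through
the identical engine — positive throughout, i.e. the representative-animal
approach underestimates. Per-animal detail, a per-source breakdown table in
the standard mean (min–max) layout, test statistics and (optionally) Monte
Carlo intervals live in `run$results`, `run$breakdown`, `run$report` and
`run$mc`:

```r
head(run$results[c("animal_id","sex","days","adg","lwg_kg","total_co2e_kg","ei")], 3)
#>   animal_id    sex days   adg lwg_kg total_co2e_kg    ei
#> 1     PP_01 heifer  362 0.812  293.9          4541 15.45
#> 2     PP_02 heifer  339 0.746  252.9          4162 16.46
#> 3     PP_03  steer  430 0.801  344.4          4376 12.71
```

Absolute levels depend on the upstream emission-factor table, which ships
as a clearly-flagged assumed default (licensed database factors cannot be
redistributed); supply your own via `default_upstream_efs()`'s structure.
A thin command-line wrapper is included at `inst/scripts/herdlca.R`
(`--gwp ar5|ar4`, `--allocation economic|mass`, `--mc`, `--seed`, `--out`).

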