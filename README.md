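# paleodecay

Degradation kinetics of biomolecules in dated lake-sediment cores.

Lake sediments are major organic-carbon sinks, and the biomolecules they
archive — marker-gene copies (*rbcL*, 18S rRNA genes), lipid biomarkers,
pigments, lignin, pyrolysis-derived macromolecules — are eroded after burial
at rates that differ sharply between compounds and between their source
organisms (diatoms, green algae, vascular plants).  `paleodecay` is for
paleolimnologists and biogeochemists who have content-versus-age records
from dated cores and want to quantify that erosion and reason about its
mechanism.

## What it computes

The core model is power-law decay of content $Y$ (per g dry sediment) with
sediment age $t$ (years):

$$Y = a\,t^{b}, \qquad k = -b,$$

fitted by OLS on $(\log t, \log Y)$, with exponential and linear
alternatives and R²-based model ranking.  Because apparent reactivity
declines with age, half-lives grow linearly with age:
$\Delta(t) = t\,(2^{1/k}-1)$, and a tabulated schedule over ages
{1, 20, 50, 100, 200, 500, 1000} y is pinned down by the half-life at age
1 y alone (`calibrate_k_from_h1()`).  Around the fits the package provides:

* reliability flagging of fits (p > 0.05 and/or R² < 0.2);
* group averages of decay constants and exact small-sample Wilcoxon
  rank-sum contrasts (full enumeration for n_x + n_y ≤ 12);
* log10 Pearson correlations between records;
* piecewise-linear age-depth models from dated anchors;
* amplicon-community tools: relative abundances, partitioning of qPCR
  totals by group read fractions, Bray–Curtis dissimilarity, ANOSIM with
  seeded permutations;
* a rule-based classifier for three preservation scenarios —
  adsorption/complexation control, chemical-reactivity control, and biotic
  exclusion (physical shielding by recalcitrant cell walls);
* a seeded synthetic-core generator (power-law profiles with lognormal
  noise, Dirichlet-multinomial communities) so every stage is testable at
  desk scale.

## Worked example

Simulate a lake core with the paper-like analyte panel, fit power models,
and summarise decay constants:

```r
library(paleodecay)

core <- simulate_core("paper_like", seed = 1)
fits <- lapply(core, fit_power)
fits[["lake_1.deep.diatom_rbcL"]]
#> <decay_fit> power model for diatom_rbcL
#>   Y = 1.229e+08 * t^-1.363   (decay constant k = 1.363)
#>   R^2 = 0.926, slope p = 1.29e-11, n = 20 (0 excluded)

summarize_decay(fits, by = "analyte_id")
#> <decay_summary> mean decay constants (power fits)
#>        label  mean_k       sd_k n_fits             note
#>  diatom_rbcL 1.35000 0.05529168      3
#>   FA_C18_2n6 0.58520 0.00000000      1            n = 1
#>   FA_C20_5n3 0.75340 0.00000000      1            n = 1
#>   green_rbcL 0.79810 0.05846211      3
#>       lignin      NA         NA      1 na (no decrease)
#>   plant_rbcL 0.09973 0.07864379      3
```

Diatom DNA decays an order of magnitude faster than vascular-plant DNA,
lignin shows no resolvable decrease (`na`), and the per-station SD
quantifies within-lake spread.  A half-life schedule calibrated from an
age-1 half-life of 0.77 y (diatom *rbcL*):

```r
half_life_schedule(h1 = 0.77, label = "diatom rbcL")
#> <half_life_schedule> diatom rbcL (k = 1.214, exact_halving)
#> age       1.00 20.0 50.0 100 200 500 1000
#> half_life 0.77 15.4 38.5  77 154 385  770
```

A 0.77-year half-life in fresh sediment stretches to 77 years once the
layer is a century old.  Finally, classify what controls diatom biomolecule
preservation across a five-lake study:

```r
study <- simulate_study("paper_like", seed = 1, stations = "deep")
classify_from_fits(lapply(study, fit_power), "diatom")
#> <scenario_call> diatom -> chemical_reactivity
#>   DNA decays significantly faster than the group's resistant compounds
#>                     comparison    label_a            label_b n_a n_b statistic     p_value significant
#>                cross_group_DNA diatom_DNA     green_alga_DNA   5   5        25 0.007936508        TRUE
#>                cross_group_DNA diatom_DNA vascular_plant_DNA   5   5        25 0.007936508        TRUE
#>  within_group_DNA_vs_resistant diatom_DNA   diatom_resistant   5   5        25 0.007936508        TRUE
```

Diatom DNA outpaces diatom lipids (chemical-reactivity control), whereas a
core generated under the shielding scenario yields `biotic_exclusion` for
green algae (`simulate_study("biotic_exclusion", seed = 2, ...)`).

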