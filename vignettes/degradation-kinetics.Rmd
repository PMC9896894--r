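---
title: "Modelling biomolecule degradation kinetics in dated lake-sediment cores"
author: "paleodecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biomolecule degradation kinetics in dated lake-sediment cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodecay)
```

## The problem

Lake sediments archive the biomolecules of the organisms that lived in and
around the lake: marker-gene copies (e.g. chloroplast *rbcL* of diatoms,
green algae and vascular plants; eukaryotic 18S rRNA genes), lipid
biomarkers (group-diagnostic fatty acids, sterols, *n*-alkanes), pigments,
lignin phenols and pyrolysis-derived macromolecule classes.  Once a layer is
buried, microbial degradation erodes each of these pools at its own pace, and
the downcore record of content versus sediment age is the observable trace of
that erosion.  `paleodecay` packages the quantitative machinery needed to
turn such records into decay constants, age-dependent half-lives, group-wise
statistical contrasts, community-level cross-checks, and a rule-based call on
*why* a group's biomolecules persist or vanish.

## The decay model

The core model is a power law in sediment age $t$ (years since deposition):

$$ Y(t) = a \, t^{b}, \qquad k = -b, $$

where $Y$ is content (or gene copies) per g dry sediment.  The exponent acts
as an apparent first-order decay constant whose effect weakens with age —
the classical observation for bulk organic matter, whose apparent reactivity
declines as the most labile fractions are consumed first.  `fit_decay()`
estimates $(a, b)$ by ordinary least squares on $(\log t, \log Y)$.  Fitting
in log space is a deliberate choice: contents span four or more orders of
magnitude downcore, errors on such measurements are multiplicative
(lognormal), and an R² quoted for a "best-fit line" through such data is
meaningful in log space.  Raw-space nonlinear least squares is available via
`method = "nls"` for sensitivity analysis, started from the OLS solution.

Exponential ($\log Y$ on $t$) and linear ($Y$ on $t$) alternatives are fitted
the same way, and `compare_models()` ranks the three by R² in their
respective fitted spaces.  Ties are broken in favour of power, then
exponential, because the power model is the mechanistic default for
heterogeneous organic matter; the tie only matters for degenerate inputs
(e.g. constant series, where all three models report slope 0, R² 0, p 1).

### Degenerate and dirty inputs

* Zero or negative values (non-detects) cannot enter a log fit.  The default
  policy excludes them and records the count (`n_excluded`); an optional
  pseudo-value policy substitutes half the smallest positive value of the
  series.  The detection limits behind real non-detects are instrument- and
  assay-specific, so the policy is configurable rather than fixed.
* Surface layers with age $\le 0$ are always excluded from power fits.
* Fewer than 3 usable points is an error (`"insufficient data"`), not a fit.
* A constant series returns slope 0 with $R^2 = 0$ and $p = 1$ — no evidence
  of decay — rather than the `NaN`s of a zero-residual regression.

### Reliability flag

`flag_fit()` marks a fit unreliable when the slope is nonsignificant
($p > 0.05$) and/or the fit is weak ($R^2 < 0.2$), with strict inequalities,
so boundary values are not flagged.  Flagged rows are marked with an asterisk
in half-life tables.

## Age-dependent half-lives

Under power-law decay the half-life is not a constant.  The exact halving
time from age $t$ solves $(t+\Delta)^{-k} = t^{-k}/2$:

$$ \Delta(t) = t\,(2^{1/k} - 1), $$

the package default (`formula = "exact_halving"`).  An alternative derives
from the instantaneous first-order rate $k/t$: $\Delta(t) = t \ln 2 / k$.
Both are *linear in age*, which is the structural signature of tabulated
half-life schedules: every column is the age-1 column times the age.
Because published schedules print the half-life at age 1 y rather than $k$
itself, `calibrate_k_from_h1()` inverts the formula at age 1
($k = \ln 2 / \ln(1 + h_1)$ for exact halving), after which
`half_life_schedule()` reproduces a full row over the standard age grid
{1, 20, 50, 100, 200, 500, 1000} y.  Under calibration the two candidate
formulas give identical schedules (both reduce to $h_1 t$), so the choice of
formula does not affect calibrated tables, only half-lives computed directly
from a fitted $k$.

```{r halflife}
half_life_schedule(h1 = 0.77, label = "diatom rbcL")
```

`half_life()` warns and returns `Inf` for $k \le 0$: a pool that does not
decrease has no finite half-life.

## Group contrasts

Decay constants are compared with a two-sided Wilcoxon rank-sum test
(`wilcoxon_rank_sum()`).  Group sizes in this design are tiny — three
stations per lake or five lakes — so the implementation enumerates all rank
assignments exactly when $n_x + n_y \le 12$ and there are no ties; with ties
it uses mid-ranks and a seeded permutation p (10,000 draws by default); only
larger samples fall back to the continuity- and tie-corrected normal
approximation.  A consequence worth remembering: with 3 vs 3 the smallest
achievable two-sided p is 0.1, so no 3-vs-3 contrast can be significant at
$\alpha = 0.05$.  `pairwise_contrasts()` tests all unordered pairs and
reports raw p-values by default (Holm adjustment available); raw reporting
matches the convention of presenting each pairwise contrast on its own.

`summarize_decay()` averages per-station or per-lake decay constants
(arithmetic mean ± sample SD, power fits only).  A group whose contents did
not decrease with age (mean $k \le 0$) is reported as not applicable rather
than as a negative decay constant.  Pearson correlations between biomolecule
records (`pearson_correlation()`) default to log10 transformation of both
variables, again because copy numbers span orders of magnitude; whether to
correlate raw or log values is a documented choice, not a printed convention.

## Age-depth models

Ages enter as externally dated anchors (radionuclide-based chronologies are
produced upstream).  `age_model()` builds a piecewise-linear depth-to-age
mapping — constant sedimentation rate per segment — and `age_at_depth()`
interpolates, extrapolating beyond the deepest anchor with the deepest
segment's rate.  Linear interpolation, not splines: this stage is assignment
plumbing, and a spline would invent curvature the anchors do not constrain.
A configurable `max_age` cap guards against silently absurd extrapolated
ages.  Layers sampled over a finite thickness are represented by their
midpoints.

## Community cross-checks

Marker-gene decay constants can be corroborated from amplicon data:
group-specific read fractions (`group_fractions()`) times total gene copy
numbers (`partition_total_abundance()`) give absolute group abundances whose
age profiles can be fed back through `fit_power()`.  Partitioning conserves
the total by construction.  Community structure is compared with Bray–Curtis
dissimilarity on relative abundances (via `vegan::vegdist`; the metric for
such tests is a convention, and Bray–Curtis is the standard for amplicon
tables) and ANOSIM (`anosim()`), implemented in-package because the
permutation convention is fixed here: $R = (\bar r_B - \bar r_W)/(M/2)$ on
the ranked dissimilarities, $p = (1 + \#\{R^* \ge R\})/(n_\mathrm{perm}+1)$
under seeded relabellings (999 by default, so $p > 0$ always), with an
exhaustive-enumeration mode for small sample sets.
`fraction_vs_age_regression()` asks whether a taxon's relative contribution
drifts with age.

## The three preservation scenarios

The decision rule in `classify_group()` operationalises a conceptual
framework for what controls degradation, using only fitted decay constants
and Wilcoxon tests at level $\alpha$ (default 0.05), evaluated in order:

1. **Adsorption/complexation control.**  DNA is chemically identical across
   organisms; if electrostatic adsorption to minerals or complexation with
   organic matter governed its fate, DNA decay constants should not differ
   between organism groups.  Rule: *all* cross-group DNA contrasts
   nonsignificant.
2. **Chemical-reactivity control.**  Labile DNA outpaces the group's
   resistant compounds (lipids, lignin, macromolecules).  Rule: within-group
   DNA-vs-resistant contrast significant, with DNA decaying faster.
3. **Biotic exclusion (physical shielding).**  DNA decays no faster than the
   resistant compounds — e.g. shielded inside algaenan- or lignin-rich cell
   walls — even though DNA decay differs between groups.  Rule: within-group
   contrast nonsignificant while cross-group DNA decay differs.

Anything else is `indeterminate` (including the case of DNA decaying
*slower* than the resistant compounds, which no scenario predicts).  Two
caveats are built in.  First, the ordering and $\alpha$ are an explicit
design choice for what is, in narrative form, a qualitative argument; both
are arguments of the function.  Second, rule 3 reads failure to reject as
similarity, which conflates low power with equality — with fewer than 4
values per group the call carries a `low_power` flag and the printed report
says so.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised,
and its estimators validated, without any external data.  It emulates:

* **Power-law decay profiles** (`simulate_profile()`):
  $Y_i = a t_i^{b} e^{\varepsilon_i}$, $\varepsilon_i \sim N(0, \sigma^2)$ —
  multiplicative lognormal noise, matching the fitting model.  Optional
  censoring below a detection limit.
* **Core geometry** (`simulate_core()`): 20 layer midpoints over a 40 cm
  core at a constant sedimentation rate, 0.22 cm/y by default (≈180 y of
  record); the multi-lake wrapper `simulate_study()` uses rates
  0.20–0.30 cm/y plus one slow core at 0.065 cm/y (≈600 y), echoing a set of
  temperate lakes with one long oligotrophic record.
* **The analyte panel** (`decay_preset()`): three *rbcL* markers measured at
  all three stations plus one group-specific resistant compound each,
  measured at the deep station only (12 series) — biomarker chemistry is
  typically run on one core per lake.  The `"paper_like"` decay constants
  sit near published group-level values (diatom DNA 1.57, green algal DNA
  0.70, vascular plant DNA 0.12; biomarkers back-calculated from their age-1
  half-lives).  They are calibration inputs, not ground truth.
* **Between-lake heterogeneity**: per-lake decay constants are
  $k \cdot e^{N(0, \tau^2)}$ with $\tau = 0.25$ on the log scale, chosen to
  match a reported relative spread of roughly 28% (1.57 ± 0.44) for diatom
  DNA across lakes.
* **Measurement noise**: $\sigma = 0.4$ (natural log) by default — scatter
  of a factor ~1.5, typical of qPCR copy numbers and biomarker
  quantification on sediment matrices.
* **Communities** (`simulate_community()`): group intensities
  $I_g(t) = A_g t^{-k_g}$; totals $\sum_g I_g$ with lognormal qPCR noise
  (SD 0.3); reads Dirichlet-multinomial around the exact proportions
  (concentration 50, depth 10,000), with each group split over three taxa.
  Totals and fractions are jointly consistent with per-group power decay, so
  the partition-then-refit route recovers each $k_g$.

Determinism is a contract: every stochastic function requires (or accepts) a
seed, restores the caller's RNG state, and `write_fixture_bundle()` produces
byte-identical CSVs under the same seed.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: primer and PCR bias, chimeras and
sequencing error; event layers (turbidites) and non-monotone age-depth
artefacts; eutrophication-driven changes in input fluxes (amplitudes are
constant per analyte); fossil/pre-aged terrestrial inputs with inherited
age; detection-limit structure of specific instruments; spatial
heterogeneity within a station.  Scenario-recovery rates on synthetic cores
quantify the classifier's behaviour under the stated noise model, not the
probability that a published interpretation is correct.

## Numerical conventions

* OLS via `stats::lm`; slope p-values are two-sided t-tests from the
  regression; exact fits (zero residual variance) report $p = 0$, constant
  series $p = 1$.
* Exact Wilcoxon enumeration compares $|U - mn/2|$ with a
  `sqrt(.Machine$double.eps)` slack so ties at the observed distance are
  counted as at least as extreme.
* Permutation p-values always use the $+1$ correction.
* Numeric CSV output is written with 17 significant digits so
  write-then-read is exact for doubles.
* Half-life calibration round-trips to $10^{-12}$ relative error.

## Problem sizes used in the validation suite

The test suite validates estimator recovery with 500 simulated cores of 20
points ($b = -1.5$, $\sigma = 0.2$), model selection with 500 power-law
simulations ($b = -1$, $\sigma = 0.3$), scenario recovery with 50 five-lake
studies per scenario, and test calibration with 1,000 null replicates
(Wilcoxon and regression) and 500 ANOSIM runs of 199 permutations on
12-sample tables — sizes at which the binomial/KS acceptance bands are
informative while the whole suite runs in well under a minute per property
family on a single CPU.

## Limitations

* A single power law is descriptive, not mechanistic: it aggregates a
  continuum of reactivities and says nothing about which fraction is being
  consumed.  Reactive-continuum or multi-pool diagenesis models are out of
  scope.
* Decay constants from regression on observational depth profiles conflate
  degradation with any systematic change in deposition; the model assumes
  inputs were stationary.
* The scenario classifier inherits the weaknesses of null-hypothesis logic
  at $n = 3$–5: "not significantly different" is weak evidence of equality,
  and the adsorption rule can fire simply because small samples cannot
  reject.
* Ages are taken as exact; chronological uncertainty is not propagated into
  the fits.
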