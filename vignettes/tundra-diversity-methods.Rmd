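---
title: "Models and methods for tundra vegetation resurvey analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for tundra vegetation resurvey analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundiv)
```

`tundiv` analyses change in vascular plant diversity from hierarchical
vegetation resurveys: permanently marked plots (typically at most 1 m²),
nested in subsites, nested in study areas, each surveyed in two or more
calendar years. This vignette explains the models and conventions the
package implements, the choices made where several defensible options
existed, and what the synthetic-data generator does and does not emulate.

## Data model and harmonization

The pipeline's atom is one species × plot × year cover record in the survey
method's native unit. Three method families are supported and harmonized to
a common currency, *relative cover*:

* **percent cover** — used directly;
* **point framing** (top hit, top–bottom, or all hits) — hits divided by the
  total number of grid points, times 100. The three hit-order variants are
  converted identically because they yield very similar relative covers;
  the method label is preserved so sensitivity filters can distinguish them;
* **cover classes** — class labels mapped through conventional midpoints
  (`r` = 0.1, `+` = 0.5, `1` = 2.5, `2` = 15, `3` = 37.5, `4` = 62.5,
  `5` = 87.5 percent). The midpoint table is configurable; because every
  row is subsequently relativized, the analysis is insensitive to the
  overall scale of any particular midpoint convention.

After conversion, covers within each plot-year are rescaled so vascular
plant cover sums to exactly 100. Relativization is idempotent and the row
sum is enforced to within 10⁻⁶ throughout the test suite.

### Retention rules

Two analysis sets are derived from the raw table. The *spatial set* keeps
control (ambient) plots, strictly north of 60° N, with surveyed area at
most 1 m². The *temporal set* additionally requires at least two survey
years spanning at least 5 years, and a constant survey method and plot size
across years (a plot that switches methods is excluded and counted). The
latitude threshold is strict: a plot at exactly 60.0° N is excluded.
Exclusion counts attribute each dropped plot to the first failing rule, in
the order control → latitude → plot size → survey count → span →
consistency, so the counts sum exactly to the number of plots dropped. A
configuration switch restricts the analysis to plots of exactly 1 m² for
the plot-size sensitivity re-run.

## Diversity states and temporal change

Per plot-year: richness *S* (species with cover > 0; no minimum-cover
threshold), Shannon *H* in nats, and Pielou evenness *J = H / ln S*,
undefined for *S* ≤ 1. Natural logarithms are used consistently; the base
cancels in *J* so long as one base is used for both *H* and ln *S*.

Temporal turnover compares each plot's **baseline (first)** and **final
(last)** surveys only; intermediate surveys inform per-plot trend slopes
but not the two-time-point metrics. With *a* shared species, *b* species
present only at baseline (lost) and *c* only at the final survey (gained):

* Jaccard family (presence–absence):
  total = (b + c)/(a + b + c); replacement = 2·min(b, c)/(a + 2·min(b, c));
  nestedness-resultant = total − replacement.
* Bray–Curtis family (relative covers), with A = Σ min(xᵢ, yᵢ) and B, C
  the baseline/final surpluses: total = (B + C)/(2A + B + C); balanced
  variation = min(B, C)/(A + min(B, C)); abundance gradient = total −
  balanced.

Both partitions satisfy the additive identities exactly, and species
trajectory proportions (lost, gained, persisting, divided by the union
richness) satisfy prop_lost + prop_gained = Jaccard total. The package's
headline "turnover" scalar defaults to the **replacement** component for
the Jaccard family and the **balanced-variation** component for
Bray–Curtis, because turnover is defined here as the *replacement rate*;
the totals are always stored alongside, and the choice is configurable
(`turnover_component` in the pipeline configuration).

## Two-step trend modelling

Change over time is estimated in two steps. First, one ordinary
least-squares line per plot (or subsite, for climate) of the metric against
calendar year — richness change, evenness change, functional-group cover
change (shrub/graminoid/forb, and dwarf vs erect shrubs where recorded),
and MTWQ (mean temperature of the warmest quarter) and precipitation change
over the climate window (1979–2013 by default). Slopes are computed on the
untransformed metric; link-scale modelling happens only inside the
hierarchical regressions. Because coordinates exist at subsite level,
plots of one subsite share their climate covariates; the hierarchical
models account for this with a subsite random effect.

For the shrub-sensitivity analysis the package computes, per survey time
point, the mean MTWQ over a trailing 5-year window — the survey year and
the four preceding years (the window includes the surveyed growing season;
inclusivity at the survey year is a package convention) — centred within
subsite.

## Hierarchical regression layer

Models are declared (`hier_spec()`) by response, likelihood family, fixed
terms and random structure, and fitted by a Bayesian sampler built into the
package. Families: gaussian (identity link), negative binomial (log link,
counts), and a beta family with logit link in plain, zero-inflated and
zero–one-inflated forms for proportion responses. The inflated mixtures are
defined in the package itself: mass `zi` at zero, or mass `zoi` at the
boundary split by a conditional-one probability `coi`, with a
mean–precision beta density on the interior. Each density is verified by
numerical integration to be proper.

Priors are weakly informative: Normal(0, 2.5) on coefficients, half-Normal
(0, 2.5) on random-effect and residual standard deviations, half-Normal
(0, 20) on the negative-binomial dispersion and beta precision (a precision
parameter lives on a larger scale than a standard deviation, so a 2.5-scale
half-normal would be strongly informative there), and Beta(1, 1) on
inflation probabilities. Reported intervals default to 95% (97.5%
selectable per model).

The sampler is an adaptive Metropolis-within-Gibbs scheme written in C++:
proposal scales adapt toward 44% acceptance during warmup and freeze
afterwards; random effects are updated with group-local likelihood
evaluations. The fixed-effects block is sampled in a QR-orthogonalized
basis and mapped back to the coefficient scale, which decorrelates the
posterior and makes componentwise proposals efficient even for collinear
covariates such as latitude and summer temperature. Random
intercept–slope pairs are given independent variance components (no
correlation parameter); this is a deliberate simplification of the full
covariance structure and is the main difference from what a
general-purpose Bayesian regression package would fit. Convergence is
summarized by split-R̂ (threshold 1.01 for the `converged` flag) across
chains (four by default, 2000 iterations each including warmup, matching
common practice for these models). Fits are exactly reproducible given a
seed.

Design assembly derives the standard sampling covariates: natural log of
plot size (included in all models except evenness models, where there is
no theoretical expectation of a plot-size effect), monitoring duration,
per-plot mean richness, and centred year. Functional-group covariates are
fitted one group at a time — group covers are compositionally
anti-correlated, so a joint fit would be collinear by construction.

The battery (`model_battery()`) mirrors the standard analysis layout:
high-level richness/evenness over time with nested random year-slopes per
plot within subsite; spatial models of last-survey richness/evenness
against latitude, climatology and composition; two-time-point models of
turnover components and trajectory proportions against climate, climate
change, functional-group change and sampling covariates; temporal models on
per-plot slopes; post hoc shrub models (cover against trailing temperature
with a dwarf-versus-erect interaction, cover change against long-term
warming and latitude); the rarity-versus-loss regression; and
turnover-versus-richness models with their null-model counterparts. A
failing battery entry is recorded and the suite continues.

## Homogenization analysis

Plot-level data are aggregated to subsite profiles — the unweighted mean
relative cover per species across a subsite's temporal plots, separately at
each plot's baseline ("start") and final ("end") survey; start profiles may
therefore mix calendar years, mirroring the plot-level definition. All
start and end profiles are ordinated jointly (a joint ordination is what
makes the per-subsite shift meaningful), by principal coordinates analysis:
Gower double-centering of the squared dissimilarities and
eigendecomposition, with scores `v√λ` on positive axes. Negative
eigenvalues, which arise for non-Euclidean metrics, are retained without
Lingoes/Cailliez correction; distances to group centroids accumulate
squared differences positively on positive axes and negatively on negative
axes, floored at zero — the standard multivariate-dispersion treatment,
cross-checked in the tests against `vegan::betadisper` and `cmdscale`.

Six dissimilarity metrics span the presence-to-abundance gradient: Jaccard,
Sørensen, Bray–Curtis, modified Gower (mean |log₂(cover)+1| difference over
non-double-zero species; base configurable), Manhattan, Euclidean — all
computed through `vegan::vegdist`. The start-versus-end difference in mean
distance to centroid is tested with a one-way ANOVA (a decrease indicates
homogenization), and each subsite's compositional shift is the Euclidean
distance between its start and end positions on the first two principal
axes (the full-space shift is reported alongside for sensitivity). The
per-subsite change in distance to centroid is exported for second-stage
regressions.

## Null model

The turnover null model removes `round(0.2·S)` resident species per plot
uniformly at random and adds `round(0.2·S)` species drawn uniformly from
the donor pool — species recorded anywhere in the same subsite (or study
area, configurable) and absent from the plot. Rounding is
half-away-from-zero; additions are truncated (and flagged) when the pool is
too small. Added species receive the pool-mean relative cover of that
species before the row is re-relativized. Counts are deterministic given
S, so the per-plot total Jaccard dissimilarity equals (r + g)/(S + g) for
every seed — an identity the tests exploit — while Bray–Curtis varies
across replicates through the species identities and covers. One hundred
seeded replicates are run by default; the replicate-level summary also
records the within-replicate OLS slope of turnover against richness, the
a-priori relationship against which the observed turnover–richness models
are compared. (The replicate-level comparison uses OLS slopes; the full
hierarchical turnover-versus-richness models are fitted once on observed
data in the model battery.)

## Synthetic data generator

The generator emulates the study conditions end to end so that every stage
is testable without any external download: a latitudinal ladder of study
areas (61–81° N), subsites with climatologies declining 0.4 °C per degree
latitude plus 1 °C subsite-level noise, warming at 0.05 ± 0.02 °C/yr, and
plots whose initial richness is negative-binomial with log-mean
`3.75 − 0.03·latitude + 0.06·MTWQ` — the spatial gradients the spatial
models are expected to recover. Species come from nested pools (400
overall, 80 per study area, 50 per subsite) with lognormal commonness
weights and a 30/30/40 shrub/graminoid/forb mix, shrubs split evenly into
dwarf and erect. Dynamics operate on presence first and covers second:
each year, resident species go locally extinct with probability 0.026 and
colonists arrive at Poisson rate 0.028·S₀ from the subsite pool; these two
rates were back-calculated once from the target trajectory mix (about 64%
persisting, 19% gained, 17% lost over a decade) and verified by a single
calibration run, not tuned further. Persisting covers wobble with
lognormal noise (σ = 0.35) so abundance turnover is non-trivial. A per-plot
shrub trend tilts (erect) shrub weights exponentially so relative shrub
cover drifts at a chosen rate in percent points per year, and can boost the
loss probability of co-occurring non-shrub species — the mechanism behind
the `shrubification` scenario (trend 1.5 ± 1 pp/yr, loss boost 0.6 per
pp/yr, chosen so the induced richness-change signal is statistically
detectable at the scenario's size). The observation layer re-expresses true
covers as percent cover, deterministic point framing (present species
always score at least one hit, so presence is preserved exactly and the
truth record reconciles with computed trajectories), or cover classes.

Canned scenarios: `null_change` (no dynamics, no warming — every change
metric is exactly zero), `paper_like` (the calibrated defaults, 12 × 3 × 8
plots surveyed in 2000/2005/2010), `homogenizing` and `differentiating`,
and `shrubification`. The homogenizing construction blends final covers
toward the across-plot mean profile; the differentiating construction
injects subsite-exclusive marker species and removes globally widespread
ones at the final survey — a pure "scaling away from the mean" would cancel
under relativization, whereas exclusive species provably expand dispersion
under both presence- and abundance-based metrics. Both constructions run
without background dynamics so the dispersion contrast carries the
construction's sign deterministically.

What the generator does **not** emulate: observation error in cover
estimates (off by default so metric tests are exact), taxonomic
misidentification, uneven survey schedules across plots, spatial
autocorrelation within subsites, and mechanistic vegetation dynamics
(dispersal, demography). Passing tests therefore demonstrate that the
pipeline's computations and inferences are correct under a faithful
statistical caricature of the sampling design — not that the scientific
conclusions would survive every messiness of real field data.

## Numerical conventions and scaled problem sizes

Degenerate inputs are handled explicitly: empty plot-years give S = 0 and
undefined evenness; all-zero turnover denominators give components of 0;
two-proportion z tests with pooled proportions of 0 or 1 return z = 0,
p = 1 with a degeneracy flag; a grouping factor with a single level drops
the random term with a warning; ANOVA on identical distances is flagged
degenerate. Ties in eigenvalues only affect coordinates, never distances,
and the dispersion tests assert invariance under axis sign flips and
profile reordering.

The test suite and the reproduction script run everything at deliberately
scaled sizes chosen as the package's defaults: parameter-recovery checks
use 20 seeded replicates with two chains of 700–1000 iterations, the
spatial-gradient recovery uses the full 45 × 3 × 15 design, and the
homogenization contract uses the 8 × 2 × 6 scenario geometry. These sizes
give stable accept/reject behaviour for the properties being tested while
keeping a complete run in the minutes range on one CPU.

## Known limitations

* The MCMC backend is a random-walk scheme; posteriors for weakly
  identified variance components (random-effect sds near zero) mix slowly
  and can show elevated R̂ even when fixed-effect summaries are stable.
  The battery flags such fits rather than hiding them.
* Random intercept–slope correlations are not modelled.
* The climate interface consumes subsite-level tables; raster extraction,
  downscaling and snow-season variables are out of scope.
* Taxonomic name resolution is out of scope; the data model assumes clean,
  consistent taxon names and one consistent trait assignment per species.
* Cover-class conversion relies on a conventional midpoint table; analyses
  dominated by cover-class plots inherit that convention (though
  relativization removes the scale, it cannot recover within-class
  information).
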