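---
title: "Quantifying thermophilisation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thermophilisation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

As climates warm, species track their thermal requirements poleward, upslope
and to greater depths, so the composition of local communities drifts toward
species with warmer affinities. This drift — *thermophilisation* — is
quantified by attaching to each species a scalar thermal affinity (the
**species temperature index, STI**: the mean temperature over the species'
geographic occurrence range), summarising each community at each time point
by the **community temperature index (CTI)**, the unweighted mean STI of the
species present,

$$\mathrm{CTI} = \frac{1}{N}\sum_{i=1}^{N} \mathrm{STI}_i,$$

and taking the per-site OLS slope of CTI on calendar year as the
**thermophilisation rate** (°C/yr). Positive slopes mean warm-affinity
species are gaining prevalence; negative slopes (cryophilisation) mean the
reverse. `thermophilr` implements this pipeline end to end: from occurrence
records and gridded temperatures to STIs, from long-format community
time-series to rarefied CTI series and rates, a decomposition of rates into
species immigration and extirpation, and mixed-effects models of the rates'
drivers. Because the monitoring datasets this style of analysis runs on are
typically restricted or very large, the package ships a virtual-species
simulator with known ground truth, so every stage has a recovery test.

## Species temperature indices

STIs are estimated from cleaned occurrence records
(`clean_occurrences()`: exact duplicates on (species, lat, lon), invalid and
(0, 0) coordinates, optionally preserved specimens) laid over a
climatological annual-mean temperature grid (`bio01`). Records are assigned
to grid cells (half-open cells indexed from the north-west origin, so every
point belongs to exactly one cell) and the STI is the mean `bio01` over the
species' **unique occupied cells**. Averaging cells rather than raw records
blunts the enormous spatial sampling bias of aggregated occurrence data: a
thousand records in one well-surveyed cell count once. The per-record mean
is available (`cells = FALSE`) for comparison. Species with fewer than
`min_sti_records` (default 5) retained records get no profile — range means
over a handful of points are dominated by sampling noise.

Thermal **niche breadth** is the difference between warmest-quarter
(`bio10`) and coldest-quarter (`bio11`) range means. We take the difference
of range-wide means rather than the range mean of cell-wise differences;
the two agree whenever both layers cover the same cells (always, here), and
the choice is configurable (`mode = "cell_diff_mean"`).

Taxa recorded only at genus level, or as inseparable species complexes,
receive the unweighted mean STI of their profiled members
(`aggregate_sti()`), recorded with provenance `genus_mean` /
`complex_mean`. A temporal-stability check (`sti_temporal_stability()`)
re-estimates STIs in year bins (defaults ≤1990, 1991–2000, 2001–2010,
>2010) and correlates them pairwise: if species ranges had shifted enough
to move the STIs, these correlations would fall.

## Community filters and effort standardisation

`filter_communities()` applies the inclusion rules in a fixed order, and
reports the first rule each excluded site trips: observation years before
1980 are dropped; a site must then span ≥ 5 years (last − first), hold ≥ 4
distinct species over its series, and have thermal profiles for ≥ 75% of
its species. The thresholds live in `analysis_config()`.

Heterogeneous within-year sampling effort inflates apparent turnover, so
`rarefy_timeseries()` standardises it: with m the minimum number of
distinct sample units in any year of a series, each of 99 replicates draws
m units per year without replacement, pools the species, and computes the
derived variables (richness, CTI). The per-site-year output is the median
across replicates of each **derived variable** (not of species lists,
which have no meaningful median); the replicate count is kept odd so the
median is an attained value, and replicate r is seeded `seed + r` so any
single replicate is independently reproducible. The downstream rate is
fitted to the median CTI series; fitting a slope per replicate and taking
the median slope is a defensible alternative we considered and rejected for
the main path, since the median-series slope is what the variable-wise
median implies. Fate classification (below) uses the pooled per-year
species sets: rarefaction standardises the *variables* entering the trend,
while the fate decomposition is a census of observed arrivals and
disappearances.

## Turnover decomposition and sign tests

Between consecutive *sampled* years (calendar gaps allowed, unweighted),
each species either persisted, was added, or was lost
(`classify_fates()`). For each transition, `fate_sti_contrasts()` computes
mean-STI differences — added − persisted, added − lost, lost − persisted —
each defined only when both groups are non-empty and contain a profiled
species; per site, each contrast is averaged across the transitions where
it is defined. Whether immigration or extirpation drives thermophilisation
is then a sign question: `sign_binomial_test()` drops zeros (evidence for
neither direction) and computes the exact one-sided binomial tail
P(X ≥ k | n, ½). The exact tail matters because per-group site counts can
be small; a normal approximation is never used.

## Driver models

Per-site predictors (`assemble_predictors()`): the site's own temperature
trend (OLS slope of mean annual temperature over the site's observation
window), baseline temperature (climatological mean annual temperature over
a configurable window, default 1980–2010 — the period is a genuine
free choice, as "baseline" has no canonical definition), community mean
body size (m) and mean niche breadth (°C) as unweighted means over recorded
species with data (body-size coverage below 70% is flagged), total distinct
richness over the series, and series length in years. Predictors are
z-scored (sample sd) before modelling, and `predictor_correlations()`
warns above |r| = 0.7.

The driver model's fixed effects are the six main effects plus
temperature change × {body size, niche breadth, baseline temperature,
richness}, body size × niche breadth, and the three-way temperature
change × body size × niche breadth (all lower-order terms of the three-way
are retained in a single hierarchical formula). Random intercepts: study
nested in taxon group at realm scope, study alone at taxon scope. Residual
spatial correlation is Gaussian, `(1 − nugget)·exp(−(d/ρ)²)`.

Estimation is by REML through `nlme::lme` / `nlme::gls` — the standard
engine for this model family — with ρ (and the optional nugget) estimated
jointly with the variance components. Distances are Euclidean on a local
equirectangular projection of lon/lat to kilometres, which matches
great-circle distance to first order at the regional extents monitored
sites span; raw-degree coordinates are available
(`spatial_coords = "degrees"`). With the spatial term on, correlation acts
among sites within the innermost random-effect group. If the spatial fit
fails to converge the model refits without it, with a warning, rather than
returning an unusable object. Reported t and p values are `nlme`'s
(inner-group denominator df); with no random and no spatial terms
`fit_lmm()` dispatches to `stats::lm` and is *exactly* OLS, which the
tests exploit as a closed-form oracle. Kenward–Roger/Satterthwaite df and
crossed random slopes are out of scope.

After the initial fit, points with residuals beyond 2 SD of the residual
mean are excluded and the model is refitted **once** (no iteration),
a standard safeguard for residual normality. Note the trim is data
dependent: on exactly-null data it removes the ~4.6% largest residuals and
so mildly shrinks the residual variance and liberalises nominal test size.
Calibration checks therefore run on the pre-trim fit
(`refit_outliers = FALSE`); the trim is a robustness step, not part of the
test's sampling model.

## The virtual warming study

The simulator is the package's ground-truth instrument, not a fixture.
Species are given true STIs (normal), true breadths and body sizes
(log-normal), and genus blocks. The landscape is a regular grid with a
latitudinal baseline gradient, seasonal half-amplitude (so cell-wise
`bio10 − bio11` is known by construction), per-cell warming slopes, and
i.i.d. interannual noise. Occupancy is the simplest mechanism that makes
thermal generalism literally protective: species s is present at a site
with temperature T with probability

$$p = p_{det}\cdot\exp\!\left(-\frac{(T - \mathrm{STI}_s)^2}
{2\,(\mathrm{breadth}_s/k)^2}\right),$$

with k = 4 by default, so a species' occupancy width is a quarter of its
seasonal-range breadth. Presences are scattered across the year's sample
units; optional abundances are `1 + Poisson(scale · p/p_det)`, which makes
the occurrence vs abundance CTI comparison meaningful.

Default scenario (chosen once, as the study conditions): 120 sites on a
40 × 40 grid, 150 species, 15 monitored years with staggered site entry
(minimum 8-year span, so series lengths vary as they do in collated
monitoring data), per-site warming drawn uniformly from 0–0.06 °C/yr
(mean 0.03, the order of recent temperate warming; the between-site
heterogeneity is what identifies the temperature-change effect), baseline
gradient 4–16 °C, seasonal half-amplitude 6–10 °C varying with latitude
(constant amplitude would make every species' breadth identical and the
breadth predictor degenerate), detection 0.8, 2–4 samples per site-year,
interannual temperature noise sd 0.3 °C.

What the simulation does *not* emulate — dispersal limitation, biotic
interactions, evolutionary adaptation, land-use covariates, observer
effects beyond binomial detection — bounds what passing tests show: they
demonstrate the estimators recover the quantities this occupancy model
defines, not that real communities obey it.

## What the tests compute, at which sizes

Exact fixtures and oracle equivalences (binomial tails vs enumeration for
all k ≤ n ≤ 12; `fit_lmm` vs closed-form OLS to 1e−8; rarefaction under
uniform effort vs the pooled computation) run in well under a second.
Stochastic checks use sizes chosen to keep the full suite in the tens of
seconds while leaving comfortable Monte-Carlo margins: null symmetry of
fitted rates over 500 no-warming sites (3-SE band around ½); sign-test and
per-term driver-model size over 200 and 60 null replicates; effect
recovery over 100 replicates of 40 studies × 10 sites; the three-way
interaction sign over 40 replicates at n = 500; strict monotonicity of the
mean realised rate over warming rates {0, 0.02, 0.05} °C/yr at 200 sites
each; STI recovery (r > 0.9) at 200 records/species over a > 10 °C pool;
and the warming-direction fate contract at 250 sites. The STI-recovery
fixture uses a 0–20 °C landscape with STI ~ N(10, 3) so that thermal
optima stay inside the sampled gradient — edge truncation would attenuate
any range-mean estimator, a property of the fixture rather than the
estimator.

## Numerical conventions and degenerate inputs

Grid cells are half-open (south/east edge ownership), so boundary points
are deterministic and cell centroids map back uniquely. No-data cells are
explicit `NA`, never zero. The plain-text grid dialect round-trips doubles
at `%.17g`. CTI points with profile coverage below threshold are rejected,
not imputed; rate fitting needs ≥ 2 distinct years and warns below 3;
z-scoring a constant is an error naming the predictor; singular fixed
designs error listing the aliased columns; a saturated (zero-residual) fit
excludes nothing in the outlier pass. All generators are pure functions of
their seed.

## Known limitations

STIs from occurrence ranges are realised-niche proxies; the rarefaction
median is taken variable-wise; transitions with unequal calendar gaps are
unweighted; inference on mixed models uses `nlme`'s df approximation; and
the spatial correlation acts within random-effect groups, so cross-study
spatial dependence is not modelled. These mirror the method's standard
practice rather than package shortcuts.
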