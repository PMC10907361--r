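# thermophilr

Tools for quantifying **thermophilisation** — the increasing prevalence of
warm-affinity species in ecological communities as climates warm — from
long-format community time-series, species occurrence records and gridded
temperature climatologies, and for modelling what drives it. The package is
aimed at community ecologists and macroecologists working with collated
monitoring data (multi-site, multi-year species lists with heterogeneous
sampling effort).

## The method

Each species gets a **species temperature index** (STI): the mean annual
temperature over its geographic occurrence range, estimated from cleaned
occurrence records assigned to cells of a climatological grid (unique
occupied cells, to blunt sampling-density bias). A community at time t is
summarised by the **community temperature index**

CTI = (1/N) Σᵢ STIᵢ

over the N species present, and each site's **thermophilisation rate** is
the OLS slope of CTI on calendar year (°C/yr). Around this core the package
provides:

- record cleaning, genus/complex STI aggregation, thermal niche breadth
  (Bio10 − Bio11 range means) and a temporal-stability check;
- community inclusion filters (≥ 4 species, ≥ 5-year span, ≥ 75% STI
  coverage, post-1980) and rarefaction-based sampling-effort
  standardisation (99 replicates, variable-wise medians);
- decomposition of composition change into species fates — persisted,
  added, extirpated — with mean-STI contrasts and exact one-sided binomial
  sign tests;
- driver models: linear mixed models (REML via `nlme`) of rates on
  temperature change, community mean body size, thermal niche breadth,
  baseline temperature, series length and richness, with interaction terms,
  study-within-taxon random intercepts, Gaussian spatial correlation
  `(1 − nugget)·exp(−(d/ρ)²)` and a one-pass 2-SD residual-outlier refit;
- a virtual-species simulator (warming landscapes, Gaussian thermal
  occupancy, heterogeneous effort) with known ground truth, so every stage
  has a recovery test.

See the methods vignette (`vignettes/thermophilisation-methods.Rmd`) for
the model, its assumptions and the design choices.

## Worked example

```r
library(thermophilr)

## CTI of a three-species community
profiles <- data.frame(species = c("Poa alpina", "Carex alba", "Festuca ovina"),
                       sti = c(10, 12, 14))
compute_cti(c("Poa alpina", "Carex alba", "Festuca ovina"), profiles)$cti
#> [1] 12

## thermophilisation rate of a short CTI series
r <- thermophilisation_rate(c(2000, 2003, 2006, 2009, 2012),
                            c(11.8, 12.0, 12.1, 12.4, 12.4))
sprintf("rate: %.4f  se: %.4f", r$slope, r$se)
#> [1] "rate: 0.0533  se: 0.0077"
```

The CTI is the mean of the three STIs; the rate says this community's
thermal composition warmed by ~0.053 °C/yr.

A complete virtual warming study — simulate, estimate STIs from generated
occurrences, filter, rarefy, fit per-site rates, fates and the driver
model:

```r
sc  <- simulation_scenario(n_sites = 60, n_species = 80, rng_seed = 42)
res <- run_warming_study(sc, spatial = "none")

nrow(res$rates); mean(res$rates$slope); mean(res$rates$slope > 0)
#> [1] 60
#> [1] 0.0207
#> [1] 0.733

fit_term(res$driver, "temp_change")
#> beta = 0.0096 (se 0.0050, p = 0.062)

sign_binomial_test(res$fates$added_lost, "above")
#> 39/60 above zero, one-sided p = 0.0137
```

Sites warm at 0–0.06 °C/yr in this scenario, and the pipeline recovers the
expected signature: most communities thermophilise (73% positive rates,
mean +0.021 °C/yr), faster-warming sites thermophilise faster (positive
z-scored temperature-change coefficient), and species arriving at a site
tend to be warmer-affiliated than those extirpated from it (39 of 60
sites, exact binomial p = 0.014).

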