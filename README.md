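# florivis

Quantitative analysis of floral resource supply and wild pollinator
visitation in flowering plant communities.

Plant communities at urban–rural boundaries are often invaded by a few
alien species with large floral units and months-long flowering. Such
species can dominate the community's supply of the two primary floral
resources — nectar sugar and pollen — raising a conservation question: do
wild flower-visiting insects (bees and wasps, hoverflies, butterflies)
concentrate their visits on the dominant suppliers, or do they spread
visits over many co-flowering species, so that floral *diversity* rather
than gross floral *quantity* is what sustains them?

`florivis` implements the full measurement-to-inference chain for
year-round plot surveys of this kind, for ecologists running or emulating
them:

* **Resource quantification** — per-flower nectar sugar mass
  `s = 10 d v C` with the sucrose density calibration
  `d = 0.0037921 C + 0.0000178 C² + 0.9988603` (direct microcapillary or
  rinse-dilution measurements), and per-flower pollen volume from aliquot
  grain counts and spheroid grain volume `V = 4/3 π A B²`.
* **Area-based availability** — µg sugar and µL pollen per 1 m² plot per
  survey occasion, from open floral-unit counts × species means, with
  unmeasured species excluded (never zero-filled) and flagged.
* **Contribution shares** — monthly and annual site-scale proportions
  `p_i` of resources supplied and of insect visits received per species,
  from pooled raw totals.
* **Seasonal trends** — per-site GAMs over census day: gamma log-link on
  resource + 0.0001, negative-binomial log-link (theta estimated) on visit
  counts; basis dimension 10, per-plot observations.
* **Diversity comparison** — Shannon `H′ = −Σ p_i ln p_i`, richness and
  evenness `J′ = H′/ln S` for resource-supplying (Sug, Pol) vs
  insect-visited (AP, WB, HF, BF) flowering species, with Tukey HSD
  comparisons across categories using sites as replicates.
* **A synthetic survey generator** — seed-deterministic two-year datasets
  (4 sites × 5 plots, biweekly then monthly surveys, 29-species community
  with resource-rich long-flowering aliens) under competing visitation
  regimes (`resource_proportional`, `even_preference`, `native_biased`),
  with ground truth for recovery testing.

## Worked example

Simulate a survey in which insects visit co-flowering species evenly
regardless of resource content, then ask whether the diversity of visited
flowers exceeds the diversity of the resource supply:

```r
library(florivis)

cfg <- simulation_config(seed = 42, regime = "even_preference")
ds  <- generate_survey_data(cfg)
ds
#> <synthetic_survey>
#>   regime: even_preference, seed: 42
#>   species: 29 rows
#>   floral_counts: 4540 rows
#>   visits: 13446 rows
#>   nectar_samples: 396 rows
#>   pollen_counts: 252 rows
#>   pollen_grains: 280 rows

prof <- build_species_profiles(ds$tables$nectar_samples,
                               ds$tables$pollen_counts,
                               ds$tables$pollen_grains, ds$tables$species)
head(prof, 3)
#> # A tibble: 3 × 5
#>   species_id mean_sugar_ug mean_pollen_ul n_nectar n_pollen
#>   <chr>              <dbl>          <dbl>    <int>    <int>
#> 1 alien_01           110.            4.48       18        9
#> 2 alien_02            44.0           1.65       18        9
#> 3 alien_03            34.9           1.54       18        9

gap <- diversity_gap(ds)
head(as.data.frame(gap), 4)
#>      site study_year H_Pol H_Sug H_AP delta_H
#> 1 site_01          1  1.17  1.33 3.12    1.87
#> 2 site_01          2  1.19  1.35 3.06    1.79
#> 3 site_02          1  1.18  1.34 3.12    1.86
#> 4 site_02          2  1.21  1.36 3.05    1.76
```

Reading the numbers: the dominant alien holds about 60% of the annual
resource supply, so the Shannon diversity of the nectar-sugar and pollen
supply (`H_Sug` ≈ 1.3, `H_Pol` ≈ 1.2 nats) is low. Visits spread evenly
over the ~25 co-flowering species push the diversity of insect-visited
flowers to `H_AP` ≈ 3.1, a gap `delta_H` of ≈ 1.85 nats — the signature
that distinguishes even-preference visitation from visits tracking
resources (under `regime = "resource_proportional"` the same pipeline
yields `delta_H` ≈ 0).

`run_pipeline(cfg, "out/")` runs every stage (validation, quantification,
availability, contributions, GAM trends, diversity, Tukey) and writes the
output tables, a run log with per-stage record counts (including how many
honeybee/Coleoptera/Hemiptera records the wild-taxon filter removed), and
an MD5 manifest; identical config and seed reproduce identical checksums.

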