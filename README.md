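# frugnet

Individual-based analysis of plant–frugivore seed-dispersal networks along a
range-expansion gradient.

## The problem

When a fleshy-fruited plant population expands its range, the frugivores that
disperse its seeds can reorganize their visits across the expansion gradient,
and that reorganization decides which individual plants feed the seed rain
that drives colonization. Quantifying this requires working at the level of
*individual plants*: a weighted bipartite network whose rows are focal plants,
whose columns are frugivore species, and whose weights are estimated visits.

`frugnet` implements the full analysis chain for such studies, motivated by a
Mediterranean juniper (*Juniperus phoenicea* subsp. *turbinata*) system with
three 1-ha stands along a natural colonization gradient (mature stand MAR,
intermediate stand OJI, colonization front COL; 35 focal plants each, N = 105,
surveyed for 434 days with camera traps and DNA-barcoded scat collections):

1. **Survey standardization** — camera records cover a fraction of each plant
   (60/40/20% by size class) for a fraction of the study; seed traps sample a
   small canopy fraction (~0.56 m²). Counts are scaled to whole-plant,
   whole-study visit estimates, `n / area_fraction / time_fraction`, and the
   two channels are merged cellwise into one adjacency matrix `A`.
2. **Modularity** — Barber's bipartite weighted modularity

   `Q = (1/F) Σᵢⱼ [Aᵢⱼ − kᵢdⱼ/F] δ(gᵢ, gⱼ)`

   maximized by weighted label propagation (LPAwb+, with a multi-restart DIRT
   variant), with significance from a connectance-preserving null ensemble
   (cell probabilities ∝ kᵢdⱼ, link count and integer total conserved,
   marginals free) and node roles *c* (among-module connectivity) and *z*
   (within-module degree).
3. **Module composition** — Pearson's χ² of independence on the stand × module
   plant counts with Haberman adjusted residuals to flag over/under-represented
   cells.
4. **Trait discrimination** — VIF pruning (threshold 3), forward Wilks' Λ
   selection, then LDA of module membership with resubstitution accuracy.
5. **Seed rain** — the multiplicative seed-dispersal-effectiveness estimator

   `seeds_pf = visits_pf × feeding_rate_f × seeds_per_cone_p × undamaged_f × viability_p`,

   followed by OLS drivers of log-contributions, all-subsets AICc selection,
   exact LMG decomposition of R², ANOVA + Tukey comparisons between modules
   and stands, within-stand contribution z-scores and ranked cumulative-share
   curves, and log–log size/centrality regressions.
6. **Synthetic generator** — a fully parameterized emulation of the field
   design (stand-correlated traits, negative-binomial latent visits, both
   survey channels with their detection thinning, the 52% behaviour-filter
   reduction, 92.6% barcoding identification) with planted module ground
   truth, so every stage is testable without the field data.

## Worked example

```r
library(frugnet)

cfg <- pipeline_config(synthesis = study_config(rng_seed = 1),
                       n_null = 100, rng_seed = 1)
res <- run_all(cfg)
print(res)
#> Individual-based frugivory network analysis
#>   visit matrix: 105 plants x 12 species, total 228297 visits
#>   modules: 4 (Q = 0.137)
#>   modularity z = 157.35 (normal p = 0)
#>   stand x module: X2 = 30.29, df = 6, p = 3.5e-05
#>   pooled viable seed rain: 1788559 seeds

round(sort(res$shares, decreasing = TRUE)[1:3], 3)
#>  Turdus_philomelos      Turdus_merula Erithacus_rubecula
#>              0.841              0.063              0.042

res$ranking$plants_to_share
#> COL MAR OJI
#>   4   9   9
```

Reading this output: the merged survey estimates 228,297 whole-study visits;
the network splits into modules far more strongly than the null ensemble
(z = 157); module membership is associated with stand provenance
(χ² = 30.3, p < 10⁻⁴); the song thrush accounts for 84% of the estimated
viable seed rain; and only 4 colonization-front plants accumulate half their
stand's seed rain versus 9 in the mature stand — the truncated contribution
curve characteristic of a founder-dominated front.

The worked single-cell numbers of the estimator chain are also directly
reproducible:

```r
coverage_fraction_for_cover(15)          # 0.60 for a small plant
round(4 / 0.60, 1)                       # 6.7 whole-plant visits
# recorded during 20% of the study:
# 4 / 0.60 / 0.20 = 33.3 whole-study visits
# 5 fox visits x 7.4 cones/visit x 5.22 seeds/cone x 0.97 x 0.21
# = 39.3 viable seeds dispersed
```

## Input schemas

Four CSV tables (UTF-8, `.` decimal), as written by `synthesize_study()`:

| table | required columns |
| --- | --- |
| plants | `plant_id`, `stand`, `cover`, `crop_size`, `seeds_per_cone`, `seed_viability` (+ traits) |
| species | `species_id`, `functional_group`, `feeding_rate`, `undamaged_fraction` |
| camera_records | `plant_id`, `species_id`, `n_records`, `recorded_days`, `coverage_fraction` (+ `behaviour`) |
| scat_records | `plant_id`, `species_id` (or `UNIDENTIFIED`), `n_samples`, `sampled_area`, `canopy_area`, `active_days` |

`read_tables()` validates all of this and reports every violation with row
numbers. See `vignettes/frugnet-methods.Rmd` for the model assumptions,
numerical choices and limitations.
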