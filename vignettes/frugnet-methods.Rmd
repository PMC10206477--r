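---
title: "Methods: individual-based plant-frugivore network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based plant-frugivore network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`frugnet`, in the order the pipeline runs them, together with what the
synthetic-data generator does and does not emulate.

## Study design being modelled

The package targets individual-based frugivory studies of the following
shape: three stands along a range-expansion gradient of a fleshy-fruited
plant (a mature stand, an intermediate stand, a colonization front), a fixed
panel of focal plants per stand (35 each, N = 105 by default), and two
complementary interaction surveys run over one long study window (434 days by
default):

* **camera traps** rotate across the focal plants, film a known fraction of
  each plant's surface (60% for plants under 20 m² cover, 40% for 20-40 m²,
  20% above 40 m²) and yield records that must first pass a behaviour filter
  (only genuine cone-foraging visits count; passive perching, scent marking
  and passing animals are discarded — about half of all records);
* **seed traps with DNA barcoding** sample scats under each plant on a small
  known surface (mean 0.56 m²) for a known number of active days, with a
  species identification succeeding for a fraction (92.6%) of samples.

## Effort standardization and fusion

Both channels observe a fraction of a plant for a fraction of the study, so
each observed count is scaled to a whole-plant, whole-study visit estimate:

\[
\hat A_{pf} \;=\; \frac{n_{pf}}{\text{area fraction}_p \times \text{time fraction}_p}.
\]

For cameras the area fraction is the size-class coverage above and the time
fraction is recorded days / study days; for seed traps the area fraction is
min(1, sampled area / canopy area) and the time fraction uses trap-active
days. Unidentified barcoding samples are dropped without reweighting (an
optional inflation by the inverse identification rate exists but is off by
default, matching the convention of dropping them silently). The two
standardized matrices are fused **cellwise by summation** over the union of
ids: both are unbiased estimates of visits from disjoint detection processes,
so the sum conserves totals (`F_merged = F_a + F_b`); a cellwise mean is
available as an option. Size-class boundaries put 20 m² and 40 m² in the
middle class (closed on both sides) — the verbal definition leaves the
boundaries ambiguous and this choice is fixed here once.

Internal precision is never rounded; display values such as 4/0.6 = 6.7 are
rounded only for reporting.

## Modularity

For the weighted bipartite matrix \(A\) with grand total \(F\), row strengths
\(k_i\) and column strengths \(d_j\), Barber's modularity of a joint module
assignment \(g\) is

\[
Q = \frac{1}{F}\sum_{i,j}\Bigl[A_{ij} - \frac{k_i d_j}{F}\Bigr]\,
\mathbf 1(g_i = g_j),
\]

summed over plant-species pairs. `lpawb_plus()` maximizes Q by weighted label
propagation: every plant starts in its own module, each side alternately
adopts the partner-side module with the largest summed Barber weight (a node
whose best existing module has negative score opens a fresh singleton, which
contributes exactly zero), then pairwise module merges are attempted; the
loop stops when the Q improvement falls below the tolerance (default 1e-10)
or after `max_steps` (default 1000) sweeps. Because each one-sided relabeling
is an exact coordinate ascent given the other side, Q is non-decreasing
throughout, and the result is a local optimum under single relabels and
pairwise merges. Ties go to the lowest module index. `dirt_lpawb_plus()`
restarts from varied random initial module counts (cycling 1..min(dim)) and
keeps the best Q; all randomness flows from one seed.

On matrices small enough for exhaustive search the heuristic is checked
against `exhaustive_barber_optimum()`, which enumerates the set partitions of
the row side and exploits the fact that, given the row partition, Q separates
over columns so each column can be optimally assigned independently. This
oracle is exact and algorithmically independent of the label propagation.

### Null model and significance

Significance of the observed Q uses a connectance-preserving ensemble. The
observed matrix is first rounded to integer interactions with occupied cells
floored at one (the null allocates discrete interactions; modularity itself
always runs on the unrounded weights). Each null matrix draws cells with
probability proportional to \(k_i d_j\): first covering every row and column
(drawing from the uncovered-row x uncovered-column block so no draws are
wasted), then opening further cells until the observed link count L is
reached, then distributing the remaining (total − L) interactions
multinomially over the occupied cells. Marginal totals are deliberately
**not** conserved. Each null is remodularized with the same optimizer, and
the report carries the z-score of observed Q, its upper-tail normal p-value,
and the empirical rank p-value (1 + #{null ≥ obs}) / (n_null + 1). Default
ensemble size is 100.

### Node roles

With \(\kappa_{it}\) the strength (or link count, if `weighted = FALSE`;
weighted is the default) of node \(i\) into module \(t\) and
\(k_i = \sum_t \kappa_{it}\):

* among-module connectivity \(c_i = 1 - \sum_t (\kappa_{it}/k_i)^2\);
* within-module degree \(z_i\), the own-module strength standardized over the
  same-side members of the node's module.

Zero-degree nodes are excluded with a warning; modules whose same-side
members have zero spread give z = 0 with a warning rather than NaN.

## Module composition vs stand

Plant counts by (module, stand) are tested with Pearson's χ² of independence
(no continuity correction; expected counts from the margins), and cellwise
structure is read from Haberman adjusted residuals
\(r = (O-E)/\sqrt{E(1-\text{row}/N)(1-\text{col}/N)}\) flagged at |r| > 1.96.
The cellwise method is a package choice: the underlying studies assert
over/under-representation without naming one, and adjusted residuals are the
standard tool. The χ² implementation is the closed formula, cross-checked in
the tests against `stats::chisq.test`.

## Trait discrimination

1. **VIF pruning**: iteratively drop the variable with the largest
   \(1/(1-R^2_j)\) until all are below the threshold (default 3).
2. **Forward Wilks' Λ selection**: Λ = det(W)/det(T) of the selected set;
   at each step the candidate minimizing Λ enters if its partial
   \(F = \frac{n-g-p}{g-1}\bigl(\Lambda_p/\Lambda_{p+1}-1\bigr)\) has
   p < `entry_alpha` (default 0.2, the conventional lenient entry threshold
   of greedy selection routines).
3. **LDA** via `MASS::lda` with priors proportional to class sizes (equal
   priors optional), classification by the largest discriminant score, and
   **resubstitution** accuracy (leave-one-out CV available as an option).

Modules represented by a single plant are excluded with a warning — a
one-member class has no within-class scatter. Nutrition traits (pulp ash,
protein, fibre, lipids) are analysed on the complete-case subset, the same
operation on a different column set.

## Seed rain and its drivers

The seed-dispersal-effectiveness estimator is multiplicative:

\[
S_{pf} = \hat A_{pf}\times FR_f \times \text{seeds/cone}_p \times
\text{undamaged}_f \times \text{viability}_p ,
\]

a quantity component (visits x cones per visit x seeds per cone) times a
quality component (gut-treatment survival x seed viability). It is exactly
multilinear, which the tests exploit.

Downstream analyses:

* **Contribution regression**: OLS of log(plant total + 1) on the visits of
  the dominant disperser (its own predictor), the remaining species
  aggregated by functional group, and the plant reproductive traits
  (seeds/cone, viability). The log(x+1) guard is the package's resolution of
  "log-transformed" for plants that may have zero estimated seeds. The
  response is the per-plant total; a per-plant-by-species variant of the
  question is deliberately not the default since the reported predictor
  structure (one row per functional group, one R²) corresponds to per-plant
  totals.
* **AICc selection**: Gaussian AICc
  \(n\log(RSS/n) + 2k + 2k(k+1)/(n-k-1)\), k counting coefficients including
  the intercept plus the error variance; all-subsets enumeration up to 12
  predictors; undersized candidates are skipped with a warning.
* **LMG importance**: exact subset-enumeration decomposition (weights
  \(|S|!\,(p-|S|-1)!/p!\)), equal to averaging sequential R² gains over all
  p! orderings; shares are nonnegative and sum to the full-model R². Limited
  to 10 predictors.
* **Group comparisons**: one-way ANOVA on log contributions with Tukey HSD
  pairwise comparisons (`stats::TukeyHSD`, studentized-range p-values on
  N − k df); singleton groups are excluded with a warning.
* **Inequality**: within-stand z-scores with the sample (n−1) standard
  deviation; plants ranked descending with cumulative-share curves; the
  summary statistic is the number of plants needed to reach half the stand
  seed rain. A stand with zero spread yields z = 0 with a warning; a stand
  with zero total seed rain is an error.
* **Size and centrality effects**: log-log OLS of contributions on canopy
  cover (an age proxy) and on network node strength. Strength is the default
  centrality; weighted closeness-type measures were considered and rejected
  as the default because strength is derivable from the adjacency matrix
  alone and is the measure most directly tied to interaction frequency.

Bootstrap standard errors for per-species seed totals resample plants with
replacement (1000 draws, seeded).

## The synthetic generator

`study_config()` encodes the design constants: 3 stands x 35 plants, 434
days, coverage rule 60/40/20%, trap area 0.56 ± 0.1 m², trap-active days
415 ± 8, camera days 82 ± 27, foraging fraction 0.48 (so the behaviour filter
discards ~52% of camera records), identification success 0.926. Species
defaults (12 frugivores, functional groups, feeding rates, per-stand
visitation intensities) come from the observed assemblage table shipped with
the package (`frugivore_reference()`), with per-plant intensity = stand visit
total / 35. Undamaged-seed fractions are set per functional group (small
birds 0.95, medium birds 0.90, fox 0.97, other medium mammals 0.95, rabbit
0.50) — plausible values chosen once, since gut-treatment data are not part
of the shipped table.

Latent visits are negative binomial (`dispersion` = 1.5 by default; Inf gives
the Poisson limit) with mean = per-stand intensity x module concentration x
plant attractiveness, where attractiveness is log-linear in standardized crop
size and cone diameter (coefficients 0.3 and 0.2), normalized to mean one so
the intensity scale is preserved. Surveys subsample these latent visits by
binomial thinning with exactly the probabilities that the standardization
stage later inverts, so standardized estimates are unbiased for the latent
visits channel by channel.

Trait gradients follow the documented pattern: size, fecundity, cone size and
viability increase toward the colonization front while conspecific
neighbourhood density collapses there (8.8 to 1.3 plants/100 m², mirroring
882 vs 126 plants/ha); neighbourhood fecundity peaks at the intermediate
stand. Within-stand spreads were chosen once so that each trait's
between-stand variance share stays below ~0.55: this gives realistic overlap
between stands and keeps the variance inflation factors of the
stand-correlated traits below the pruning threshold of 3, so collinearity
pruning removes genuinely redundant variables rather than the gradient
itself. The colonization front additionally contains a small founder fraction
(3/35) of pioneer plants with five-fold crops, doubled cover and elevated
seed viability — the size-and-fecundity hierarchy of young stands that
produces a truncated ranked-contribution curve at the front.

Ground truth is planted by mapping stands to modules (MAR→C, OJI→B, COL→A)
and assigning each species its module; `module_boost`/`module_damp` scale a
species' intensity on plants inside/outside its module. The defaults (1, 1)
leave the empirical stand profiles untouched; `strong_signal_config()`
(boost 2, damp 0.02) produces the near-block structure used by the recovery
experiments, where the pipeline is expected to retrieve the planted modules
(normalized mutual information is the score), the stand-module association,
and the planted trait discriminators (neighbourhood density, neighbourhood
fecundity, cone diameter).

What the generator does **not** emulate: spatially explicit frugivore
movement, within-season phenology, multi-year demography, the camera
rotation schedule (recorded days are drawn as a random total, not as 10-day
blocks), and correlations between the two survey channels beyond their shared
latent visits. Passing recovery tests therefore demonstrates the pipeline's
correctness under the stated sampling model, not robustness to field
artefacts outside it.

## Problem sizes and seeds

The shipped tests run the full pipeline on 105-plant studies (about a quarter
second per run without the null ensemble), 20-replicate recovery experiments,
100-null significance ensembles, and exhaustive modularity oracles on
matrices up to 4x4 — sizes chosen so the whole suite completes in well under
a minute while each check retains clear statistical margins. Every stochastic
stage takes an explicit seed, and pipeline stages derive child seeds from one
master seed, so complete runs are byte-reproducible.

## Known limitations

* The label-propagation optimizer guarantees a local, not global, optimum;
  the exhaustive cross-checks cover only small matrices, and hard instances
  can require more restarts.
* The null ensemble interprets weights as discrete interactions; matrices
  whose weights are far from integers are rounded for null generation, a
  convention (floor at one for occupied cells) that slightly inflates sparse
  totals.
* The normal p-value for modularity assumes an approximately normal null Q;
  the empirical rank p is reported alongside and is the safer choice for
  small ensembles.
* Resubstitution accuracy is optimistic by construction; use the
  leave-one-out option for honest error rates.
* Dropping unidentified barcoding samples without reweighting biases absolute
  visit totals slightly downward (never the camera channel), though shares
  and network structure are essentially unaffected at 92.6% identification.
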