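# qmprof

Quantitative microbiome profiling (QMP) for cohorts at risk of rheumatoid
arthritis (RA).

## What this package is for

Studies of the gut microbiome in preclinical RA ask whether specific taxa —
*Prevotellaceae* above all — track the progression from genetic risk through
autoimmunity to symptomatic disease. Answering that requires more than a
count table: participants must be assigned to preclinical stages by an
explicit algorithm, sequencing counts must be converted to absolute scale
(estimated cells per gram of stool) using flow-cytometric microbial loads,
and inference must respect compositional, non-normal data. `qmprof`
implements that analysis stack end to end for epidemiologists and
bioinformaticians working with 16S cohort data:

* **Cohort classification** — the four-stage algorithm (control /
  high genetic risk / autoimmunity / symptomatic) built from autoantibody
  titres relative to their upper limits of normal (ACPA ≥ 1× ULN,
  RF and anti-Ra33 ≥ 3× ULN), shared-epitope genotype, and the 7-item
  clinically-suspect-arthralgia (CSA) score with its standard (≥ 4) and
  lowered (≥ 3) cutoffs; plus pronounced-phenotype subgroup selection with
  sex/age-matched controls.
* **QMP construction** — 16S copy-number correction, rarefaction of every
  sample to the even sampling depth `s* = min_i(corrected_depth_i / load_i)`,
  exclusion of samples below 150 rarefied reads, and rescaling to cells per
  gram so that each sample's column sums to its measured load.
* **Community ecology** — Shannon diversity, Bray–Curtis dissimilarities,
  principal-coordinate analysis, and a from-scratch one-factor PERMANOVA
  (pseudo-F, R², seeded permutation p with the +1/+1 convention).
* **Enterotyping** — Dirichlet-multinomial mixture fitting by damped EM,
  BIC model selection over K, and assignment to the canonical Bact1 / Bact2 /
  Prev / Rum community types.
* **Differential abundance** — prevalence filtering (≥ 10 reads in ≥ 5% of
  samples), Monte-Carlo Dirichlet instances, centred log-ratio transform,
  per-taxon rank tests and Benjamini–Hochberg correction.
* **Resampling inference** — the 10 000-sample permutation test on
  subgroup median differences, pairwise rank-sum tests versus control, and
  Monte-Carlo Fisher contingency tests.
* **Synthetic cohorts** — a generator reproducing the full study design
  (371 participants: 226 / 50 / 49 / 46 across the four groups,
  enterotype-structured compositions, loads, copy numbers, serology,
  calprotectin), with verified round-trip label fidelity, so the whole
  pipeline runs without access to restricted cohort data.

Everything is tidyverse-native: metadata and results are tibbles, fitted
objects have `tidy()` / `glance()` methods, and `autoplot()` /
`plot_*()` functions produce ggplot2 figures.

## Worked example

```r
library(qmprof)

cfg <- simulation_config(
  group_sizes = c(control = 40, high_genetic_risk = 12,
                  autoimmunity = 12, symptomatic = 12),
  n_taxa = 40, n_ra_symptomatic = 2, seed = 42
)
cohort <- simulate_cohort(cfg)

assignments <- classify_cohort(cohort$participants)
table(assignments$group)
#>      autoimmunity           control high_genetic_risk       symptomatic
#>                12                40                12                12

qmp <- qmp_transform(cohort$counts, cohort$copy_numbers, cohort$loads, seed = 1)
qmp
#> QMP matrix: 115 taxa x 76 samples (0 excluded), even sampling depth 8.55e-09

groups <- setNames(assignments$group, assignments$participant_id)
d <- bray_curtis(qmp$cells_per_gram)
permanova(d, groups[colnames(qmp$cells_per_gram)], n_permutations = 999, seed = 2)
#> PERMANOVA: pseudo-F = 1.053, R2 = 0.04204, p = 0.382 (999 permutations)
```

The QMP matrix holds estimated cells per gram (columns sum to each sample's
microbial load); the even sampling depth is the community fraction every
sample was downsized to. The PERMANOVA R² says ~4% of the Bray–Curtis
variance lies between preclinical stages, and p = 0.382 means the grouping
explains no more than random relabellings would — the expected answer here,
since this synthetic cohort was generated without any group effect.

Enterotyping and the subgroup permutation test continue from the same
objects:

```r
genus <- aggregate_taxa(cohort$counts, cohort$taxonomy, "genus")
deep  <- genus[, colSums(genus) >= 10000]
sel <- dmm_select(rarefy_counts(deep, 10000, seed = 3), k_range = 2:5,
                  seed = 4, n_restarts = 2, max_iter = 150, tol = 1e-3)
sel$scores
#>       k log_likelihood n_parameters    bic converged
#> 1     2        -15950.           81 32248. TRUE
#> 2     3        -15672.          122 31868. TRUE
#> 3     4        -15290.          163 31279. TRUE
#> 4     5        -15257.          204 31389. TRUE

table(assign_enterotypes(sel$best_model, genus)$label)
#> Bact1 Bact2  Prev   Rum
#>    35    13    12    16

prev <- aggregate_taxa(to_relative(cohort$counts), cohort$taxonomy,
                       "family")["Prevotellaceae", ]
subgroup_permutation_test(
  prev,
  idx_a = assignments$participant_id[assignments$group == "control"][1:10],
  idx_b = assignments$participant_id[assignments$group == "autoimmunity"][1:10],
  n_permutations = 10000, seed = 5
)[, 1:4]
#>   observed_median_difference p_one_sided n_permutations group_size
#> 1                    -0.0274       0.809          10000         10
```

BIC bottoms out at K = 4 — the four community types the mixture was asked to
find — and the one-sided permutation p of 0.809 says the autoimmunity
subgroup's median *Prevotellaceae* proportion does not exceed the control
subgroup's more than random size-10 subsets would.

The full pipeline (classification → QMP → ecology → enterotypes →
differential abundance → subgroup tests → calprotectin) runs as one call and
writes per-stage artifacts plus a machine-readable report:

```r
report <- run_pipeline(pipeline_config(output_dir = "run1", seed = 1))
```

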