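# Example pipeline configuration: a small synthetic cohort, all stages on.
seed: 1
stages: [qmp, ecology, enterotype, diffabund, subgroups, calprotectin]
min_rarefied_reads: 150
permanova_permutations: 999
enterotype_k_range: [2, 3, 4, 5, 6]
subgroup_k: 10
permutation_samples: 10000
simulation:
  seed: 1
  n_taxa: 60
  n_ra_symptomatic: 3
  group_sizes: {control: 60, high_genetic_risk: 15, autoimmunity: 15, symptomatic: 15}
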