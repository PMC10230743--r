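# Example pipeline configuration for run_pipeline().
# Either give a `simulate` block (as here) or an `inputs` block with paths
# to the five standard files: asv, taxonomy, metadata, pedigree, logger.
simulate:
  n_individuals: 40
  n_mothers: 6
  adult_decay: 0
  samples_per_individual: 2.5
  seed: 42
metric: jaccard
model:
  interactions:
    - "mo_status:age_sim"
    - "sri:age_sim"
sampler:
  chains: 2
  warmup: 500
  iter: 500
  max_leapfrog: 8
  seed: 1
mantel: true
mantel_permutations: 999
scan: false
output_dir: pipeline_out
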