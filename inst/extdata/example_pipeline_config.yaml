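# Example configuration for promstate::run_pipeline() /
# inst/scripts/promstate.R. A `simulate` block generates a synthetic
# study; replace it with an `inputs` block (annotation, probes,
# intensities, expression file paths) to analyze real tables.
seed: 1
simulate:
  n_genes: 500
  n_chroms: 5
  n_background_probes: 500
peaks:
  min_probes: 4
  fdr: 0.05
  n_permutations: 200
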