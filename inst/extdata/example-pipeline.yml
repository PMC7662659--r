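# Example pipeline configuration for run_pipeline(read_pipeline_config(...)).
# A synthetic input on a coarse axis so the full workflow runs in seconds;
# point `input` at a wide-CSV path to analyse real spectra instead.
input: synthetic
synthetic:
  axis_step: 16
  seed: 1
trim: [700, 3450]
wavelet:
  basis: db3
  level: 4
  threshold_rule: universal_soft
selection: [uve_spa]
classifiers: [ELM, PLSDA]
tasks: [origins]
partition_seed: 1
seed: 1
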