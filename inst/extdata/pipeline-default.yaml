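# Default desk-scale configuration for run_pipeline(); every key mirrors an
# argument of pipeline_config() / sim_config().
sim:
  n_individuals: 2000
  n_snps_auto: 8000
  n_snps_x: 500
  maf_range: [0.01, 0.5]
  ld_decay: 0.9
  block_break_prob: 0.05
  # rows: MAF bins (rare, low-frequency, common); columns: LD quartiles 1-4
  bin_enrichment:
    - [0.0, 0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.0, 0.0]
    - [0.34653465, 0.33663366, 0.18811881, 0.12871287]
  h2_auto: 0.36
  h2_x: 0.03
  h2_fam: 0.21
  category_freqs: [0.32, 0.23, 0.27, 0.18]
  age_slope: 0.02
  age_range: [40, 73]
  repeat_target: 0.88
  fertility_mean: 1.81
  fertility_score_slope: -0.030
  n_brother_pairs: 200
  n_father_son_pairs: 200
  seed: 1
maf_min: 1.0e-4
miss_max: 0.05
hwe_min: 1.0e-6
prune_r2: 0.9
rel_cutoff: 0.05
gws_p: 5.0e-8
collinearity_r2: 0.9
cojo_window_bp: 1.0e7
ldsc_blocks: 200
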