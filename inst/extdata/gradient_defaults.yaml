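seed: 1
n_sites_per_type: 2
n_reps_per_site: 3
plfa_log_means:
  basalt: 4.00733318523247117
  shale: 3.78418963391826102
  ironstone: 2.89037175789616452
  sandstone: 2.99573227355399085
plfa_log_sd: 0.29999999999999999
allocation_intercepts:
  nlfa_c: 2.56494935746153674
  phb_c: 2.99573227355399085
  trehalose_c: 1.38629436111989057
allocation_contrast:
  nlfa_c: 0.91629073187415511
  phb_c: 0.91629073187415511
  trehalose_c: 0.0
covariate_slope: 1.0
site_sd: 0.10000000000000001
residual_sd: 0.20000000000000001
fungal_fraction:
  fertile:
    mean: 0.20000000000000001
    sd: 0.02
  infertile:
    mean: 0.38
    sd: 0.03
phosphatase_link: 0.80000000000000004
phosphatase_log_mean: 5.52146091786224602
phosphatase_log_sd: 0.29999999999999999
chem_sdlog: 0.20000000000000001
mbc_per_plfa: 8.5
mbc_sdlog: 0.14999999999999999
mbp_cp:
  fertile: 15.0
  infertile: 60.0
mbp_sdlog: 0.29999999999999999
.config_class: gradient_config
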