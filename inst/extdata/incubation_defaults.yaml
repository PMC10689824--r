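seed: 1
n_reps: 5
days:
- 0.0
- 1.0
- 2.0
- 3.0
- 4.0
- 8.0
- 10.0
control_respiration_total:
  basalt: 454.0
  sandstone: 201.0
resp_shape:
- 1.19999999999999996
- 1.10000000000000009
- 1.05000000000000004
- 1.0
- 1.0
- 0.94999999999999996
- 0.90000000000000002
control_pools:
  basalt:
    mbc: 553.0
    plfa_total_c: 13.40000000000000036
    plfa_fungal_c: 1.89999999999999991
    plfa_bacterial_c: 8.5
    nlfa_c: 22.30000000000000071
    phb_c: 33.39999999999999858
  sandstone:
    mbc: 235.0
    plfa_total_c: 4.79999999999999982
    plfa_fungal_c: 1.19999999999999996
    plfa_bacterial_c: 1.89999999999999991
    nlfa_c: 20.5
    phb_c: 41.0
effects:
  glucose_c:
    basalt:
      respiration: 6.0
      mbc: 4.0
      plfa_total_c: 2.5
      plfa_fungal_c: 3.0
      plfa_bacterial_c: 1.0
      nlfa_c: 2.5
      phb_c: 2.5
    sandstone:
      respiration: 6.0
      mbc: 4.0
      plfa_total_c: 2.5
      plfa_fungal_c: 3.0
      plfa_bacterial_c: 1.0
      nlfa_c: 2.5
      phb_c: 2.5
  po4_p:
    basalt:
      respiration: 1.0
      mbc: 1.0
      plfa_total_c: 1.0
      plfa_fungal_c: 1.0
      plfa_bacterial_c: 1.0
      nlfa_c: 1.0
      phb_c: 1.0
    sandstone:
      respiration: 2.0
      mbc: 1.10000000000000009
      plfa_total_c: 1.30000000000000004
      plfa_fungal_c: 1.0
      plfa_bacterial_c: 1.80000000000000004
      nlfa_c: 1.0
      phb_c: 1.0
noise_sdlog: 0.12
resp_day_sdlog: 0.05
.config_class: incubation_config
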