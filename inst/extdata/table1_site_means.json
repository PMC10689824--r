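{
  "level": "site_mean",
  "n_records": 8,
  "provenance": "Published site means (n = 3 field replicates per site) for the eight-site soil fertility gradient; per-SOC storage columns are stored as printed (means of replicate-level ratios, not ratios of the tabulated means)."
}
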