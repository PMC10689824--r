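sample_id,site_id,soil_type,fertility_class,total_organic_c,soluble_organic_c,total_n,total_p,mehlich_po4,mbc,mbp,substrate_cp,microbial_cp_mass,microbial_cp_molar,plfa_total,plfa_bacterial,plfa_fungal,nlfa_c,phb_c,trehalose_c,phosphomonoesterase,phosphodiesterase,glucosidase,nlfa_per_soc,phb_per_soc,trehalose_per_soc
basalt_1,basalt_1,basalt,fertile,0.0428,102,2577,620,1.96,553,38.2,59.6,29.4,75.6,67.0,42.7,9.5,22.3,33.4,0.9,952,296,205,532,807,22.1
basalt_2,basalt_2,basalt,fertile,0.0305,53,2240,243,0.67,273,28.5,80.0,9.7,25.1,42.5,27.4,5.4,10.3,15.1,4.3,270,229,61,339,514,138
shale_1,shale_1,shale,fertile,0.0239,68,1766,168,1.41,327,22.4,53.6,14.4,37.1,42.1,23.2,7.8,14.3,20.5,41.0,381,162,229,603,858,1740
shale_2,shale_2,shale,fertile,0.0451,87,2765,164,2.48,419,38.1,53.2,10.5,27.1,46.5,27.2,7.0,17.1,25.4,7.2,1155,244,412,393,587,248
ironstone_1,ironstone_1,ironstone,infertile,0.012,66,750,131,0.03,203,0.7,2981,417,1075,15.5,7.0,3.5,14.6,36.1,0.8,513,307,97,1238,3114,68.3
ironstone_2,ironstone_2,ironstone,infertile,0.0141,48,1059,119,0.17,186,3.5,528,59.9,154,21.4,8.1,6.2,18.4,30.0,12.5,774,282,95,1431,2248,686
sandstone_1,sandstone_1,sandstone,infertile,0.0097,57,900,95,0.07,156,3.3,1266,43.5,112,15.2,6.4,3.5,9.9,18.7,1.0,630,245,54,1016,1924,98.2
sandstone_2,sandstone_2,sandstone,infertile,0.0162,62,851,36,0.17,235,3.2,636,78.7,203,24.1,9.5,6.0,20.5,41.0,1.7,931,407,160,1361,2605,165
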