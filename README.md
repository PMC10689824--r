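# micstore

Analysis of intracellular **mic**robial carbon **stor**age across soil
fertility gradients, for soil microbial ecologists and biogeochemists
working with lipid-biomarker (PLFA/NLFA), polyhydroxybutyrate (PHB) and
trehalose data.

Soil microbes store carbon in two conceptually different ways. *Reserve*
storage is constitutive — a fixed, taxon-specific fraction f_res of
acquired C is diverted to storage at the expense of growth. *Surplus*
storage is plastic — under nutrient limitation, C in excess of growth
demand is stored rather than lost to "overflow" respiration. `micstore`
provides:

* **A storage-explicit stoichiometric model** of microbial C–P growth. Per
  unit C uptake u_C, growth is G = min(e·s, r_B·u_P) (C-allowed vs
  P-allowed, with s the growth-side C supply), respiration is
  (1−e)/e·G plus overflow, and net storage follows the strategy (none /
  reserve / surplus). The threshold element ratio — the substrate C:P at
  which growth switches from C- to P-limitation — is TER = r_B / e.
  Gradient sweeps raise organic C at fixed P above the baseline C:P and
  raise P at fixed C below it, normalising all rates by baseline C uptake.
* **Covariate-scaled allocation statistics**: mixed models
  `log(storage) ~ log(PLFA) + group + (1 | site)` with likelihood-ratio
  tests and estimated marginal means at the overall mean log covariate
  (bacterial PLFA is the covariate for PHB); Bray–Curtis dissimilarity and
  seeded PERMANOVA for PLFA composition.
* **Incubation effect sizes**: trapezoid-integrated cumulative
  respiration and log response ratios ln(mean_treatment / mean_control)
  with delta-method 95% CIs.
* **A seeded synthetic-data generator** emulating the study designs
  (4 soil types × 2 sites × 3 replicates; 2 soils × 3 treatments × 5
  replicates) for parameter-recovery, power, and type-I-error
  experiments, plus a packaged fixture of the eight published site means
  (`inst/extdata/table1_site_means.csv`; column schema documented in
  `?load_gradient_csv` and `?table1_fixture`).

## Worked example

```r
library(micstore)

fx <- table1_fixture()
ix <- gradient_summary_indices(fx)
#  NLFA max: 22.3 ug C/g soil at basalt_1
#  mean NLFA per SOC: 864 ug C/g SOC
#  storage = 20.0% of MBC; F:B fold = 2.41
```

Across the eight site means, storage compounds hold ~20% of microbial
biomass C, and infertile (ironstone/sandstone) communities carry a
2.4-fold higher fungal:bacterial PLFA ratio than fertile (basalt/shale)
ones.

```r
ps <- soil_params("sandstone")       # r_B = 78.7, baseline C:P = 636
threshold_element_ratio(ps)
# [1] 174.8889
sweep_gradient("all", ps, 50, 5000, n_points = 101)
# <gradient_sweep> C:P 50-5000, baseline 636, TER 174.89, modes: none, reserve, surplus
```

The sandstone baseline (636) sits far right of its TER (175): the
community is P-limited, so C addition raises respiration only for the
no-storage and reserve strategies, while the surplus strategy stores the
excess and its respiration stays flat.

```r
g   <- generate_gradient(gradient_config(seed = 1))
fit <- fit_allocation_model(g, "nlfa_c", "plfa_total", "fertility_class")
fit
# <allocation_fit> log(nlfa_c) ~ log(plfa_total) + fertility_class + (1 | site), n = 24
#   LRT: chisq = 11.51, df = 1, p = 0.000692
fit$emm
#       group emmean    se ci_low ci_high
# 1   fertile   2.63 0.117   2.40    2.86
# 2 infertile   3.43 0.117   3.21    3.66
```

The generator injected a 2.5-fold allocation contrast (log 2.5 = 0.92);
the fitted EMM difference is 0.80 with the LRT rejecting no-contrast at
p < 0.001.

```r
inc <- generate_incubation(incubation_config(seed = 1))
eff <- incubation_effect_sizes(inc)
subset(eff, variable %in% c("mbc", "respiration") & soil == "sandstone")
#         soil treatment    variable      rr     se ci_low ci_high significant
#    sandstone glucose_c         mbc  1.3674 0.0907  1.190   1.545        TRUE
#    sandstone glucose_c respiration  1.8268 0.0748  1.680   1.973        TRUE
#    sandstone     po4_p         mbc -0.0147 0.0808 -0.173   0.144       FALSE
#    sandstone     po4_p respiration  0.7318 0.0660  0.602   0.861        TRUE
```

Glucose raises MBC about 4-fold (rr = 1.37 ≈ ln 4) and phosphate roughly
doubles sandstone respiration (rr = 0.73 ≈ ln 2), while leaving MBC
unchanged.

`reproduce_paper(out_dir = "out")` runs the fixture-based pipeline end to
end (summary indices plus both model parameterisations across all three
storage strategies) and writes `report.json`, `model_sweeps.csv`, and a
run manifest.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model
equations and their assumptions, the default parameterisations, the
generator's calibration, numerical choices, and known limitations.
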