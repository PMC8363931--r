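# mesozone

Compartment-aware quantification of multiplexed immunofluorescence (mfIHC)
tissue-microarray cores, and survival screening of the resulting marker
variables — the pixel-based analysis used to ask whether fibroblast markers
(PDGFRA, PDGFRB, aSMA, FAP, SPARC, POSTN, collagen I) in the tumor-cell and
stromal compartments of malignant pleural mesothelioma carry prognostic
information.

It is written for image-analysis and biostatistics researchers who want the
whole chain as tested, seedable functions rather than a GUI pipeline:

1. **Overlay** two staining rounds per 1.0 mm core (integer-pixel
   registration on the nuclear counterstain, QC on tissue coverage).
2. **Mask** pixels as autofluorescence / vessel / background / tissue with a
   seeded random-forest pixel classifier (intensity + two-scale Gaussian
   features).
3. **Segment** tissue into the mesothelioma (tumor-cell) compartment and
   stroma by thresholding the tumor-marker signal (CK5 / CK5+CK5-6+calretinin),
   with monotone morphological cleanup.
4. **Zone** the stroma into concentric 12 µm rings by Euclidean distance
   from the mesothelium (meso Z1–Z4) and from vessels (vessel Z1–Z4).
5. **Quantify** mean intensity per marker × compartment, averaged over each
   patient's QC-passed cores, plus the marker-positive fraction of the
   tumor-cell area (classification confidence ≥ 0.85).
6. **Screen** the `markers × 10 compartments` variables (×1000 scale)
   against survival: univariate Cox models with Bonferroni correction
   (`p_corr = min(1, m·p)`), multivariable Cox adjusted for age, sex, side,
   stage and histology, Schoenfeld-residual proportional-hazards
   diagnostics, and log-rank / Mann–Whitney / Spearman utilities.

Because no patient images are distributed, the package carries a first-class
synthetic-data layer: TMA-core **phantoms** with exact geometric and
intensity ground truth (including brute-force zone oracles), and survival
**cohorts** whose hazard is `h0 · exp(β · 1000 · marker)`. Every pipeline
stage is tested against these oracles.

## Worked example

Simulate a 24-patient study (2 cores each) in which only `PDGFRB_meso` —
PDGFRB mean intensity in the tumor-cell compartment — carries a true hazard
ratio of 1.02 per scaled unit, then run the full pipeline:

```r
library(mesozone)

cfg <- run_config(n_patients = 24, cores_per_patient = 2,
                  beta = log(1.02), effect_variable = "PDGFRB_meso",
                  multivariable_sets = list("PDGFRB_meso"), seed = 1)
res <- run_pipeline(cfg)
#> [mesozone] run 11ee8714: seed 1, 24 patients x 2 cores
#> [mesozone] classifier trained on 3349 labeled pixels from 8 cores
#> [mesozone] 48/48 cores passed QC
#> [mesozone] screen: 70 variables, Bonferroni m = 70, top variable PDGFRB_meso

head(res$screen$report, 5)
#>         variable n_used    HR ci_low ci_high       p p_corrected ph_p
#>      PDGFRB_meso     24 1.024  1.011   1.037 0.00026       0.018 0.13
#>  SPARC_vessel_Z3     24 0.989  0.976   1.001 0.06700       1.000 0.80
#>  SPARC_vessel_Z2     24 0.989  0.977   1.001 0.06800       1.000 0.79
#>     SPARC_stroma     24 0.989  0.977   1.001 0.06800       1.000 0.80
#>  SPARC_vessel_Z4     24 0.989  0.976   1.001 0.06900       1.000 0.78
```

Reading the top row: the injected effect is recovered as HR 1.024 per
scaled intensity unit (95 % CI 1.011–1.037) and survives Bonferroni
correction over all m = 70 screened variables (corrected p = 0.018); the
Schoenfeld test (`ph_p = 0.13`) gives no evidence against proportional
hazards. All 69 null variables stay non-significant after correction. The
adjusted multivariable model tells the same story:

```r
subset(res$screen$report, model_id == "multivariable_1" &
         variable == "PDGFRB_meso")
#>     variable n_used    HR ci_low ci_high       p p_corrected ph_p
#>  PDGFRB_meso     24 1.032  1.014    1.05 0.00043          NA 0.18

lr <- logrank(res$cohort$months, res$cohort$event,
              ifelse(res$scaled_table$PDGFRB_meso >
                       median(res$scaled_table$PDGFRB_meso), "high", "low"))
#> chisq = 4.77, p = 0.029
```

Set `out_dir` in `run_config()` to write the QC table, patient variable
table, screen report, log and a provenance manifest (config hash included)
to a run directory; identical configs reproduce identical outputs bit for
bit. A thin CLI (`inst/cli/mesozone`) exposes `run`, `simulate` and
`survive` over YAML configs.

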