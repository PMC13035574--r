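# esohsi

Hyperspectral imaging (HSI) analysis of esophagogastric tissue in R:
phantom simulation, physiological index maps, and pixel-wise tissue
classification with a hybrid 3D-1D convolutional network under
leave-one-patient-out cross-validation (LOPO-CV).

## Who this is for

Researchers working on intraoperative HSI of the upper gastrointestinal
tract who need a tested, self-contained pipeline to (a) prototype
tissue-classification and perfusion-parameter analyses without access to
clinical recordings, and (b) evaluate such analyses the way the field
reports them: patient-wise, one-vs-rest, mean ± SD across patients.

## What it computes

**Phantoms.** Annotated hyperspectral cubes (default 64 × 64 pixels ×
100 bands, 500–1000 nm) of three tissue classes — esophageal mucosa,
gastric mucosa, cancer — built from a Beer–Lambert forward model
`R(λ) = S(λ)·10^(−A(λ))` with Gaussian extinction templates for oxy- and
deoxyhemoglobin and water, power-law scattering `S(λ) = a(λ/500)^(−b)`,
log-normal per-pixel chromophore jitter and sensor noise. Cohorts carry
per-patient tumor stages; T3/T4 patients receive a programmed
water-content increment. Cubes are written as ENVI header + binary,
masks as PNG.

**Preprocessing.** Spectral median filter (kernel 5, reflect padding) →
per-pixel standard normal variate (SNV) → crop to 520–1000 nm (96 of
100 bands).

**Physiological indices.** StO2, NIR-PI, TWI and OHI as absorbance
band-mean ratios on the raw cube (windows e.g. TWI 955–980 / 880–900 nm),
min–max clamped to [0, 1]; summarized as per-patient region means.

**Classifier.** Hybrid 3D-1D CNN on 3 × 3 × 96 patches: two Conv3D
layers (3×3×7 kernels, collapsing the spatial extent), two spectral
Conv1D layers, flatten, dropout, dense softmax — 28,915 parameters at
the defaults — trained with class-weighted cross-entropy (balanced
weights `N/(K·n_c)`) under Adadelta, early-stopped on validation
cancer-F1. Implemented from scratch in base R with an exact,
numerically verified backward pass.

**Evaluation.** LOPO-CV (1 test / 3 validation patients per fold);
patient-wise sensitivity, specificity, F1, Matthews correlation
coefficient and rank-sum ROC-AUC per class; macro summaries across
tissue types as mean ± sample SD of the per-class means.

**Statistics.** Welch t-tests on per-patient region means for the four
panel designs (healthy stomach vs cancer, healthy esophagus vs cancer,
and early vs late tumor stage within cancer and within healthy regions),
with strict significance stars.

## Worked example

```r
library(esohsi)

cohort <- generate_cohort(8, phantom_spec(), seed = 1)
res <- run_lopo(cohort,
                model_cfg = model_config(max_epochs = 25,
                                         early_stop_patience = 5,
                                         seed = 1),
                seed = 1)
subset(res$summary$per_class, metric == "auc")
#>    class_index tissue_class metric      mean           sd n_patients
#> 5            1    esophagus    auc 0.9995696 5.624064e-04          8
#> 10           2      stomach    auc 0.9996227 4.240687e-04          8
#> 15           3       cancer    auc 0.9999953 4.205929e-06          8
```

Each row is the across-patient mean ± SD of that class's one-vs-rest
ROC-AUC on the held-out patient of each fold: on well-separated
phantoms the pipeline ranks essentially every pixel correctly, and the
cancer class — the rare one, ~7.5% of pixels — is the easiest to rank,
which is exactly what the class weighting and cancer-F1 early stopping
are there to achieve.

```r
summaries <- summarize_cohort(cohort)
cmp <- compare_groups(summaries)
cmp[cmp$design == "C_stage_cancer" & cmp$index == "TWI",
    c("index", "design_label", "mean_a", "mean_b", "p", "stars")]
#>    index                    design_label    mean_a    mean_b          p stars
#> 11   TWI T1/T2 vs T3/T4 (cancer regions) 0.3124473 0.4324425 0.03637591     *
```

The tissue water index of cancer regions is significantly higher in
T3/T4 than in T1/T2 patients — recovering the programmed stage effect
(+0.15 water fraction) from the image data alone.

## Package layout

- `R/phantom.R` — chromophore templates, phantom and cohort generation
- `R/io.R` — ENVI cube I/O, PNG masks, RGB previews, cohort manifests
- `R/preprocess.R` — median filter, SNV, wavelength crop
- `R/physio.R` — absorbance, band-ratio indices, region summaries
- `R/nn.R`, `R/classifier.R` — the CNN engine, patch extraction, training
- `R/evaluation.R` — LOPO splits, metrics, ROC, aggregation, maps
- `R/stats.R` — Welch tests, panel comparisons, report bundle
- `vignettes/esohsi-methods.Rmd` — model, assumptions, design decisions
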