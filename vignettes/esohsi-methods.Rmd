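---
title: "Hyperspectral classification of esophagogastric tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral classification of esophagogastric tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intraoperative hyperspectral imaging (HSI) records, for every pixel of a
surgical field, a reflectance spectrum across the visible and
near-infrared range (here 100 bands, 500–1000 nm, on 480 × 640-pixel
frames). Because hemoglobin, water and scattering shape these spectra
differently in healthy mucosa and in carcinoma, two analyses become
possible on esophagogastric specimens:

1. **Physiological index maps** — band-ratio summaries of tissue
   oxygenation (StO2), near-infrared perfusion (NIR-PI), water content
   (TWI) and hemoglobin content (OHI), compared between tissue classes
   and between tumor stages; and
2. **Pixel-wise tissue classification** — a hybrid 3D-1D convolutional
   network fed small spatial–spectral patches, evaluated patient-wise
   under leave-one-patient-out cross-validation (LOPO-CV).

Clinical recordings of this kind are not publicly deposited, so `esohsi`
ships a first-class synthetic-data module: annotated phantom cohorts
whose spectra carry the chromophore structure both analyses rely on.
Every downstream stage is exercised and tested against these phantoms.

## The phantom forward model

A pixel's reflectance follows a Beer–Lambert composition:

$$R(\lambda) = S(\lambda)\,10^{-A(\lambda)}, \qquad
A(\lambda) = c_{\mathrm{Hb}}\left[f\,\varepsilon_{\mathrm{HbO_2}}(\lambda)
+ (1-f)\,\varepsilon_{\mathrm{Hb}}(\lambda)\right]
+ w\,\varepsilon_{\mathrm{H_2O}}(\lambda),$$

with $S(\lambda) = a (\lambda/500)^{-b}$ a power-law scattering
background, $c_{\mathrm{Hb}}$ total hemoglobin, $f$ its oxygenated
fraction, and $w$ the water fraction. The extinction curves are
*synthetic Gaussian templates*, not published molar extinction tables:
oxyhemoglobin carries its alpha/beta bands (542/577 nm) plus a broad
near-infrared shoulder at 850 nm, deoxyhemoglobin its 555 nm band and
760 nm peak, water its dominant 970 nm band and a minor 740 nm overtone.
The templates keep exactly the qualitative features the indices and the
classifier need — hemoglobin structure at 500–600 and 750–800 nm, water
absorption near 970 nm — without importing any external data.

Default class parameters give cancer higher hemoglobin, water and oxygen
saturation than the two healthy mucosa classes, mirroring tumor
angiogenesis and peritumoral edema. Within-class variability is modeled
as multiplicative log-normal jitter (SD 0.15 on the log scale) on
`total_hb` and `water_fraction` per pixel — reproducing the large
within-class spectral variance of real mucosa — plus additive Gaussian
sensor noise (SD 0.01). Tumor stage is a per-patient label whose only
physiological consequence is a configurable water-fraction increment
(default +0.15) in T3/T4 patients, applied to cancerous *and* healthy
regions: water is the stage-dependent parameter the statistical module
is meant to recover.

The default layout places esophageal mucosa left of a 40% column split,
gastric mucosa right of it, and a cancer ellipse (7.5% of pixels)
straddling the boundary. This reproduces the order-of-magnitude class
imbalance of a gastric-dominated clinical cohort (roughly 55/37/7.5%).
Test-scale cubes are 64 × 64 × 100; the geometry scales to the clinical
480 × 640 frame by configuration.

What the phantoms do *not* model: radiative transfer or multiple
scattering, specular glare, instrument spectral response, spatial
texture within a region, and annotation errors. Passing tests therefore
demonstrate that the pipeline recovers programmed structure under
realistic variance and imbalance — not clinical-grade performance.

## Preprocessing

Spectra are (1) median-filtered along the spectral axis (kernel 5,
edge-inclusive reflect padding — the smallest window that removes one-
and two-band spikes), (2) normalized per pixel by the standard normal
variate (SNV: subtract the mean, divide by the sample SD, `n − 1`), and
(3) cropped to the closed interval 520–1000 nm, dropping the noisiest
short-wavelength bands (96 of 100 bands remain on the default grid).
The stage order is fixed: smoothing and normalization are described
before the crop in the source protocol, so SNV moments are taken over
the full recorded range; the two orders genuinely differ, and the tests
assert the non-commutativity. Spectra whose SD falls below `1e-8` map
to the zero spectrum rather than erroring, so fully shadowed pixels
cannot abort a run.

## Physiological indices

The four indices are **absorbance band-mean ratios on the raw
reflectance cube** — SNV destroys the absolute scale the ratios need, so
the index branch leaves the pipeline before normalization. Absorbance is
$-\log_{10}\max(R, 10^{-4})$. Windows (numerator / denominator, nm):

| index | numerator | denominator |
|-------|-----------|-------------|
| StO2 | 570–590 | 740–780 |
| NIR-PI | 825–925 | 655–735 |
| OHI | 530–590 | 785–825 |
| TWI | 955–980 | 880–900 |

The vendor-side formulas behind the clinical maps are not published, so
the acceptance surface here is *ordinal*: the indices must recover
programmed orderings (TWI strictly monotone in water, OHI in total
hemoglobin, StO2 in the oxygenated fraction), not absolute values. Each
ratio is min–max clamped through a per-index scaling interval to [0, 1].
The scaling floors (0.3473, 1.7092, 1.1456, 0.2295 for StO2, NIR-PI,
TWI, OHI) equal each index's absorber-free scatter-baseline ratio on the
default 100-band grid — with unit scattering amplitude the baseline is
independent of the scattering slope — so chromophore-free tissue maps to
exactly 0. The ceilings (4.0, 4.0, 3.5, 4.5) sit beyond the
physiological extremes of the phantom parameter space so that ordering
information is never saturated away. On a different wavelength grid the
baselines shift slightly; the intervals are config keys.

Region summaries average each index over a region's valid pixels; the
analysis unit everywhere downstream is the **per-patient region mean**,
never the pixel, to avoid pseudo-replication.

## The hybrid 3D-1D CNN

Input is a `p × p × B` patch (default `p = 3`, `B = 96` after
preprocessing) labeled by its center pixel; patches must lie fully
inside the image (no padding), so the prediction map shrinks by
`(p−1)/2` per side. The architecture is

```
input p×p×B×1
  → Conv3D (3×3×7, 8 filters, ReLU)     spatial 3×3 → 1×1
  → Conv3D (1×1×7, 16 filters, ReLU)    (spatial kernel shrinks to the
                                         remaining extent)
  → Conv1D (7 → 5-wide, 32 filters, ReLU)  along the spectral axis
  → Conv1D (5-wide, 64 filters, ReLU)
  → flatten → dropout 0.5 → dense softmax (3 classes)
```

28,915 parameters at the defaults. The engine (valid convolutions as
sums of shifted BLAS matmuls, exact backprop, Adadelta/Adam/SGD) is
implemented in the package; the backward pass is verified against
numerical differentiation to ~1e-8 relative error. Filter counts,
kernel widths, epoch budget and early-stopping patience are not part of
the source protocol; the defaults are chosen so the model trains on a
single CPU in minutes at phantom scale.

Training minimizes class-weighted cross-entropy (balanced weights
`N/(K·n_c)`, countering the ~7.5% cancer prevalence), shuffles samples
under the config seed after bringing them into a canonical
(patient, row, column) order — making training invariant to the input
row order — and early-stops on the validation F1 of the cancer class:
training halts once that F1 has failed to improve for more than
`early_stop_patience` epochs, and the best-epoch parameters are kept.
The validation F1 is computed unweighted; whether the clinical analysis
weighted it is unknowable from the protocol, and the unweighted score is
the sharper stopping signal for the rare class.

**The optimizer.** The source protocol names a "delta optimizer" with a
learning rate of 1e-4. Read as Adadelta, these two facts conflict at
desk scale: Adadelta's update is already RMS-normalized (the ratio of
running update-RMS to gradient-RMS), so the learning-rate slot is a pure
step multiplier, and at 1e-4 the network provably cannot leave its
initialization within any realistic epoch budget — we observe the loss
pinned at ln 3. The package therefore defaults to the canonical
scale-free parameterization (`learning_rate = 1.0`, rho 0.95, eps 1e-6),
under which the phantom task converges within ~6 epochs; the multiplier
remains a config key, so the literal 1e-4 (appropriate for framework
defaults at clinical data scale) or Adam/SGD can be substituted.

## Evaluation protocol

LOPO-CV: one fold per patient; in each fold one patient is the test set,
three randomly drawn patients (seeded) validate the early stopping, the
rest train. Per-class training patches are capped (default 400 per class
per fold; validation 250) to keep CPU training tractable — prediction and
scoring of the held-out patient always use *all* annotated pixels.

All metrics are patient-wise, one-vs-rest per class: sensitivity,
specificity, F1, Matthews correlation coefficient, and ROC-AUC computed
by midrank (Mann–Whitney) statistics — identical, to 1e-9, to
trapezoidal integration over the tie-grouped threshold sweep. Zero
denominators yield 0 by documented convention so patient-wise averages
stay total; a class absent from a patient's annotation produces a
*missing* row, excluded from averages rather than zero-filled (not every
specimen contains all three tissues). Per-class summaries are
mean ± sample SD across patients; the "across all tissue types" macro
summary is the unweighted mean of the three per-class means with the
sample SD of those three means — the convention that exactly reproduces
a "74 ± 8%" style headline from per-class values of 0.65/0.77/0.81.

## Statistical comparisons

Four panel designs, for each index: (A) healthy stomach vs cancer,
(B) healthy esophagus vs cancer, (C) T1/T2 vs T3/T4 within cancer
regions, (D) T1/T2 vs T3/T4 within healthy regions. The test is Welch's
unequal-variance t-test on per-patient region means (group variances
differ visibly between healthy and tumor tissue; a pooled-variance
switch exists). Stars follow the strict thresholds *p* < 0.05 / 0.01 /
0.001. No multiple-testing correction is applied by default, matching
the per-comparison annotation convention; Holm adjustment is one
argument away. On null cohorts (stage increment 0) the stage comparison
holds its nominal 5% size — verified by 1000 seeded replicates at
12 × 12 × 20 phantom scale, where patient-level parameter jitter
dominates and cube size is statistically irrelevant to the patient-mean
test.

## Numerical and degenerate-input choices

- Median filter: row-wise sorting networks (exact, vectorized) on the
  symmetric-padded spectra matrix.
- SNV: sample SD (`n − 1`); sub-epsilon SD → zero spectrum.
- Probability ties in the argmax map break toward the lower class index.
- Early stopping with patience 0 stops after the first non-improving
  epoch; improvement is strict (`> best + 1e-12`).
- Confusion counts are cast to double before the MCC product, which
  overflows 32-bit integers at clinical pixel counts.
- ENVI I/O: float64 BSQ written (bit-exact round trips); BSQ/BIL/BIP and
  integer data types accepted on read; readers reject inconsistent
  metadata rather than coercing.

## Worked example

```{r example}
library(esohsi)

cohort <- generate_cohort(8, phantom_spec(), seed = 1)
res <- run_lopo(cohort,
                model_cfg = model_config(max_epochs = 25,
                                         early_stop_patience = 5,
                                         seed = 1),
                seed = 1)
res$summary$macro

summaries <- summarize_cohort(cohort)
compare_groups(summaries)

build_report("report", eval_rows = res$rows, summary = res$summary,
             comparisons = compare_groups(summaries),
             config = list(model = model_config(),
                           preprocess = preprocess_config()),
             predictions = res$predictions,
             masks = setNames(lapply(cohort, `[[`, "mask"),
                              vapply(cohort, `[[`, "", "patient_id")))
```

## Known limitations

- The phantom spectra are smooth Gaussian-template compositions; real
  mucosa shows sharper extinction structure, specular highlights and
  spatial texture. Classifier performance on phantoms is an upper bound.
- Index values are ordinal summaries on an arbitrary [0, 1] scale; they
  are not calibrated concentrations and are not comparable to
  vendor-device readouts.
- The inception-based alternative architecture is not implemented; the
  hybrid 3D-1D CNN is the only registered model. Patch sizes other than
  1/3/5 would need a different spatial kernel plan.
- Hyperparameter search is limited to seeded manual configuration; no
  Bayesian optimization is included.
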