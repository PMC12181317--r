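---
title: "Classifying liver tissue from ATR FT-IR spectra: methods and design"
author: "irtissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying liver tissue from ATR FT-IR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtissue)
```

## The problem

Infrared absorbance spectra of resected liver tissue carry a biochemical
fingerprint: protein backbone (amide I/II/III), CH~2~/CH~3~ deformation,
carbohydrate (glycogen) and phosphate (DNA, phospholipid) bands. Normal
liver is glycogen-rich; hepatocellular carcinoma (HCC) retains an
intermediate glycogen level because it arises from hepatocytes;
cholangiocellular carcinoma (CCC) and metastases are glycogen-poor, and
CCC additionally shows elevated amide-III/collagen signals (1240, 1282,
1340 cm^-1^) from its desmoplastic stroma. `irtissue` implements the full
chemometric pipeline that turns such spectra into tissue-class calls —
both for fiber-probe ATR point spectra and for focal-plane-array (FPA)
spectroscopic images — together with a synthetic spectrum generator so the
whole pipeline is testable without patient data.

## Preprocessing

The fixed chain for ATR spectra is:

1. optional atmospheric (water-vapor) compensation,
2. restriction to 950–1800 cm^-1^,
3. linear two-point baseline correction,
4. restriction to the classification range 950–1480 cm^-1^,
5. area normalization over 950–1480 cm^-1^,
6. min–max normalization per spectrum.

Decisions an implementer must make, and the choices taken here:

* **"Area" is the discrete sum** of absorbance values over the range, not
  a trapezoidal integral. This matches the convention of the image
  outlier rule (a plain sum of absorbance values) and is
  spacing-invariant after normalization.
* **Baseline anchors default to the range endpoints** (950 and
  1800 cm^-1^). A two-point baseline in a stated range most naturally
  anchors at its ends; the anchors are configurable
  (`preprocess_spec(baseline_anchors = ...)`). Corrected values at the
  anchors are set to exactly zero.
* **Order of area vs. min–max normalization.** Area normalization belongs
  to spectral preprocessing (thickness/contact-pressure correction);
  min–max scaling is applied to training and test sets immediately before
  classification. Both orders are supported
  (`preprocess_spec(minmax_last = FALSE)` swaps them); the default runs
  area first.
* **Atmospheric compensation** subtracts a scaled water-vapor reference.
  The scale is fitted by least squares on *first differences* over
  1300–1800 cm^-1^: the derivative of a narrow symmetric line is
  antisymmetric and decorrelates from the locally near-linear slopes of
  broad tissue bands (amide I sits right on a water line at
  ~1653 cm^-1^, so a plain least-squares fit would be badly biased). The
  fitted scale is clipped at zero. On simulated spectra this removes
  planted lines to below 1% of their height.
* Wavenumber-to-index lookups use the nearest grid point, and a window
  [lo, hi] is a closed interval; nothing in the pipeline interpolates.
  Spectra are stored in ascending wavenumber order (readers reverse
  conventional descending files and record that they did).

The default ATR grid is 950–1800 cm^-1^ at 2 cm^-1^ point spacing
(spectral resolution 4 cm^-1^ with zero filling), the default imaging
grid 3 cm^-1^; the point spacing is configurable everywhere because
instrument settings vary.

## Imaging

FPA tiles of 64 × 64 pixels (175/64 µm per pixel) are assembled row-major
into mosaics — the standard 4 × 12 layout spans 700 × 2100 µm. Outlier
pixels are those whose absorbance sum falls *strictly below* 20 or whose
amide-I absorbance (nearest grid point to 1650 cm^-1^) is strictly below
0.01; they are masked, left out of every mean spectrum, and rendered as
missing in contrast images (the per-pixel sum over 950–1800 cm^-1^).
The sum threshold of 20 is only meaningful for raw absorbance spectra on
a grid of a few hundred points — it scales with the number of grid
points — so it is a configurable default, not a constant. Mean-spectrum
bands use the sample (n−1) standard deviation, computed after area
normalization by default.

## Region selection

A genetic routine searches for the wavenumber windows within
950–1480 cm^-1^ that best separate the classes:

* chromosome: a fixed-length list of (center, width) genes with an
  on/off bit each (2–5 active windows, widths 4–40 cm^-1^ by default);
* fitness: the training set is split once per run, 65% to fit a
  quadratic discriminant on the candidate's features and 35% to score
  it; the same split serves every candidate;
* operators: tournament selection (size 3), uniform gene exchange
  (probability 0.7), Gaussian jitter of centers and widths plus bit
  flips (probability 0.1 per gene), elitism (2), so the best fitness is
  non-decreasing over generations;
* repair: windows are clipped to the range, sorted, and merged when they
  overlap, making every emitted region set canonical and the repair
  idempotent;
* tie-breaks: equal fitness goes to the candidate with fewer features,
  then the lower mean wavenumber — runs are exactly reproducible from
  the seed.

Population 60 and 80 generations are the defaults; these
hyperparameters are not prescribed by the underlying method and were
chosen for desk-scale runtime, all configurable. The historically
reported optimal windows for the two liver tasks ship as presets
(`preset_regions("normal_vs_tumor")`: 995–1005, 1102–1114,
1151–1155 cm^-1^; `preset_regions("tumor_entities")`: 968–972,
1252–1258 cm^-1^ and ±2 cm^-1^ windows around 1396 and 1450 cm^-1^), so
classification can be run without the selector.

The 65/35 fitness split is drawn at spectrum level by default, matching
the historical protocol ("65% of the spectra"). Spectrum-level splitting
leaks patient effects: spectra of one patient are correlated, and placing
some on each side of the split flatters the fitness estimate. The
selector therefore also supports `split_level = "patient"`, which we
recommend for honest internal estimates. Relatedly, the fitness recorded
with a selected region set is the maximum over all candidates evaluated
on one fixed holdout, so on null data it is optimistic (winner's curse);
chance-level behavior of the selector must be judged on independent data,
which is how the package's tests check it.

## Classification

The classifier is quadratic discriminant analysis: one Gaussian per
class with its own covariance. Class covariances are the sample
covariances with trace-scaled ridge shrinkage,
Σ~k~ + λ·(tr(Σ~k~)/d)·I with λ = 10^-3^ by default. Narrow selected
windows keep the feature count small, but adjacent grid points are
nearly collinear and unregularized covariances can be numerically
singular; the shrinkage value is recorded in the model. Posteriors are
computed in log space via Cholesky factors and normalized with
log-sum-exp; tests require agreement with naive density ratios to 10^-8^
on well-conditioned problems, and with an independent QDA implementation.

Decisions are made per tissue sample, not per spectrum: the posterior
vectors of all of a sample's spectra are averaged with equal weight
(slices are not re-weighted — the protocol gives no weighting rule), and

* **binary rule:** the sample is assigned to the class whose mean
  probability exceeds 0.5. An exact 0.5 is assigned to the tumor class
  and flagged ambiguous — the clinically conservative choice for a
  screening context.
* **three-class rule:** the highest of P(Met), P(CCC), P(HCC) wins.
  Exact ties go to the class holding the highest single-spectrum
  posterior, then to class order, and are flagged.

Training-set quality is estimated by stratified k-fold cross-validation;
k is not prescribed, so the default is k = 10, with spectrum- or
patient-level folding. Models refuse to score spectra whose recorded
preprocessing chain differs from the one they were trained under.

## Evaluation

Confusion matrices are tallied at sample level with predicted classes in
rows ("classified as") and true classes in columns. For the binary task,
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
accuracy = (TP+TN)/total and F1 = 2·prec·sens/(prec+sens), with **tumor
as the positive class** — the reading under which the published binary
test table (44/5/4/41) reproduces its stated 0.89/0.92/0.90/0.90 at
two decimals, which the acceptance tests verify. Metrics are kept at
full precision and rounded only for reporting; zero-denominator metrics
are reported as undefined (`NA`), never as 0.

Per-wavenumber two-sample t-tests compare the area-normalized
absorbances of two groups at every grid point, pooled-variance by
default (the classical equal-variance test), Welch optional, α = 0.05,
no multiple-testing correction by default (Benjamini–Hochberg is
available and reported alongside when enabled). Zero-variance points are
flagged degenerate with p set to 0 or 1 by whether the means differ.

## The synthetic generator

Real cohorts of this kind are not publicly deposited, so the generator
is a first-class module. A class is a catalogue of Gaussian/Lorentzian
bands (`default_band_models()`), with:

* relative class amplitudes encoding the qualitative contrasts above
  (glycogen: normal > HCC > CCC ≈ metastasis; amide-III/collagen highest
  in CCC; CH bands near-equal everywhere). The absolute amplitudes are
  invented calibration constants, documented as such — they are **not**
  estimates of real tissue chemistry;
* a per-patient, per-band log-normal amplitude multiplier (sdlog 0.2 by
  default) shared across all of a patient's spectra. Perturbing band
  amplitudes rather than the overall scale matters: a global scale
  factor would be divided out by area normalization, whereas real
  biovariability survives it — this is also what makes patient-level vs
  spectrum-level splitting consequential;
* a per-spectrum global multiplier (sdlog 0.08) for section thickness
  and contact pressure, a random affine baseline, additive white noise
  (sd 0.004 absorbance), and an optional fixed comb of narrow
  (4 cm^-1^) water-vapor lines between 1300 and 1800 cm^-1^ for the
  compensation step to remove;
* cohort designs specifying patients, samples and spectra per sample
  (typically 3–8 cuts per sample). The default binary design yields
  exactly 135 normal and 147 tumor spectra (27 × 5 and 3 × 7 × 7), and
  the default three-class design yields 38/39/37
  metastasis/CCC/HCC spectra over each entity's first six patients —
  the documented training-set sizes of the two tasks.

What the generator does **not** emulate: ATR penetration-depth
dispersion, Mie scattering, detector nonlinearity, spatial correlation
between neighboring image pixels, and co-occurring pathologies
(fibrosis, steatosis, necrosis). Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline, not clinical
performance on real tissue.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so a
full run completes in well under a minute of compute per experiment:
cohorts of 16–48 patients, genetic-selector settings of population 24 ×
15 generations for repeated (20-seed) recovery runs and the 60 × 80
defaults for single experiments, 50 replicates for the t-test
calibration. Parameter-recovery thresholds (≥ 90% of runs overlapping
the planted band's ±10 cm^-1^ neighborhood) were calibrated once against
an exhaustive sweep of all width-10 windows. Degenerate inputs are
errors, not silent repairs: empty ranges, constant spectra under min–max,
non-positive areas, singular covariances, and preprocessing-signature
mismatches all fail loudly.

## Known limitations

* The genetic selector is a faithful-in-spirit re-implementation of the
  published selection idea, not a bit-compatible port of any particular
  historical code; its encoding and operators are documented above.
* Spectrum-level 65/35 fitness splitting (the default, for protocol
  fidelity) optimistically biases internal fitness on patient-clustered
  data; use patient-level splitting when the estimate matters.
* The cube container is the package's native RDS layout; vendor formats
  (OPUS, SPC, JCAMP-DX) and interferogram-level processing are out of
  scope — the pipeline starts from absorbance.
* Binary decisions at exactly p = 0.5 and multiclass ties are rare
  measure-zero events in practice but are resolved deterministically and
  flagged, as described above.
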