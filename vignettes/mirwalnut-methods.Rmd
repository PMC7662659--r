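---
title: "Methods: FT-MIR fingerprinting, wavelength selection and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FT-MIR fingerprinting, wavelength selection and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Walnut varieties and their geographic origins differ in composition
(oil, protein, phenolics), and those differences leave a fingerprint in
Fourier-transform mid-infrared (FT-MIR) absorbance spectra. `mirwalnut`
implements a complete chemometric authentication pipeline for such data:
wavelet denoising, wavelength (variable) selection, and supervised
classification of origin and variety, organised around three designs —
classifying the four origins, classifying varieties within one origin, and
classifying all ten varieties at once.

A dataset is a wide tibble: `sample_id`, `origin`, `variety`, then one
numeric column per wavenumber (cm^-1^). All stages take this tibble first
and return tibbles or tidy-able result objects, so the pipeline composes
with the pipe.

```{r, eval = FALSE}
library(mirwalnut)
spec <- synthetic_spec(seed = 1)
data <- generate_spectra(spec) |>
  trim_range(700, 3450) |>
  denoise_spectra(wavelet_config())
```

## Sampling design and partition

The reference design nests 10 varieties in 4 origins with 16–20 samples per
variety (192 total); `walnut_design()` carries it, together with the
published per-variety training counts (126 train / 66 test overall).
`stratified_split()` draws the training subset uniformly within each
variety under a seed. Two sizing rules are supported: an explicit
per-variety count table (the default path for the reference design) and a
fraction with a rounding rule (default `round_half_up(2/3 * n)`). The two
are both needed because the published partition is not expressible as any
single rounding of 2/3: 19 samples map to 13 train (rounding 12.67 up)
while 16 samples map to 10 (rounding 10.67 down). When emulating the
reference study the explicit counts are authoritative; the fractional rule
is the general-purpose default for other datasets.

## Wavelet denoising

Spectra are smoothed by orthogonal discrete wavelet shrinkage with the
Daubechies db3 basis at decomposition depth 4 (`wavelet_config()`):

1. forward DWT to depth `level` with half-sample symmetric extension
   (coefficient length `floor((n + F - 1)/2)` per level, so reconstruction
   is exact for any signal length, odd lengths included);
2. shrink every detail coefficient, leaving the approximation band
   untouched. The default threshold is the universal rule
   `t = sigma * sqrt(2 log n)` with the robust noise scale
   `sigma = median(|finest detail|)/0.6745`, applied with soft shrinkage
   (`universal_hard` is available, and a fixed `threshold` — including 0,
   which makes the transform a lossless round trip — can be forced);
3. inverse DWT.

Soft universal shrinkage is the standard sparse-signal reading of
"shrink small coefficients, they are noise"; nothing in the pipeline
depends on the specific rule and both variants are exposed in the
configuration. One practical caveat: soft shrinkage subtracts the
threshold from every surviving coefficient, so signals whose energy sits
in the coarse detail bands (e.g. a slow sinusoid) can be biased more than
they are denoised — `universal_hard` is the better choice there, while on
band-structured absorbance spectra the soft rule reduces the error toward
the noise-free signal. Denoising is deterministic and row-wise
(`denoise_spectra()`), and the pipeline order is fixed as trim → denoise:
the discarded ends of the acquisition range are noise-dominated and would
otherwise bias the noise-scale estimate.

## The PLS engine

All selection criteria and PLS-DA ride on one latent-variable engine
(`fit_pls()`), a deflation-based NIPALS with mean centering and no
scaling (absorbance units are homogeneous across the axis). Per component
the weight vector is the NIPALS fixed point, computed exactly as
`w = S v / |S v|` with `S = X'Y` and `v` the dominant eigenvector of the
small `m × m` matrix `S'S` — deterministic to machine precision, with no
dependence on iteration counts; for a single response column this reduces
to `w = X'y/|X'y|`. Components deflate X by `t p'` and Y by `t q'`;
coefficients are `B = W (P'W)^{-1} Q'`.

`cross_validate_pls()` refits every fold from scratch and pools held-out
squared errors over samples and response columns;
`RMSECV(A) = sqrt(mean(err^2))` for `A = 1..a_max`, and `best_a` is the
smallest component count within `1e-12` of the minimum (parsimony
tie-break). Leave-one-out is the default; venetian-blind k-fold is used
inside the genetic algorithm for speed. The candidate grid extends to 12
components, the factor count used throughout the reference workflow.

## Wavelength selection

### UVE

`uve_select()` appends `n_artificial` uniform-noise columns (default: as
many as there are real variables; amplitude `0.01 * mean(|X|)` — the
stability statistic is scale-free, the amplitude only keeps the appended
block numerically harmless), runs leave-one-out PLS at `pls_factor = 12`
components, and scores every variable by the stability
`c_j = mean(b_j)/sd(b_j)` of its regression coefficient across folds. The
cutoff band is `±max|c|` over the artificial variables; real variables
inside the band are indistinguishable from noise and are dropped. With a
dummy-coded multi-class response the screening is per response column —
each column gets its own noise cutoff and a variable survives by beating
the cutoff in any column; the reported stability is cutoff-normalised
(band edges at ±1). The per-column comparison matters: the maximum of a
variable's stabilities over many dummy columns is a high order statistic
with essentially the same distribution for real and artificial variables,
so a single pooled cutoff loses its discriminating power as the class
count grows. A coefficient with zero spread yields infinite stability: such a
real variable is retained, such an artificial one widens the cutoff to
infinity (everything is then discarded — a diagnostic that the noise block
is degenerate).

### SPA, and the UVE-SPA chain

`spa_select()` grows a candidate chain from every start column by
repeatedly projecting the remaining columns onto the orthogonal complement
of the selected span and taking the largest projection norm (columns whose
projection collapses below `1e-10` of their original norm are skipped as
rank-deficient). Each (start, size) prefix with `k_min ≤ k ≤ k_max`
(default 5–30) is scored by leave-one-out RMSE of an
intercept-plus-subset linear regression, computed from the hat diagonal of
an incrementally grown orthonormal basis; the global minimiser wins, with
ties broken toward fewer variables and then the lower start index.
`uve_spa_select()` feeds only the UVE-retained pool into SPA and reports
indices against the original axis; it fails loudly if UVE retains fewer
than `k_min` variables.

### GA-PLS

`ga_pls_select()` searches binary chromosomes (one bit per variable) with
the reference GA settings: population 30, crossover probability 0.5,
per-bit mutation probability 0.01, and 1000 fitness evaluations per run —
"iterations" is read as chromosome evaluations, the convention of the GA
wavelength-selection literature this parameterisation comes from. Fitness
is the negated minimum RMSECV of a PLS model on the encoded subset
(venetian 5-fold by default; a cross-validated explained-variance fitness
is available). Selection is a size-2 tournament with elitism 1; uniform
crossover swaps each bit with probability 0.5 when a pair crosses over; an
all-zero chromosome is repaired by activating one random bit. Axes wider
than 500 variables are encoded as adjacent windows (window-mean
intensities, `ceiling(p/500)` wide) and selected windows map back to all
member wavenumbers — full-resolution chromosomes on thousands of
correlated wavenumbers would make the search space needlessly large
relative to the information content of a 4 cm^-1^-resolution spectrum.

Runs are repeated (`n_runs`, default 100; scaled study sizes below) and
aggregated into a per-variable frequency: each run contributes the
fraction of its final population containing the variable, weighted by the
run's final fitness (`1/RMSECV` of its best chromosome, normalised). The
RMSECV trace then adds variables in decreasing-frequency order, and three
conventional marks are placed on it: *global* (trace minimum), *suggested*
(smallest size within one standard error of the minimum, the 1-SE rule),
and *better* (smallest size with RMSECV within 2% of the minimum). The
*better* model's variables are the returned selection. The frequency
weighting and the three mark definitions are package conventions — the
workflow this mirrors names the marks but does not define them.

## Classifiers

Five classifiers share one `fit_*()`/`predict()` contract
(`fit_classifier()` dispatches by name); each reports the single headline
parameter used in the evaluation tables.

* **ELM** — random sigmoid hidden layer (seeded uniform(-1, 1) input
  weights), output layer solved by pseudoinverse against one-hot targets;
  `n_hidden = "auto"` sweeps 1..n~train~ and keeps the minimum-training-error
  model, smallest size on ties.
* **RF** — bagged CART with `ceiling(sqrt(p))`-feature splits and majority
  vote, via the randomForest package behind the contract.
* **RBF** — seeded k-means centers, Gaussian activations
  `exp(-d^2/(2 s^2))` with spread defaulting to the median inter-center
  distance, pseudoinverse output layer, argmax decision.
* **PLS-DA** — one-hot targets through the PLS engine; argmax decision,
  plus the classical 0.5-threshold acceptance flag
  (`threshold_accept()`): the threshold rule alone can abstain or
  multi-assign with more than two classes, so accuracies are always
  computed from argmax while the flags remain available.
* **BPNN** — one sigmoid hidden layer, sigmoid outputs, full-batch
  gradient descent on MSE at learning rate 0.6, at most 1000 epochs,
  stopping early at MSE ≤ 1e-5; weights start seeded uniform(-0.5, 0.5)
  and inputs are min-max scaled to [-1, 1] internally (the scaling is part
  of the model and is reapplied at prediction).

ELM, RF, RBF and BPNN are exactly reproducible given (seed, data,
parameter). Training a BPNN on the full spectral range (thousands of
inputs, ~126 training samples) is refused by the task runner and the
pipeline validator; the network is only fitted on selected variables.

## Evaluation

`run_pca()` is a column-centered SVD (no autoscaling) on pre-treated
spectra, reporting per-component explained variance that sums to 100%
across all components. `accuracy()` converts a confusion matrix into
per-class recall and overall accuracy, both in percent rounded to two
decimals — the convention of the field's report tables; confusion counts
stay exact integers. `run_task()` executes one (task, variable-input,
classifier) cell with selection fitted strictly on the training rows, and
`build_report_tables()` assembles cells into the three standard tables
(rows ordered full → UVE-SPA → GA-PLS). On the reference design every
overall accuracy is a multiple of 100/66.

## The synthetic generator

No public walnut FT-MIR dataset exists, so `synthetic_spec()` +
`generate_spectra()` define the package's reference conditions and give
every selection method an exact ground truth:

* axis 700–3450 cm^-1^ at 1 cm^-1^ (2751 variables) — near the reference
  workflow's 2853-variable scale without claiming its (unstated) gridding;
* shared absorption bands at standard mid-IR assignments: broad O–H
  stretch (3350), the C–H stretch triplet (2855/2925/2960), sharp C=O
  (1740), C=C/N–H (1630), aromatic C–C (1450), and a C–O cluster
  (1050–1240);
* origin effects (amplitude multipliers ±30% and center shifts of a few
  cm^-1^) on three designated bands (1740, 1160, 2925); nested variety
  effects at roughly a third of that spread on two further bands (1450,
  1100) — encoding the nested separability seen in score plots of real
  provenance data (origins separate on PC1-scale structure, varieties
  within an origin on finer structure);
* a linear baseline draw (offset ±0.02 AU, slope ±1e-5 AU/cm^-1^) and
  i.i.d. Gaussian noise. The default noise level is calibrated so the
  class-effect signal-to-noise ratio — RMS deviation of the variety
  templates from their grand mean over the informative support, divided by
  the noise sd — equals 10.

`ground_truth()` returns the axis points within ±3 widths of any
class-affected band (optionally restricted to origin- or variety-affected
bands); `band_recovery()` scores a selection as the fraction of affected
bands containing at least one selected wavenumber. Band-level recall is
the right granularity for selectors that return 5–30 of 2751 points: a
selector cannot (and should not) cover every point of a 60-point-wide
band.

What the generator does **not** emulate: physical line shapes (Voigt, Mie
scatter), instrument response, water-vapour and CO₂ interference,
batch/day effects, or correlated (pink) noise. Passing tests therefore
demonstrate that the algorithms recover planted, band-localised class
structure under additive noise and drift — not that the published
accuracies on real walnuts are reproduced; those numbers depend on data
that was never deposited.

## Numerical choices and scaled study sizes

* PLS tolerance: component weights are exact eigen solutions; CV tie-break
  `1e-12`; SPA degenerate-projection cutoff `1e-10`; pseudoinverse
  singular-value cutoff `1e-10` relative.
* Seeds: every stochastic stage (noise draw, split, UVE noise block, GA,
  classifier initialisation) takes an explicit integer seed and restores
  the RNG state afterwards (`withr::local_seed`).
* Study sizes used by the test-suite and the acceptance script: the
  default 192 × 2751 dataset for selection recovery with GA-PLS reduced to
  10 runs; the 12-variable instance for the exhaustive-search comparison;
  a 4-class, 72-sample, high-SNR dataset for the classifier sanity bar;
  and a 4 cm^-1^ axis for the task-ordering check. These sizes keep each
  property cheap to recompute while leaving the algorithms' default
  parameters untouched.

## Limitations

* UVE's multi-class screening (per-column cutoffs, union of survivors) is
  one of several defensible conventions; a one-against-all sweep would
  give per-class retained sets at higher cost.
* The GA frequency definition (final-population counts, fitness-weighted)
  and the global/better/suggested marks are conventions; other codebases
  count only best chromosomes or use unweighted averages.
* The BPNN is a deliberately plain full-batch network; it matches the
  described training regime rather than modern practice (no momentum,
  no adaptive rates).
* Synthetic results bound what can be claimed about real spectra; see the
  generator section above.
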