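---
title: "Metabolomic prediction of malting-quality phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metablup)
```

## The problem

Malting-quality traits of spring barley — filtering speed, extract yield,
wort color, beta-glucan content, wort viscosity — are expensive to measure:
each requires micro-malting a grain sample and assaying the resulting wort.
A 1D ¹H-NMR spectrum of the same wort is cheap and captures the abundance
of many metabolites at once. Because those metabolites reflect both the
genetics of the line and the environment of the plot, a spectral
fingerprint can serve as a proxy for the quality phenotypes themselves.
This package implements the two standard prediction routes — a
similarity-kernel mixed model (MBLUP) and partial least squares regression
(PLSR) — together with the preprocessing that turns raw binned spectra
into a feature matrix, and the cross-validation designs that quantify how
well each route predicts unseen plots, unseen lines, and unseen locations.

## From spectrum to feature matrix

The raw substrate is a plots × bins intensity matrix with an explicit ppm
axis. Preprocessing runs in a fixed order; each stage preserves plot
order.

1. **Region exclusion.** Bins below 0.70 ppm and above 9.00 ppm carry no
   metabolite signal; the residual water resonance (4.7–4.9 ppm) and the
   chemical-shift reference standard (−0.2–0.2 ppm) are instrument
   artifacts. All four regions are dropped before anything else, so that
   solvent and reference intensity cannot distort the normalization
   quotients. Region bounds are treated as *closed* intervals; this makes
   retained-bin counts exactly reproducible.
2. **Probabilistic quotient normalization (PQN).** Each sample's dilution
   is estimated as the median over bins of sample/reference intensity and
   divided out. The reference is the element-wise median spectrum — the
   method's canonical choice. PQN with a fixed reference is idempotent,
   and with dilution as the only between-sample difference it recovers the
   true dilution factors up to one common constant.
3. **Interval alignment.** Small chemical-shift drifts between samples are
   corrected by a simplified interval-correlation scheme: the axis is cut
   into fixed-width intervals (default 50 bins) and each sample segment is
   shifted by the integer offset (default budget ±3 bins) that maximizes
   its Pearson correlation with the reference segment, computed on the
   non-padded overlap only — scoring on the overlap stops flat, low-signal
   intervals from drifting to the budget edge. Vacated positions are
   filled with the segment's boundary value; ties go to the smallest
   absolute shift, then to the negative one. This is deliberately simpler
   than full icoshift: no variable segment optimization, no interpolation,
   integer shifts only.
4. **Standardization.** Every retained bin is centered and scaled to mean
   0, standard deviation 1, so that low- and high-intensity features
   contribute equally. The divisor is *n* (population convention), not
   *n − 1*: under divisor *n* the mean diagonal of the similarity matrix
   below is exactly 1, which keeps the variance-component scale
   interpretable without a correction factor. Zero-variance bins cannot be
   scaled and are dropped with a warning, and recorded in the output.

## The similarity kernel and MBLUP

With `Q` the n × m standardized feature matrix, the metabolomic similarity
matrix is `M = QQ′/m` — the same construction as a VanRaden method-1
genomic relationship matrix with features in place of markers. A feature
mask restricts the kernel to a subset of bins (the divisor becomes the
masked count), which supports screened-subset kernels generically.

The mixed model is `y = 1μ + m + e` with `m ~ N(0, Mσ²ₘ)` and
`e ~ N(0, Iσ²ₑ)`. Only an intercept is fitted as a fixed effect: the
metabolome already absorbs environmental differences (location, year),
so environmental fixed effects would compete with the term of interest.
The REML fit works in the kernel's eigenbasis:

* `M = UΛU′` is computed once; rotating `y` and the intercept column makes
  the covariance diagonal, `d_i(h) = h λ_i / M̄ + (1 − h)`, where
  `h = M̄σ²ₘ/σ²_P` is the metabolomic variance fraction (identical to the
  relative variance component RVCₘ).
* At each `h`, the GLS intercept and the total variance `σ²_P` have closed
  forms, so the REML criterion is a smooth 1-D function of `h`, maximized
  by bounded search on `[10⁻⁶, 1 − 10⁻⁶]` to tolerance 10⁻⁸. Estimates at
  a bound are flagged (`at_bound`), not treated as errors.
* The reported `rvc_se` is an approximate standard error from the
  curvature of the profiled criterion at the optimum (a central second
  difference). It quantifies the sharpness of the profile, not a full
  sampling distribution, and is labeled accordingly.

Held-out plots are predicted by BLUP,
`ŷ = μ̂ + M_{v,t}(M_{t,t} + λI)⁻¹(y_t − μ̂)` with `λ = σ̂²ₑ/σ̂²ₘ` and `μ̂`
the GLS intercept on the training block. The implementation's primary
correctness oracle is the kernel/feature duality: these predictions equal
ridge regression on the columns of `Q` with penalty `mλ`, and the test
suite checks that identity to 10⁻⁸ on random instances. A Cholesky solve
is used; if the training block is singular a one-off ridge jitter of
10⁻¹⁰ is added to the diagonal before giving up. With `σ̂²ₘ = 0` all
predictions collapse to the training mean.

## PLS1

The PLSR route is the textbook NIPALS PLS1: center `Q` and `y` on training
means (no re-scaling — standardization is global and happens once, in
preprocessing; re-scaling inside the fit would leak validation
information), then per component take `w ∝ Q′y`, score `t = Qw`, loadings
`p = Q′t/t′t`, `q = y′t/t′t`, and deflate both matrices. Coefficients on
the original scale are `W(P′W)⁻¹q`. A weight vector that collapses to
zero (rank-deficient data) stops the loop early with a warning and the
attained number of components.

The inner leave-one-sample-out tuning refits the model once per held-out
training sample at the largest grid value and reads predictions for every
smaller count off the same fit (the coefficient path), reporting LOO
correlation and RMSE per count. The selected count maximizes LOO
correlation with ties broken toward fewer components (parsimony). Both a
fixed-count mode (default, 20 components) and the LOO-selected mode are
available in cross-validation, and results record which was used — with
latent dimension well below the training size the two agree, and the
fixed-count mode is substantially cheaper.

## Cross-validation designs

* **SIZE** draws a training population of fixed size uniformly without
  replacement; the validation set is the complement. Default sizes are
  {50, 100, 200, 400} with 15 replicates; replicate *r* uses the derived
  seed `(seed + 7919 r) mod (2³¹ − 1)` so any single replicate is
  reproducible in isolation. Accuracy is computed per replicate and
  summarized as mean ± sample standard deviation (divisor n − 1); the
  spread is always labeled "sd".
* **LINE** leaves out all plots of one line per fold; pooled predictions
  cover every plot exactly once, and the pooled (not fold-averaged)
  correlation is reported at plot level and after averaging within line.
* **LOC** leaves out one location per fold, one fold per location, pooled
  the same way.

Every fold asserts train/validation disjointness. REML is re-estimated
inside each training fold by default (`refit_per_fold = TRUE`); reusing
full-data variance components is also supported, because either reading is
defensible, and outputs record the mode. Predictor failures in a fold are
logged and the fold skipped rather than aborting a several-hundred-fold
run. Missing trait values are excluded per trait with a logged count.

## The synthetic generator

The generator emulates the structure of a multi-year, two-location barley
breeding trial and the physics of binned wort spectra, with every latent
quantity stored:

* **Field design.** 100 lines, each grown in one of three years, at both
  locations, with three replicate plots: 600 plots. Lines are chunked
  into trials of about 30 lines within each location × year, mirroring a
  randomized-block layout. Trial effects are off by default — they are
  not part of the prediction model — but a standard-deviation knob exists
  for robustness studies.
* **Spectra.** Each of 80 metabolites gets 1–3 Lorentzian peaks (width =
  half-width at half-maximum, 0.005–0.03 ppm) on a 2000-bin axis over
  0–11 ppm. Per-plot concentrations are line value + location effect +
  year effect + plot noise (standard deviations 1, 0.3, 0.3, 0.3 around
  bases uniform on 1–3). The observed spectrum is
  `dilution × shift(clean) + noise`, with log-normal dilution (median 1,
  log-sd 0.15; PQN's canonical use case), a whole-spectrum shift of up to
  ±2 bins, and additive bin noise (sd 0.02). Eighty metabolites make the
  retained axis signal-dense, as real wort spectra are once signal-free
  regions have been excluded.
* **Phenotypes.** Each trait is `intercept + Σ_k β_k c_ik + e_i`, linear
  in the *true concentrations*, not in the observed bins — so preprocessing
  quality genuinely limits attainable accuracy, as in the real measurement
  chain. The coefficient vector is drawn once per trait and scaled so the
  metabolomic share of phenotypic variance hits the target fraction
  (default 0.95 for all traits, the middle of the plausibly attainable
  range for wort traits); the residual variance is solved analytically
  from the realized variance of the metabolomic term, which makes
  parameter-recovery tests sharp. Intercepts and total standard deviations
  default to realistic malting-trait values (e.g. FS 4.83 ± 0.61 cm/20 min,
  BG 217 ± 115 mg/L).

The decomposition `phenotype = intercept + m + e` holds exactly by
construction, and identical configurations with identical seeds are
bit-identical.

**What passing tests do and do not show.** The generator produces
Gaussian concentrations (occasionally negative for weak metabolites),
perfectly Lorentzian peaks, a single global shift per sample, and
phenotypes exactly linear in concentrations. Real spectra have baseline
drift, peak-shape distortions, position-dependent shifts, and nonlinear
concentration–phenotype relationships; a pipeline that recovers the truth
here is necessary but not sufficient evidence that it extracts everything
from field data. Conversely, the leakage, duality and determinism
contracts that the tests verify are data-independent.

## Numerical choices

* Variance-fraction bounds `[10⁻⁶, 1 − 10⁻⁶]`; kernel eigenvalues clamped
  at zero after a PSD check (smallest eigenvalue ≥ −10⁻⁸ × largest,
  otherwise an error).
* BLUP solves via Cholesky with a single 10⁻¹⁰ jitter retry.
* Alignment tie-breaks: smallest |shift| first, then negative — encoded in
  the candidate evaluation order with strict improvement.
* LOO tuning ties break toward fewer components; grid values above
  `n − 2` are skipped with a warning.
* Tables are tab-delimited UTF-8 with `.` decimals; intensities at 17
  significant digits (lossless round trip for doubles), ppm headers at 4
  decimal places (exact for the default synthetic axis, whose spacing
  11/2000 ppm is a multiple of 10⁻⁴).

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 600-plot datasets with 2000 bins for the end-to-end checks
(estimation, SIZE/LINE/LOC cross-validation with 15 replicates), a
2000-plot dataset for the variance-fraction convergence check, and
instances of a few dozen samples for the algebraic oracles. These sizes
were chosen so the realized variance fractions are within sampling noise
of their targets while a full run stays in the minutes range on a single
CPU; the estimators themselves are dense-matrix implementations that
handle a few thousand samples comfortably.

## Known limitations

* No raw free-induction-decay processing: apodization, Fourier transform,
  phasing and baseline correction are assumed done upstream of the binned
  table.
* The alignment is an integer-shift simplification of icoshift; strongly
  nonuniform shift fields need the real thing.
* Single-kernel models only — no multi-kernel combinations, no additional
  fixed or random effects, no genomic relationship matrices.
* `rvc_se` is a profile-curvature approximation, not a full standard
  error.
* Across-year cross-validation is not offered: with lines nested almost
  entirely within years, year-wise folds confound line and year novelty.
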