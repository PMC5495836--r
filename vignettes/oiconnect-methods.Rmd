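---
title: "Methods: seed-based functional connectivity for multispectral intrinsic optical imaging"
author: "oiconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based functional connectivity for multispectral intrinsic optical imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`oiconnect` implements a complete resting-state functional-connectivity
(fc) analysis chain for multispectral intrinsic optical signal (OIS)
imaging of rodent cortex, together with a synthetic-data generator that
provides ground truth for every stage. The chain is:

1. spectral unmixing of reflectance movies into oxy-/deoxy-hemoglobin
   concentration changes (modified Beer–Lambert law, Moore–Penrose
   pseudoinverse);
2. nuisance regression against physiological traces and the global
   cortical signal (per-pixel GLM);
3. spatial Gaussian smoothing and zero-phase Butterworth band-pass
   filtering of the low-frequency hemodynamic band;
4. seed-based connectivity: seed-to-seed matrices, Fisher z, homotopic
   connectivity, normalized seed-to-pixel maps, group one-sample t-maps
   with FDR height thresholding and cluster-extent filtering, and the
   spatial-extent statistic;
5. group inference (Mann–Whitney rank-sum, Benjamini–Hochberg, Hedges' g,
   Fisher's exact mid-P);
6. machine learning on the 56 seed-pair connectivity features: RBF-kernel
   SVM classification of injury status and a Bayesian-regularized
   feed-forward network regressing fractional lesion volume;
7. ventricular-volume quantification from serial histology sections.

# The measurement model

Reflectance at wavelength $\lambda$ is converted to differential optical
density $\Delta OD = \log_{10}(I_0 / I)$ and unmixed through

$$\Delta OD(\lambda, t) = \sum_{i \in \{HbO_2, HbR\}}
  \epsilon_i(\lambda)\, C_i(t)\, D(\lambda),$$

where $\epsilon_i(\lambda)$ are molar extinction coefficients (base-10
convention, cm$^{-1}$M$^{-1}$) and $D(\lambda)$ the differential
pathlength factor (cm). With three wavelengths (525/590/630 nm) and two
chromophores the system is overdetermined and solved per pixel and frame
by the cached Moore–Penrose pseudoinverse; the residual is orthogonal to
the column space of the system matrix.

Numerical conventions that matter:

* **Log base.** Base-10 OD is paired with base-10 extinction tables. The
  binding requirement is forward/inverse consistency, enforced by a
  round-trip test (noiseless forward optics followed by unmixing is the
  identity to $10^{-8}$).
* **Extinction and pathlength tables are configuration**, not constants:
  the shipped values are approximate literature magnitudes and should be
  replaced by calibrated values for real rigs. Sensor/LED spectral
  response is reduced to per-wavelength scalar weights on the system
  rows; full spectral integration would enter the same way.
* **Reference intensity.** $I_0$ defaults to the stored illumination
  reference when present and to the per-pixel temporal mean otherwise,
  the usual differential resting-state choice. Concentration changes are
  reported in µM relative to baseline.

# Preprocessing

The GLM regresses each pixel's chromophore series on an intercept,
standardized physiological traces (heart rate, respiration signal, ECG,
respiration rate; linearly interpolated to frame times) and the global
cortical mean of the chromophore being regressed. Collinear columns are
dropped with a warning. Residuals are orthogonal to every regressor by
construction. The printed form of the regression model in the source
literature is treated as the standard least-squares GLM
$C_i(t) = X(t)\beta + \varepsilon$; the residual definition
$C_i'(t) = C_i(t) - X(t)\hat\beta$ is only consistent with least-squares
$\hat\beta$.

Spatial smoothing uses an 11×11-pixel truncated Gaussian kernel with
σ = 3 px, unit-normalized, with renormalization over the in-mask support
at borders (constants are preserved exactly).

Temporal filtering is a fourth-order Butterworth band-pass
(0.009–0.08 Hz) applied forward and backward: zero phase and a squared
(eighth-order) magnitude response, the standard reading of
"fourth-order, zero-phase". Implementation details:

* coefficients come from `signal::butter`; the forward–backward pass over
  odd-reflected padding (three settling lengths, capped at record length)
  runs in compiled code, one series per pixel;
* the temporal mean is removed first, so constants map to exactly zero;
* at a 0.009 Hz cutoff the filter settles over roughly $f_s/f_{low}$
  samples. Edge transients within the settling regions are inherent to
  finite records — the implementation reproduces the reference
  forward–backward filters to their printed precision — and spectral
  checks in the tests therefore evaluate the steady-state mid-record.
  A 0.04 Hz probe passes at unit gain (±5%) with zero lag; 1 Hz is
  attenuated below 1%.

Registration is a normalized-DLT projective homography fit to user
control points, with bilinear movie warping; synthetic cohorts are
generated in atlas space, so the pipeline applies registration only when
control points are supplied.

The stage order is fixed — unmix, regress, smooth, band-pass, seed
analysis — and each preprocessing stage can be toggled in the pipeline
configuration.

# Seed analysis and the spatial-extent statistic

Seed time courses average the 17 in-mask pixels nearest the seed center
(Euclidean distance; ties broken by polar angle then row-major order —
the published seed is "17 pixels" without a defined shape, and this rule
is deterministic and portable). Seed-to-seed and seed-to-pixel Pearson
correlations are Fisher z transformed with correlations clipped to
$\pm(1-10^{-7})$ so self-correlation pixels stay finite. Seed-to-pixel
maps are normalized to zero mean and unit SD over valid in-mask pixels.

Group maps use a two-tailed one-sample t-test of the normalized z values
against zero (df = n−1). Pixels with zero variance around a non-zero
mean are flagged invalid rather than infinite; all-zero pixels are a
genuine null (t = 0, p = 1). The height threshold is Benjamini–Hochberg
FDR at q = 0.05 over the in-mask p values (the cortex mask delimits the
test family); clusters smaller than 5% of the height-surviving count are
removed (8-connectivity by default, 4-connectivity by option), and the
spatial extent is the ratio of surviving pixels to cortex pixels. The
group summary aggregates the eight per-seed extents; group comparison
uses the rank-sum test over per-seed extents per contrast, with BH
adjustment across contrasts and Hedges' g effect sizes.

"One-sample Wilcoxon rank sum" in the source description is read as the
two-sample Mann–Whitney test: the comparison is between two animal
groups, and a one-sample test has no second group. Exact enumeration is
used for pooled sizes ≤ 12 without ties; otherwise the normal
approximation with tie correction. Fisher's exact mid-P (for the sex
confound check) halves the observed table's probability; the two-sided
value doubles the smaller tail, capped at 1.

# Machine learning

Features are the 28 upper-triangle Fisher-z seed-pair values per
contrast, concatenated over HbO$_2$ and HbR (56 features), in a canonical
order (sorted seed names) that is invariant to input seed order.

**SVM.** RBF kernel $\exp(-\|u-v\|^2/2\sigma^2)$ to match a "kernel
sigma" parameterization; box constraint C and σ selected by stratified
inner cross-validation over log2-spaced grids (C ∈ 2^{−5..15},
σ ∈ 2^{−3..9}, step 2). Features are z-scored with training-fold
statistics only. Evaluation is repeated stratified 10-fold
cross-validation (10 repeats); hyperparameters are re-selected inside
every training split, so held-out subjects never influence
standardization, selection or training. Metrics (Se, Sp, PPV, NPV, Acc)
are computed per repeat and averaged; the pooled confusion matrix is
also reported because the published headline accuracy is consistent with
a pooled confusion over runs. The published "ten 10-fold runs" and the
70/15/15 narrative are reconciled as repeated stratified 10-fold with an
inner validation split — at 13 subjects this reproduces the stated 1–2
sample test folds.

**ANN.** A two-layer network (20 tanh hidden units, linear output) maps
features to lesion size. Training is Levenberg–Marquardt minimization of
$\beta E_D + \alpha E_W$ with MacKay evidence updates
($\gamma = K - \alpha\,\mathrm{tr} H^{-1}$, $\alpha = \gamma/2E_W$,
$\beta = (n-\gamma)/2E_D$), the standard reading of "Bayesian
regularization"; the published description names the algorithm but not
its internals. Implementation choices: the Gauss–Newton curvature is
handled through the eigendecomposition of the n×n matrix $JJ^\top$, so
cost scales with subjects rather than the ~1,200 weights; the prior
precision starts at zero and evidence updates begin after a 10-epoch
warm-up, because updating $\alpha$ while the weights are still near
their small random initialization grossly overestimates the prior
precision and collapses the network to a constant. Stopping: training
MSE ≤ 10⁻⁵ on min-max-scaled targets or 1,000 epochs. Evaluation pools
held-out predictions over a rotation of test folds and reports Pearson r
and RMSEP on the pooled set.

# The synthetic-data generator

The generator is the package's acceptance surface: it emulates the study
conditions — a 13-animal cohort (8 control, 5 injured), 7 minutes of
5 Hz multispectral acquisition, a (14.7 mm)² field of view — with known
ground truth at every level.

* **Network fluctuations.** Each seed anchors a cortical network patch
  with a Gaussian spatial profile (σ = 5% of the image dimension, patch
  FWHM ≈ 1.7 mm at full scale — resting-state nodes are focal, and
  pixels far from every seed carry noise only). Per-network latent
  signals are zero-mean Gaussian processes strictly band-limited to
  0.009–0.08 Hz (spectral shaping of white noise: out-of-band FFT
  coefficients are zeroed), and the realized latents are whitened before
  coloring with the symmetric square root of the target coupling matrix,
  so the empirical latent correlation matrix equals the target exactly;
  seed-region correlations then converge to the coupling matrix up to
  pixel-noise attenuation (mean |error| < 0.05 at 2,100 frames).
  An early design assigned every cortex pixel to its nearest network;
  that made normalized maps essentially deterministic across subjects
  and saturated group t-maps at any coupling, so it was replaced by the
  focal patches before the acceptance runs were finalized.
* **HbR** is −0.5 × the HbO₂ network signal plus independent in-band
  noise (ratio configurable), reproducing the observation that both
  contrasts carry the same networks with anti-correlated polarity.
* **Injury** multiplies interhemispheric couplings by
  $1 - \kappa \cdot \text{lesion fraction}$ (clipped to [0, 1]);
  lesion fractions are drawn from [0.6, 1] for injured subjects and are
  0 for controls. Between-subject variability adds symmetric jitter
  (SD 0.1) to the coupling matrix, eigenvalue-clipped back to a valid
  correlation matrix.
* **Noise levels** (chosen once as field-realistic): in-band pixel noise
  at 50% of the 1 µM fluctuation amplitude, HbR noise 30%, sensor noise
  5 counts on a 3,000-count reference (12-bit range). The amplitude
  scale itself is a free parameter — resting-state ΔHb amplitudes are
  not standardized — and defaults to 1 µM.
* **Physiology**: slow drifts around rodent-typical baselines
  (450 bpm heart rate, 60 breaths/min) and quasi-periodic respiration
  and (frame-rate-aliased) cardiac traces.
* **Reproducibility**: every subject derives its own RNG stream from the
  cohort seed; cohort generation is bit-reproducible.
* **Histology**: coronal sections through an ellipsoidal brain phantom
  with a concentric bright ventricle whose analytic volume is a known
  fraction of the brain volume; defaults 228 px/mm, 50 µm thickness,
  300 µm spacing. Volumes follow the literal slice-summation rule
  (area × thickness) by default, with Cavalieri (area × spacing)
  estimation as an option — fractional volumes cancel the convention,
  and phantom-recovery checks use the spacing convention because the
  phantom is a continuous solid sampled every 300 µm.

What the generator does **not** emulate: photon-transport optics,
vascular compartments and Mayer waves, awake-motion artifacts,
registration error between subjects, spatially heterogeneous
illumination, and inter-areal lag structure. Passing tests on this
generator therefore certify the pipeline's correctness and its
sensitivity to interhemispheric decoupling, not performance on real
acquisitions. One visible consequence: synthetic group maps are far more
consistent across subjects than real ones, so absolute spatial extents
run higher than published values; the group *difference* (injured below
control, rank-sum significant for both contrasts) is the reproduced
quantity.

# Problem sizes and determinism

Simulations in the tests and the acceptance script run at 48×48 pixels
with the field of view preserved (spatial extent is a
resolution-normalized fraction; the statistical content is set by the
13 subjects and 2,100 frames, which are kept at the study values), a
size chosen to keep a 20-replicate Monte-Carlo of the full cohort
analysis at desk scale. The default configuration is 128×128, and the
image size is an ordinary configuration option. The replicate study
works at the chromophore level — the optics forward/inverse round trip
is separately certified as the identity, and its sensor noise
contributes negligibly after band-passing — while the acceptance script
runs the full optics path once. All randomness flows from explicit
integer seeds through a deterministic stream-splitting hash, and rerun
outputs are byte-identical.

# Known limitations

* The bilinear warp loses accuracy at mask borders; border pixels are
  flagged invalid rather than extrapolated.
* Group t-maps require ≥ 3 valid subjects per pixel.
* The evidence-framework ANN assumes a single isotropic weight prior;
  grouped priors (per layer) are a possible refinement.
* Absolute spatial-extent magnitudes on synthetic cohorts exceed
  published in-vivo values for the reason discussed above; comparisons
  should always be within-generator, between groups.
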