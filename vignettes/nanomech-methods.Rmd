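---
title: "Methods: nanomechanical fingerprinting of fibrotic tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanomechanical fingerprinting of fibrotic tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomech)
```

## Scope and data flow

`nanomech` implements an in-silico version of an AFM-based workflow for
staging pulmonary fibrosis: force-volume maps are fitted curve by curve to
yield per-pixel Young's moduli; pooled per-specimen moduli are decomposed
into a soft (LEP) and a stiff (HEP) component; picrosirius-red image pairs
yield collagen I/III area fractions; a statistics layer mirrors the analysis
protocol; and a specimen-grouped cross-validated kernel classifier fuses
optical and nanomechanical features. Every stage is driven by a synthetic
generator with known ground truth, so each estimator can be tested against
the parameters that produced its input.

## The indentation model and its estimator

A rigid cone of half-angle $\theta$ indenting an incompressible elastic
half-space obeys

$$F = \frac{2}{\pi}\,\tan\theta\,\frac{E}{1-\nu^2}\,\delta^2,$$

with indentation $\delta = (z - z_0) - (d - d_0)$ and force $F = k(d - d_0)$.
Defaults follow the acquisition protocol: $\theta = 20^\circ$, $\nu = 0.5$,
spring constant 0.03 N/m, force cap 1.8 nN, 16 x 16 grids over 20 x 20 um
(pixel 1.25 um; at 1 kPa the cap is reached at $\delta \approx 2.41$ um).

**Estimation is linearized**: given the contact point, $E$ is the slope of
an origin-constrained least-squares regression of $F$ on $\delta^2$, divided
by the geometric prefactor. This is convex, deterministic, and checkable
against a brute-force grid search over $(z_0, E)$ on the full forward model
(the test suite does exactly that). A nonlinear refinement adds nothing on
the forward model itself and is deliberately omitted.

**Contact-point detection** scans candidate split indices coarse-to-fine.
Each candidate is scored by the total squared residual of a linear baseline
on the left plus the cone model on the right (with the baseline extrapolated
under contact, since the optical-lever tilt persists there). A curve is
declared non-contact when no split improves the all-baseline residual by at
least 5% or when the fitted stiffness is non-positive. This piecewise-
residual scan was chosen over derivative thresholding because it remains
stable at the low signal-to-noise of soft tissue and has an obvious oracle.
On noiseless curves the detected split is exact; the simulator therefore
places the true contact point exactly on a ramp sample (the discretization
is the simulator's free choice), which is what makes the machine-precision
round-trip contract attainable at all.

**Quality control** per pixel rejects non-contact curves, non-converged
fits, non-positive moduli, fewer than 10 post-contact samples, and fits with
$R^2 < 0.80$ on the $F$-vs-$\delta^2$ regression. The $R^2$ and sample-count
thresholds are not given by the protocol; they are conservative defaults and
are configurable. Maps with more than half their pixels rejected are kept
but flagged unusable. Only the approach segment is analyzed; retraction (and
hence adhesion) is out of scope.

## Elasticity spectra and the LEP/HEP fingerprint

Moduli are pooled per specimen (post-QC) and summarized on $\log_{10} E$:
a Freedman-Diaconis histogram and a Gaussian KDE with Silverman bandwidth,
both density-normalized over the log domain. Mixtures are fitted on
$\log_{10} E$ because moduli are positive and right-skewed, matching the
log-axis convention of elasticity spectra.

One- and two-component Gaussian mixtures are fitted by EM with a
deterministic quantile start plus fixed-seed random restarts (a local RNG
stream, so the global seed is untouched), an sd floor of $10^{-3}$ against
spike collapse, and selection by BIC ($p = 3k - 1$ parameters). "Peaks" are
reported as component modes back-transformed to kPa ($10^{\mu}$), which is
unambiguous and directly comparable with the generator's mode
parameterization. Components are labeled by mean: lower = LEP, higher = HEP,
so labels are invariant to EM output order. If EM fails to converge after
all restarts the single-component fit is returned with a fallback flag.

Heterogeneity metrics are computed on the linear kPa scale: CV% =
100 sd/mean (sample sd) and IQR = Q3 - Q1 (type-7 quantiles). ROUT removal
before metric computation is available and the order is recorded; the
pipeline default applies ROUT first. One non-obvious property drove a
design choice: for a lognormal mixture the CV is maximized by a *rare* stiff
component, so a control arm with even 5% HEP mass would have a higher CV
than chronic fibrosis. The control stage default is therefore unimodal
(HEP weight 0), which also matches control spectra exhibiting a single soft
peak; heterogeneity then increases with disease stage by construction.

## The synthetic world

The generator's defaults state the acquisition protocol: 21 control mice
(5/10/6 at days 3/14/21), 23 bleomycin-treated (5/11/7), 6 per pirfenidone
arm; 15 maps per specimen (up to 3840 curves). Stage-graded mixture
parameters rise monotonically (HEP weight 0 / 0.12 / 0.25 / 0.40 and HEP
mode 20 / 22 / 28 / 35 kPa for control / d3 / d14 / d21); the preventive
pirfenidone arm reverts to near-control at day 14 (weight 0.06), the
therapeutic arm removes most HEP mass at day 21 (weight 0.12). The kPa
positions of the peaks (LEP ~2 kPa, HEP ~20-35 kPa) are configuration, not
literature claims: soft parenchyma sits in the low-kPa range and fibrillar
collagen an order of magnitude stiffer.

Per-pixel moduli are drawn from the stage mixture with *spatial clustering*:
a Gaussian-smoothed random field is thresholded at the HEP-weight quantile,
so stiff pixels form contiguous patches like fibrotic collagen, and
segmentation-based augmentation is meaningful. The threshold is by count, so
each map's realized HEP fraction equals its target up to rounding.

Pre-contact baselines are modeled as linear tilt plus white noise (defaults:
0.5 nm deflection noise, 1 nm/um tilt, 20 nm contact-point jitter) - the
simplest model that exercises contact-point detection. The generator does
not emulate viscoelasticity, adhesion, tip blunting, or cantilever
hydrodynamics; a green test therefore establishes correctness of the
estimators under the stated contact model, not robustness to physics outside
it.

Polarized picrosirius-red pairs are built from a ground-truth class map
(background / tissue / collagen I / collagen III). Tissue is a central mass
against a border-connected background sea (as for a section on a slide) -
without this, morphological hole filling absorbs interior background and
inflates tissue area. Collagen fractions are exact pixel counts of tissue
area, so the quantifier's recovery error is attributable to the quantifier.
Brightfield colors: white background, pale-yellow tissue, red collagen;
crossed-polarizer colors: dark field, red-orange birefringent collagen I,
green collagen III, with 8-bit Gaussian pixel noise (sd 3).

## Collagen quantification

Tissue is segmented from the brightfield image by background thresholding
(HSV value >= 0.85 and saturation <= 0.15) followed by hole filling.
Birefringent pixels (HSV value >= 10% of full scale) inside the tissue mask
are classified by hue: collagen I in [0, 45) U [315, 360) degrees, collagen
III in [75, 165). The numeric bands are not stated by the red-orange/green
convention itself, so they are configurable defaults echoed into the output;
whether yellow-green hues belong to collagen III is genuinely undecidable
from the convention and is left to the band configuration. Fractions are
reported relative to tissue area (not frame area), masks are disjoint by
construction, and everything is pixelwise, hence invariant to rotations.
SHG stacks are averaged pixelwise; SNR is mean(signal region) /
sd(background region), infinite-SNR (constant) stacks are flagged.

## Statistics layer

* **Median centering** divides by the sample median (fold-of-median), since
  moduli are positive and downstream comparisons are fold-scale; a
  subtraction variant is available by flag and the choice is recorded in the
  output attributes. Control-mean normalization and z-scoring carry their
  reference parameters as attributes, so all normalizations invert exactly.
* **ROUT (Q = 1%)** is applied in its constant-model restriction (the protocol
  applies it to measurement distributions, not regressions): center = median,
  robust scale RSDR = 68.27th percentile of absolute residuals with an
  n/(n-K) small-sample correction (K = 1), residual t-ratios with n-K
  degrees of freedom, and a Benjamini-Hochberg sweep at rate Q over their
  two-sided p-values. With n < 10 nothing is removed and a warning is
  attached. Location and scale are equivariant, so the flag set is invariant
  under affine transforms.
* **Group tests** follow the protocol: Shapiro-Wilk decides parametric vs
  non-parametric; two groups get a t-test or Mann-Whitney U, three or more
  get ANOVA + Bonferroni pairwise t-tests or Kruskal-Wallis + Dunn's post
  hoc (rank-sum z with tie correction, unadjusted by default - the protocol
  does not fix an adjustment variant, so
  unadjusted is the documented default with Bonferroni available). Stars:
  * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001.
* **Exact Spearman**: rho = 1 - 6 sum(d^2)/(n(n^2-1)); for n <= 10 without
  ties the two-sided p doubles the one-sided exact tail of the permutation
  distribution of sum(d^2) (lower tail for positive rho), capped at 1 -
  the convention of common commercial statistics software. Ties
  fall back to midrank rho with the t approximation, with a method note.
  Enumeration is chunked by the first element so n = 10 stays in memory.
* **Delta-delta-Ct**: fold = 2^-ddCt.

## Classifier

Segmentation-based augmentation tiles images and splits maps into
non-overlapping segments that inherit their specimen id; cross-validation
partitions *specimens*, so no specimen's segments ever span a train/test
boundary (asserted structurally in the CV loop, and the reported accuracies
are test-fold accuracies by construction).

Image features are a 4x4-cell, 9-bin HOG (per-cell L2 normalization;
constant tiles yield a zero HOG rather than an error) concatenated with a
59-bin uniform 8-neighbor LBP histogram. SIFT/SURF were considered and
excluded from defaults: they are keypoint-based and yield variable-length
outputs, which the fusion design (fixed-length concatenation) cannot use.
AFM features are a 16-bin log10 histogram over a global 0.1-1000 kPa range
plus deciles, median, CV%, and IQR - order-invariant and fixed-length.

Kernels: linear, RBF, sigmoid, and a "ReLU" kernel interpreted as the
order-1 arc-cosine kernel $k(x,y) = \frac{1}{\pi}\lVert x\rVert \lVert
y\rVert(\sin\vartheta + (\pi-\vartheta)\cos\vartheta)$ - the standard
positive-definite kernel whose feature map is a ReLU layer; the name alone
does not pin down a kernel, so this documented choice is the one PSD
interpretation in common use. No SVM solver is available in the dependency
set, so the SVM is trained in its least-squares formulation (LS-SVM): the
hinge inequalities become equalities and training is a single symmetric
linear solve - deterministic, convex, and exact, at the cost of losing
sparsity of the support set (irrelevant at these problem sizes).
Hyperparameters (C; gamma and coef0 where the kernel uses them; grids
C in {0.01, ..., 100}, gamma log-spaced 1e-3..10, coef0 in {-1, 0, 1}) are
selected per outer fold by an inner grouped 3-fold grid search; ties go to
the first grid entry so selection is reproducible. Accuracy is reported as
the min-max range over the k = 20 folds plus the mean. An optional
PCA-style reduction stage exists but is disabled by default, since the
protocol leaves the dimensionality-reduction step open; the defaults simply
skip it.

**Fusion** pairs segments within a specimen by index and concatenates
block-standardized feature vectors, with each block scaled by
$1/\sqrt{\text{dim}}$ so both modalities contribute equal total variance -
otherwise a 203-dimensional optical block mechanically swamps a
28-dimensional AFM block. Specimens present in one modality only, and
unpaired trailing segments, are dropped and counted. External validation
calls held-out specimens by majority vote over their segments; exact ties
are flagged indeterminate, never silently broken.

The default classification cohort (16 control, 17 treated) draws a latent
severity per specimen that both modalities observe through independent unit
noise, with additional map-to-map jitter of the HEP weight (logit sd 0.9;
regions of one lung differ). The latent effect size (2.5 sd) and jitter were
fixed once so that the two single modalities perform comparably in the
70-90% band with fusion above both - the qualitative regime such mechano-optical
comparisons report - and were not revisited afterwards. Measured
over 12 seeds during design: optical ~76%, AFM ~78%, fused ~84% mean
test-fold accuracy.

## Numerical and degenerate-input choices

* Moduli are handled in kPa throughout (1 N/m = 1 nN/nm makes the unit
  algebra exact); the curve container serializes with `%.17g` so text
  round-trips are bit-exact.
* Empty pools after QC raise an explicit empty-spectrum error; single-pixel
  spectra degenerate to one occupied histogram bin.
* Zero-median samples refuse median centering; degenerate references refuse
  z-scoring.
* A zero RSDR in ROUT (majority of identical values) treats any nonzero
  residual as an outlier.
* Constant tiles give zero HOG blocks; zero-norm vectors give 0 under the
  arc-cosine kernel.
* All stochastic stages take explicit integer seeds; cohort, image, and
  stack generation are bit-reproducible from them.

## Known limitations

The synthetic world omits adhesion, viscoelastic creep, substrate effects,
tip-shape convolution beyond the ideal cone, stain variability across
scanners, and fiber-orientation structure; conclusions about estimator
robustness to those effects cannot be drawn from these tests. Absolute
accuracies measured on real murine specimens are not reproducible without
those specimens, so classifier tests check structural properties (no leakage,
chance on permuted labels, fusion ordering) rather than absolute accuracy
values. Human-cohort heterogeneity (e.g., specimens without a clear second
peak) is represented only through the unimodal/bimodal selection path.
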