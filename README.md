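# nanomech

Nanomechanical fingerprinting of fibrotic lung tissue from AFM force
spectroscopy, with matched optical (picrosirius-red) collagen quantification
and a fused "mechano-optical" classifier.

## Who this is for

Groups studying pulmonary fibrosis (e.g., the intratracheal-bleomycin mouse
model) who characterize tissue with atomic force microscopy force-volume
maps and picrosirius-red histology, and want a tested, reproducible pipeline
from raw force-displacement curves to per-specimen elasticity fingerprints,
collagen area fractions, the study's statistics, and a specimen-grouped
cross-validated classifier. Because raw specimens are rarely shareable, the
package ships a synthetic-data module that emulates every input with known
ground truth, so the whole pipeline is testable end to end.

## The model at the core

A force curve records cantilever deflection `d` against piezo displacement
`z`. After the contact point `(z0, d0)`, a rigid conical tip indenting an
elastic half-space follows the Sneddon relation

    F = (2/pi) * tan(theta) * E / (1 - nu^2) * delta^2,
    delta = (z - z0) - (d - d0),  F = k * (d - d0)

with `theta` the cone half-angle (20 degrees), `nu` the Poisson ratio (0.5),
`k` the spring constant, and `E` the Young's modulus. `E` is estimated by a
linear fit of `F` on `delta^2` up to a 1.8 nN force cap, per pixel of a
16 x 16 map over 20 x 20 um (256 curves per map, pixel 1.25 um; 10-15 maps,
up to 3840 curves per specimen).

Pooled per-specimen moduli form an elasticity spectrum on log10(E). A 1- vs
2-component Gaussian mixture (EM, BIC selection) decomposes it into the
lower elasticity peak (LEP, soft cell-dominated tissue) and higher
elasticity peak (HEP, collagen patches) - the nanomechanical fingerprint,
together with heterogeneity metrics (CV%, IQR). The stats layer provides
median centering, ROUT outlier removal (Q = 1%), group tests with
significance stars, exact small-n Spearman correlation, and delta-delta-Ct
fold changes. The classifier extracts HOG+LBP image features and
log-modulus histogram features, trains kernel SVMs (linear, RBF, sigmoid,
arc-cosine "ReLU"; least-squares SVM formulation) under specimen-grouped
20-fold cross-validation, and fuses both modalities.

## Worked example

```r
library(nanomech)

# one synthetic force curve at 1 kPa with realistic noise, then fit it
curve <- simulate_force_curve(true_E_kpa = 1, seed = 1)
fit <- fit_sneddon(curve)
print(fit)
#> <sneddon_fit> E = 1.002 kPa (theta = 20 deg, nu = 0.5), R^2 = 0.9992, n = 220
#>   contact at z0 = 1987 nm, max indentation 2403 nm

# a fibrotic specimen: 15 maps, pooled spectrum, LEP/HEP decomposition
tissue <- stage_mechanics("chronic_d21")
set.seed(2)
maps <- lapply(1:15, function(i) simulate_force_map(tissue, curves = FALSE))
nmf <- decompose_peaks(pool_specimen(maps))
print(nmf)
#> <nmf_summary> 2 component(s), n = 3840
#>   LEP 1.99 kPa (weight 0.60); HEP 34.1 kPa (weight 0.40)
#>   median 3.45 kPa, CV 159.5%, IQR 26.7 kPa

# collagen quantification from a polarized picrosirius-red pair
img <- simulate_polarized_image(col1_fraction = 0.12, col3_fraction = 0.03,
                                seed = 5)
quantify_collagen_polarized(img)
#> <collagen_quantification> tissue 13926 px; collagen I 0.120, III 0.031 (of tissue)

# the printed six-pair Spearman example
spearman_exact(1:6, c(2, 1, 3, 4, 6, 5))
#> <correlation_result> rho = 0.8857, two-sided p = 0.03333 (n = 6, exact-permutation)
```

The fitted modulus recovers the generating 1 kPa (noiseless curves invert to
machine precision); the fingerprint recovers the generating mixture (LEP
2 kPa, HEP 35 kPa at mode, weight 0.40); the collagen fractions recover the
generating 12%/3%; and the six-pair rank configuration reproduces rho =
0.886, p = 0.0333.

An end-to-end run (simulate -> fit -> spectra -> collagen -> stats ->
classify -> report) is one call:

```r
manifest <- run_pipeline(default_pipeline_config(out_dir = "run1", seed = 1))
```

or from a shell, `exec/nanomech all --out run1 --seed 1`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch using only the installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It evaluates the exact two-sided permutation p-value of the Spearman
statistic for the fixed six-pair rank configuration (two disjoint adjacent
transpositions), enumerating all 720 permutations.
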