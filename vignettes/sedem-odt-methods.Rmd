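---
title: "SeDeM-ODT scoring of granules: model, conventions and numerical policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SeDeM-ODT scoring of granules: model, conventions and numerical policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedemodt)
```

## The scoring model

SeDeM (12 parameters) and SeDeM-ODT (15 parameters) are rule-based expert
systems for judging whether a powder or granulate can be compressed directly
into tablets. Every judgement is a fixed linear rescaling of a bench
measurement; there is no fitting anywhere in the core method, which is what
makes it attractive for quality-by-design work — the whole analysis is
auditable by hand.

Each basic parameter has an admissible experimental range and an applied
factor mapping its value V onto a radius r on a 0–10 scale
(`parameter_registry()` is the authoritative table). Radii are grouped into
six incidence factors; group means localise deficiencies, and three summary
indices judge the material overall: IP (fraction of radii ≥ 5), IPP (mean
radius) and IGCB = IPP × f. The reliability factor f is the area ratio of a
regular n-gon to its circumscribed circle — the maximum fraction of the
diagram a profile with n axes can shade — conventionally 0.971 for n = 15
and 0.952 for n = 12. A material with IGCB (or classic IGC) ≥ 5 is declared
suitable for compression.

### Numerical conventions

* **Disintegration factor constant.** The applied factor for both
  disintegration times is `(3 − V) × 3.33` with the constant exactly as
  conventionally printed, not 10/3. Consequently the best attainable radius
  for DCD and DSD is 9.99, and the package asserts 9.99 — not 10 — at the
  favourable limit.
* **Clamping.** Raw radii are preserved unclamped; indices, incidence
  factors and diagrams use radii clamped onto [0, 10]. This is required to
  reproduce the published index tables: granulated material routinely
  exceeds the disintegration limits, producing negative raw radii that must
  contribute exactly 0 to IPP. The IP threshold is applied to *raw* radii
  (a negative radius can never count, so the choice is observationally
  irrelevant, but it is fixed for determinism).
* **Reliability factors.** The printed lookup values take precedence over
  the polygon formula `n·sin(2π/n)/(2π)`: at n = 12 the formula gives 0.955
  but the published analyses use 0.952; at n = 15 formula (0.97101) and
  lookup (0.971) agree to 3 dp. Other parameter counts fall back to the
  formula.
* **Rounding.** Internal computation is full precision; reported values are
  rounded half away from zero (`round_half_up()`) at the reporting boundary
  only. Fixture comparisons use ±0.01 for radii/indices and ±0.001 kg/mm²
  for tablet strengths.
* **π.** Tensile strength uses the true π. The source text states 3.143;
  both choices reproduce every printed strength cell to three decimals, so
  the exact constant is preferred.

### The homogeneity index

The granulometric homogeneity index is implemented as

\[ I_\theta = \frac{F_m}{100 + \sum_n \Delta d_{mn} F_n} \]

with F_m the percent mass in the majority sieve fraction, F_n the percent in
each other fraction and Δd_mn the absolute difference of mean fraction
diameters in µm. Mean diameters are aperture midpoints (425–600 µm → 512.5);
the pan (< 50 µm) is assigned 25 µm. The fraction retained on the coarsest
sieve has no observed upper bound; we assign it the aperture itself
(850 µm). This choice only matters when substantial mass sits on the top
sieve, which a properly milled granulate avoids; any fixed convention ≥ the
aperture changes Iθ by well under the reporting tolerance for the
distributions handled here. Ties for the majority fraction are broken toward
the coarser fraction and logged. Percentages are validated to total
100 ± 0.5 and renormalised exactly, making the index invariant to
proportional rescaling.

### Diagram geometry

The radar diagram starts at 12 o'clock and proceeds clockwise in registry
order; the published figures do not fix an orientation, so one is declared
for reproducible output (SVG bytes are deterministic for a fixed profile).
Negative raw radii plot at the origin. The shaded-area ratio (shoelace area
over the r = 10 circle) of a constant profile equals
`(c/10)² · n·sin(2π/n)/(2π)` — at full score it reproduces the reliability
factor, which is the geometric origin of that constant.

## Fixture reconstruction and its documented exceptions

The package ships the printed tables of a 13-run atenolol wet-granulation
study as plain-text fixtures and `reproduce_paper()` rebuilds every derived
cell. Two trials (9 and 10) cannot be reconstructed exactly: their printed
Disgregability incidence and ODT indices are consistent only with the
effervescence radius having been counted while the positive
disintegration-with-disk radius was dropped. The package does **not**
imitate that slip — it recomputes faithfully and asserts those six cells as
an exact expected-mismatch list, so any drift in either the fixtures or the
arithmetic surfaces immediately. Two further printed values (atenolol IGCB
quoted as 4.71 in prose vs 3.47 in the index table; powder-blend
Disgregability 0.713 vs computed 0.710) are resolved toward the tables,
whose values recompute correctly within tolerance.

## The synthetic study

`simulate_study()` generates the raw data the analysis expects, not the
physics that produced it. Each latent response is linear in the coded
factor levels, `base + b_binder·x₁ + b_time·x₂ + ε`, with Gaussian noise
truncated to physical bounds, then dressed into a full measurement record
(replicate lists with within-trial noise, a sieve distribution around a
majority fraction, densities converted to volumes, a first-order dissolution
curve inverted into sampled concentrations). Effect signs encode the stated
process behaviour — binder concentration and granulation time increase
densification, cohesion and disintegration times and decrease flow time,
fines and Q15 — and magnitudes are set so simulated ODT profile indices span
roughly the observed 4.4–5.5 band. Baselines are centre-point values a
formulator would call ordinary for a lactose/MCC granulation (bulk density
0.63 g/mL, cohesion 128 N, Q15 58 %); they were chosen once, from the
fixture ranges, and are not tuned against test outcomes.

Per-trial sub-seeds are derived as `(seed mod 1e5)·20011 + trial index`, so
extending the design never perturbs existing trials, and a fixed master
seed reproduces the study byte for byte. With `noise_scale = 0` the study
is exactly linear, and least squares recovers the configured slopes to
machine precision — the structural check that the generator and the
pipeline agree about units and aggregation.

What a green recovery test establishes: that the pipeline preserves
monotone factor–response structure through every stage (parameters → radii
→ indices → tablet metrics → rank correlations). What it does not: the
generator has no granule-growth mechanics, no factor interactions, no
heteroscedasticity, and its center replicates differ only by noise, so it
cannot validate the expert system's thresholds against real materials —
only the arithmetic built on top of them.

## Known limitations

* The 12-parameter classic subset and the reliability lookup are the only
  supported variants; other published SeDeM subsets are out of scope.
* Wetting time has no derived quantity — it is stored and summarised only.
* The dissolution withdrawal correction assumes equal-volume replacement
  with fresh medium after every sample (togglable); no release-model
  fitting (Weibull, f2) is provided.
* Drug content is peak-area arithmetic; chromatography itself is out of
  scope.
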