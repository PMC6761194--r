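---
title: "Probabilistic query-based synapse detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic query-based synapse detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synquery)
```

This vignette documents the models behind `synquery`, the parameters that
matter, the numerical choices made where the design was genuinely open, and
what the synthetic-data tests do and do not establish about real array
tomography data.

## Imaging model and calibration

A dataset is a set of aligned grayscale stacks, one per immunofluorescent
channel, indexed `[row, col, slice]` with 1-based R indexing. The physical
calibration is an `at_geometry`: 0.1 µm lateral pixel pitch and 70 nm section
thickness by default, so one voxel is 7 × 10⁻⁴ µm³ and a 100 × 100 × 30
stack is 210 µm³. All physical coordinates are voxel-center micrometres;
densities are counts per µm³ of neuropil. Registration and alignment are
assumed done upstream; the readers only validate congruent shapes and
preserve integer intensities bit-exactly.

## Foreground probability

Background noise in each channel is modeled as a Gaussian estimated from the
data itself. Two estimation choices were open:

* **Robust vs plain moments.** Puncta contaminate plain moments (1% bright
  puncta roughly double a plain SD estimate), so the default is the median
  and the scaled MAD; plain moments remain available via
  `estimate_background(method = "moments")` for fidelity experiments.
* **Scope.** Section-to-section staining variability is intrinsic to array
  tomography, so one model is fitted per slice by default
  (`scope = "slice"`); a whole-volume scope is selectable.

The foreground probability is the upper-tail rule `p(x) = pnorm((I - mu)/sd)`
— monotone in intensity, exactly in [0, 1], with the mean over true
background voxels equal to ½ by construction. The degenerate `sd = 0` case
(constant slice) maps intensities strictly above the mean to 1, everything
else to 0.

## Query evaluation

A query declares presynaptic, postsynaptic and optionally astrocytic marker
sets, a minimum lateral footprint per marker (default 2 × 2 px) and a slice
span requirement (query-level, with per-marker overrides such as VGluT2's
two-section minimum). Evaluation composes three operators:

1. **Punctum evidence.** On each slice, the *product* of foreground
   probabilities over the footprint window anchored at the voxel; across
   slices, the maximum over all fully-contained windows of `min_slices`
   consecutive sections of the product of windowed values. The product form
   (rather than a window mean) is deliberate: background probabilities are
   uniform on [0, 1], and the mean of four uniforms exceeds 0.9 with
   probability ~10⁻³ per voxel — enough to scatter single-voxel false
   detections around every real synapse, since the adjacent-marker term is
   near 1 over a large neighborhood there. Requiring every pixel of the
   footprint to be foreground suppresses that tail by two orders of
   magnitude while true puncta (per-pixel p ≈ 0.998) are unaffected.
2. **Colocalization within a subclass.** Each punctum map is laterally
   max-dilated by `r_coloc` (default 1 px, tolerating partial pixel sharing)
   and the maps are multiplied. Dilation applies uniformly — including to a
   single-marker subclass — because that is what keeps the algebra
   anti-monotone (adding a marker multiplies by one more factor ≤ 1) and
   invariant to marker order; both properties are asserted in the tests.
3. **Adjacency across subclasses.** `q = pre · maxN(post) · maxN(astro)`,
   where `maxN` is the maximum over ±2 px laterally and ±1 section axially.
   Lateral and axial reaches are separate parameters because voxels are
   anisotropic (0.1 µm vs 0.07 µm).

Window and neighborhood edges are clipped with zero padding, so probabilities
attenuate naturally at volume borders; a punctum whose slice window would
leave the stack scores the clipped (small) value. `min_slices` larger than
the stack yields an all-zero map with a warning.

## Detection, size classes, densities

Probability maps are thresholded at 0.9 (the empirically optimal value for
these maps) and grouped into 26-connected 3-D components — blob-like puncta
across anisotropic voxels justify the most permissive connectivity, and the
choice is configurable. Components are ordered deterministically by centroid
(slice, row, col). One subtlety is worth stating: raising the threshold
always shrinks the supra-threshold voxel *set*, and every higher-threshold
component nests inside a lower-threshold one, but the *count* of components
can rise when two merged synapses separate; the tests assert the nesting
property, which is the true guarantee.

Size classes use query subtraction, not per-detection matching: with counts
N₁ ≥ N₂ ≥ N₃ at span requirements 1, 2, 3, small = N₁−N₂, medium = N₂−N₃,
large = N₃, and the three classes sum to the total exactly by construction.
A violated ordering would indicate an anti-monotonicity bug and raises a
hard error.

The density denominator is the neuropil volume: total imaged volume minus
DAPI-segmented nuclei. The nuclei recipe is threshold at t = 0.6 on DAPI
foreground probability, then per-slice opening (disc radius 2 px), closing
(same radius), hole filling, a one-pixel lateral erosion, and removal of 3-D
components under 200 voxels. Two steps deserve justification. The opening
comes first because a 0.6 cut on a probability map keeps ~40% of pure
background voxels by construction; closing such scatter directly would weld
it into large components, whereas opening annihilates it (survival
probability 0.4¹³ per disc). The final erosion compensates the outward halo
of thresholding a PSF-blurred bright edge at a permissive cut (analytically
≈ 1.9 px at 8σ contrast); its one-pixel radius, on top of the boundary
shaving of the opening, was calibrated against simulated ellipsoids of known
volume, where it brings a ~+1.6 percentage-point bias at a 10% nuclear
fraction down to under 0.2 points. The erosion replicates image-frame
borders so nuclei clipped by the field of view are not eroded from the
frame side. Saturated DAPI (probability 1 everywhere) leaves zero neuropil
and warns; downstream densities refuse a nonpositive denominator.

## Cohort statistics

WT/KO comparisons operate on per-sample density tables keyed by (layer,
query, size class): group means and SDs, percent difference
`100·(KO−WT)/WT`, and a two-tailed t-test. The pooled-variance (Student)
variant is the default — the conventional reading for n ≈ 3–4 per group —
with Welch selectable. No multiple-testing correction is applied by default,
mirroring the practice of reporting raw p-values per cell alongside
per-sample data; zero-variance degeneracies resolve to p = 1 (equal means)
or p = 0 (unequal). Excitation/inhibition ratios are computed on densities
(equivalent to counts when volumes match, and robust when they do not).
Astrocytic-association fractions are tripartite/bipartite density ratios,
clipped at 1 with a warning since detection noise can push them slightly
over.

## Van Steensel colocalization

Shift correlation is computed on raw intensities (not probability maps)
inside a region of interest (default 40 × 26 µm, centered and clipped)
applied through the stack: channel B is shifted along image columns, Pearson
r is pooled over all in-bounds pixels of all slices, and shifted-out pixels
are excluded from both channels. Shifts run along one lateral axis only —
synapses in these volumes are randomly oriented, so the profile is
direction-independent in expectation, and the axis is configurable. The
significance of the zero-shift correlation is its two-sided empirical rank
among large-shift correlations (default: |shift| ≥ 1 µm, well beyond synapse
scale) with add-one correction, so a value more extreme than every null
yields p = 1/(n_null + 1). The defaults (±2 µm maximum shift, 1 px step)
are declared choices; the original tool's exact dialect is not documented.

## The synthetic scene generator

`generate_volume()` draws a scene and renders it:

* **Synapses.** Per-type counts are Poisson with mean density × neuropil
  volume. Default densities are calibrated to reported wild-type cortex:
  glutamatergic 1.63/µm³ (VGluT1 1.24, VGluT2 0.265, dual 0.12) plus
  GABAergic 0.311/µm³ — 1.94 synapses/µm³ of embedded tissue in total with
  an excitation/inhibition ratio of 5.2 and VGluT2 at ~21% of glutamatergic
  synapses. Placement is uniform in the neuropil (never inside nuclei), with
  a 3 px lateral margin and slice range chosen so the punctum's span fits
  the stack.
* **Sizes.** A synapse-level span is drawn log-normal (meanlog 0.5, sdlog
  0.6 → median ≈ 1.6 sections, ~24% spanning ≥ 3, a few percent ≥ 6) and
  rounded to whole sections with a floor of one; all synaptic markers of a
  synapse share it, which makes the size-class truth well defined. Size
  classes are drawn per class from the truncated law so knockout
  `size_multipliers` scale exactly the targeted class.
* **Geometry of a synapse.** Presynaptic markers are co-centered; the
  postsynaptic punctum is displaced 0.15–0.25 µm in a random lateral
  direction (the cleft); an associated GS punctum sits 0.1–0.25 µm from the
  cleft midpoint, perpendicular to the pre/post axis, the way a peripheral
  astrocytic process apposes a cleft. GS puncta are smaller than synaptic
  ones (0.08–0.18 µm) since they label thin processes.
* **Rendering.** A punctum of radius r (its visible half-width) is a 2-D
  Gaussian with σ = r/2, constant across its span — sections are physical
  slices, so there is no axial blur and spans stay crisp. Channels are
  blurred laterally by the PSF (σ 0.1 µm) and Gaussian background noise
  (mean 100, SD 15) is added. The configured peak amplitude (background + 8
  SD) is the *observed post-blur* peak, so small puncta are not silently
  dimmed by the convolution.
* **Confounders.** The VGluT2 channel carries 2/µm³ of single-slice speckle
  (the reason for that marker's two-section rule); true VGluT2 synapses
  always label ≥ 2 sections. Sparse unassociated GS puncta (0.05/µm³) keep
  the chance-adjacency floor of tripartite queries at a few percent. DAPI
  nuclei are ellipsoids whose global scale is bisected to hit the target
  volume fraction (10%) to within ~0.1 point.

The generator does **not** emulate section compression or registration
error, flat-field/illumination gradients, antibody elution residue,
nonspecific staining structure beyond the two confounders above, blood
vessels, or a rigorous optical PSF. Passing tests therefore demonstrate the
pipeline's correctness and calibration under the stated generative model,
not performance on raw microscope output.

## Problem sizes and experiment design

The validation experiments use desk-scale volumes (the study-scale datasets
are ~135,000 µm³ per animal; simulations here use 200–2,900 µm³, a two- to
three-order scale-down), sized by pre-hoc power analysis:

* Detection accuracy: 100 × 100 × 30 at 0.24 synapses/µm³ (~50 synapses),
  matching radius 0.3 µm.
* Density additivity (glutamatergic = VGluT1 + VGluT2 − dual): 140 × 140 ×
  40 at 0.25 glutamatergic/µm³. At the full 1.6/µm³, closely spaced
  synapses merge query-dependently at light-level resolution and the
  identity degrades to ~4–8%; the identity is a consistency check and is
  evaluated where synapses are resolvable.
* Astrocytic association (0.72): 240 × 240 × 50 at 0.2/µm³, n ≈ 350
  bipartite detections, so binomial noise (±2.4 points) plus the ~1 point
  chance-adjacency inflation sit well inside the ±5 point band. The
  association-zero floor uses the same machinery and stays below 5%.
* Knockout recovery (−15% large inhibitory): 3 WT vs 4 KO samples of
  160 × 160 × 40 with GABAergic density enriched to 1.0/µm³, giving ≈ 150
  large inhibitory synapses per sample; the sign of the difference is then
  recovered in ≫ 90% of cohorts (z ≈ 2.5 per cohort). Enrichment stands in
  for the ~200,000 synapses per animal that power the real study.
* Excitation/inhibition ratio: densities at the wild-type ratio (5.2) but
  scaled to a resolvable 0.18 synapses/µm³ total, pooled over 12 samples of
  240 × 240 × 50 (~600 inhibitory detections). At full wild-type density the
  excitatory population loses ~14% of counts to same-type merging while the
  sparse inhibitory population loses ~3%, biasing the measured ratio
  downward by ~7%; the scaled scene keeps both populations resolvable.
* Adjacency signature: 2,500 marker pairs at 0.35–0.45 µm separation in a
  300 × 300 × 12 stack put the shift-correlation peak at 0.3–0.4 µm; random
  pair orientation projects onto the shift axis with density peaking at the
  full separation, and the blob autocorrelation (σ ≈ 1.2 px) pulls the
  empirical peak inward by roughly one pixel, which the chosen separation
  range accounts for.

## Known limitations

* The detector's operators are simple closed forms chosen to satisfy the
  probabilistic semantics exactly; the original research implementation has
  additional machinery and may behave differently in dense neuropil, where
  merging is the dominant error mode here.
* Chance adjacency puts a floor under tripartite association fractions that
  grows with marker density; association estimates are interpretable when
  the GS punctum density × capture volume is small, and the van Steensel
  profile is the appropriate control otherwise.
* Per-marker slice spans in detection tables are measured from thresholded
  punctum maps within the detection footprint and are a diagnostic, not the
  basis of size binning (which uses query subtraction throughout).
* The t-test's small-sample applicability is inherited from the study
  design, not re-derived; per-sample values are retained in the output for
  any alternative analysis.
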