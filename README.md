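# synquery

Probabilistic, query-based synapse detection and quantification for
multiplexed immunofluorescent array tomography (AT).

## The problem

Array tomography images ribbons of ultrathin (70 nm) resin sections,
immunolabeled in multiple rounds and reconstructed into aligned multi-channel
3-D volumes at ~0.1 µm lateral pixel pitch. Individual cortical synapses
appear as small clusters of fluorescent puncta: a presynaptic punctum
(synapsin, plus VGluT1/VGluT2 for glutamatergic or GAD for GABAergic
synapses) juxtaposed to a postsynaptic punctum (PSD-95 or gephyrin), with an
optional adjacent glutamine synthetase (GS) punctum marking an astrocytic
process — a *tripartite* synapse. Counting synapses by molecular type, size
and astrocytic association across cortical layers, and comparing wild-type
and knockout cohorts, requires a detector that needs no training data and
whose definition of each synapse type is explicit.

## The method

`synquery` implements a declarative, probabilistic detector:

1. **Foreground probability.** Each channel's background noise is modeled as
   a Gaussian whose location/scale are robustly estimated (median and scaled
   MAD, per section by default). A voxel's foreground probability is the
   upper-tail rule *p(x) = Φ((I(x) − µ)/σ)*.
2. **Queries.** A synapse type is a query: presynaptic, postsynaptic and
   optional astrocytic marker sets, each with a minimum lateral footprint
   (2 × 2 px = 0.2 µm × 0.2 µm) and slice span. Punctum evidence is the
   product of foreground probabilities over the footprint window on each
   slice, combined across the required number of consecutive sections.
   Markers of one subclass are colocalized (dilate by `r_coloc`, multiply);
   subclasses are combined by adjacency (`pre · maxN(post) · maxN(astro)`
   over a ±2 px × ±1 slice neighborhood). The result is a per-voxel synapse
   probability map.
3. **Detections and densities.** Maps are thresholded at 0.9 and 26-connected
   components become detections. Densities are reported per µm³ of
   *neuropil* — the imaged volume minus DAPI-segmented nuclei (probability
   threshold 0.6 plus morphological cleanup). Size classes come from query
   subtraction: running the query at span requirements 1, 2, 3 gives counts
   N₁ ≥ N₂ ≥ N₃ with small = N₁−N₂, medium = N₂−N₃, large = N₃.
4. **Cohorts and colocalization.** WT/KO comparisons use per-sample density
   tables, percent differences and two-tailed pooled-variance t-tests. The
   van Steensel shift-correlation test (Pearson r vs lateral shift, ranked
   against large-shift nulls) provides an independent check of marker
   adjacency.
5. **Simulator.** A calibrated scene generator renders all eight channels
   (including VGluT2 single-slice speckle and DAPI nuclei) with ground truth,
   so every stage is testable without the original ~40 GB dataset.

## Worked example

```r
library(synquery)

cfg <- simulation_config(
  densities = c("VGluT1" = 0.15, "VGluT2" = 0.03, "VGluT1/2" = 0.015,
                "GABAergic" = 0.045))
sim <- generate_volume(cfg, seed = 1)
sim
#> <at_simulation> seed 1: 46 synapses, 8 channels, neuropil 189 um^3

pc <- lapply(sim$channels[c("synapsin", "PSD95", "GAD", "gephyrin", "DAPI")],
             foreground_probability)
np <- nuclei_mask(pc$DAPI)
np
#> <neuropil_mask> total 210 um^3, nuclei 20.94 um^3 (10.0%), neuropil 189.1 um^3

qs <- default_queries()
size_binned_densities(pc, qs[["Glutamatergic"]], np$neuropil_um3)
#>           query size_class  n    density
#> 1 Glutamatergic      small 20 0.10578680
#> 2 Glutamatergic     medium 16 0.08462944
#> 3 Glutamatergic      large  6 0.03173604
#> 4 Glutamatergic        all 42 0.22215229

det <- detect_synapses(pc, qs[["Glutamatergic"]])
match_ground_truth(det, sim$truth[sim$truth$type != "GABAergic", ])[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 1
```

The density table reads: 42 glutamatergic synapses in 189 µm³ of neuropil
(0.22 per µm³), of which 20 have at least one marker on a single section
(small), 16 are medium and 6 span three or more sections (large); the three
size classes sum to the total by construction. Against the simulator's
ground truth, every detection matches a true synapse within 0.3 µm.

A thin command-line wrapper is installed with the package
(`inst/scripts/synquery`): `synquery simulate`, `synquery detect --config
cfg.yaml`, `synquery coloc`. See `inst/extdata/example_config.yaml` for the
full ten-query catalog (glutamatergic overall / VGluT1 / VGluT2 / dual and
GABAergic, each with and without the GS astrocyte marker).

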