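# Example synquery pipeline configuration: the standard ten-query catalog
# for cortical synapse typing on an eight-channel array tomography volume.
geometry:
  pixel_size_xy: 0.1      # um per pixel
  slice_thickness: 0.07   # um per section

channels:
  synapsin: synapsin.tif
  PSD95: psd95.tif
  VGluT1: vglut1.tif
  VGluT2: vglut2.tif
  GAD: gad.tif
  gephyrin: gephyrin.tif
  GS: gs.tif
  DAPI: dapi.tif

thresholds:
  probability: 0.9   # synapse probability map threshold
  dapi: 0.6          # nuclei probability threshold

params:
  min_xy_px: 2       # minimum lateral punctum footprint (px per side)
  r_coloc: 1         # lateral colocalization tolerance (px)
  adjacency_xy: 2    # adjacency search half-width (px)
  adjacency_z: 1     # adjacency search half-depth (slices)

# The VGluT2 channel requires a two-or-more-slice span wherever it appears.
queries:
  - name: Glutamatergic
    presynaptic: [synapsin]
    postsynaptic: [PSD95]
  - name: Glutamatergic VGluT1
    presynaptic: [synapsin, VGluT1]
    postsynaptic: [PSD95]
  - name: Glutamatergic VGluT2
    presynaptic: [synapsin, VGluT2]
    postsynaptic: [PSD95]
    min_slices: {VGluT2: 2}
  - name: Glutamatergic VGluT1/VGluT2
    presynaptic: [synapsin, VGluT1, VGluT2]
    postsynaptic: [PSD95]
    min_slices: {VGluT2: 2}
  - name: GABAergic
    presynaptic: [synapsin, GAD]
    postsynaptic: [gephyrin]
  - name: Glutamatergic adjacent to astrocyte
    presynaptic: [synapsin]
    postsynaptic: [PSD95]
    astrocyte: GS
  - name: Glutamatergic VGluT1 adjacent to astrocyte
    presynaptic: [synapsin, VGluT1]
    postsynaptic: [PSD95]
    astrocyte: GS
  - name: Glutamatergic VGluT2 adjacent to astrocyte
    presynaptic: [synapsin, VGluT2]
    postsynaptic: [PSD95]
    astrocyte: GS
    min_slices: {VGluT2: 2}
  - name: Glutamatergic VGluT1/VGluT2 adjacent to astrocyte
    presynaptic: [synapsin, VGluT1, VGluT2]
    postsynaptic: [PSD95]
    astrocyte: GS
    min_slices: {VGluT2: 2}
  - name: GABAergic adjacent to astrocyte
    presynaptic: [synapsin, GAD]
    postsynaptic: [gephyrin]
    astrocyte: GS

stats:
  var_equal: true    # pooled-variance (Student) t-test
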