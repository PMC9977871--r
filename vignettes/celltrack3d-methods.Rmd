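---
title: "celltrack3d: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celltrack3d: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their units
and defaults, what the synthetic phantoms establish and what they do not,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The problem

Time-lapse 3D confocal stacks of membrane-tagged plant epidermis show
space-filling cells separated by thin bright walls. Quantifying
morphogenesis — in particular lobe formation in pavement cells — needs
three things per time point: a *closed* labelling of every cell (an open
boundary makes downstream wall measurements meaningless), the
sub-cellular landmarks (junctions where three cell walls meet, and the
anticlinal wall segments that run between neighbouring junctions), and a
persistent identity for every cell across the series.

## Membrane probability: rotation-equivariant group convolutions

Tissue orientation in the microscope is arbitrary, so a membrane
classifier should not prefer any axis. The package implements
convolutions that are exactly equivariant under the 24 orientation
preserving symmetries of the voxel cube — every signed axis permutation
matrix with determinant +1 (6 faces down × 4 in-plane rotations). Acting
on voxel indices these rotations are exact (no interpolation), which is
why the layer contract can be tested to numerical precision rather than
approximately:

* a *lift* layer convolves the intensity volume with all 24 rotated
  copies of each base kernel, producing feature maps with an orientation
  axis of length 24;
* *group convolution* layers mix orientation slots through the group's
  composition table (output slot g sums input slot h convolved with the
  kernel indexed by g⁻¹∘h, rotated by g);
* rotating the input rotates every feature map spatially and permutes
  the orientation axis — nothing else; a final per-voxel maximum over
  the 24 slots (orientation pooling) makes the output invariant up to
  the spatial rotation itself.

Rotated kernel copies are derived from a single stored base kernel and
never parameterized independently.

The assembled U-Net (defaults: depth 3, 4 group channels of 24 slots
each, 3³ kernels, ReLU, spatial-only max pooling and nearest-neighbour
upsampling, concatenation skips, logistic head) processes stacks in
16-slice z-windows with 4-slice overlap, averaging the overlaps; stacks
with fewer than 16 slices are reflection-padded. The architecture
defaults are declared, not derived: they form the smallest U-Net that
exercises every layer type at desk scale.

**Training.** There is no automatic-differentiation stack in this
runtime, so the optional smoke-scale training fits only the final
logistic readout (IRLS on voxel-wise binary cross-entropy against
phantom membrane masks; one epoch = one IRLS pass, at most 5) on top of
the fixed random equivariant features. This is enough to demonstrate the
training hook end to end — the suite verifies the trained head separates
membrane from interior — but it is not a substitute for training the
convolutions; anyone needing a fully trained network should export the
architecture to a deep-learning framework. The **fallback probability**
(Gaussian-smoothed intensity, robustly normalized) is the default front
end and is what the acceptance runs use.

One numerical choice in the fallback deserves a note: normalization is by
the 99th percentile (clipped) rather than the maximum, because wall
*junctions* — where several walls meet — are systematically ~2× brighter
than plane wall faces; max-normalization would push ordinary faces below
the `q < 0.5` interior cut used for seeding and bridge neighbouring cell
interiors.

## Segmentation: seeds, watershed, dense CRF

**Seeds.** The probability map is thresholded at 0.5 into interior
voxels (intensity below the "Threshold" hyperparameter is first
suppressed as membrane evidence — typical values 0–0.1 on a normalized
image). Seeds are regional maxima of the Euclidean distance transform of
the interior, after two stabilizations that the plain
"local-maxima-with-minimum-separation" recipe turned out to need:

* the volume border counts as boundary (otherwise cells clipped by the
  field of view carry spurious deep maxima at the corners), and the EDT
  accepts an anisotropic voxel spacing so plate-shaped cells in
  anisotropic stacks keep a single deepest point;
* maxima with prominence below `seed_prominence` (2 voxels) are merged
  into their parent by h-maxima morphological reconstruction — the
  discrete EDT has plateau duplicates along every cell's medial axis,
  and Gaussian-smoothing the EDT instead leaks across thin membranes and
  deletes the maxima of small cells (both failure modes were observed on
  phantoms before settling on h-maxima).

Surviving maxima are then kept at least "Minimum Distance" voxels apart,
deepest first. Minimum Distance is set by the smallest cell size one is
willing to detect (default 10 voxels).

**Watershed.** Priority flooding of the probability map from the seeds,
6-connectivity, deterministic FIFO tie-break. Every voxel receives a
label: the partition is closed by construction.

**Dense CRF refinement.** The watershed boundary is closed but noisy;
the refinement minimizes (by five fixed mean-field rounds, no convergence
test) a Gibbs energy with unary cost `−log P(x_i)` — `P = 1 − q_i` for
the voxel's watershed label, a small floor `ε = 10⁻⁶` for every other
label — and a Potts pairwise term over the two Gaussian kernels with
defaults σ_α = 3, σ_β = 5, σ_γ = 10 and γ₁ = γ₂ = 1. Per-label weights
w⁽ᵐ⁾ default to 1 (no published values exist). Messages are computed by
separable Gaussian filtering; the q-axis of the appearance kernel is
discretized into 16 bins, and collapsed entirely whenever σ_β covers the
q range (with σ_β = 5 and q ∈ [0,1] the q factor lies in [0.98, 1], so
the appearance kernel is effectively spatial; a `q_scale = 255` switch
rescales q to an 8-bit-like range where σ_β is meaningful — the binned
path is exercised in the tests that way).

Two interpretation decisions, both recorded because the printed
formulation is ambiguous or degenerate:

* **Position units.** Voxel coordinates enter the kernels in *voxels*,
  not normalized to [0,1]: σ_γ is the "Minimum Distance" hyperparameter,
  a voxel quantity, and with [0,1] coordinates all three Gaussians are
  effectively constant, collapsing the pairwise term into a global
  label-mass penalty that erases small cells.
* **Message normalization.** Messages are normalized per voxel by the
  kernel's response to an all-ones field, as dense-CRF solvers do; the
  unnormalized σ = 10 Gaussian sums exceed the unary scale by four
  orders of magnitude and have the same label-erasing effect.

With γ₁ = γ₂ = 0 the refinement reproduces the watershed voxel-exactly
(ties in the final argmax break in favour of the watershed label — with
`q = 1` exactly, all labels share the ε floor). The label set never
grows: the CRF refines, it does not invent cells.

**Small-region filter.** Labels below "Label Threshold" voxels (e.g.
protrusions and inter-cellular spaces) merge into the neighbour with the
longest shared interface; remaining labels are renumbered densely.

## Adjacency graph, walls, junctions

The cell graph's edge weight w_ij is the number of simultaneous
6-connected dilation rounds until cells i and j meet ("become one
connected component" is operationalized as "the dilated masks
intersect", which is equivalent under equal simultaneous dilation).
Distance-1 pairs are neighbours; the default cap `r_max = 3` keeps the
graph sparse because the degree feature uses only distance-1 edges and
the weighted degree averages over stored edges.

Wall points of a neighbour pair are the voxels whose neighbourhood —
*self plus face neighbours* — intersects both cells; junction points of
a pair (i, j) are the voxels incident to i, j and a common neighbour k.
Face-neighbour incidence (rather than the full 26-neighbourhood) is a
deliberate consistency choice: at a generic tessellation vertex four
cells meet, the two diagonal cells touch only at a voxel corner, and
26-incidence would assign such pairs a "wall" although their dilation
distance is 2. With face incidence the two notions coincide exactly —
a pair has wall points if and only if it is a distance-1 pair — and the
suite verifies wall and junction voxel sets against an independent
brute-force per-voxel scan, exactly, on every phantom tested (the
26-neighbourhood variant remains available via `connectivity = 26`).

Wall point sets are cut at junction voxels into maximal runs, each
ordered into a polyline by nearest-neighbour chaining from the point
farthest from the centroid; runs shorter than 3 voxels are discarded as
noise. A limitation worth knowing: a 3D wall run is a 2-voxel-thick
*patch*, not a curve, so the chain necessarily takes occasional return
jumps; the tests assert the bulk of the traversal is local (median step
≤ √3) and strict step bounds only on curve-like sets. Downstream curve
metrics (Fréchet, end-point displacement) are orientation-minimized, so
chain direction is immaterial.

## Tracking

Per cell: size S (voxels), degree (distance-1 neighbours) and weighted
degree (mean stored-edge weight; 0 for isolated cells). The similarity
of detections in consecutive frames normalizes by the earlier frame's
features — asymmetric exactly as defined; zero denominators substitute 1
so isolated cells stay comparable. Linking is greedy: repeatedly take
the globally most similar unmatched pair while below the threshold
(one-to-one, O(M²) similarity evaluations per frame pair, instrumented
and asserted in the tests). Track ids seed from frame 0, unmatched
detections open new tracks, unmatched predecessors terminate; divisions
are not modelled (parent id always 0).

The package default threshold is 0.3, the midpoint of the documented
0.1–0.5 working range. The phantom acceptance runs use 0.5, the
permissive end, for a measured reason: under the phantom's
nearest-neighbour label transport at `max_shift = 2`, a ±1 change in a
cell's degree produces a similarity jump of ~0.2–0.45 even for the true
correspondence; at 0.5 all tested sequences track perfectly, at 0.3 four
of five do. Real pavement-cell data deform more smoothly than the
discrete warp, so 0.3 remains the sensible general default.

## Evaluation metrics

* Boundary precision/recall/F at range R (default 5): TP/FN counted from
  the ground-truth side, FP from the prediction side, via exact
  Euclidean distance transforms. Boundary voxels are those with a
  6-neighbour of a different label.
* Cell-count mean and population standard deviation per sequence.
* Junction precision/recall/F1 at a voxel tolerance (default 5), greedy
  one-to-one assignment by ascending distance.
* End-point displacement error: the published formula averages each
  curve's *own* end-to-end chord — it is nonzero for identical curves —
  so the default `corrected` mode measures the actual endpoint
  displacements (minimized over the two endpoint pairings) and the
  formula as printed stays available as `as_printed`.
* Discrete Fréchet distance by dynamic programming over monotone
  couplings, verified against exhaustive coupling enumeration for all
  curve lengths ≤ 6; reported as the minimum over the two orientations
  of the non-reference curve.
* Length difference (voxels) and percentage difference (normalized by
  the ground-truth length).
* AOGM/TRA: the weighted edit cost (node splits/additions/deletions,
  edge additions/deletions) of turning the result tracking graph into
  the reference, with node correspondence by majority voxel overlap;
  `TRA = 1 − min(AOGM, AOGM₀)/AOGM₀` where AOGM₀ builds the reference
  from scratch. The edit weights (5, 10, 1, 1, 1.5, 1) follow the cell
  tracking challenge convention — no values are published for this
  pipeline — and are configurable.

## The phantom generator: what a green test establishes

Phantoms are anisotropic Voronoi tessellations (sites rejection-sampled
to at least half the expected cell diameter apart; z-axis scaled by 2 to
mimic coarser optical sectioning) rendered either as bright membranes on
inter-cell faces or as bright eroded nuclei cores, Gaussian-blurred
(σ = 1), with additive Gaussian noise, clipped to [0, 1]. Time-lapse
sequences transport the labels by a smooth bounded displacement (global
translation plus a low-frequency sinusoidal warp, nearest-neighbour
transport so the ground truth stays exact), tapered to zero at the
volume border so every cell persists — matching the source imagery,
where each sequence has a fixed set of cells. Two reproducibility
details follow from the stated invariants: the additive noise field is
drawn once per sequence (so `max_shift = 0` gives bit-identical frames),
and identical specs give bit-identical phantoms.

What phantoms do *not* emulate: the confocal point-spread function and
depth-dependent attenuation, lobed (non-convex) cell shapes, cell
division, intensity variation between walls, and real anisotropy in the
probability signal. A green suite therefore establishes internal
correctness — layer equivariance, watershed/CRF contracts, exact oracle
equivalence of graphs and features, metric definitions — and recovery on
idealized geometry; it does not certify accuracy numbers on real
confocal data.

Scale: tests run on 24–32-slice phantoms (desk scale) rather than
512×512 stacks, to fit a single-CPU budget; every algorithm is
resolution-independent.

## Known limitations

* The equivariant U-Net trains only its readout in-package (see above).
* Wall segments are voxel patches ordered into polylines, not sub-voxel
  curves; no sub-voxel localization is attempted.
* The adjacency graph counts dilation rounds in voxel space; weights are
  not corrected for anisotropy.
* No division/merge handling in tracking; no global multi-frame
  trajectory optimization.
* The TIFF layer supports the uncompressed grayscale baseline subset
  (8/16-bit unsigned, 32-bit float, both endiannesses on read) — enough
  for round-tripping this pipeline's volumes, not a general TIFF reader.
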