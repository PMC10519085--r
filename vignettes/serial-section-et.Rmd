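---
title: "Reconstructing continuous volumes from serial-section electron tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing continuous volumes from serial-section electron tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sset)
```

Electron tomography (ET) reconstructs a single ~100 nm thick section at
sub-nanometre voxel size, but a synapse spans about a cubic micrometre —
several sections. Serial-section ET therefore images consecutive thick
sections, reconstructs each one tomographically, and must then solve four
problems that `sset` addresses in order: finding the same region of
interest (ROI) on every section at the microscope, aligning the per-section
volumes to each other, restoring the slices that were physically lost
between them, and segmenting/measuring the target ultrastructure. This
vignette explains the models behind each stage, the tunable parameters, and
what the synthetic phantoms do and do not establish.

## ROI propagation across sections

Sections are collected side by side on a slotted grid, so the stage
coordinates of one structure in consecutive sections are related by a
low-order 2D map. With the position written homogeneously as $(x, y, 1)^T$,
the predicted rough position in section $n+1$ is $A \cdot
\mathrm{Loc}^{exact}_n$, where the family of $A$ escalates with the
available evidence:

* one confirmed consecutive pair — pure translation ($t_x, t_y$);
* two pairs — similarity ($s R(\Theta)$ plus translation);
* three or more non-collinear pairs — full affine (six coefficients),
  always fit by least squares.

Every operator confirmation triggers a full refit (no damping — the
problems are tiny, typically under a dozen sections). The point of the
scheme is not precision but search-area reduction: a prediction lands well
inside the 10.83 µm low-magnification (5K) field of view, so the operator
only fine-positions at 20K. On simulated layouts with 0.1 µm placement
jitter the predictions are good to a few tenths of a micrometre.

## Coarse alignment

ET reconstructions of adjacent sections share little directly usable
appearance: their mutual surfaces are the most damaged parts of each
volume, and the tomographic contrast differs strongly from directly
captured TEM images. The coarse stage therefore never matches two ET
volumes against each other. It matches along a bridge of images that do
share appearance: the ET z-mean projection against the same section's 20K
TEM image, 20K against 5K (after rescaling by the magnification ratio), and
5K of one section against 5K of the next. Chaining the five affines yields
the inter-section transform.

Each link uses the same machinery: percentile contrast stretch to $[0,1]$
(1st/99th percentiles), difference-of-Gaussian keypoints with subpixel
refinement and edge rejection, orientation-normalised 4×4×8
gradient-histogram descriptors, Lowe-ratio plus mutual-best matching, and
RANSAC (3-point hypotheses, 3 px inlier threshold at the working scale,
2000 iterations, fixed seed) with a least-squares refit on the consensus
set. For same-modality links an optional Gauss–Newton polish on the
intensities follows; it estimates a photometric gain/bias alongside the six
affine coefficients because separately contrast-stretched images otherwise
bias the geometric optimum, and it ignores a 12% border margin where
warped images carry fill. On noiseless phantoms the full
match–RANSAC–polish chain recovers known affines to well under 0.1 px RMS;
RANSAC alone is typically near 0.1–0.3 px.

## Fine (elastic) alignment

Cutting and irradiation deform sections nonlinearly, so one affine per pair
is not enough. The elastic stage block-matches the two volumes' z-mean
images on a regular grid (defaults: 64 px blocks, 64 px stride, ±16 px
search, 3 candidates per block retained) and keeps, per block, the top
normalised-cross-correlation peaks rather than only the best one — repeated
biological textures produce multiple near-equal peaks, and committing early
is exactly the failure mode to avoid. Zero-variance blocks are flagged
texture-less and excluded entirely.

One candidate per block is then selected by minimising the
truncated-quadratic neighbour-consistency energy

$$\min_p \sum_{(i,j) \in E} \min\left( \lVert p_j - p_i - d_{ij} \rVert_2^2,\; C \right)$$

over the 4-connected block grid, where $p_i$ is the selected matched
centroid, $d_{ij}$ the preset offset between neighbouring block centres
(mutually consistent matches cost zero), and $C$ caps the penalty so one
genuine outlier cannot bend its neighbourhood ($C = 64$ px², i.e. 8 px,
by default). Two solvers share this objective:

* an exact transfer-matrix dynamic program over grid columns, used
  automatically whenever the joint per-column state space is small
  (≤ 256 states) — this makes the solver provably optimal on the small
  instances where optimality can be checked by enumeration;
* synchronous min-sum belief propagation with message normalisation,
  best-so-far decoding (which makes the reported objective trajectory
  monotone) and a final coordinate-descent polish, for production-size
  grids.

Ties break by match score, then candidate index; with $C = 0$ every
pairwise term truncates to zero and the tie-break alone decides. The
energy as implemented has no data term, matching its definition; an
optional unary weight on match scores exists but defaults to zero.

The selected matches become control points of a thin-plate spline solved
in closed form; with zero regularisation the spline interpolates the
control displacements exactly and reproduces any affine with zero bending
energy. The resulting dense field backward-warps every z-slice of the
moving volume (one 2D field per pair — no per-slice deformation, since
the physical deformation is a property of the section, not of depth).

## Missing-information estimation

Material is lost between volumes to knife damage, the missing wedge and
beam-induced shrinkage. Three measurements are reconciled:

1. **Per-volume total**: $(L^{cut} - L^{ET})/R_{ET}$ — cutting thickness
   minus reconstructed thickness, in slices. With the study's constants
   (100 nm cut, 135 slices at 0.664 nm) this is 15.60 slices. Negative
   values (volume thicker than its cut) are reported with a warning and
   clipped to zero for the solver.
2. **Per-pair total** from image content, under the stated assumption that
   content change is uniform along z. A sensitivity map $s$ — slices per
   unit gray change, the reciprocal per-pixel mean $|I(z{+}1)-I(z)|$,
   capped at 10× its median and smoothed with a 25×25, σ 13 Gaussian —
   converts the gray distance between the two volumes' mean images
   (outlier-filtered with a 10×10, σ 3 Gaussian) into a slice count.
   Under the uniform assumption that count spans the distance between the
   two volume centres, so half of each volume's thickness is subtracted to
   leave the gap alone.
3. **Reconciliation**: the per-volume and per-pair totals become equality
   constraints on the per-volume top/bottom losses $(L_i^{top},
   L_i^{bot})$; the remaining single degree of freedom is resolved by
   minimising $\sum (L_i^{top}-L_i^{bot})^2 + \sum
   (L_{i+1}^{top}-L_i^{bot})^2$, which has a closed-form solution after
   expressing every variable as an affine function of $L_1^{top}$.
   Nonnegativity is enforced by projection, integers by
   round-half-away-from-zero with a repair pass that keeps each rounded
   per-volume sum within one slice of its constraint.

Numerical choices that matter here, all exposed as arguments: the mean
images and sensitivity maps are computed at ≈256² regardless of input
size; the outermost 20% of slices are excluded from the sensitivity
estimate (the missing wedge makes them unrepresentative of the interior
gradient); the flat-pixel guard is 0.01 gray of an 8-bit scale (the cap,
not the guard, handles genuinely flat regions); pixels invalidated by
warping are excluded from the difference map and replaced by the in-mask
median in the sensitivity map before smoothing. Finally, although the
product map's spatial *maximum* is the literal estimator, under the
uniform-change assumption the map is constant, so the package aggregates
with the *median* by default: on warped phantom pairs the median matches
the known deletion count to a fraction of a slice while the maximum locks
onto the worst residual-misregistration spike. `agg = "max"` restores the
literal form.

## Missing-information generation

The missing slices are synthesised by frame interpolation between the
facing boundary slices of consecutive volumes. The reference interpolator
is a deterministic flow blend: bidirectional dense optical flow by
pyramidal, iteratively refined Lucas–Kanade (Gaussian-aggregated normal
equations, ~32 px coarsest level), then

$$\hat I_t = (1-t)\,\mathrm{warp}(I_0,\ t F_{0\to1}) + t\,\mathrm{warp}(I_1,\ (1-t) F_{1\to0}).$$

Identical boundary frames reproduce themselves exactly at every $t$ (the
flow is exactly zero), and a pure texture shift of 8 px yields the
half-shift at the midpoint to sub-pixel accuracy. Interior slices receive
$t = k/(M+1)$.

For adapting a small learned interpolator to a new volume pair with almost
no data, the package implements distillation fine-tuning: the middle slice
of each volume acts as a fixed boundary frame, every real slice between
the two middles is a training sample at
$t = i / (l_1/2 + M + l_2/2 - 1)$, and the student minimises

$$L = (1-\alpha) L^s_{rec} + \alpha T^2 L_{dis}, \qquad
L_{dis} = \tfrac12 \lVert N^s_{flow}/T - N^t_{flow}/T \rVert_1 +
\tfrac12 \lVert N^s_{arb}/T - N^t_{arb}/T \rVert_1$$

with $T = 2$, $\alpha = 0.2$ by default; norms are elementwise means so
the loss is independent of image size. The shipped teacher is the
flow-blend reference (deterministic, CPU-only); an externally trained
interpolation network can be plugged in through the same
`interpolator_model` interface. The shipped student is deliberately tiny —
global bidirectional flow parameters plus a gain/bias on the blended frame,
trained by finite-difference gradient descent with backtracking (which
makes the loss trajectory monotone and bit-reproducible for a fixed seed).
It exercises the full distillation mechanics at desk scale; it is not a
capacity match for a convolutional student.

## Segmentation and morphometrics

Membrane segmentation consumes a per-voxel affinity map (three channels,
one per axis; low affinity marks boundaries). The channel-weighted mean is
thresholded at θ (defaults: equal weights, θ = 0.5 — the upstream model's
calibration should inform both), the sub-threshold voxels form the
contour, connected components of its complement (6-connected) become
watershed basins, and contour voxels are assigned to adjacent basins by
breadth-first flooding in distance order with ties to the smaller label —
fully deterministic and voxel-conserving. Anchored selection, merging and
a replayable paint/erase edit log stand in for interactive proofreading
with full provenance.

The affinity predictor itself is pluggable and is *not* trained here: the
reference implementation scores dark voxels by inverted intensity, which
suffices for phantoms and keeps the post-processing pipeline — the part
that is reusable — fully testable offline.

Vesicles are detected only inside the presynaptic ROI (class imbalance is
the motivation: vesicles are a tiny fraction of the full volume),
thresholded, connected-component labelled (26-connected) and size-filtered
against an admissible equivalent-sphere diameter range (20–60 nm by
default, bracketing the 30–40 nm physiological range with margin for
partial-volume effects). Morphometrics are computed in physical units with
anisotropic voxel sizes honoured: voxel-count volumes, centroid distance
to the nearest active-zone voxel, and nearest-neighbour centre-to-centre
distances. The active-zone distance uses the centroid as reference point;
a surface-to-surface variant can be derived from the same label volumes if
needed.

## The phantom generator

Every stage is tested against `synthetic` fixtures with exact ground
truth, generated as pure functions of a seed:

* textured volumes (`blobs`, `filaments`, `checker`, `ramp`) whose
  structures drift slowly in z, mimicking the z-coherence of tomographic
  data; `ramp` adds an exact constant per-slice intensity increment on a
  strictly positive textured base, realising the uniform-change
  assumption exactly;
* serial "cutting" that partitions a source volume into contiguous
  blocks, discards known top/bottom slices, warps each section by a known
  affine and elastic field, optionally blurs the outermost 10% of slices
  with a z-graded Gaussian (a cheap proxy for the missing wedge's obscured
  surfaces; a Fourier-domain wedge simulation is out of scope), and keeps
  the warp validity mask so estimators can distinguish fill from tissue;
* a synapse phantom at ~1 µm scale: two compartments separated by a
  curved membrane slab, non-overlapping 35 nm spheres in the presynaptic
  compartment, a binary reference affinity map and an active-zone surface
  mask.

What passing these tests shows: the geometry, energies, solvers and
bookkeeping are implemented correctly, and the pipeline composes. What it
does not show: performance on real tomograms — phantoms have no
reconstruction artifacts beyond the blur proxy, no stain variation, no
genuinely ambiguous membranes, and their intensity statistics are milder
than tissue. In particular the sensitivity-based gap estimator inherits
the uniform-change assumption; content whose change is concentrated at
the gap violates it and is only partially captured by the thickness
constraints. Independent per-slice noise also biases the per-pixel
gradient (and hence the sensitivity map) upward; the phantom studies
therefore run in the low-noise regime where the assumption the estimator
is built on actually holds.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on generated
phantoms: 256² section images for alignment recovery, a 256×256×300
source volume split into four sections for the end-to-end reconstruction,
one hundred ≤10-node match graphs for solver/enumeration agreement, one
hundred 160² decoy-texture trials for the consistency-vs-raw-NCC
comparison, twenty two-section phantoms for gap-count recovery, and a
48×96×96 synapse phantom with ten vesicles for segmentation. These sizes
were chosen so the whole suite completes in minutes on a single CPU while
every check still exercises the full code path at meaningful resolution.
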