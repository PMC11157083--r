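---
title: "Quantifying photoreceptor outer segments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoreceptor outer segments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posquant)
```

# The measurement problem

Photoreceptor outer segments (POS) are the light-detecting compartments of
rods and cones. Two structural properties track their maturation and their
collapse in inherited retinal degenerations:

* at the **ultrastructural scale** (transmission electron microscopy), the
  degree to which the stacked disc membranes are mutually aligned; and
* at the **cellular scale** (fluorescence microscopy of S-opsin labelled
  cone POS), their number, size, shape, and staining intensity.

`posquant` implements one measurement arm for each scale, plus synthetic
generators that make both arms testable end to end without microscope data.

# TEM arm: nematic orientation and coherency

## Model

Membranes are osmium-stained and appear dark, so the local membrane
direction is perpendicular to the image intensity gradient. Directors are
*nematic*: a direction and its 180-degree rotation are the same physical
orientation. We represent a pixel's orientation by the angle
$\theta \in [0^\circ, 180^\circ)$ of the vector $(g_y, -g_x)$ and weight it
by the gradient magnitude $m = \sqrt{g_x^2 + g_y^2}$; pixels with $m = 0$
carry no orientation and contribute nothing to any sum.

Alignment over a pixel set $N$ is summarized by the Q-tensor

$$Q = \sum_{x \in N} m(x)\begin{pmatrix}
\cos^2\theta - \tfrac12 & \cos\theta\sin\theta\\
\cos\theta\sin\theta & \sin^2\theta - \tfrac12
\end{pmatrix}
= \begin{pmatrix} Q_{xx} & Q_{xy} \\ Q_{xy} & -Q_{xx} \end{pmatrix},$$

whose **coherency** is twice the larger eigenvalue after weight
normalization, $2\sqrt{Q_{xx}^2 + Q_{xy}^2} / \sum m$ — the scalar nematic
order parameter, equal to $|\sum m e^{2i\theta}| / \sum m \in [0, 1]$. The
Q-tensor formula itself is an unnormalized sum; we divide by the total
weight because only that normalization yields the stated $[0,1]$ range and
the order-parameter identity. The dominant director is the four-quadrant
inverse tangent of the doubled-angle vector, halved:
$\tfrac12\,\mathrm{atan2}(Q_{xy}, Q_{xx})$. Halving is required for the
reported angle to match the visible membrane direction; all angles are
reported as directors in $[0^\circ, 180^\circ)$, measured counterclockwise
from the $+x$ (column) axis with $y$ increasing downward.

## The gradient operator

Gradients come from a separable 5-tap derivative/smoothing pair applied as a
5x5 kernel. The published source of the operator's coefficient table was not
available offline, so the pair was **re-derived from its defining design
criterion**: minimize the maximum orientation-estimation error over
sinusoidal patterns with wavelengths of 8 px and longer at all orientations
(minimax over the band $k \le \pi/4$). The frozen coefficients in
`scharr5_kernels()` achieve a maximum angular bias of about `6.4e-7`
degrees on that band — two orders of magnitude below the design family's
documented bound of 0.00007 degrees — which the acceptance suite re-measures
from rendered gratings. Because optimized derivative pairs of this size are
essentially unique up to normalization, numerical differences to any
published table are immaterial at the measured bias level.

No padding is used anywhere: a pixel is valid only when the full 5x5 support
lies inside the image, and all downstream statistics are restricted to valid
pixels via explicit masks.

## Local vs global coherency, and their ratio

* **Local coherency**: Q-tensor over a 25x25 box (`box_radius = 12`) around
  each query pixel. At the reference magnification (287.5 px/um) the box
  spans two to three membrane layers of 0.02–0.03 um repeat. A query pixel
  is valid iff the box *and* every underlying gradient support lie inside
  the ROI — equivalently the ROI eroded by `box_radius + 2` pixels. The box
  is un-apodized and the mean local coherency is an unweighted mean over
  valid query pixels, both literal readings of the procedure.
* **Global coherency**: one Q-tensor over all ROI pixels whose gradient
  support is inside the ROI (erosion by 2 px).
* Their **ratio** indexes maturation: internally aligned but mutually
  rotated membrane patches ("partly stacked") give mean local coherency well
  above global coherency (ratio « 1); uniformly stacked membranes give a
  ratio near 1.

Per biological replicate, the angles of global coherency of all ROIs are
themselves aggregated by a unit-weight Q-tensor; its coherency is the
replicate **alignment** (1 iff all ROI directors agree mod 180 degrees).

ROI polygons (ImageJ `.roi`/`.zip` dialect) are rasterized with a
pixel-center-in-polygon rule, which is deterministic and resolution
independent. Polar histograms of local directors are count-weighted;
duplication to the full circle is left to rendering. Grayscale downsampling
is a block mean; orientation-level downsampling aggregates each super-pixel
with the Q-tensor, carrying $|\sum m e^{2i\theta}|$ as the new weight.

# LM arm: pixel classification and morphometry

## Preprocessing

Stacks are background-subtracted with a true 3D top-hat (box structuring
element, half-width 3 voxels, i.e. 7x7x7 support — "radius 3 in all three
dimensions" is read as a 3D filter, not per-slice) and then normalized per
stack to a maximum of exactly 4096, kept in floating point. Order matters
and is fixed: top-hat first, then normalization.

## Classifier

A random forest of 100 trees with 2 decisions per tree classifies voxels as
signal or background from a convolutional feature bank. The bank vocabulary
is `original`, `gaussian`, `difference_of_gaussian`,
`laplace_of_gaussian_box`, `sobel_of_gaussian`, `median_box`, `mean_box`,
`tophat_box` at sigma 1 or 2; the production default is the most efficient
combination (original + Gaussian + difference-of-Gaussian + Laplace-box, all
sigma 1). Where the named filter families leave room, the conventional
readings are used and documented: difference of Gaussian is
$G(\sigma)-G(2\sigma)$; the Laplace box is the 6-neighbour discrete
Laplacian after $G(\sigma)$; Sobel is the 3D Sobel gradient magnitude after
$G(\sigma)$; box filters use half-width = sigma. The raw image is included
as a feature by default since the vocabulary lists it; the bank is
configurable and serialized with the model, so any deposited bank can be
matched exactly later.

Training uses sparse annotations (typically 100 voxels per class per
image), deduplicated with a warning; trees are CART stumps-of-depth-2 with
gini splits and sqrt-mtry feature subsampling; given a seed, the serialized
model (portable JSON) is bit-reproducible. At prediction, an exact vote tie
counts as background — the conservative, deterministic choice.

## Morphometry

Predicted masks are labelled under 26-connectivity, then labels
(nearest-neighbour) and intensities (trilinear) are resampled to isotropic
0.323 um voxels. Per label we measure: volume (voxel count x voxel volume);
bounding-box height along y (the apical–basal axis as imaged; configurable);
Feret diameter (maximum pairwise distance between surface-voxel centers,
with a deterministic support-point reduction for large surfaces); and
sphericity $\pi^{1/3}(6V)^{2/3}/A$. The surface area $A$ uses the **coarea
formula** on the Gaussian-smoothed indicator
($A = \sum |\nabla (G_\sigma * \chi)| h^3$, $\sigma$ = 1 voxel) computed on
a 2x nearest-neighbour upsampled indicator so that opposite faces of thin
labels do not cancel. This mesh-free estimator replaces an iso-surface mesh
(no marching-cubes implementation is available in the target environment)
and reaches sphericity >= 0.95 on a digital ball of radius 10 voxels, the
calibration the mesh was meant to provide. Sphericity of very thin (1–2
voxel) labels is still biased upward; the package reports it as-is and the
bias is shared by all labels of similar size.

The 5–95 percent volume filter removes segmentation clusters and speckle.
Percentiles are linear-interpolation quantiles (type 7) computed over the
**pooled experiment dataset**, not per image (a `pool` argument exposes the
per-group option); the unfiltered label set is retained because summed-POS-
volume analyses deliberately include clusters.

## Statistics

The replicate hierarchy is the part easy to get wrong, and it is owned by
this package: values are averaged technical-replicate-first, then per
biological replicate, and group mean ± SEM is computed over biological
replicates, so a replicate with many technical measurements counts once.
SEM is flagged `NA` for single-replicate groups rather than silently 0.
Both ROI-level and replicate-averaged aggregations are emitted where the
distinction matters. The tests themselves (Pearson matrix, one-way ANOVA
with Tukey HSD, Welch's t) delegate to base R, with the conventional
p < 0.05 decision rule.

# The synthetic worlds, and what green tests establish

**Membrane textures** are sinusoidal stripes of wavelength 8 px (a membrane
repeat of ~0.028 um at 287.5 px/um) rendered from a phase field. Angular
disorder is a Gaussian-filtered white-noise phase perturbation with
correlation length of about one wavelength, rescaled so the local director
deviates with the requested standard deviation; the exact per-pixel ground
truth director comes from the numerical phase gradient of the rendered
pattern. "Partly stacked" morphology is a patchwork of internally aligned,
mutually rotated patches; "chaotic" morphology is an isotropic field of
ring-shaped vesicles. These reproduce the *directions* of the published
developmental and degeneration signatures (coherency decreasing with
disorder; ratio « 1 for patchwork vs ≈ 1 for coherent), not their numeric
values, which depend on real tissue texture: synthetic stripes have no
stain granularity, no section artifacts, and a single spatial frequency.
A green signature test therefore establishes correct ordering and
discrimination, not calibration against micrographs.

**POS phantoms** are non-overlapping ellipsoids elongated along y
(default semi-axes 0.6 x 1.8 x 0.6 um — POS about 3.6 um long and 1.2 um
wide, typical of maturing cone POS), placed in a 24 x 96 x 96 voxel stack
with 1 x 0.323 x 0.323 um voxels, over a dim background with a shallow
apical–basal gradient and mixed Poisson–Gaussian noise. Separation is
enforced per axis (bounding boxes inflated by 4 voxels of the respective
axis must be disjoint along at least one axis), which guarantees the stated
voxel gap without over-rejecting dense packings. Objects thinner than one
z-slice are snapped onto the nearest slice center so every planted object
renders. Synthetic annotations draw half of the background voxels from the
2-voxel shell around objects, emulating how human annotators label both
near-structure and far-field background; with far-field-only annotations
the learned intensity threshold sits too low and predictions grow a
one-voxel halo. The phantoms have hard edges, no anisotropic PSF, and no
touching clusters, so a green recovery test establishes the pipeline's
bookkeeping (counts, volumes, features), not segmentation performance on
real tissue.

# Numerical choices and degenerate inputs

* Convolution edge policy is replicate ("nearest") for LM filters; the TEM
  gradient instead masks unsupported pixels — no synthetic values enter any
  coherency statistic.
* Zero-weight Q-tensors have coherency 0 and an undefined (`NA`) dominant
  angle; empty local-coherency maps are flagged, not raised as errors,
  while an ROI that vanishes under the 2-px global erosion is an error.
* Scores with zero denominators are `NA` (undefined), distinct from 0.
* All generators are bit-reproducible from their seed; classifier training
  is bit-reproducible from its seed.
* Multi-channel images are rejected rather than converted; an all-zero
  stack cannot be max-normalized and is rejected as degenerate.

# Known limitations

* No instance segmentation on EM images (unsolved in this domain) and no
  cluster splitting by watershed on LM segmentations (tried and rejected in
  the source workflow); clusters are handled by the volume filter instead.
* The TIFF reader/writer covers uncompressed single-channel baseline files
  only — by design, as the analysis rejects color input anyway.
* Reported per-ROI angles follow this package's angle convention; replicate
  alignment is convention-invariant, but cross-tool comparisons of raw
  angles should verify the convention first.
* Sphericity is biased upward for labels only 1–2 voxels thick.
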