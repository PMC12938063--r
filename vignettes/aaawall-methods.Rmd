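---
title: "Membrane wall-stress estimation from segmented AAA images: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane wall-stress estimation from segmented AAA images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaawall)
```

`aaawall` chains four stages — outer-wall segmentation, NURBS contour
refinement, surface meshing, and inverse membrane stress analysis — into a
pipeline that turns a stack of cross-sectional vessel images into a
patient-specific wall-stress field. This vignette explains the models
behind each stage, the parameters that matter, and the numerical choices
made where the design was genuinely open. It states no empirical result
beyond what the package's own tests and `scripts/acceptance.R` compute.

## The membrane model and why no material law is needed

A thin pressurised shell whose *deformed* geometry is known is (nearly)
statically determinate: force balance on the wall mid-surface,

$$\frac{1}{\sqrt{g}}\left(h\,\sigma^{\alpha\beta}\mathbf{g}_\alpha\right)_{,\beta} + p\,\mathbf{n} = 0,$$

determines the in-plane Cauchy stress components
$\sigma^{\alpha\beta}$ from the surface metric (determinant $g$, covariant
basis $\mathbf{g}_\alpha$), the wall thickness $h$ and the pressure $p$
alone. No constitutive model enters, which matters clinically because
aortic wall properties cannot be measured non-invasively. The assumptions
bought with this convenience are those of any membrane model: no bending
stiffness, no through-thickness stress gradient, uniform thickness, and a
pressure assumed to act directly on the modelled wall (intraluminal
thrombus is not load-sharing). The imaged configuration is taken to be the
equilibrium configuration at the stated pressure.

### Discretisation

The surface is a triangle mesh in physical units (cm). Stress is
represented by one symmetric in-plane tensor per *vertex*, expressed as
three components $(s_{11}, s_{12}, s_{22})$ in a per-vertex orthonormal
tangent frame, and interpolated linearly over each element. Per-element
constant stresses would leave roughly twice as many unknowns as balance
equations; nodal unknowns make the count $3V$ against $3$ equations per
interior vertex. Each free (non-boundary) vertex $a$ contributes a weak
(Galerkin) force balance

$$\sum_{e \ni a} h\,A_e\,\bar{S}_e\,\nabla N_a \;=\; p \sum_{e \ni a} \frac{A_e}{3}\,\mathbf{n}_e,$$

with $\bar S_e$ the mean of the element's three vertex tensors,
$\nabla N_a$ the linear shape-function surface gradient and
$\mathbf{n}_e$ the outward facet normal ("pressure applied outwards to
the internal faces"). Boundary-ring vertices carry no equations — the
"fixed ends" of the tube — so their reactions absorb the net load; the
package checks that these reactions cancel the total pressure load to
machine precision (`force_balance()`).

### Regularisation: why a smoothing term, and its scale

The system is linear in the stress unknowns and mildly under-determined
(statically indeterminate directions such as uniform axial tension on an
open tube have zero residual). A plain minimum-norm least-squares solve
works well on structured tube meshes, but on irregular triangulations the
discrete operator has near-null *mesh-scale oscillation* modes: driving
the residual of the (inevitably $O(h^2)$-inconsistent) discrete system to
zero excites them and can corrupt the field by tens of percent on an
icosphere. `solve_stress()` therefore minimises the equilibrium residual
plus a smoothing functional

$$\beta \sum_{\text{edges}} \left(h\,A_{\text{edge}}\,\frac{\ell_0}{\ell_{\text{edge}}}\right)^2 \lVert S_a - S_b \rVert_F^2,$$

the discretisation of $\beta\,h^2\ell_0^2 \int |\nabla S|^2\,dA$ with a
**fixed physical smoothing length** $\ell_0$. Defaults: $\ell_0 = 0.1$ cm
— of the order of the wall thickness, below which stress detail is
physically meaningless in a membrane model — and $\beta = 2$, calibrated
once against the two closed-form pressure-vessel references (cylinder
hoop stress $pR/h$, sphere stress $pR/2h$) and then frozen. Because the
weight is tied to a fixed physical length, refinement suppresses
mesh-scale modes ever harder while the bias on smooth fields stays at the
$(\ell_0/R)^2$ level, and the cylinder hoop-stress error decreases
monotonically under refinement (asserted in the tests). A small Frobenius
Tikhonov term (`reg_scale = 1e-8` relative) pins the indeterminate
directions at zero; it is weighted by $s_{11}^2 + 2 s_{12}^2 + s_{22}^2$,
the frame-invariant tensor norm, so rigid rotations of the mesh change
principal stresses only at the $10^{-10}$ level. All terms scale
identically in $p$ and $h$, hence stresses are *exactly* proportional to
pressure and to $1/h$.

Element-level results — centroid stress (vertex average projected to the
element plane), contravariant components in the edge basis, and principal
stresses (ordered eigenvalues in the tangent plane) — are what the
summaries consume, reported in N/cm².

The relative equilibrium residual is returned as a diagnostic; the solver
errors above `max_residual = 0.2`. Image-derived meshes carry pixel-scale
jitter that typically leaves residuals near 0.1 on otherwise clean
phantoms without harming the smooth part of the solution, which is why the
gate is not tighter.

## NURBS contour refinement

Mask boundaries are replaced by closed rational B-spline curves
$c(t) = \sum_i N_{i,p}(t) w_i P_i / \sum_i N_{i,p}(t) w_i$, evaluated by
the Cox–de Boor recursion. Closed curves use a periodic-uniform knot
vector with the first $p$ control points wrapped (so the seam is
$C^{p-1}$); open clamped curves are retained for generality. Defaults:
degree 3 and 24 control points — aortic cross-sections are smooth and
nearly convex, and 24 cubic spans reproduce a circle to well under a
pixel. Programmatic editing (`move_control_point()`,
`set_control_weight()`) exercises the local-support property that makes
interactive boundary correction practical: samples outside the moved
point's basis support are bit-identical.

Three fitting modes resolve a genuine ambiguity in how "a smooth curve
drawn through evenly spaced points" should be constructed:

- `"approximate"` (default): the arc-length-resampled boundary points
  *are* the control points. Simple and robust, with a known slight inward
  bias (a factor $(4 + 2\cos(2\pi/n))/6$ on a circle's radius for cubic
  curves).
- `"interpolate"`: control points solved so the curve passes through the
  samples; exact but it follows rasterisation noise.
- `"lsq"`: periodic least-squares approximation of a dense boundary
  sampling; unbiased and noise-averaging, the preferred mode when
  physical measurements are taken from the curve
  (`measure_hydraulic_diameter()` uses it with 16 control points).

Boundary tracing itself runs through the centres of the outermost
foreground pixels, which sits about half a pixel inside the true region
edge. `mask_to_contour()` pushes the traced polygon outward along its
local normals by the offset that makes the polygon area equal the
pixel-count area (a nearly unbiased area estimator). Without this
correction every mask-derived diameter and round-trip is biased inward by
half a pixel. Rasterisation back to masks samples the curve at 10 points
per control point and fills by the even-odd scanline rule on pixel
centres. Contours with holes are unsupported: the outer wall is simply
connected per slice.

## Geometry: diameters and lofting

The per-slice hydraulic diameter is $4A/P$ (shoelace area, polygon
perimeter) in physical units; it equals the geometric diameter for a
circle and is the package's maximum-diameter measure, taken in the slice
plane (the stacks are axial; a centerline-orthogonal convention would
need 3-D resampling that the input masks do not support). Lofting
resamples every contour to `points_per_ring` (default 48)
arc-length-equal points with counter-clockwise winding, aligns
consecutive rings by the cyclic shift minimising the sum of squared
distances (least twist, verified optimal against brute force over shifts
in the tests), and joins rings with alternating-diagonal triangle strips:
$2m$ triangles per band, Euler characteristic 0, exactly two boundary
loops. Vertices are $(x\,s_{px},\ y\,s_{px},\ z_i\,s_{slice})$ scaled to
cm; the lowest slice is the proximal ring by convention.

## Segmentation at phantom scale

The segmentation stage is a 2-D encoder–decoder ("U") network whose
encoder convolutions use the dilation schedule 1, 2, 3, 1 — the effective
receptive field of a dilated convolution is $(k-1)d + 1$, so dilation
widens context without extra parameters — with 2×2 max pooling between
stages, skip connections, nearest-neighbour upsampling, and a final 1×1
convolution + sigmoid. Optimisation follows standard practice for this
task: Adam at $10^{-4}$, validation-Dice plateau halving (factor 0.5,
patience 5, floor $10^{-6}$), batch size 16, early stopping at patience
5, Dice + BCE loss with equal weights, and flip/rotation (±15°)/zoom
(0.9–1.1)/intensity (0.9–1.1) augmentation — all configurable in
`unet_config()`. Patch-based processing (`extract_patches()` /
`reassemble()`, mean aggregation over overlaps, reflect padding) keeps
memory bounded and is lossless when the stride equals the patch size.

Architecture depth, channel widths and patch size are deliberately open
parameters; the package defaults (depth 4, base 16 channels, 64×64
patches) are sized so that CPU training is feasible. The tests overfit a
ten-slice phantom with a smaller configuration (depth 3, base 8, learning
rate $10^{-3}$) — a learning rate tuned for a large clinical corpus moves
weights far too slowly for a 200-update toy run — and reach training Dice
≥ 0.95 in about a minute, which validates the gradients (also checked
directly against finite differences), the schedules and the
patch/predict plumbing, *not* clinical segmentation accuracy. Prediction
thresholds at 0.5 and keeps the largest connected component (one outer
wall per slice).

## The phantom generator

`fusiform_spec()` emulates what the pipeline needs from contrast CT
angiography and nothing more: a tube of baseline outer radius
$r_0 = 1$ cm dilating along a Gaussian profile
$r(z) = r_0 + (r_{max}-r_0)\,e^{-((z-z_0)\Delta z)^2/w^2}$ to
$r_{max} = 2.5$ cm (a 5 cm aneurysm, the elective-repair threshold for
men) over $w = 2.5$ cm, 40 slices of 96×96 pixels at 0.8 mm in-plane and
2 mm slice spacing (clinical CTA slices run 1–3 mm). Intensities are
ordered lumen (300) > wall (150) > background (50) in arbitrary synthetic
units with additive Gaussian noise (SD 10); every draw is fixed by the
spec's seed. Cross-sections are circles, so masks, contours, diameters
and (via the cylinder limit) stresses all have analytic truth.

What the phantom does *not* emulate: CT physics (beam hardening, partial
volume), anatomy (non-circular lumens, thrombus, calcification,
branches), patient variability, or annotation noise. Passing the suite
therefore demonstrates that the algorithms are implemented correctly and
are internally consistent on geometry with known truth — it says nothing
about performance on clinical images, which would require real annotated
data.

## Numerical details and degenerate inputs

- Percentiles use linear interpolation between closest ranks (R type 7),
  so the 99th-percentile wall stress of 1…100 is 99.01.
- $R^2$ is squared Pearson correlation by default, with a
  `1 - SS_{res}/SS_{tot}`-about-the-identity mode available, since scatter
  around equality and linear association answer different questions.
- The Friedman test uses mid-ranks; an all-tied table returns FS = 0,
  p = 1 by convention.
- Mean arterial pressure is the one-third pulse-pressure rule
  $(SBP + 2\,DBP)/3$, reported to 0.1 mmHg; pressure converts to N/cm² at
  exactly 133.322 Pa/mmHg.
- Segmentation metrics with empty masks: a ratio whose defining sets are
  all empty is 1, exactly-one-empty is 0; Hausdorff distances are
  undefined (error) for empty masks. HD95 pools both directed
  boundary-distance sets before taking the percentile, making it
  symmetric; boundary pixels are foreground pixels with a 4-neighbour
  background.
- Empty masks, single-pixel components (< 5 px), degenerate triangles
  (area ≤ 1e-10 cm²), zero-perimeter contours, non-positive weights and
  out-of-range parameters all raise informative errors rather than
  propagating NaNs.

## Problem sizes used by the test suite

The suite validates the solver on a 32×25-ring cylinder (1536 elements)
and a subdivision-3 icosphere (1280 elements), refinement behaviour on
16/32/64-ring cylinders, and the end-to-end pipeline on 15-slice, 64×64
phantoms; the U-Net smoke test trains on ten 64×64 slices for 60 epochs.
These sizes keep a full run at a few minutes on one CPU while leaving
every assertion's margin wide (the Laplace-law checks pass at 5% with
observed errors near 1% for the cylinder and 4% for the sphere).

## Known limitations

- The membrane model ignores bending, thickness variation, thrombus load
  sharing and residual stress; absolute stresses inherit the uncertainty
  of the assumed uniform pressure and thickness, although their scaling
  in both is exact.
- The smoothing length $\ell_0$ trades stress resolution against noise
  rejection; features genuinely smaller than $\ell_0$ are attenuated.
- Lofting assumes one simply connected outer wall per slice and a
  roughly prismatic topology; bifurcations and severely tortuous
  centerlines are out of scope.
- The segmentation network is a faithful, CPU-trainable implementation of
  the architecture family, not a pretrained clinical model.
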