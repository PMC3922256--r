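---
title: "The double geo-vector flow: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double geo-vector flow: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dgfseg)
```

## The segmentation problem

A frontal tongue photograph contains the protruded tongue body, the lips
around it, the dark mouth opening between tongue root and upper lip, and
facial skin. The tongue boundary is heterogeneous: the lower half runs
against lips and chin whose color may be close to the tongue's (especially
for red tongues), while the upper half is not an intensity edge of the
tongue at all but the border of the dark opening behind it. A single active
contour must either be stiff enough to ignore the clutter (and miss the
boundary) or compliant enough to over-learn it.

The double geo-vector flow (DGF) splits the region at the row of the mouth
corners (the *angular points*); that row is the partition line `sline`.
Below it a geodesic level-set flow shrinks onto the lower boundary; above
it a gradient-vector-flow (GVF) snake driven by the *binarized* mouth
opening swells onto the upper boundary. The two arcs are pinned at the
angular points and joined into one closed contour.

## Lower part: distance-regularized geodesic flow

The lower contour is the zero level of Φ, initialized piecewise-constant
from the initial contour (−ρ strictly inside, 0 on the contour, +ρ
outside; `init_level_set()`), and evolved by

∂Φ/∂t = μ[ΔΦ − div(∇Φ/|∇Φ|)] + λ δ_ε(Φ) div(g ∇Φ/|∇Φ|) + ν g δ_ε(Φ)

with the edge indicator g = 1/(1 + |∇(G_σ∗I)|²) (`edge_indicator()`).
The first term penalizes deviation of Φ from a signed distance function, so
no re-initialization is ever performed; the second attracts the zero set to
minima of g; the third is the shrinking balloon force. Because the enclosed
region is the negative phase, a positive ν shrinks the contour — the
initialization must therefore enclose the true boundary, which is why the
detected tongue tip is deliberately nudged below the strongest midline edge.
Updates are computed on the full grid but written only to rows `>= sline`
(the row `sline` itself belongs to the updated set); the frozen upper rows
hold the straight initial chords in place.

Numerical choices:

* δ_ε is the standard raised-cosine regularization with ε = 1.5 px.
* |∇Φ| is guarded as sqrt(|∇Φ|² + 1e−10); finite differences are central
  with replicated (Neumann) borders.
* Explicit Euler with τ = 0.2 under the stability guard τμ < 0.25. The flow
  weights are the published setting μ = 1, λ = 3, ν = 0.5; with μ = 1 the
  guard forces a sub-unit time step (time-step values quoted elsewhere in
  the level-set literature pair with μ two orders of magnitude smaller).
* Convergence: the pixel set {Φ < 0} unchanged for 20 consecutive
  iterations, capped at `geodesic_iters = 600`.

**Intensity scale of the edge indicators.** `edge_indicator()` (and the
geometric term's g_B below) differentiates the image on the 8-bit scale
(intensities × 255, the representation the flow weights were tuned on). On
a unit-interval image no realistic edge produces a gradient magnitude near
1, so g would never leave the vicinity of 1 and the λ and ν terms could
never balance: a full-range step smoothed with σ = 1.5 yields |∇I| ≈ 0.1
on the unit scale but ≈ 27 on the 8-bit scale, i.e. g ≈ 0.0014 — a real
barrier. The scale is exposed as the `gain` argument.

## Upper part: binary-map GVF with geometric propulsion

The rows above `sline` are thresholded to isolate the dark mouth opening B
(`binarize_upper()`). The GVF field V_B solves

∂V_B/∂t = w ∇²V_B − |∇B|² (V_B − ∇B)

by explicit iteration from V_B = ∇B, with constant smoothing weight
w = 0.2 and time step 0.9·2/(8w + max|∇B|²), the stability bound of the
combined diffusion–reaction update. The field is held at zero on the rows
below `sline`: there is no upper-flow force in the lower part.

The snake is an open polyline from the left to the right angular point
(endpoints pinned throughout), updated semi-implicitly: the internal forces
αC″ − βC⁗ (α = β = 1) are solved as a banded linear system per step, the
external force is explicit. The external force switches per point: the GVF
V_B where its magnitude reaches θ_v = 0.05, otherwise the geometric
propulsion G_B = g_B·n̂ with n̂ the unit outward normal (oriented away from
a tongue-interior reference point). Far from the opening g_B ≈ 1 and the
arc advances at unit speed; near it the GVF takes over. The published
`max(V_B, G_B)` is not defined for vectors; this magnitude-threshold switch
implements its prose semantics (far-field propulsion, near-field
attraction). The snake is resampled to ~1 px spacing every iteration and
declared converged when the maximum displacement stays below 0.05 px for
10 iterations (cap `snake_iters = 400`).

Two properties of this construction are worth stating plainly:

* Because the force target is ∇B (a step, not an edge-strength ridge), the
  stable locus of the snake between the two edges of the opening is the
  *centerline* of the dark band — the tractive forces from the two sides
  balance there, which is also what prevents over-learning past the band.
  The converged upper arc therefore sits about half the opening's thickness
  above the true tongue root line; with a physically thin opening (a few
  pixels, i.e. lips resting on the protruded tongue) this bias is
  sub-pixel to ~2 px.
* The propulsion term only makes sense over columns where the binarized
  opening exists; beyond its lateral extent there is no boundary above to
  stop an outward push, so the external force is masked there and the
  internal forces interpolate from the pinned endpoints.

## Initialization

* **Window.** The saliency map is the CIELab distance of each pixel to the
  mean image color, smoothed (σ = 3 px) and normalized — a deliberately
  simple context-contrast model whose only required property is that the
  tongue region is the brightest compact blob. The window objective is
  (saliency inside) − 0.5·(saliency in a 10% margin ring) − 0.15·area; the
  per-pixel area cost is needed because the ring is clamped at the image
  borders, which would otherwise make the full frame the maximizer. Small
  maps are searched exhaustively, large ones on a coarse grid with greedy
  boundary refinement. Of the top two windows the smaller is adopted; a
  second window is only reported when a candidate overlapping the first by
  at most 30% reaches 10% of its score. The adopted window is expanded by
  15% per side before cropping so the lip corners and the mouth opening
  stay in frame.
* **Angular points.** The mouth corners bound the dark opening laterally.
  The opening is found by a dark-mode threshold (Otsu re-applied to the
  sub-threshold population until the dark class is a small, compact mode —
  a single global split on this multi-modal region can land at the skin
  boundary instead). The per-column height of the opening tapers to zero at
  the corners: a local linear fit at each end is extrapolated to its root
  (capped at 10 px — overshooting past the corner throws the initial arc
  beyond the lip band, which costs far more than the small wedge left by a
  conservative estimate), the corner row comes from a quadratic fit of the
  opening's bottom edge, the column is refined to the outermost column
  still carrying a strong horizontal edge below the corner row (beyond the
  corner there is only smooth skin), and the point is snapped to a nearby
  Harris-response peak when one stands out.
* **Tip and root.** The tip is the lowest strong gradient peak on the
  vertical midline below the angular row, nudged 2 px down so the geodesic
  arc starts at or outside the boundary. The root is placed midway between
  the bottom of the dark opening and the angular row — strictly inside the
  tongue, so the upper chords swell outward.
* **Initial contour.** Lower half: one parabola per side through angular
  point and tip (apex at the tip), resampled at 1 px. Upper half: straight
  chords angular → root → angular. For a convex tongue the chords lie
  inside the body and the arc tracks the boundary from outside; residual
  inward slivers of a few pixels are the main contribution to the
  pipeline's false-negative rate.
* **Nose removal.** The upper lip is assumed at most twice as thick as the
  dark opening below it; everything above `dark_top − 2·dark_height` is cut
  off before the upper flow runs.

## Error metrics

`metrics_report()` computes the symmetric Hausdorff and mean nearest-point
distances on 1 px-resampled contours, normalized as a percentage of the
image diagonal (the diagonal is scale-free; the normalizer is not pinned
down by any published definition, so it is a documented choice), and the
FP/FN/TP volume fractions with the reference area as the common
denominator, so TP + FN = 100 exactly.

## The synthetic scene generator

`generate_scene()` renders the scene structure the method assumes — skin,
upper lip band, thin dark mouth opening, tongue body bounded by two
per-side quadratics meeting at the corners, a lateral lower lip band
(absent at the midline, where the protruded tongue covers it), optional
nose block, optional darker streak across the upper tongue (a gray-level
local-minimum trap), plus seeded Gaussian noise (σ = 0.01). Ground truth
(mask, boundary, feature points) is exact by construction.

Design notes, fixed once:

* **Geometry** (256×256 defaults): corner row 120, tip row 218, half-width
  65, opening 4 px at the midline tapering to zero at the corners, upper
  lip 8 px, lower lip 12 px. The thin opening is both the realistic
  condition (lips resting on a protruded tongue) and the regime where the
  centerline equilibrium of the binary GVF is near the true root line.
* **Palettes.** Gray-level separations: skin 0.65, lip 0.49, opening 0.07;
  tongue 0.77 (light white), 0.51 (red), 0.39 (purple), 0.30 (carmoisine).
  The red class is defined by tongue-lip proximity: its separation
  (≈ 0.027, hue-separated so the colors remain distinct) sits where the
  edge-stopping term measurably under-performs, reproducing the published
  ordering (red worst, light white and carmoisine best) as an ordering,
  not a numeric match. `generate_suite()` jitters geometry and colors per
  scene under the master seed, and assigns classes by proportion.
* **What the scenes do not emulate:** teeth, coating texture, specular
  highlights, shading gradients, camera noise correlation. Passing the
  synthetic study shows the flows converge to the geometry they were
  designed for under controlled contrast; it does not certify clinical
  performance.

## Study sizes and limitations

The shipped study segments 20 scenes at 256×256 (mixed classes), a size at
which the complete run takes a few minutes on one core; the class-contrast
comparison uses 6 scenes per class and the ablations one scene each. Known
limitations: the upper arc carries the half-opening centerline bias; corner
localization is conservative by design, leaving small wedges near the
mouth corners; gray-scale-only edge detection ignores chroma contrast (a
pale tongue on pale skin relies on the lip band for its lower boundary);
and the saliency stand-in assumes a single dominant salient object.
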