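# dgfseg — tongue image segmentation by the double geo-vector flow

Automatic segmentation of the tongue body in frontal face photographs, the
image-analysis step that computerized tongue-diagnosis systems (as used in
traditional Chinese medicine research) rely on before any color or coating
feature can be measured. Tongue photographs are hard to segment with a single
active contour: the lower tongue boundary meets lips and chin of similar
color, while the upper boundary (the tongue root) hides behind the dark mouth
opening, where gray-level snakes over-learn or stall in local minima.

`dgfseg` implements the double geo-vector flow (DGF), which splits the
problem at the row of the two mouth-corner ("angular") points, called the
partition line `sline`:

* **Lower part — geodesic level-set flow.** The region below `sline` is
  initialized as a piecewise-constant level set Φ (−ρ inside the initial
  contour, 0 on it, +ρ outside) and evolved by the distance-regularized
  geodesic flow

  ∂Φ/∂t = μ [ΔΦ − div(∇Φ/|∇Φ|)] + λ δ(Φ) div(g ∇Φ/|∇Φ|) + ν g δ(Φ),

  with edge indicator g = 1/(1 + |∇(G_σ ∗ I)|²). Updates are restricted to
  rows at or below `sline`; the upper rows keep their initial values, so the
  lower contour shrinks onto the tongue boundary while the upper chords hold.

* **Upper part — Geo-GVF snake.** The rows above `sline` are binarized to
  isolate the dark mouth opening B. A gradient vector flow field V_B is
  diffused from ∇B (∂V_B/∂t = w∇²V_B − |∇B|²(V_B − ∇B)), and an open snake
  pinned at the angular points evolves under
  C_t = αC″ − βC⁗ + max(V_B, G_B), where the geometric propulsion term
  G_B = g_B·n̂ pushes the curve outward wherever the GVF is negligible, so a
  far-initialized arc still reaches the boundary neighborhood.

The two converged arcs are joined at the angular points into one closed
contour and rasterized to the final mask.

The package also provides the saliency-window tongue localizer (a documented
context-contrast stand-in for an external salient-object detector),
feature-point initialization (Harris-assisted mouth-corner detection, tongue
tip and root), boundary/area error metrics (normalized Hausdorff and mean
distance, FP/FN/TP volume fractions), a deterministic synthetic tongue-scene
generator with pixel-perfect ground truth, and a CLI.

## Worked example

```r
library(dgfseg)

# a reproducible synthetic mouth scene with ground truth
scene <- generate_scene(scene_spec(seed = 3))

# full pipeline: saliency window -> feature points -> DGF -> closed contour
res <- segment(scene$image)
res
#> <dgf_result: mask 256 x 256, 488 contour points, sline 119>
#>   geodesic: 241 iters (converged: TRUE); snake: 400 iters (converged: FALSE)

# compare against the ground-truth mask and boundary
evaluate_segmentation(res, scene)
#> norm.HD 1.002%  norm.MD 0.270%  FN 0.85%  FP 2.46%  TP 99.15%
```

`norm.HD` and `norm.MD` are the Hausdorff and mean nearest-point distances
between the automatic and reference boundaries, as a percentage of the image
diagonal; `TP`, `FP` and `FN` are area fractions relative to the reference
tongue (so `TP + FN = 100`). Here the automatic contour stays within a pixel
of the true boundary on average and recovers 99.2% of the tongue area.

The same run from the shell:

```sh
Rscript inst/cli/dgf.R synth --n 1 --seed 3 --out scenes/
Rscript inst/cli/dgf.R segment scenes/image_001.png -o out/
Rscript inst/cli/dgf.R evaluate --auto out/mask.png --ref scenes/mask_001.png --json
```

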