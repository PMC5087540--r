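# gvfsnakes

Parametric active-contour (snake) segmentation with gradient vector flow
external force fields, for images whose targets have **weak edges and
heavy noise** — the regime of infrared, low-dose and other low-contrast
modalities, where the classical trade-off is stark: smoothing the force
field enough to suppress noise also destroys the faint edge responses the
contour is supposed to lock onto.

A snake is a closed curve $c(q)$ minimizing
$E = \tfrac12\int \alpha|c'|^2 + \beta|c''|^2\,dq + \int E_{ext}(c)\,dq$.
The external force here is a vector field $V$ obtained by diffusing the
gradient of an edge map $f$. The package implements the classical **GVF**
field, its **GGVF**, **NGVF** and **NBGVF** variants, and a
**convex-coefficient field** that splits diffusion between the edge-normal
direction (noise smoothing) and the edge-tangent direction (edge
preservation) as a function of edge-map *intensity*:

$$V_t = g(|\nabla f|)\,\bigl(g_s(f)\,V_{NN} + h_s(f)\,V_{TT}\bigr)
      \;-\; h(|\nabla f|)\,\bigl(V - \nabla f\bigr),$$

with $g = e^{-|\nabla f|/K}$, $h = 1-g$, and the piecewise-cubic weight
$h_s(f)$ that is 0 at $f=0$, $-f^3/(8\tau^3)+5f/(8\tau)+1/2$ on
$(0,\tau)$, and 1 for $f \ge \tau$ ($g_s = 1-h_s$). Any nonzero edge
response — however weak — tilts diffusion toward the edge-preserving
tangent direction, so raising $K$ against noise no longer erases weak
edges.

Around the fields the package provides the full experimental bench:
synthetic phantoms with exact ground truth (disk, square, U-shape,
long-thin-indentation), salt–pepper and multiplicative noise models, a
semi-implicit snake evolver with arc-length resampling, polygon
rasterization, precision/recall/F1 scoring, a pipeline runner with YAML
configs, and ggplot2 views (`autoplot()`, `plot_field()`,
`plot_displacement()`).

## Worked example

Segment a binary disk phantom with the convex-coefficient field at
$\{K,\tau\} = \{0.1, 1\}$:

```r
library(gvfsnakes)

ph   <- make_phantom(phantom_spec("disk", radius = 20))    # 64x64, truth mask
f    <- edge_map(ph$image)                                 # normalized |grad I|
V    <- solve_field(f, field_config("proposed", K = 0.1, tau = 1, n_iter = 500))
init <- make_initial_contour("ellipse", c(32.5, 32.5), c(56, 56), n_points = 100)
fit  <- evolve_snake(init, V, snake_config(n_iter = 250))
fit
#> <snake_fit> 129 points, 18 iterations, converged (final mean displacement 0.01939 px)

mask <- contour_to_mask(fit$contour, dim(ph$mask))
evaluate_mask(mask, ph$mask)
#> # A tibble: 1 × 3
#>   precision recall    f1
#>       <dbl>  <dbl> <dbl>
#> 1         1      1     1
```

The initial circle (radius 28) lies 8 px outside the disk; the diffused
field pulls it in and the contour settles on the boundary to subpixel
accuracy — precision, recall and F1 all reach 1.0 against the ground-truth
mask. `autoplot(fit, image = ph$image)` overlays the final contour;
`print(V)` reports the field's equilibrium residual (here `0.00108` after
500 iterations).

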