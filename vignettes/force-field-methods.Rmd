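---
title: "Gradient vector flow snakes with convex weak-edge-preserving coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient vector flow snakes with convex weak-edge-preserving coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvfsnakes)
```

## The model

A parametric snake is a closed curve $c(q) = [x(q), y(q)]$, $q \in [0,1]$,
that minimizes

$$E(c) = \tfrac12 \int_0^1 \alpha\,|c'(q)|^2 + \beta\,|c''(q)|^2 \, dq
        + \int_0^1 E_{ext}(c(q))\,dq,$$

where $\alpha$ penalizes stretching (tension), $\beta$ bending (rigidity),
and $E_{ext}$ is derived from the image. Gradient-vector-flow methods
replace $-\nabla E_{ext}$ by a vector field $V = (u, v)$ obtained by
diffusing the gradient of an *edge map* $f$ (a nonnegative image that is
large on edges) over the whole domain, which extends the snake's capture
range far beyond the thin shell where $\nabla f$ itself is nonzero.

The family of evolution PDEs implemented here, all iterated from
$V_0 = \nabla f$:

| method | evolution equation |
|---|---|
| GVF | $V_t = \mu\,\nabla^2 V - |\nabla f|^2 (V - \nabla f)$ |
| GGVF | $V_t = g\,\nabla^2 V - h\,(V - \nabla f)$ |
| NGVF | $V_t = \mu\,V_{NN} - |\nabla f|^2 (V - \nabla f)$ |
| NBGVF | $V_t = \mu\,(V_{TT} + \beta_{nb} V_{NN}) - |\nabla f|^2 (V - \nabla f)$ |
| convex-coefficient (`proposed`) | $V_t = g\,(g_s V_{NN} + h_s V_{TT}) - h\,(V - \nabla f)$ |

with $g = e^{-|\nabla f|/K}$, $h = 1 - g$,
$\beta_{nb} = e^{-|\nabla f|^2/K^2}$, and $V_{NN}$, $V_{TT}$ the second
directional derivatives of each component along and across its own
gradient, which split the Laplacian: $V_{NN} + V_{TT} = \nabla^2 V$.
Diffusion along the *tangent* (edge) direction preserves edges; diffusion
along the *normal* smooths noise. The convex-coefficient model allocates
the two directions by the **intensity** of the normalized edge map rather
than its gradient:

$$h_s(f) = \begin{cases} 0 & f = 0\\
  -\dfrac{f^3}{8\tau^3} + \dfrac{5f}{8\tau} + \dfrac12 & 0 < f < \tau\\
  1 & f \ge \tau, \end{cases} \qquad g_s = 1 - h_s.$$

The cubic rises steeply from $1/2$ near $0$ and joins the upper branch
continuously ($h_s(\tau) = 1$; its derivative $(5\tau^2 - 3f^2)/(8\tau^3)$
is positive on $(0,\tau)$, so it is strictly increasing there). The
consequence: *any* nonzero edge response — however weak — tilts diffusion
toward the edge-preserving tangent direction, while pixels with exactly
zero response diffuse normally. This is what protects weak edges while $K$
is raised to smooth noise. Note the deliberate jump at $f = 0^+$: the
definition pins $h_s(0) = 0$ although the cubic's limit is $1/2$; we
implement the branch structure as defined.

Because $h_s$ is thresholded on edge-map *intensity*, $\tau$ is only
meaningful if intensities are comparable across images; the edge map is
therefore normalized to $[0, 1]$. The default edge map is the plain
gradient magnitude $|\nabla(G_\sigma * I)|$ rather than its square: the
squared form compresses weak-edge responses toward zero, which works
against the model's purpose. The squared variant remains available via
`edge_map(..., squared = TRUE)`.

## Numerical implementation

**Differencing.** All spatial operators use central differences on the
unit pixel grid with replicate (Neumann) boundaries — the standard choice
for diffusion PDEs, keeping fields flat at the borders. The cross
derivative $V_{xy}$ is the centered 4-point stencil.

**Degenerate gradients.** Where $|\nabla V|^2 < \varepsilon$
($\varepsilon = 10^{-10}$) the normal/tangent split is undefined; both
parts are set to $\tfrac12 \nabla^2 V$, which preserves the exact identity
$V_{NN} + V_{TT} = \nabla^2 V$ everywhere instead of silently dropping the
diffusion term. Above the threshold the exact denominator $|\nabla V|^2$
is used, so the identity holds to machine precision.

**Time stepping.** Explicit forward Euler. For the combined
diffusion-plus-data update the worst von Neumann amplification factor on
the unit grid is $1 - \Delta t\,(8 D_{\max} + B_{\max})$, where $D_{\max}$
is the largest diffusion coefficient ($\mu$, or $\max g$) and $B_{\max}$
the largest data coefficient ($\max |\nabla f|^2$, or $\max h$). The
default $\Delta t$ is 90% of the resulting bound $2/(8 D_{\max} +
B_{\max})$. The often-quoted $\Delta t \le 1/(4\mu)$ rule ignores the data
term; at that step size the GVF iteration on a binary disk visibly
diverges, which is why the sharper bound is the default (a user-supplied
$\Delta t$ is still validated against $\Delta t\, D_{\max} \le 1/4$, a
necessary condition).

**Residual.** Every solve records the per-iteration RMS of the PDE
right-hand side — zero exactly at the method's equilibrium. For the linear
schemes (GVF/GGVF) this residual decays monotonically. For the nonlinear
normal/tangent schemes it decays with occasional $\sim 10^{-5}$ upticks
where the diffusion front passes through pixels whose local gradient
direction flips; this is intrinsic to the nonlinearity (the RMS residual
of a nonlinear scheme is not a Lyapunov function), so monotonicity should
be checked at checkpoint spacing rather than per iteration.

**Snake evolution.** Semi-implicit: internal forces through the classical
cyclic pentadiagonal system $(\gamma I + A)\,p_{t} = \gamma\,p_{t-1} +
\kappa\,V(p_{t-1})$, with $A$ built from the second ($\alpha$) and fourth
($\beta$) cyclic differences — unconditionally stable in the internal
terms; the external force is sampled by bilinear interpolation and treated
explicitly. The contour is resampled to uniform 1-px arc-length spacing
every 5 iterations (linear interpolation along segments) and the iteration
stops when the mean displacement drops below `tol`.

**Rasterization.** `contour_to_mask()` marks pixel centers inside the
polygon by an even–odd crossing test; centers exactly on an edge count as
inside, and a polygon whose shoelace area is below half a pixel produces
an empty mask. The implementation is cross-checked against an independent
point-in-polygon routine in the test suite.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $\mu$ | isotropic smoothing weight (GVF/NGVF/NBGVF) | 0.2 | customary GVF setting; raise with noise |
| $K$ | decay constant of $g, h$ (px of edge-gradient) | per experiment | larger $K$ = more smoothing; benchmark settings: $\{K,\tau\}$ = {0.1, 1} (clean phantoms), {1, 0.5} (indentation), {0.1, 0.2} (noisy) |
| $\tau$ | edge-intensity threshold of $h_s$ | per experiment | in $[0.2, 1]$ on the normalized edge map |
| `n_iter` (field) | PDE iterations | 100 | classical budget; end-to-end phantom runs here use 500–2000 so the field is at equilibrium at 64 px |
| $\sigma$ | Gaussian pre-smoothing of the edge map | 0 | binary phantoms need none; 1 px for noisy images |
| $\alpha, \beta$ | snake tension, rigidity | 0.1, 0.1 | tuned once on the disk phantom and frozen |
| $\gamma$ | viscosity | 1 | step-size scale of the implicit solve |
| $\kappa$ | external force weight | 0.5 | with a unit-normalized field the external step is $\kappa/\gamma$ px per iteration; 0.5 keeps it inside the ~1 px edge transition so the displacement-based stopping rule can actually fire (at $\kappa = 2$ the contour jitters $\pm 2$ px indefinitely) |
| `tol` | mean-displacement stop | 0.05 px | subpixel settle |

The final field is unit-normalized before snake evolution by default
(`normalize = TRUE`): magnitude-normalized external forces decouple the
step size from local field strength and are standard practice for
gradient-vector-flow snakes.

## The synthetic phantoms and what they do (not) show

`make_phantom()` renders binary two-level images with exact ground-truth
masks: a disk, a square, a U-shape (a square blob with a wide opening —
the classical concavity-convergence test) and an LTI image (long thin
indentation: a blob with a slot of *even* pixel width, default 4 px,
depth 60% of the blob side — the classical failure case of
gradient-vector-flow fields, whose opposing wall gradients cancel across
an even-width slot). Default canvas 64×64 for tests, 256×256 for demos.
Noise corruptions: salt–pepper at density $D$ (exactly
$\operatorname{round}(D \cdot N)$ distinct pixels forced to 0 or 1 with
equal probability — a deterministic-count variant chosen so tests can
assert exact counts; the common convention draws per-pixel Bernoulli
trials) and zero-mean multiplicative (speckle) noise $I + nI$ with $n$
uniform of variance $V$, clipped to $[0,1]$.

These phantoms emulate the *geometry* stressed by the benchmark — capture
range, concavities, thin slots, impulse and speckle noise — but not the
properties of real infrared captures: spatially varying background,
low-contrast soft edges, sensor non-uniformity, resolution. Passing the
phantom suite therefore validates the mechanics of the fields and the
snake, not performance on any particular imaging modality.

**Problem sizes.** All routine tests run at 64×64 (fields at 500–2000
iterations, snakes at 100–3000); these sizes put every field at numerical
equilibrium (residual $\le 10^{-3}$) while keeping the full suite fast,
and 64–128 px is where the published phantom experiments of this family
are customarily reproduced.

## Design choices where the design was open

- **Normal/tangent formulas.** The source's printed pair for
  $V_{NN}/V_{TT}$ has identical symmetric terms differing only in the
  cross-term sign, which cannot sum to the Laplacian; the standard second
  directional derivative forms are used instead (they are what the
  NGVF/NBGVF lineage requires).
- **Sign of the data term.** The intermediate PDE form carries
  $+h(V-\nabla f)$ while the final evolution equation carries
  $-h(V-\nabla f)$; the minus sign is used — it is the gradient-descent
  direction toward the stated equilibrium, and the plus sign diverges.
- **$h_s$ argument.** The coefficient is evaluated on the normalized
  edge-map intensity (not its gradient), which is the model's stated
  point; where its definition writes $|e|$ and $f$ interchangeably they
  are read as the same quantity.
- **Convexity naming.** The cubic branch is concave on $(0, \tau)$
  despite the "convex form" label; it is implemented as printed.
- **Energy functional.** The printed energy for the combined model is
  typographically garbled; the PDE (its stated Euler–Lagrange descent) is
  the implemented object.
- **Grayscale weights.** Rec. 601 luma (0.299, 0.587, 0.114).

## Known limitations

- The even-width LTI slot is segmented only to its mouth at 64-px desk
  scale: at equilibrium the in-slot downward field component is of order
  $10^{-3}$ of the wall-directed component (walls anchor the field in
  $\pm x$), so after magnitude normalization no parametric snake with
  nonzero tension can descend the slot. What *does* distinguish the
  convex-coefficient field — verified by the test suite — is the sign
  structure: its vectors point down the full indentation axis, while
  GVF/NGVF/NBGVF develop upward (repelling) mid-slot components.
  Reported full-slot convergence in this model family relies on
  component-wise normalization, a different external-force construction
  that is out of scope here.
- Topology changes (splitting/merging), geometric/level-set contours and
  region-based energies are out of scope.
- The explicit field solver is $O(\text{pixels} \times \text{iterations})$;
  no multigrid or implicit acceleration is provided.

## A worked run

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec("disk", radius = 20))
f <- edge_map(ph$image)
V <- solve_field(f, field_config("proposed", K = 0.1, tau = 1, n_iter = 500))
init <- make_initial_contour("ellipse", c(32.5, 32.5), c(56, 56),
                             n_points = 100)
fit <- evolve_snake(init, V, snake_config(n_iter = 250))
mask <- contour_to_mask(fit$contour, dim(ph$mask))
evaluate_mask(mask, ph$mask)
autoplot(fit, image = ph$image)
```
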