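---
title: "Level-set refinement and evaluation of liver segmentations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-set refinement and evaluation of liver segmentations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrefine)
```

## Scope and data model

`segrefine` post-processes and evaluates binary 3D segmentations of the
liver parenchyma in contrast-enhanced T1-weighted MR volumes. Its two core
objects are a `volume` (3D scalar grid plus voxel spacing in mm) and a
`binary_mask` (same grid restricted to {0, 1}). The axis convention is
fixed throughout: axis 1 sagittal, axis 2 coronal, axis 3 axial, so
`data[, , k]` is an axial slice. NIfTI files carrying a spatial transform
are reoriented to the closest-to-RAS orientation on load so "axial" is
well defined; files without a transform are taken as already following the
convention.

The package does not train networks. It takes a network's binary
prediction as given (or manufactures one with known flaws, below) and
covers what happens next: level-set refinement, metric evaluation, and the
loss-function reference implementations that document how such networks
are trained.

## The refinement model

Refinement is distance-regularized level-set evolution (DRLSE) applied
independently per axial slice. The level-set field $\phi$ is negative
inside the contour; the slice's prediction initializes it as a binary step
$\phi_0 = \pm c_0$ ($c_0 = 2$). The evolution is the gradient flow

$$\frac{\partial\phi}{\partial t}
  = \mu\,\mathrm{div}\!\left(d_p(|\nabla\phi|)\nabla\phi\right)
  + \lambda\,\delta_\epsilon(\phi)\,
    \mathrm{div}\!\left(g\frac{\nabla\phi}{|\nabla\phi|}\right)
  + \alpha\,g\,\delta_\epsilon(\phi),$$

with the edge indicator $g = 1/(1+|\nabla(G_\sigma * I)|^2)$ computed once
per slice. The three terms are: distance regularization (keeps $\phi$
close to a signed-distance profile near the contour, via the double-well
potential with minima at $|\nabla\phi| = 0$ and $1$), the length term
(shortens/smooths the contour, weighted by $g$ so smoothing relaxes at
edges), and the area term ($\alpha < 0$ inflates a contour initialized
inside the organ; $g$ throttles the inflation at edges). $\delta_\epsilon$
is the cosine-bump regularized Dirac delta of width $\epsilon$,
concentrating all forces near the zero level set. The functional forms of
$d_p$ and $\delta_\epsilon$ follow the standard DRLSE formulation; they
are not free parameters here.

### Parameters, defaults, and their meaning

| parameter | default | meaning |
|---|---|---|
| `alpha` | −5 | area coefficient; negative = expand an inside-initialized contour |
| `lam` | 5 | length (smoothing) coefficient |
| `mu` | 0.2 | distance-regularization weight; must satisfy `mu * dt < 0.25` |
| `epsilon` | 0.2 | Dirac width (voxels of $\phi$) |
| `sigma` | 0.2 | Gaussian width of the edge-indicator pre-smoothing (voxels) |
| `dt` | 1 | explicit-Euler time step |
| `inner_iters`, `outer_iters` | 45, 25 | total updates = product; outer iterations are checkpoints |
| `c0` | 2 | binary initialization height |
| `intensity_scale` | 255 | working intensity range of the evolution (below) |

`alpha`, `lam`, the iteration pair, `dt`, `epsilon` and `sigma` are the
optimum reported for this refinement task; `mu = 0.2` and `c0 = 2` are the
standard DRLSE choices the task's parameter set was derived from.
`epsilon = 0.2` is notably smaller than common DRLSE practice (1.5): the
Dirac band is narrower than one voxel, so once the field has relaxed to a
unit-slope profile the contour is usually lattice-pinned and the
refinement makes small, local adjustments rather than large excursions.
That matches the intended use — a near-correct network prediction needs
nudging toward edges, not re-segmentation.

### The working intensity scale

The edge indicator has no gain factor, so it is *scale-dependent*:
$g = 1/(1+|\nabla I|^2)$ only falls well below 1 when intensity
differences per voxel are large compared to 1. The DRLSE coefficient
regime above originates from 8-bit image scales, where interior texture
and noise keep $g \approx 10^{-2}$–$10^{-1}$ and organ edges drive
$g \approx 10^{-4}$ — the force balance that makes the contour creep
through homogeneous tissue and stop dead at edges. On intensities
normalized to $[0,1]$ the same coefficients are far above the explicit
scheme's stability range ($\delta_\epsilon$ peaks at $1/\epsilon = 5$, so
the per-step area force reaches $|\alpha| \cdot 5 = 25$ against a field of
height 2) and the contour degenerates. `refine_volume()` therefore
min-max normalizes the volume and multiplies by
`intensity_scale = 255` before computing $g$; the option is exposed for
users who want the unit-scale behavior (`intensity_scale = 1`) or who pass
native-scale data. This is a numerical-conditioning choice, not a change
to the model: the PDE and all coefficients are exactly as stated.

### Discretization

All spatial derivatives are central differences on the unit voxel lattice
(in-plane anisotropy is ignored during evolution; only HD95 uses physical
spacing — MR in-plane spacing is near-isotropic). Boundaries are replicate
(Neumann). $|\nabla\phi|$ is floored at $10^{-10}$ in the normal vector.
The distance-regularization divergence uses the decomposition
$\mathrm{div}((d_p-1)\nabla\phi) + \nabla^2\phi$ with the five-point
Laplacian. Updates are explicit Euler, `inner * outer` of them, with $g$
frozen per slice; foreground is $\phi < 0$ (ties to background). The
evolution is fully deterministic, and slices with an empty initial mask
are passed through unchanged — a field at $+c_0$ everywhere has no zero
crossing, $\delta_\epsilon$ vanishes, and nothing can move. The inner
loop is compiled (Rcpp); a slice update pass is two sweeps of the grid.

### Parameter sweeps

`parameter_sweep()` evaluates `refine_volume()` over the grid
$\alpha \in [-3,-7]$, $\lambda \in [3,7]$, iteration pairs $(x,x)$,
$x \in \{5,15,\dots,65\}$ by default, reporting mean Dice/Jaccard/OS/US/
HD95 per point and the argmax-mean-Dice winner. Ties break
deterministically to the first point in grid order (iteration pairs vary
slowest, then $\lambda$, then $\alpha$); failed cases exclude the grid
point from ranking but stay in the report.

## Evaluation metrics

From voxel confusion counts (TP, FP, FN, TN over the full grid):
Dice $= 2TP/(2TP+FP+FN)$, Jaccard $= TP/(TP+FP+FN)$,
OS $= 2FP/(|GT|+|Pred|)$ and US $= 2FN/(|GT|+|Pred|)$ with
$|GT| = TP+FN$, $|Pred| = TP+FP$. Two identities follow algebraically and
are enforced by tests on every evaluated pair: $OS + US = 2(1-\text{Dice})$
and $\text{Jaccard} = \text{Dice}/(2-\text{Dice})$. US ranges up to 2 (an
empty prediction against nonempty truth). Both-empty pairs are defined as
perfect (Dice = Jaccard = 1, OS = US = 0, HD95 = 0): the degenerate case
must be fixed by convention, and "no disagreement" is the least surprising
one.

HD95 is computed symmetrically: boundary voxels are foreground voxels with
a face-adjacent background neighbour (grid exterior counts as background),
scaled to physical mm by the voxel spacing; each directed
nearest-neighbour distance set is reduced to its 95th percentile (linear
interpolation between order statistics, R's default quantile type 7,
pinned so results are bit-stable) and the larger directed value is
returned. The percentile is applied before the max, and the distance is
`NA` when exactly one mask is empty. `border_strip(mask, k)` is erosion by
a $k^3$ cube (odd $k$), implemented as separable per-axis running minima;
it removes a $(k-1)/2$-voxel boundary shell so the same metrics can be
read on the inner region, where leakage and boundary noise do not
dominate. `combine_masks()` provides the logical-or and Hadamard-product
combinations used when comparing against multiple corrected references.

## Loss functions

`dice_loss()`, `generalized_dice_loss()` and `tversky_loss()` operate on
flat vectors in $[0,1]$ — soft counts ($TP = \sum p\hat p$ etc.) so the
same code serves binary evaluation and differentiable-training reference
values; hard binary input is the special case. The Tversky weights must
satisfy $\alpha+\beta = 1$, $\beta \ge \alpha$ (false negatives weighted
at least as heavily as false positives); at $\alpha=\beta=0.5$ the Tversky
index reduces exactly to the Dice score, and the four standard sweep
presets are exposed as `tversky_presets()`. Two deliberate fidelity
choices: the smoothing constant $\epsilon = 10^{-6}$ enters numerator and
denominator of the Dice loss exactly as printed in its source; and the
generalized Dice weight defaults to the prediction-based first-power form
$w_l = 1/\sum_n \hat p_{ln}$ as printed there, with
`weighting = "squared_gt"` switching to the conventional
$1/(\sum_n p_{ln})^2$ — the printed form is unusual and possibly a typo in
its source, so both behaviors are available, defaulting to the printed
one. Under the $\alpha+\beta=1$ constraint the Tversky loss is monotone
non-decreasing in $\beta$ exactly when $FN \ge FP$ (raising $\beta$
necessarily lowers $\alpha$).

## Augmentations

`apply_augmentations()` reproduces the seven on-the-fly training
transforms — intensity scaling, gamma contrast, Gaussian smoothing,
Gaussian sharpening, flipping, rotation, elastic 3D deformation — each
applied independently with probability 0.3, all draws from one seeded
stream. Documented choices where no numeric ranges were specified
upstream: scale factor U(0.9, 1.1), gamma U(0.7, 1.4), smoothing
$\sigma$ U(0.25, 1) voxels, unsharp amount U(0.1, 0.5), elastic
displacement U(1, 4) voxels on an 8-voxel control grid — conservative,
visually plausible ranges, all exposed in the config. The flip axis is
drawn uniformly from {1, 2, 3}, one axis per draw; rotation is about the
axial axis only (U(−0.4, 0.4) rad), the anatomy-preserving choice.
Spatial transforms resample the mask nearest-neighbour so it stays exactly
binary; intensity transforms never touch it.

## The phantom

`generate_phantom()` builds the test scene the clinical data cannot ship
with: a bright ($0.75$) smoothly deformed superellipsoidal liver over dark
background ($0.15$), an adjacent ellipsoidal confounder organ at $0.65$ —
within the configured `edge_weakness` of the liver, manufacturing the
weak-edge contact through which real segmentations leak — two hypo-intense
spherical lesions inside the parenchyma (included in the ground-truth
mask, as the parenchyma is delineated as a whole organ), and additive
Gaussian noise ($\sigma = 0.02$). Default grid 64×64×32 at 1×1×2 mm: large
enough that a 2-voxel boundary error is clearly sub-organ scale, small
enough that the full refine-and-evaluate suite runs in minutes on one CPU.
The ground truth is guaranteed a single 6-connected component with ≥2
voxels of margin. `perturb_mask()` produces the four documented failure
modes (uniform boundary erosion; localized boundary leakage; dropped
lesion; punched interior holes), each one-directional by construction so
tests can assert FP = 0 or FN = 0 exactly. Everything is bit-reproducible
from the `phantom_spec()` seed.

What the phantom does *not* emulate: MR bias fields, acquisition-protocol
contrast differences, partial-volume boundaries wider than one voxel,
vessels and bile ducts, or anatomically realistic liver shape. Tests
passing on the phantom therefore demonstrate the algorithmic properties
(edge-seeking expansion, stability on correct masks, metric correctness) —
not clinical performance on MR data.

## Numerical and degenerate-input conventions

* Min-max normalization of a constant volume returns all zeros with a
  warning.
* Masks resample nearest-neighbour only; requesting linear interpolation
  is an error rather than a silent re-threshold.
* Resampling preserves physical extent exactly: output spacing is input
  spacing times the shape ratio.
* `hd95()` on an empty mask is an error when called directly; inside
  `evaluate_pair()` it becomes `NA` (one empty) or 0 (both empty).
* A single-report summary defines SD = 0 with a warning.
* Non-finite level-set fields abort with the failing outer iteration in
  the message; `mu * dt >= 0.25` is refused unless explicitly overridden.

## Problem sizes used by the test and acceptance runs

Metric identity and oracle checks use 200 pairs at $8^3$ and 50 pairs at
$16^3$ — large enough to exercise every confusion-count regime, small
enough for brute-force oracles. Refinement properties run the five-seed
default phantom suite (64×64×32) at the full default 45×25 iterations;
the restricted sweep uses two grid points over the same suite. These sizes
were chosen as the smallest configurations at which each property is
meaningfully exercised.

## Known limitations

* The evolution is 2D slice-wise; restacked masks can show slice-to-slice
  steps that a volumetric level set would avoid.
* With the narrow default Dirac ($\epsilon = 0.2$) the contour moves
  conservatively; under-segmentations deeper than a few voxels are only
  partially recovered (Dice improves on every suite case, but does not
  return to 1).
* The edge indicator stops contours at *any* strong edge, including lesion
  boundaries near the organ surface.
* A weak-edge contact (contrast gap below noise scale) will eventually
  leak if the evolution is run long enough; the iteration budget is part
  of the parameter optimum for a reason.
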