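# segrefine

Post-processing and evaluation of automated 3D liver parenchyma
segmentations.

Automated (deep-learning) liver segmentation of contrast-enhanced
T1-weighted MR volumes is good but rarely clinically perfect: predictions
under-segment boundaries, leak into adjacent organs with similar
enhancement (heart, spleen, stomach, kidney), miss peripheral lesions, and
leave holes. `segrefine` implements the two halves of the workflow that sit
around the network:

* **Refinement** — distance-regularized level-set evolution (DRLSE),
  applied independently to every axial slice of a binary prediction mask,
  using the prediction as the initial contour and the image's edge
  structure to move it. The gradient flow is

  ∂φ/∂t = μ div(d_p(|∇φ|)∇φ) + λ δ_ε(φ) div(g ∇φ/|∇φ|) + α g δ_ε(φ),

  where φ is the level-set field (negative inside the contour),
  g = 1/(1+|∇(G_σ∗I)|²) the edge indicator, δ_ε a regularized Dirac delta,
  d_p the double-well distance-regularization response, λ the length
  (smoothing) coefficient and α the area coefficient — negative α expands a
  contour initialized inside the organ. Defaults are the study optimum
  α = −5, λ = 5, 45 inner × 25 outer iterations, Δt = 1, ε = 0.2, σ = 0.2.

* **Evaluation** — the clinical metric suite: Dice similarity coefficient
  2TP/(2TP+FP+FN), Jaccard index TP/(TP+FP+FN), over-segmentation
  OS = 2FP/(|GT|+|Pred|), under-segmentation US = 2FN/(|GT|+|Pred|), and
  the 95th-percentile Hausdorff surface distance (HD95) in mm; plus
  border stripping (cube-erosion of the boundary shell so metrics can be
  read on the inner region), logical mask combinations (union / Hadamard
  product), and mean/SD/median/IQR aggregation.

It also ships reference implementations of the Dice, generalized Dice and
Tversky loss families used to train such networks (with the TL46/TL37/
TL28/TL19 weight presets), the seven seeded training augmentations, NIfTI
I/O with resampling and min-max normalization, and a **synthetic liver
phantom generator**: a deformed superellipsoidal bright organ with
hypo-intense lesions, a weakly contrasted adjacent confounder organ and
Gaussian noise, paired with systematically flawed "predicted" masks
(boundary erosion, localized leakage, dropped lesions, punched holes). The
phantom makes every pipeline stage testable without clinical data.

## Worked example

```r
library(segrefine)

# 1. simulate a study case: phantom + systematically flawed prediction
ph   <- generate_phantom(phantom_spec(seed = 0))
init <- perturb_mask(ph$gt, "erode_boundary", magnitude = 2)

# 2. evaluate the flawed prediction against ground truth
evaluate_pair(ph$gt, init, volume_id = "seed0/eroded")
#>   volume_id     dice jaccard    os    us hd95_mm
#> 1 seed0/eroded 0.713   0.554     0 0.574    4.90

# 3. refine it with slice-wise DRLSE at the study-optimum parameters
refined <- refine_volume(ph$volume, init, drlse_params())
evaluate_pair(ph$gt, refined, volume_id = "seed0/refined")
#>   volume_id      dice jaccard        os    us hd95_mm
#> 1 seed0/refined 0.755   0.606 0.0000588 0.491    4.58
```

Reading the numbers: the eroded "prediction" has OS = 0 (erosion creates no
spurious voxels) and US = 0.574 — all of its disagreement is missed
boundary. Refinement expands the contour back towards the image edge:
Dice rises from 0.713 to 0.755, US drops, and the almost-zero OS shows the
edge indicator halting the contour at the organ boundary rather than
letting it leak into the neighbouring structure. Border-stripped variants
(`border_strip(mask, 5)` before `evaluate_pair()`) re-read the same
comparison on the inner region only.

A parameter sweep over the study grid (α ∈ [−3, −7], λ ∈ [3, 7],
iteration pairs (x, x), x ∈ {5, 15, …, 65}) is one call:

```r
suite  <- make_suite(5, modes = "erode_boundary", magnitude = 2)
report <- parameter_sweep(suite)   # tibble + attr(report, "best")
autoplot(report)
```

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/segrefine.R`:

```sh
Rscript inst/cli/segrefine.R phantom --out work --n 5 --seed 0
Rscript inst/cli/segrefine.R refine  --image img.nii.gz --mask pred.nii.gz \
        --out refined.nii.gz --alpha -5 --lam 5 --inner 45 --outer 25
Rscript inst/cli/segrefine.R eval    --gt gt.nii.gz --pred refined.nii.gz --strip 5
Rscript inst/cli/segrefine.R sweep   --config sweep.yaml --csv grid.csv
```

Exit codes: 0 success, 2 usage, 3 input/format, 4 computation. A YAML
config supplies defaults; flags win; the resolved configuration is echoed
to stderr as valid YAML.

## Vignette

`vignettes/segrefine-methods.Rmd` documents the model and its assumptions,
the parameter defaults and their provenance, the numerical scheme, what
the phantom does and does not emulate, and known limitations.
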