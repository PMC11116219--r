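---
title: "Image-based statistical shape models for cranial defect reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based statistical shape models for cranial defect reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cranioplasty needs a patient-specific implant: a piece of material that
exactly fills the hole a craniotomy or craniectomy left in the skull.
Designing that piece from a CT segmentation is a shape-completion problem —
given a *defective* binary skull mask, predict the *complete* skull and take
the difference. Learning-based completion methods are trained on synthetic
defects and often fail on large, irregular clinical ones, precisely because
they have learned what defects look like. A statistical shape model (SSM)
sidesteps the issue: it is trained on complete skulls only, so nothing in
the model depends on the defect at all.

`craniossm` implements such an SSM directly on the voxel occupancy grids of
segmentation masks, with no mesh conversion. The foreground voxels
themselves act as dense landmarks; correspondence across subjects is
established by registering every mask to a common reference with a
similarity transform (rotation, isotropic scale, translation).

## The model

Let $x_1, \dots, x_C$ be complete skull masks and $x_j$ the designated
reference. Every member is registered and resampled ("warped") onto the
reference grid, giving a $C \times |D_j|$ matrix $X'$ of flattened binary
shapes. The model is the classical linear shape model

$$ S \;=\; \bar S + \sum_{i=1}^{d_0} \lambda_i \, \Phi_i , $$

where $\bar S$ is the voxelwise mean of the warped shapes, the rows
$\Phi_i$ are principal modes of variation, and $\lambda_i$ are per-shape
weights. The modes are obtained from a PCA of the mean-centred $X'$; the
variation matrix is the product of the PCA scores with the Moore–Penrose
pseudo-inverse of the centred shape matrix, which makes projection
($\lambda = \Phi\,(y' - \bar S)$) and reconstruction
($\bar S + \lambda\,\Phi$) exact inverses on the training span. Because
$C \ll |D_j|$, the SVD is computed through the $C \times C$ Gram matrix;
this is algebraically identical to the full decomposition and is checked
against a brute-force eigendecomposition in the test suite.

Completion of a defective mask $y$ then runs:

1. register $y$ to the reference member, $y' = Tr(y)$;
2. project $y'$ onto the modes and reconstruct the *complete* skull
   $S = \bar S + \lambda \Phi$ (inverse PCA);
3. the missing part is the clamped subtraction $y_m = S \setminus y'$ on the
   binary grids;
4. invert the registration to bring $y_m + y'$ back to the patient's grid.

The simpler template route replaces step 2 by a fixed complete template —
a single reference skull or a binarized mean of the first $n$ warped members
(`mean_template()`). Either way the model reconstructs the whole skull and
never the implant directly, which is what makes the approach insensitive to
the defect pattern.

```{r pipeline}
library(craniossm)
cohort <- generate_cohort(20, phantom_spec(), seed = 42)
pool   <- build_pool(cohort, reference_index = 1)
model  <- fit_variations(pool)

defect <- apply_defect(cohort[[5]], defect_spec("sphere", size_fraction = 0.2))
res    <- complete_by_ssm(defect$defective, model)
implant <- extract_implant(res$missing_original)
evaluate_pair(res$completed_original, cohort[[5]])
```

## Registration

The registration objective is nowhere prescribed by the completion model, so
it is a package design choice: mean squared difference between
Gaussian-smoothed copies of the two binary masks (σ = 1 voxel at full
resolution), optimized over the 7 similarity parameters with Nelder–Mead on
a two-level shrink pyramid (factors 4 and 2) followed by a short BFGS polish
at full resolution. Smoothing gives the piecewise-constant masks a usable
gradient; the moment-based initialization (centroid translation, cube-root
volume-ratio scale, zero rotation) starts the search inside the correct
basin for anatomically plausible poses. Everything is deterministic — fixed
initialization, no random restarts — so a pipeline run is exactly
reproducible. The metric is evaluated on the padded bounding box of the
fixed foreground only; outside it both smoothed masks are zero and
contribute nothing.

A defective input biases any mask-to-mask registration: the optimizer tries
to explain the hole by shrinking or shifting the whole shape. The package
therefore re-registers once by default (`passes = 2`): the first pass's
completed skull — which has no hole — is registered to the reference and
the completion is recomputed with the refined transform. On phantoms with
25–30 % defects this recovers most of the bias; very large defects still
register slightly small, which is the main residual error source in the
benchmark and mirrors the known sensitivity of the approach to registration
accuracy.

## Warping and thresholds

Binary masks are resampled by trilinear interpolation of the occupancy
followed by thresholding at 0.5. Compared with nearest-neighbour sampling
this yields smoother warped surfaces, and hence cleaner subtraction borders.
The real-valued model reconstruction $\bar S + \lambda\Phi$ is binarized at
0.5 before subtraction as well; both thresholds are configurable. Weights
default to the raw PCA scores, which preserves the exact inverse-PCA
identity; min–max rescaled weights ($(\lambda_i - \min\lambda) /
(\max\lambda - \min\lambda)$, degenerating to zeros with a warning when all
weights are equal) are available as an option. The pseudo-inverse rank
cutoff is applied on the eigenvalue (variance) scale at $10^{-12}$ relative,
because the Gram-matrix eigenvalue noise floor would otherwise let
pure-noise null modes leak into the scores.

## Implant extraction

The raw subtraction result contains the implant plus noise from residual
misregistration. The automatic cleanup is: binary median smoothing (majority
vote over a $k^3$ window, default $k = 3$) to disconnect noise, a binary
opening (Euclidean-ball structuring element, radius 1 by default; a
Chebyshev box is available — a ball rounds convex corners, a box preserves
axis-aligned solids exactly), then connected-component analysis keeping the
largest component(s). Equal-size ties break toward the component appearing
first in raster order, so extraction is deterministic. When several
comparably sized components survive, the result is flagged for manual
review rather than silently guessed at.

One subtlety is worth recording: with the median step disabled the pipeline
(opening + component selection) is exactly idempotent, and the tests assert
this. The median filter itself is not — majority smoothing acts like a
discrete curvature flow on voxelized curved surfaces, so re-applying it
keeps nibbling staircase corners. The default keeps the median (it is what
makes the noisy subtraction results separable at all); a strictly stable
operator is available via `median_kernel = 1`.

## Metrics

`dsc()` is the standard volumetric Dice overlap (two empty masks score 1).
`border_dsc()` is a surface Dice at a distance tolerance: boundary voxels
(foreground with a background face-neighbour) of either mask count as
matched when they lie within the tolerance (default: one voxel's physical
size) of the other mask's boundary. `hd95()` is the 95th percentile of the
pooled directed surface distances of both directions, which makes it
symmetric by construction; distances are exact Euclidean distances between
voxel centres in physical units, computed with a separable distance
transform and verified against brute-force all-pairs computations in the
tests. An empty mask yields an infinite Hausdorff distance with a warning.

## The phantom cohort

Real challenge datasets are hundreds of 512³ masks and cannot ship with a
package, so every stage is exercised on parametric phantoms: hollow
ellipsoidal shells with population variation. The cranium is structurally a
smooth closed shell, which is exactly the geometry these phantoms probe; a
phantom population is *not* anatomically realistic (no facial skeleton,
sutures, or thickness gradients — an optional frontal lobe appendage only
gestures at the cranium/face imbalance), so passing benchmarks here
demonstrates the correctness and stability of the pipeline, not clinical
accuracy.

The cohort defaults, chosen once as the package's study conditions: 64³
grid at 1 mm spacing; outer semi-axes (24, 20, 17) voxels; shell thickness
5 ± 1 voxels; global size ±7 % (absorbable by the similarity transform);
per-axis shape jitter ±6 % (not absorbable — this is the anatomy the PCA
must learn); rotations up to ±8° per axis; translations up to ±3 voxels.
Defect generators cut spheres, cubes, multi-lobe and crown-crossing regions
whose volume is bisection-calibrated to a requested fraction of the shell,
and return the exact defective/implant partition as ground truth.

The benchmark sizes used throughout the tests and the acceptance script: a
20-member training pool, 10 defective test subjects with defects from 10 %
to 30 % of the shell (including a two-lobe case), all at 64³. On these
conditions the pipeline reaches a mean completed-skull Dice around
0.94–0.95 and a mean extracted-implant Dice around 0.78–0.83 (the spread is
across cohort seeds), with the largest spherical defects (≥ 25 %) the clear
worst cases — both numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the acceptance tests.

## Known limitations

* Similarity registration cannot express inter-subject anisotropy; what it
  cannot absorb must be spanned by the linear modes, and for shapes far from
  the training distribution the projection extrapolates without warning.
* Very large defects still bias the registration even with the refinement
  pass; the completed skull then sits 1–3 % small in scale.
* The linear combination of binary indicator shapes is real-valued; all
  surface positioning finer than the 0.5-threshold crossing is lost.
* Only axis-aligned grids are supported; oblique acquisitions must be
  resampled upstream.
* The manual scissors-style cleanup of pathological extraction cases is out
  of scope by design; the QC flag marks where it would be needed.
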