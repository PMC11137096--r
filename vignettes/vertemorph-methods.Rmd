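---
title: "Methods: shape modelling, mesh morphing and cohort validation in vertemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape modelling, mesh morphing and cohort validation in vertemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertemorph)
```

`vertemorph` builds statistical shape models (SSM) of corresponding
anatomical point sets, morphs hexahedral finite-element templates onto them,
and validates the resulting virtual cohorts. This vignette documents the
models, their assumptions, the parameters that matter, and the choices made
where the design was genuinely open. Units are millimetres and degrees
throughout; the anatomical frame is x lateral, +y anterior, z cranial, with
the sagittal plane fixed as y–z.

## Shape families and alignment

A *shape* is an ordered set of P points; correspondence across a family is
positional (row i of every shape is the same anatomical point). Rigid pose
is removed by Generalized Procrustes Alignment: every shape is aligned to a
reference by the SVD-based least-squares rotation+translation (no scaling,
reflections excluded by sign correction), the mean is recomputed, and the
process iterates with the mean as the new reference. Open choices and their
resolutions:

* the iteration-0 reference is the first shape in input order;
* the mean is re-centred at the origin each iteration, fixing the
  translational gauge (the rotational gauge is set by the first reference);
* convergence is declared when the RMS movement of the mean falls below
  `tol = 1e-6` mm, with `max_iter = 100`; non-convergence warns rather than
  failing silently.

These are conventions of this implementation, not claims about how any
particular published family was aligned.

## The PCA shape model

With flattened shapes `x_i` (3P-vectors, column-major x/y/z blocks), the
model is the eigendecomposition of the sample covariance. Because 3P is
typically much larger than n, the decomposition is computed in the *dual*
(Gram) form: the n×n matrix `D Dᵀ/(n−1)` shares the covariance's nonzero
spectrum and its eigenvectors lift to 3P space by multiplication with `Dᵀ`.
The suite verifies equality with the dense-covariance decomposition on small
instances (P ≤ 20, n ≤ 12) to 1e-8.

Shapes are generated as `mean + Σ √d_i · φ_i · w_i` with weights in SD
units; cohort sampling restricts `w` to integer levels in [−3, 3]. The
quality triad is computed as:

* **compactness** — cumulative eigenvalue fraction;
* **generalization** — deterministic leave-one-out folds; the left-out shape
  is reconstructed by projection onto the fold model's modes. A
  learning-curve variant (random training subsets, explicit seed) is
  exposed as `n_train`;
* **specificity** — N = 1000 random samples by default, each component
  standard normal truncated to ±3 SD (the truncation is this package's
  convention; a plain "randomly generated" prescription underdetermines
  the distribution), scored by distance to the nearest training shape.

Reconstruction error is reported as the root-mean-square per-point Euclidean
distance ("RMSE"); a mean-distance option exists because the two labels are
often conflated in the literature. Note that with per-coordinate noise σ,
the per-point RMSE aggregates three coordinates: the noise floor is
σ·√(3(3P−m)/3P) ≈ 1.73σ, and the tests assert that closed form rather than
a naive σ band.

## Non-rigid registration

Registration follows the coherent-point-drift family: the moved set's points
are Gaussian mixture centroids with shared isotropic variance σ²; a uniform
component absorbs the expected outlier mass ω. EM alternates
responsibilities (computed in the log domain, so underflow never produces
NaN) with an M-step over either

* a rigid transform (correspondence-weighted Procrustes), or
* a smooth displacement field `T(Y) = Y + G W`, where `G` is a Gaussian
  kernel of width `beta_smooth` on the template points and `W` is penalized
  by `lambda_deform` (the deformation-magnitude prior). The linear system is
  solved in the row-scaled form `(d(P1) G + λσ² I) W = P X − d(P1) Y`, which
  stays well-conditioned even when individual responsibilities underflow; a
  1e-10 identity ridge guards the fully annealed limit.

The point estimate is the MAP/EM solution; no posterior sampling is
performed (the Bayesian formulation itself reduces the posterior to its mean
or mode for this purpose). The penalized negative log-likelihood is
monitored and is non-increasing (generalized EM), which the suite asserts.
σ² collapse below 1e-12 triggers a clean, flagged stop.

Defaults mirror the published initial parameter set for spine template
morphing: λ = 2, β = 8, initial-matching randomness γ = 2 (scales the
initial σ²), ω = 0.10, at most 1000 iterations, tolerance 1e-15. Two
parameter-sheet rows are both labelled "Lambda" in that source; they are
mapped here to `lambda_deform = 2` and `beta_smooth = 8`, an interpretation
recorded as such. The Nyström/neighbour-search acceleration parameters are
accepted for provenance but the computation is exact at desk scale — at a
few hundred to a few thousand points the dense solve is cheap and removes an
approximation from the validation chain.

Two useful limits are verified numerically: `lambda_deform = 1e9` reproduces
rigid registration to 1e-4 mm (the standard trick for rigid pre-alignment
with a non-rigid code), and registration commutes with common rigid
transforms of both sets.

**Multi-layer refinement.** After registration, the maximum per-point
Euclidean distance from the deformed template to its nearest target point is
measured (a mean-distance option exists). If it is ≥ 0.04 mm, the output
becomes the new template and registration repeats — re-anchoring the kernel
on the deformed geometry adds flexibility exactly where the previous layer
left residuals. Layers stop on success, on budget exhaustion, or when a
layer improves the distance by less than 1 % (both flagged, never raised).
The optional 90° y-rotation pre-step reproduces the delivery pose of the
original vertebra templates; synthetic templates built in the target frame
disable it.

**A note on fixtures.** Point-set registration on a 1-D curve admits
tangential sliding: the geometry converges while the displacement field is
wrong. Registration fixtures are therefore 2-D surface grids with
normal-dominant planted warps, on which the field itself is recovered to
below 10 % of a 2 mm amplitude. Passing tests on such fixtures demonstrate
correct EM mechanics and field recovery for well-posed surfaces; they do not
bound errors on strongly self-similar anatomies, where multi-layer
refinement and the rigid pre-step carry more of the burden.

## The synthetic IVD template

The real morphing workflow tailors a validated hex20 disc template; that
mesh is not redistributable, so the package constructs a synthetic
structured hex8 analogue with the same controlled anatomy:

* box-section footprint (50 × 35 mm), central height 10 mm;
* the nucleus pulposus (NP) is the central quarter of the footprint, so its
  mid-plane transverse area share is **exactly 25 %** by construction;
* the annulus fibrosus (AF) half-height tapers linearly towards the rim; the
  taper slope is calibrated once at build time by bisection on the *meshed*
  volumes so the NP occupies **40.0 %** of the AF+NP volume;
* two cartilage endplate (CEP) layers are extruded 0.7 mm along per-node
  surface normals (area-weighted averages of adjacent face normals, exact on
  planar patches). The measured per-element mean is 0.694 mm — the ≈ 1 %
  shortfall is the unavoidable crease effect of offsetting a faceted
  surface, well inside the 0.62 ± 0.29 mm acceptance band.

The volume denominator is AF+NP (the disc proper). With the thin CEP layers
included in the denominator, NP = 40 % of volume and 25 % of mid-plane area
are jointly unattainable for any template whose nucleus spans the core
height — the implied taper would drive the outer annulus height negative —
so the endplates are treated as vertebral-interface tissue, consistent with
how disc composition is usually quoted. The wedge taper this forces is
steep (rim height ≈ 1 mm against 10 mm centrally), which is also why the
template honestly reports a high aspect-ratio *warning* share at the rim
while keeping zero invalid elements.

Hex volumes use a five-tetrahedron decomposition with a fixed diagonal
convention (exact for affine bricks, reproducible for warped ones);
cross-section areas clip each hex against the plane and take the convex hull
of the edge intersections. Both make the fractions invariant under rigid
motion and uniform scaling, which the suite asserts.

**Proportion control.** After morphing, the NP fraction is restored by
radial rescaling about the nucleus centroid axis: each node's transverse
distance is remapped piecewise-linearly in its *reference* radial parameter
(NP interior scaled by s, annulus redistributed so the outer boundary is
fixed), and s is solved by bisection to `target ± 2e-4`. Whether the
published workflow controls proportions before, during or after
registration is unstated; post-correction was chosen because it composes
with any registration backend and is exactly measurable. Out-of-bracket
targets return the closest achievable fraction, flagged.

## Hexahedral SSM, cohorts, personalization

The hexahedral mean model is rigidly registered onto the triangulated mean
(GMM rigid regime), ICP builds the closest-point map, and every hexahedral
node inherits the √d-scaled mode rows of its mapped triangulated point,
rotated back into the hexahedral frame: `shape = hex_mean + DF · b`.
`b = 0` reproduces the template bit-exactly, and sampling is linear in `b`.
Cohorts are enumerated in odometer order (first mode slowest, 1-based IDs —
the published naming rule is not printed, so this convention is ours) and
written as one coordinate table per member plus a single template INP, the
coordinate-replacement convention for sharing large cohorts.

Personalization inverts the sagittal parameters: it minimizes the sum of
squared normalized errors of any subset of PI, PT, SS, LL over the bounded
weight box, each error normalized by that parameter's range across a
seven-level sweep of mode 1 (balancing degrees of different magnitude). The
search is a deterministic coarse grid (full factorial up to three modes,
cyclic coordinate sweeps beyond) followed by bounded L-BFGS-B refinement; no
randomness, so runs reproduce exactly. Out-of-reach targets (e.g. PI
inconsistent with PT+SS) return best-effort weights with a positive
residual. On planted problems the weights are recovered within 0.1 SD.

## Mesh quality and clinical annotation

Hex elements are checked at their Gauss points (8 for hex8, 27 for hex20)
via the isoparametric Jacobian; `ratio = min|det|/max|det|`, and any
non-positive determinant marks the element invalid for FE analysis. The
0.30–0.80 ratio band is reported as information, invalidity is keyed only to
non-positive determinants. Coincident element nodes are flagged explicitly,
because the determinant singularity of a collapsed corner sits at the corner
itself and can leave all interior Gauss points positive. Aspect ratio is the
longest-over-shortest edge (flag > 10); quad angles are interior corner
angles (flag > 160°), with bowtie orderings detected by opposite-edge
intersection in the Newell plane. Summary percentages recompute exactly from
the per-element flags.

Spinopelvic parameters are measured from named landmarks (femoral head
centres, S1/L1/L4 endplate points, T1/C7 centres, optional coronal endplate
pairs): SS against the horizontal, PT against the vertical at the femoral
heads, PI as the angle between the caudal sacral-plate normal and the line
to the bicoxofemoral midpoint (so PI = PT + SS holds by construction), LL
signed negative in lordosis, `LL-PI = PI − |LL|` (the convention forced by
the published exemplar, whose literal label subtraction would give −152°),
SVA as the anterior C7 plumb-line offset in mm, and cobb from the coronal
projection by maximizing the inter-endplate angle. The GAP score sums
category points for RPV, RLL, LDI and RSA (ideal values 0.59·PI+9,
0.62·PI+29, 50–80 %, 0.48·PI−15) plus an age point; the full
threshold/point table ships as an editable configuration
(`gap_config()`), and the printed components of the published exemplar
reproduce its score of 1 exactly. The age category is a required input —
it is not recoverable per model from published tables.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by design:
planted families of 10–200 shapes with 12–825 coordinates, registration
point sets of 100–350 points, an IVD template of 384 hex8 elements, and a
cohort sweep of 343 instances × 160 hexes (≈ 55 000 element checks). These
sizes were chosen as the smallest at which each property is
distinguishable from its failure mode with comfortable margins. All
stochastic fixtures are seeded; generators save and restore the caller's
RNG state; the pipeline fans one global seed into per-stage seeds by a
stable hash.

## Known limitations

* Anisotropic mixture covariances, posterior sampling, and Nyström-scale
  acceleration of the registration are not implemented.
* The INP dialect covers the geometry/sets/ties subset; steps, materials
  and loads are carried as opaque text.
* Mesh *repair* of invalid elements is detection-only; a repair hook can be
  layered on the quality report.
* The synthetic IVD template and spine landmark constellations are
  idealized geometries for method validation, not patient anatomies;
  passing tests on them does not certify accuracy on clinical meshes.
* Coronal (scoliosis) targets are measured but not used by personalization.
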