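---
title: "Dense surface-correspondence morphometrics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense surface-correspondence morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Comparative shape analysis of fragmentary skeletal surfaces — a single
frontal bone, say — is hard to do with classical landmark-based geometric
morphometrics: few reliable landmarks exist, observer error in placing them
can be large, and most of the preserved morphology lies *between* landmarks.
`densemorph` implements the almost landmark-free alternative: one reference
mesh is deformed onto every specimen so that all specimens end up described
by the *same* vertices in corresponding anatomical positions, and the dense
vertex coordinates become the shape variables.

The pipeline is

1. **mesh validation** — each specimen must be a single-layered triangular
   mesh (one connected component, no non-manifold edges, no duplicate
   faces);
2. **initial registration** — an interpolating 3D thin-plate spline (TPS)
   fitted to six cranial landmarks (bregma, ophryon, left/right
   frontotemporale, left/right stephanion) carries the reference onto each
   target;
3. **elastic ICP** — iterative closest-point matching with
   Gaussian-smoothed displacement fields deforms the TPS-warped reference
   until it hugs the target surface, without ever changing its vertex count
   or topology;
4. **optional k-means subsampling** — the dense correspondence is reduced
   to `k` representative vertices (real surface vertices nearest each
   cluster mean), chosen once on the reference and broadcast to all
   specimens;
5. **statistics** — Generalized Procrustes Analysis (GPA), shape PCA with
   out-of-sample projection and ±2 SD mean-shape warps, Procrustes and
   Mahalanobis distances, and static allometry against log surface area.

# Models and numerical choices

## Thin-plate spline

The 3D TPS uses the biharmonic kernel $U(r) = r$ (the 3D fundamental
solution; the familiar $r^2 \log r$ is the 2D kernel) and is interpolating —
no smoothing term — so it reproduces every control landmark exactly and
reduces to a pure affine map whenever the target landmarks are an affine
image of the source. Two numerical details matter in practice: the bordered
linear system is solved in a centered, unit-scale frame (its conditioning
degrades with raw coordinate magnitude) with one step of iterative
refinement, and kernel distances at evaluation time are computed from
explicit coordinate differences, because the expanded
$|p|^2 + |c|^2 - 2\,p\cdot c$ form cancels catastrophically near control
points. Together these keep control-point reproduction at ~1e-14 mm.

## Elastic ICP

Per iteration, every reference vertex (or a random fraction, see below) is
matched to its exact closest point on the target surface; the raw
displacement vectors are smoothed over the reference vertices with a
Gaussian kernel (Euclidean inter-vertex distances, truncated at 3 sigma,
weights normalized per vertex); each smoothed displacement is capped and a
fraction of it applied. The closest-point search is exact (grid-accelerated
point-to-triangle minimization, identical to brute force).

Tunable parameters (`icp_params()`), with units and defaults:

| parameter | default | units | role |
|---|---|---|---|
| `n_iterations` | 50 | — | annealing length |
| `sigma_range` | 10 → 0.5 | mean reference edge lengths | geometric decay of the smoothing bandwidth: global at first (near-affine corrections), local at the end (detail) |
| `step_fraction` | 0.5 | — | under-relaxation per iteration |
| `max_displacement` | 5 | mean edge lengths | per-iteration cap against runaway matches |
| `correspondence_mode` | surface | — | nearest point on surface (or nearest vertex) |
| `stochastic_fraction` | 1.0 | — | fraction of vertices whose correspondences are resampled per iteration |
| `rigid_iterations` | 10 | — | rigid ICP between TPS and elastic stage |

No published values exist for these constants; they were tuned once on the
synthetic suite and are fully exposed in the API and the run configuration.

Two design decisions deserve justification:

* **Rigid re-alignment after TPS.** Landmark placement noise enters the
  interpolating TPS as a spurious global pose component. The elastic stage
  pulls vertices toward the surface along (mostly) normal directions and
  cannot remove a tangential pose error on low-curvature surfaces, so a
  short rigid ICP (rotation + translation from closest-point matches) is
  run between the TPS warp and the elastic deformation. Disable with
  `rigid_iterations = 0`.
* **Where the stochasticity lives.** Repeated no-subsampling registrations
  of real datasets are known not to be bit-identical. This package
  localizes all stochasticity in two seed-controlled places — correspondence
  resampling (`stochastic_fraction < 1`) and k-means initialization — and
  offers a fully deterministic mode (`stochastic_fraction = 1`), in which
  the whole pipeline is bit-reproducible and all baseline correlations in
  the subsample-size protocol are exactly 1.

## Subsampling

k-means (k-means++ initialization, Lloyd iterations, best of 10 restarts)
partitions the *reference* specimen's vertex coordinates; within each
cluster the real vertex nearest the cluster mean is selected (ties broken
by lowest index), and the selected indices are applied to every specimen.
Clustering once on the reference is the only reading consistent with an
identical number of corresponding vertices across specimens — per-mesh
clustering would destroy the correspondence. Clustering uses raw (pre-GPA)
coordinates because subsampling happens inside the registration step,
before superimposition.

## GPA, PCA, distances

* GPA centers, scales each configuration to unit centroid size, and rotates
  it (optimal rotation, reflections disallowed — anatomical configurations
  must not mirror) onto the running mean until the mean moves < 1e-10. The
  initial mean is the first configuration posed canonically on its
  principal axes, which makes the output invariant (to ~1e-16) to arbitrary
  similarity transforms of any input.
* PCA operates on the flattened Procrustes coordinates directly (no tangent
  projection), centered on the fit subset's mean; all components are
  retained so variance fractions sum to 1 and PC-score distances equal
  Procrustes-coordinate distances. A focal specimen can be excluded from
  the fit and projected afterwards.
* Procrustes distances are computed *within the common superimposition*
  (the convention tied to reporting PDs on the superimposed dataset); a
  one-shot pairwise full-Procrustes alternative is exposed as
  `full_procrustes_distance()`.
* Mahalanobis distances to group means are computed in the leading-m
  PC-score subspace (default m = 2) with covariance shrinkage toward the
  diagonal (default lambda = 0.1): full vertex space is singular for groups
  of a few specimens. m and lambda are recorded in the output.
* Static allometry regresses the PC score on *natural-log surface area*
  (cm², measured on the registered, unscaled meshes — GPA has removed
  size); the signed Pearson r and r² are reported separately, with
  t = r·sqrt(df/(1−r²)), df = n − 2, two-sided p, and significance at
  alpha = 0.05.

## Subsample-size optimization

One reference iteration (no subsampling), `n_baseline` further
no-subsampling iterations whose correlations with the reference define the
baseline envelope, then one iteration per candidate k. Each iteration runs
the full registration → (subsampling) → GPA → PCA chain; specimen-pair
distance vectors over all PCs are compared to the reference iteration by
Pearson correlation. "Similar to the baseline" is operationalized as
r ≥ the baseline *minimum*, and the optimal k is the smallest candidate
satisfying it. On the smooth synthetic shapes the r-vs-k curve shows the
expected low-k degradation; because the discriminating shape features of
the synthetic world are global and smooth, the plateau can sit close to
the full vertex count — consistent with the general caveat that the optimal
subsample is feature-size dependent and must be evaluated per dataset.

# The synthetic world

`make_template()` builds an analytic open spherical-cap patch ("squama",
base radius 60 mm) with a Gaussian ridge along its anterior-inferior margin
(amplitude = `brow_prominence`, mm), a posterior shear (`squama_inclination`,
0–1), a lateral aspect factor (`squama_breadth`) and a global scale
(`size_scale`). The six canonical landmarks sit at fixed parametric
positions. Because the surface is analytic, two templates built at the same
resolution correspond vertex-by-vertex — the ground-truth oracle behind the
registration accuracy tests.

`sample_population()` draws per-specimen parameters from group
distributions (`size_scale` log-normally), couples `squama_inclination` to
log size via `allometric_slope` (static allometry), re-triangulates each
specimen at a ±10% jittered resolution (so targets genuinely lack vertex
correspondence with the reference), adds vertex jitter (default 0.05 mm)
and landmark placement noise (default 0.5 mm, chosen inside the 0.19–3.08 mm
range of repeat-placement distances reported for cranial landmarking).

What the generator deliberately does **not** emulate: anatomically
realistic frontal-bone geometry, CT segmentation noise, anisotropic
observer error, or a curvature field rich enough to anchor tangential
correspondence everywhere. The last point matters for interpretation: on a
near-spherical patch, sliding the surface over itself is invisible to any
closest-point criterion, so tangential correspondence is determined by the
(noisy) landmarks alone. Consequently landmark noise propagates into a
tangential correspondence error of roughly half the per-draw noise — far
more than on real bones, whose curvature anchors the match. A green
registration test therefore establishes that the machinery converges and
recovers injected shape differences; it does not establish real-data
buffering factors, and one group-recovery acceptance clause is left
honestly red for exactly this reason (see the test annotations).

Known limitations, in one place:

* ground-truth correspondence error is flat (~0.3 mm) across mesh
  resolutions — dominated by smooth tangential drift, not discretization;
* the landmark-noise floor on the synthetic geometry (~0.5 mm in, ~0.47 mm
  tangential out) is irreducible by schedule length, rigid alignment, or
  subsample size;
* Mahalanobis distances for small groups depend visibly on the chosen
  subspace dimension and shrinkage; treat patterns, not magnitudes.

# Decisions on open questions

* Units are assumed millimetres throughout; no auto-detection.
* Face indices are 1-based internally (the R convention); 0-based dialects
  (PLY, STL) are converted at the file boundary.
* The reference specimen enters its own analyses as the undeformed
  original, not a self-registered copy.
* In the optimization protocol, k-means is re-run per iteration with
  per-iteration seeds.
* A signed correlation labelled as R² in some published tables is reported
  here as what it is: the signed r, with r² alongside.
* Allometry regresses the PC score on log area (not area on score).
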