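---
title: "Dense quasi-landmark phenotyping of craniofacial bone surfaces"
author: "densecranio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense quasi-landmark phenotyping of craniofacial bone surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sparse manual landmarking of skull scans is slow, needs trained
observers and carries intra- and inter-observer error on the order of
a millimetre. Dense correspondence methods replace the 10–50 manual
landmarks with thousands of *quasi-landmarks*: the vertices of a fixed
template mesh ("mask") that is non-rigidly registered to every
individual surface, so that vertex *i* of the deformed template denotes
the same anatomical location on every skull. Once skulls are in dense
correspondence, any sparse landmark can be transferred automatically,
and standard geometric-morphometrics machinery — generalized Procrustes
analysis (GPA), centroid size, shape PCA — applies at full resolution.

`densecranio` implements this workflow end to end for craniofacial
bone surfaces from cone-beam CT (CBCT) and CT scans: surface
preparation (shrink-wrapping and isotropic remeshing), template
construction, registration, barycentric landmark transfer with
leave-one-out evaluation, true/gap quasi-landmark classification, and
the observer-study statistics used to validate such pipelines. Because
clinical CBCT datasets are rarely shareable, the package also contains
a synthetic skull generator with exact ground truth, and every claim
the package makes about itself is tested against that ground truth.

## Surface preparation

CBCT segmentations are complex, two-sided, hole-ridden surfaces. The
preparation step wraps a half-cylindrical grid around the skull
(`make_half_cylinder()`) and shrinks it onto the bone
(`shrink_wrap()`). Each wrap vertex moves to its exact closest surface
point; the *displacement field* (not the positions) is Laplacian-
smoothed between iterations with weight `smooth_lambda` (default 0.5),
so vertices over holes inherit their neighbours' pull and bridge
defects smoothly while the residual distance decreases monotonically.
The wrapped surface keeps the grid topology — one connected sheet,
which is what makes dense correspondence meaningful later.

`remesh_isotropic()` then equalizes the sampling: the surface is
midpoint-subdivided until dense, vertices are clustered with Lloyd
iterations (deterministic spread seeding), cluster centroids are
projected back to the surface, and faces are rebuilt from cluster
adjacency. The default budget of 30 000 triangles matches common
practice for skull surfaces; the face count lands within 10% of the
budget and the edge-length coefficient of variation is well below
0.35 on smooth surfaces.

## Registration model

Registration proceeds in three stages (`register_mask()`):

1. **Similarity initialization from sparse landmarks.** Eleven named
   landmarks placed on both the mask and the target give a
   least-squares similarity transform (Umeyama's closed form). Because
   individual surfaces differ mainly by displacement *along the
   surface normal* (bone apposition and resorption), a plain
   least-squares fit absorbs part of that shape difference into the
   pose. `similarity_from_landmarks_normal()` therefore re-solves the
   fit iteratively with each target landmark replaced by its
   projection onto the line through it along the local template
   normal: a landmark is allowed to slide along its normal for free,
   and only its tangential information constrains the pose.

2. **Normal-shooting similarity refinement**
   (`normal_shooting_icp()`). Rays are cast from every template vertex
   along its own normal; the signed ray distances are the
   normal-projected discrepancy field, and the linearized
   rotation/translation/scale update that best explains that field is
   solved in closed form and applied, iterating to convergence. Two
   gates protect the field: hits whose target facet faces more than
   ~72 degrees away from the ray (|cos| < 0.3) and hits whose signed
   distance deviates grossly from their neighbours' (wrong-sheet
   intersections) are discarded. The iteration is a surface-driven
   attractor — its converged pose does not depend on the
   initialization landmarks — which is what makes repeated
   registrations of the same skull agree to a few hundredths of a
   millimetre. Classic closest-point ICP (`rigid_icp()`, with trimmed
   correspondences) is retained for severely truncated targets, but it
   is not the default: an unconstrained surface fit will trade
   correspondence fidelity for surface fit on smoothly deforming
   anatomy.

3. **Non-rigid adaptation** (`nonrigid_register()`). Rays are cast
   once from the aligned template along its vertex normals, giving a
   fixed target point per vertex; a target surface that is a
   displacement of the template along those rays is recovered
   *exactly*, and tangential sliding — the failure mode of
   closest-point correspondences — is impossible by construction.
   The template then relaxes onto the targets over `num_iterations`
   iterations while the displacement field is diffused over the
   template graph with an annealed stiffness (number of neighbourhood-
   averaging passes, geometric schedule from `stiffness_start` = 25
   down to `stiffness_end` = 2): early iterations move the template
   almost rigidly, late ones allow local detail, mirroring the
   viscoelastic behaviour class of dense-correspondence frameworks.
   For vertices with a valid ray target only the *scalar* distance
   along the ray is smoothed — the direction field turns quickly
   across ridges and orbital rims, and averaging it as vectors would
   bend the template off its rays exactly where the anatomy is most
   distinctive. Vertices without a valid ray (holes, truncations,
   rejected hits) carry no pull of their own and are interpolated by
   the diffusion, which is how field-of-view truncation is bridged.
   The output preserves the template topology and vertex count
   exactly.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `num_iterations` | 30 | relaxation iterations |
| `stiffness_start`, `stiffness_end` | 25, 2 | smoothing passes (graph units), annealed geometrically |
| `normal_max_range` | 40 mm | ray censoring range; several times the expected shape difference |
| `inlier_kappa` | 3 | robust cut (median + kappa·MAD) for closest-point correspondences |
| `trim` | 0.2 | scale-aware trimmed fraction for closest-point mode |
| `correspondence` | `"normal"` | `"normal"` (fixed rays) or `"closest"` (evolving closest points) |

Stiffness is counted in graph neighbourhoods, so meshes of a different
resolution need proportionally rescaled values. All defaults assume a
template of roughly 1 000–10 000 vertices at adult-skull scale
(millimetre units).

## Template construction

`build_template()` registers a preliminary mask to a set of skulls,
averages the masked shapes by GPA with scaling (`gpa()`), rescales the
consensus to the mean centroid size so it keeps millimetre units, and
symmetrizes it by reflection averaging (`reflection_average()`) under
a mirror pairing found by mutual nearest-neighbour matching under
x-negation. GPA fixes the global orientation only up to rotation, so
the starting reference is chosen by a content hash, making the
consensus independent of input order. Whether the final averaging is
done on scaled or size-restored coordinates is a genuine choice; the
package restores size so that templates remain in physical units.

## Landmark transfer and its evaluation

A sparse landmark is encoded as barycentric weights over its three
closest quasi-landmarks (`encode_barycentric()`; ties break to the
lowest index; near-collinear triples fall back to inverse-distance
weights). Transfer (`transfer_landmarks()`) encodes the landmark on
every training skull, decodes each anchor on the target's masked
shape, averages the decoded positions, and projects the average to the
exact closest point on the target surface — the average of positions
decoded from different skulls need not lie on it. Averaging decoded
positions (rather than pooling anchor weights, which are only
comparable when the nearest triple happens to agree across skulls) is
the package's resolution of a genuinely ambiguous design point.
`loo_evaluate()` wraps this in the standard leave-one-out design, per
observer and for the observer average.

## Reliability and accuracy statistics

* `rms_repeat()` — per-landmark RMS dispersion about the per-landmark
  mean over repeated configurations. The same definition serves
  intra-observer error (rounds of one observer) and automated-repeat
  error (registrations from perturbed initializations), which keeps
  the two comparable. The alternative reading — mean pairwise
  distance — differs only by a factor sqrt(R/(R-1)) and can be
  derived from the same output.
* `rms_between()` — pairwise RMS between observer-mean configurations.
* `icc()` — two-way single-measure intraclass correlation from ANOVA
  mean squares; consistency ICC(C,1) ignores systematic rater bias,
  agreement ICC(A,1) penalizes it; 95% bounds by the F-based formulas
  (Satterthwaite approximation for agreement).
* `bland_altman()` — bias and 1.96·SD limits of agreement.
* `anova_centroid()` — sequential (type-I) fixed-effects ANOVA on
  centroid sizes, in the Df / Sum Sq / Mean Sq / F / Pr(>F) layout.
* `shape_variance_decomposition()` — sequential multivariate
  decomposition of the Procrustes sum of squares with seeded
  permutation p-values.
* `residualize_covariates()` — covariate adjustment by sequential
  single-component partial least squares (one latent component per
  covariate, shared variation removed once).
* `shape_pca()` — PCA of aligned coordinates.

Mixed-effects formulations and multivariate test statistics beyond the
variance decomposition are deliberately out of scope.

## True and gap quasi-landmarks

Wrapped surfaces bridge orbits, the nasal aperture and missing
posterior regions, so some quasi-landmarks do not lie on bone.
`normal_distance()` casts a ray from each quasi-landmark along its
normal (both directions, nearer hit, censored at 50 mm — censored
distances count as exceeding any threshold) against the original
unwrapped surface; `flag_true_landmarks()` marks a quasi-landmark as
"gap" when that distance exceeds 10 mm in more than half of the
skulls, then symmetrizes conservatively: a mirror pair survives only
if both members survive. Absolute distances are used (the sign of the
offset is not informative for the rule). `topology_fidelity()`
summarizes the same distances over true landmarks as a mean ± sd
measure of how much the wrap/remesh/registration chain altered the
represented surface.

## The synthetic cohort: what it emulates and what it does not

`generate_population()` builds a closed, bilaterally symmetric base
surface — an ellipsoid at adult-skull scale decorated with strong
zygomatic, orbital-rim, nasal, brow, tooth-row and gonial features;
feature strength matters, because those structures are what makes the
pose of a real skull geometrically identifiable, and the synthetic
analog needs the same property. Each individual is produced by

* a smooth random scalar field (sum of 30 Gaussian radial basis bumps,
  kernel sd = wavelength/4) applied **along the surface normal**, RMS
  amplitude 5 mm at 60 mm wavelength by default. Bone remodels by
  apposition/resorption normal to the surface, and a purely tangential
  field is a reparameterization that carries no shape information, so
  none is generated;
* the antisymmetric field component rescaled to `asymmetry_sd`
  (1 mm default);
* a global size factor with 3% sd — natural human size variation,
  without which centroid-size reliability statistics would be
  degenerate;
* a random rigid pose (5 degrees / 10 mm), optional posterior
  truncation and punched holes (field-of-view artifacts), and
  optional vertex jitter.

The symmetric and antisymmetric fields are projected orthogonal to
the similarity modes of the base (in the normal-projection metric), so
individuals are in Procrustes-optimal pose with respect to the
template by construction — the standard morphometric convention that
makes "true pose", and hence ground-truth correspondence, well
defined. Observers (`simulate_observers()`) place landmarks as truth
plus a per-observer smooth systematic bias field plus independent
round noise, re-projected onto the surface; bias is constant across
rounds, so it inflates inter-observer but not intra-observer
dispersion, the pattern real observer studies show. Default noise sds
are 0.3/0.6/0.9 mm (a trained, an intermediate and an untrained
observer) with bias amplitudes 0.7/1.0/1.4 mm, chosen so that the
intra/inter structure matches published craniofacial observer studies
(intra roughly 0.3–1 mm, inter around 1.4 mm).

What the generator does **not** emulate: real cortical-bone texture
and scanner artifacts, open mandible/cranium topology, tooth-level
geometry, or observer blunders (mislabelled landmarks). Passing the
synthetic acceptance battery therefore demonstrates the correctness
and internal consistency of the algorithms under controlled
conditions, not clinical performance on real CBCT data.

## Numerical choices

* Units are millimetres throughout; face indices are 1-based inside R
  and converted per format on I/O (the published gap-ID text format is
  0-based).
* Duplicate-vertex merging at 1e-6 mm; below scanner precision, above
  float32 noise.
* Closest-point queries are exact (faces, edges, vertices all
  candidates); the spatial pruning used for speed never changes the
  answer, and the test suite compares against a brute-force oracle.
* GPA converges at 1e-10 on the consensus change; Procrustes rotation
  by SVD with reflection guard.
* Barycentric encoding falls back to inverse-distance weights when the
  anchor triple is near-collinear (condition number above 1e8).
* All randomness flows through explicit integer seeds
  (`with_seed()`); identical seeds give byte-identical outputs, which
  the test suite asserts on whole pipeline runs.

## Reference study conditions and problem sizes

The packaged validation study (`run_validation_study()`, also driven
by `scripts/acceptance.R`) uses 10 synthetic skulls at subdivision
level 4 (1 026 quasi-landmarks, 2 048 faces per surface), 3 observers
x 3 rounds, 3 registration repeats with initialization landmarks
perturbed by 2 mm, and the generator defaults above. These sizes are
the package's reference configuration: large enough that registration,
transfer and the statistical battery operate in their intended regime,
small enough that a full study runs in well under a minute on one CPU.
A production-scale configuration (a ~10 000-vertex mask,
30 000-triangle surfaces, a 31-skull cohort) is a straight parameter
change
(`population_spec(subdivisions = 5, n_individuals = 31)` plus
`remesh_isotropic(..., 30000)`), with runtime scaling roughly linearly
in vertex count times face count.

## Known limitations

* Normal-shooting correspondence assumes the target is reachable along
  template normals after rigid alignment; for grossly non-isomorphic
  targets (for example a skull with large displaced fragments) the
  closest-point mode with robust trimming is the safer choice.
* Registration accuracy is ultimately limited by the pose information
  in the surface; individuals whose shape difference locally mimics a
  similarity transform are registered with a small, consistent
  parameterization bias rather than an error the pipeline can detect.
* The isotropic remesher is approximate centroidal-Voronoi clustering;
  it does not guarantee manifoldness of pathological inputs.
* Confidence intervals for agreement ICC use the standard
  Satterthwaite approximation and can be slightly liberal for very
  small panels.
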