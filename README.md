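# densecranio

Dense 3D phenotyping of craniofacial bone surfaces in R.

Sparse manual landmarking of skull scans (CBCT/CT) is slow and
observer-dependent. `densecranio` replaces it with *quasi-landmarks*:
the vertices of a template mask that is non-rigidly registered to each
skull surface, so that vertex *i* marks the same anatomical location on
every individual. The package covers the whole workflow:

* **Surface preparation** — half-cylinder shrink-wrapping that bridges
  scan holes (`make_half_cylinder()`, `shrink_wrap()`) and isotropic
  remeshing to a target triangle budget (`remesh_isotropic()`).
* **Registration** — similarity initialization from sparse landmarks
  with a normal-line refinement, a normal-shooting similarity
  refinement whose converged pose is independent of the initialization,
  and annealed smoothed-displacement non-rigid adaptation
  (`register_mask()`, `nonrigid_register()`, `rigid_icp()`).
* **Template construction** — generalized Procrustes averaging and
  reflection symmetrization (`gpa()`, `build_template()`,
  `plane_symmetrize()`, `reflection_average()`).
* **Landmark transfer** — barycentric encoding over the three closest
  quasi-landmarks, training-set averaging, surface projection, and
  leave-one-out evaluation (`encode_barycentric()`,
  `transfer_landmarks()`, `loo_evaluate()`).
* **True/gap classification** — normal-ray distance to the original
  surface with the 10 mm majority rule and conservative mirror
  symmetrization (`normal_distance()`, `flag_true_landmarks()`,
  `topology_fidelity()`).
* **Observer-study statistics** — RMS reliability (`rms_repeat()`,
  `rms_between()`), two-way intraclass correlation with confidence
  bounds (`icc()`), Bland–Altman agreement (`bland_altman()`),
  sequential centroid-size ANOVA (`anova_centroid()`), Procrustes
  shape-variance decomposition, PLS covariate removal, shape PCA.
* **Synthetic ground truth** — a skull-like population generator with
  exact dense correspondence and simulated observers
  (`generate_population()`, `simulate_observers()`), which is what
  makes every stage of the pipeline testable without clinical data.

Mesh I/O supports OBJ, PLY (ascii and binary little-endian) and STL;
landmark files are CSV (`name,x,y,z`) or JSON. A thin command-line
wrapper with `wrap` / `register` / `transfer` / `simulate` / `study`
subcommands is installed at `inst/exec/densecranio`.

## Worked example

```r
library(densecranio)

# a synthetic cohort with known ground truth
pop  <- generate_population(population_spec(n_individuals = 4, seed = 1))
mask <- pop$base
ids  <- pop$landmark_ids

# register the template to the first skull using 11 named landmarks
init  <- intersect(init_landmark_names(), names(ids))
m_lm  <- landmark_config(mask$vertices[ids[init], ], init, "template")
t_lm  <- landmark_config(pop$individuals[[1]]$truth_landmarks$points[init, ],
                         init, "skull01")
reg <- register_mask(mask, pop$individuals[[1]]$mesh, m_lm, t_lm)
reg
#> mask_registration
#>   quasi-landmarks : 1026
#>   init landmark residual RMS : 4.720 mm
#>   final mask-to-target distance : 0.097 mm

# how close is the recovered dense correspondence to the truth?
err <- sqrt(rowSums((reg$masked$quasi -
                     pop$individuals[[1]]$truth_quasi$quasi)^2))
round(c(mean = mean(err), p95 = unname(quantile(err, 0.95))), 3)
#>  mean   p95
#> 0.245 0.668
```

The initialization residual (4.7 mm) is simply the magnitude of the
simulated shape difference the rigid fit correctly refuses to absorb;
the final mask-to-target distance (0.097 mm) says the deformed
template lies on the target surface; the correspondence error
(mean 0.25 mm against ground truth, for a 5 mm-RMS simulated shape
difference) says its vertices also landed on the right anatomical
locations — the quantity that matters for quasi-landmark analyses and
that only synthetic data can measure directly.

A full observer study — registration repeats with perturbed
initializations, three simulated observers, leave-one-out transfer,
ICC/Bland–Altman/ANOVA tables — is one call:

```r
res <- run_validation_study(seed = 1, out_dir = "study_out")
res
#> validation_study
#>   skulls: 10   seed: 1
#>
#> RMS reliability (mm):
#>                   Mean   Std   Min   Max
#> Automated        0.042 0.055 0.000 0.153
#> Inter-Observer   1.322 0.083 1.185 1.444
#> Intra-Observer 1 0.317 0.017 0.282 0.337
#> Intra-Observer 2 0.671 0.043 0.592 0.739
#> Intra-Observer 3 1.016 0.057 0.905 1.089
#>
#> LOO transfer mean distance: 0.510 mm
#> Inter-observer centroid-size ICC (consistency): 0.9964
#> Centroid-size bias (manual - automatic): -0.330 mm
#> True landmarks: 1026 / 1026
#> Topology fidelity: 0.206 +/- 0.378 mm
```

Automated landmarking repeats agree far better than any human observer
repeats with themselves (0.04 mm vs 0.32–1.02 mm), inter-observer
disagreement exceeds intra-observer noise, and automatically
transferred landmarks land closer to the observer consensus than the
observers land to each other — the qualitative pattern that justifies
dense automatic phenotyping. `study_out/` receives the corresponding
CSV tables, QC overlay, and a JSON summary.

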