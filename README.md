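# aortashape

Statistical shape analysis of the ascending thoracic aorta from triangulated
surface meshes.

Ascending thoracic aortic aneurysm (ATAA) management hinges on one number —
the maximum aortic diameter — yet dissections occur below every diameter
threshold, and aneurysms with the same diameter can have very different
three-dimensional shapes (root-dominant, tubular, bulged, tortuous).
`aortashape` implements the statistical shape analysis (SSA) workflow that
quantifies that full 3D variability and relates it to wall function and to
surgical outcome:

1. **Atlas construction.** Each subject's surface mesh is resampled to a
   fixed number of surface points; all clouds are rigidly aligned (iterative
   closest point; translation and rotation only, so size remains a shape
   feature); an unbiased mean template is built by iterated re-alignment and
   re-averaging; point correspondence is taken by closest-point projection
   from the template.
2. **Shape modes.** The corresponded clouds `(x_i, y_i, z_i)` are flattened
   into shape vectors and decomposed by PCA: eigenvectors of the covariance
   are the *shape modes*, eigenvalues their variance; per-subject scores
   ("shape vectors") summarise each anatomy in a handful of numbers; the
   template can be deformed from −2 SD to +2 SD along any mode for
   visualisation.
3. **Morphometrics.** Area-equivalent diameters at the sinus, sino-tubular
   junction (STJ) and mid-ascending stations, centerline tortuosity
   (arc/chord − 1) and mean curvature, and a configurable dilatation-pattern
   class (N/A/E).
4. **Wall strain.** From paired diastole/systole meshes: each diastolic point
   is projected along its outward normal onto the systolic surface; the
   displacement normalised by the local diastolic radius is a dimensionless
   radial strain (Δr/r).
5. **Statistics.** Pearson correlations of mode scores with morphometric and
   biomechanical descriptors; Mann–Whitney and chi-square group comparisons;
   a logistic surgery-risk model on the modes retained at 90% cumulative
   variance, compared by ROC/AUC against the diameter-only baseline; k-means
   clustering of the mode-1/mode-2 plane.

A synthetic-aorta generator (curved tubes with controlled size, tortuosity,
dilatation pattern, paired-phase strain, and surgery labels drawn from a
known logistic link on the generating mode weights) provides full ground
truth, so every stage is testable without patient data.

## Worked example

```r
library(aortashape)

# simulate a cohort: 30 aneurysmal subjects, 10 non-aneurysmal controls
sim <- simulate_cohort(n_ataa = 30, n_control = 10, seed = 1)

# resample, align, build the template, fit the shape atlas
clouds <- lapply(seq_along(sim$meshes), function(i)
  resample_surface(sim$meshes[[i]], n_points = 2000, seed = i))
tmpl  <- build_template(clouds, reference = select_initial_reference(sim$cohort))
atlas <- fit_pca(tmpl)
print(atlas)
#> <shape_atlas> 40 subjects, 2000 points, 39 modes; mode 1 explains 61.7%, 6 mode(s) reach 90%

# risk model: shape modes at 90% variance vs. diameter-only baseline
ataa <- sim$cohort$group != "control"
k <- modes_for_variance(atlas, 0.90)
m_modes <- fit_risk_model(atlas$scores[ataa, 1:k], sim$cohort$surgery[ataa],
                          predictor = "modes_90")
m_diam  <- fit_risk_model(atlas$scores[ataa, ], sim$cohort$surgery[ataa],
                          predictor = "diameter",
                          diameter = sim$cohort$diameter_midaa[ataa])
c(modes = m_modes$auc, diameter = m_diam$auc)
#>     modes  diameter
#> 0.8695652 0.5590062
```

The first mode is overall size (controls separate from aneurysms along it),
and the shape-mode model stratifies operated from monitored subjects better
than the diameter alone — the qualitative behaviour the method is designed
to expose. One full pipeline run, with all artifacts (scree table, scores,
ROC points, per-subject morphometrics, log) written to a directory:

```r
run_pipeline(pipeline_config(out_dir = "run1",
                             simulate = list(n_ataa = 30, n_control = 10),
                             n_points = 2000, seed = 1))
```

A thin command-line front end for simulation and full runs is installed at
`inst/cli/aortashape.R`.

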