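---
title: "Shape atlases of the ascending aorta: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape atlases of the ascending aorta: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortashape)
```

## The model

`aortashape` treats a cohort of ascending-aorta surface meshes as draws from
a point-distribution model: after resampling every surface to a common point
count N, rigid alignment, and point correspondence, subject *i* is the
flattened shape vector
$$ \mathbf{x}_i = (x_{i1}, y_{i1}, z_{i1}, \dots, x_{iN}, y_{iN}, z_{iN})^\top, $$
and PCA of the centered shape vectors gives the mean template
$\bar{\mathbf{x}}$, orthonormal shape modes $\boldsymbol\phi_k$ with
eigenvalues $\lambda_k$ (mm²), and per-subject mode scores
$s_{ik} = \boldsymbol\phi_k^\top(\mathbf{x}_i - \bar{\mathbf{x}})$.
Alignment is strictly rigid — translation and rotation, never scaling — so
overall aortic size remains in the data and is expected to dominate the
first mode. Everything downstream (mode–descriptor correlations, the
logistic surgery-risk model and its ROC, clustering of the mode-score
plane) operates on the scores.

Assumptions worth stating explicitly:

* shape variation is small enough around the mean for a linear (PCA) model
  to be meaningful;
* cross-sectional topology is a single open tube (the mesh is cut below the
  brachiocephalic artery, leaving exactly two boundary rings);
* meshes of one cohort arrive roughly co-oriented (CTA scans of supine
  patients share the scanner frame) — see *Alignment* below for why this
  matters;
* units are millimetres throughout (STL/PLY/OBJ carry no unit metadata).

## Pipeline stages and their tunable parameters

**Resampling** (`resample_surface`). Area-weighted uniform random sampling
of the triangulated surface; default N = 15,000 points, which is beyond the
resolution where the first mode stabilises for tubes of this complexity
(the package's own convergence study below; tests run at 1,000–4,000 for
speed). An approximate Poisson-disk mode exists for more even spacing but
random sampling is the default. `mode_convergence_curve()` re-runs the full
pipeline over a ladder of resolutions and flags the first resolution whose
first-mode variance fraction changes by less than 5% (relative) from the
previous one — the variance fraction is used as the scalar summary of "the
first mode" because it is invariant to basis and rigid frame. The curve uses
common random numbers across resolutions so that consecutive points differ
by sampling density, not by an independent redraw.

**Rigid alignment** (`icp_rigid`). Iterative closest point with k-d-tree
matching and Kabsch/SVD fitting; the RMS nearest-neighbour distance is
non-increasing across iterations, and non-convergence is flagged rather
than raised. Two initialisation policies exist, and the distinction is a
real design point for tubular anatomy:

* `init = "pca"` (pairwise default): multi-start — centroid superposition,
  principal-axes pre-alignment with a third-moment sign disambiguation,
  plus the three 180° flips about the target's principal axes. Candidates
  are burned in and ranked by *symmetric* RMSD (source→target and
  target→source), because one-directional RMSD can prefer a mis-oriented
  pose that drapes the source over part of the target while leaving target
  structure uncovered.
* `init = "identity"` (default inside `build_template`): local refinement
  from the co-orientation prior. A smooth curved tube is nearly symmetric
  under an end-to-end flip, and once subjects are strongly deformed the
  flipped registration can be genuinely as good as the correct one by any
  point-set distance — no initialisation scheme can disambiguate it from
  geometry alone. Cohort meshes share the scanner frame, so the honest
  prior is that the identity orientation is approximately correct, and
  local ICP from it cannot cross into the flipped basin.

**Template construction** (`build_template`). The initial reference is the
subject closest to the mean mid-ascending diameter
(`select_initial_reference`; ties broken lexicographically). Each round
aligns every subject to the current template, corresponds template→subject
by closest point, and averages; a rigid gauge fix re-aligns each new
template onto the previous one so the stopping rule ("the average mesh did
not change") sees shape change, not frame drift. Defaults: at most 10
rounds, tolerance 10⁻³ × the mean bounding-box diagonal (mean point
displacement, mm). With closest-point correspondence onto finite random
samples the round-to-round change plateaus at the correspondence-noise
level rather than reaching zero; the history is recorded and the
`converged` flag reports which regime a run ended in.

**Correspondence** (`correspond`). For each template point, its nearest
subject point. This is the minimal correspondence model consistent with
rigid-only alignment; non-rigid (diffeomorphic) registration is
deliberately out of scope. Two consequences are documented and measured
below: correspondence noise inflates total variance by roughly
(surface area)/π mm² regardless of N, and deformation components that look
locally like tangential sliding are attenuated.

**PCA** (`fit_pca`). SVD of the subjects × 3N centered matrix (equivalent
to, and far cheaper than, the 3N × 3N covariance eigendecomposition;
verified against the explicit eigendecomposition in the tests). At most
n − 1 modes are non-null; a zero-variance population yields a flagged
degenerate atlas rather than an error. Mode signs follow a deterministic
convention (non-negative inner product with the template's radial-inflation
direction; ties resolved by the first nonzero component) purely so tests
and repeated runs agree. Scores are kept in mm. `modes_for_variance()`
implements the "retain modes up to 90% cumulative variance" rule used by
the risk model; `deform_template()` produces the ±2 SD mode visualisations
(values beyond ±2 SD warn as extrapolation).

**Morphometrics.** Station diameters slice the mesh with the plane normal
to the centerline tangent at a station (defaults: sinus 0.1, STJ 0.25,
mid-ascending 0.5 of arc length) and report the area-equivalent diameter
2√(A/π) — robust to slice noise; a max-chord variant exists. Slicing is
restricted to faces near the station because an infinite plane normal to a
strongly curved centerline can also graze a distant part of the vessel;
a station whose local section is not a single closed loop (e.g. the plane
exits through the open boundary of a hugely dilated root) is an error from
`station_diameter` and an `NA` in `morphometric_profile`. Tortuosity is
arc/chord − 1 — the only convention consistent with values near 0.13 for
an ascending aorta (plain arc/chord would be ≈ 1.13). Curvature is the
arc-length-weighted mean of discrete (circumradius) curvature. The
dilatation-pattern rule (N/A/E) is a configurable default — extended (E)
when all stations exceed the 40 mm cutoff with < 10% spread, else
root-dominant (N) when the sinus exceeds the mid-ascending diameter, else
ascending-dominant (A) at the cutoff — and is not presented as any
published scheme's exact rule.

**Wall strain.** Displacement is measured from each diastolic sample point
along its outward normal to the first systolic-surface intersection
(Möller–Trumbore ray casting), falling back to the unsigned closest-point
distance when the ray misses within a cutoff (default 3 × the median local
radius); the fallback count is reported, since a silent fallback is the
stage's one quiet failure mode. The published description of this strain
is ambiguous about the normaliser ("ratio of the relative displacement to
the baseline configuration"); the package normalises by the local
*diastolic radius* — the distance from the point to its nearest centerline
point — because that gives a dimensionless radial strain consistent with
Δr/r and independent of any coordinate origin, whereas normalising by the
position magnitude would depend on where the scanner origin happens to be.
Points with baseline radius below 0.1 mm are flagged invalid and excluded
from summaries. Phases are assumed to share one frame (CTA phases do); an
ICP pre-alignment is available for data that do not. Centerlines are
extracted via a harmonic axial coordinate (the graph Laplace equation with
the two boundary rings as Dirichlet conditions — its level sets stay
ring-aligned where geodesic distances scatter within a ring), followed by
local-linear kernel regression of each coordinate against that coordinate,
with endpoints anchored at the boundary-ring centroids. Local-*linear*
fitting matters at the open ends, where an aortic centerline carries its
full curvature: a kernel average or a natural smoothing spline would
straighten it there. On constant-radius curved generator tubes the
extracted centerline is within ~1.5% of the tube radius of the truth
(Hausdorff); steep radius features (the sinus waist–bulge) distort the
harmonic coordinate locally and can push this to ~4%, which is also why
the per-subject curvature descriptor is evaluated on a ~15-station
subsample (second derivatives amplify extraction-scale wiggle).

**Statistics.** Pearson correlations report raw two-sided p-values
(t-distribution, n − 2 df) with pairwise deletion and no multiple-testing
correction by default, significance read at 0.05; Benjamini–Hochberg is
available and the output records which was used. Mann–Whitney is exact for
group sizes ≤ 20 without ties, normal approximation with tie correction
otherwise; chi-square is Pearson's without Yates correction unless asked.
The logistic risk model is unpenalised maximum likelihood (`glm`); a small
ridge (10⁻⁶) refit engages only on separation or non-convergence and is
flagged. ROC curves sweep every distinct predicted value; the trapezoid AUC
equals the rank-sum statistic (asserted in tests on every fixture). ROC is
in-sample by design — the analysis mirrors a single-cohort retrospective
workflow; no cross-validation is performed. Clustering is seeded k-means
(10 restarts) on the first two mode scores, with the silhouette-maximising
k in 2..6 when `k = "auto"` — the mode-1/mode-2 plane is where cohort
subgroup structure is inspected.

## The synthetic cohort: what it emulates, and what it does not

The generator builds open curved tubes around a circular-arc centerline
(default: 100 mm long, 100° arc — tortuosity ≈ 0.14, matching reported
aneurysmal values — with a deterministic 6 mm out-of-plane bow, since real
ascending aortas are not planar). The default radius profile models the
proximal anatomy explicitly: a narrow annulus waist at the cut (−3 mm), the
interior sinus-of-Valsalva bulge (+4 mm at 10% of length), and a broad
mid-ascending dilatation (+4.3 mm at 50%), on an 18 mm base radius — station
diameters ≈ 43/38/45 mm, the typical aneurysmal pattern. The waist–bulge
structure is also the tube's one strong axial asymmetry, which is what keeps
an end-to-end flipped registration distinguishable at all.

Population variation is generated by three smooth orthogonal deformation
fields: uniform radial inflation (size), an axial dilatation gradient
windowed to vanish at the tube ends (root-dominant vs tubular-dominant
patterns do not involve the annulus or the arch cut), and a focal bulge just
above the STJ (arc fraction 0.35, where bulged dilatations of the ascending
aorta occur — and distinct from the mid-ascending diameter station, so the
focal mode carries risk information the diameter baseline cannot see). An
optional bending field changes tortuosity. Two properties of the basis are
deliberate:

* **Pose-free fields.** Rigid alignment absorbs any deformation component
  whose surface-normal pattern matches a rigid motion's normal pattern
  (closest-point distances are blind to tangential sliding). Each field's
  normal pattern is therefore regressed on the six rigid normal patterns
  (translations, infinitesimal rotations) and the fit subtracted, so the
  generating weights remain recoverable after alignment.
* **Unit-RMS-per-point scaling** (flattened norm √N): a weight of w mm is w
  mm of RMS surface displacement, so the default SDs (4, 2, 1) mm give a
  size mode spanning a plausible severity range (±8 mm of radius at 2 SD).

Weights are drawn normal and then whitened so the realised sample
covariance equals diag(SD²) exactly (population covariance control):
recovery benchmarks then measure pipeline error against the nominal
generating model rather than the chi-square and cross-correlation
fluctuation of one finite draw. Rigid perturbations (default: rotations
≤ 30°, translations ≤ 50 mm) exercise alignment; surgery labels are
Bernoulli(sigmoid(β₀ + β·z)) on the SD-standardised weights with default
β = (−1.6, 0.8, 1.0, 1.0) — prevalence near 20%, the rate of surgical
conversion in ATAA cohorts, with risk carried by all three modes so that a
diameter-only model is informative but strictly weaker. Echo covariates
(orifice area, flow jet) are drawn at the magnitudes reported for surgical
cohorts; station diameters, tortuosity and curvature are *measured from the
meshes* (the generator centerline serves as the measurement frame when
available), never copied from ground truth.

What the synthetic cohort does **not** emulate: branch vessels, non-circular
cross-sections, segmentation noise and topology defects, valve anatomy,
wall thickness, and imaging artefacts. Passing tests on it demonstrate that
the pipeline's geometry and statistics are correct and internally
consistent — not that clinical effect sizes or the published AUC would be
reproduced on real CTA data.

## Measured limitations of the closest-point pipeline

Two effects, quantified on the synthetic tubes, bound what the full
resample + ICP + closest-point pipeline can recover; both are properties of
the method class, not bugs:

* **Correspondence noise.** Matching each template point to the nearest of
  a subject's N random samples adds total variance ≈ area/π mm² (about
  4,000 mm² for the default tube; nearly flat eigen-spectrum), independent
  of N. This inflates the variance-fraction denominator by several
  percentage points at N = 2,000 and shrinks mode-1's fraction accordingly.
* **Pose absorption and orientation ambiguity.** Rigid ICP absorbs
  deformation components reachable by pose changes, and severely deformed
  near-symmetric tubes admit end-to-end-flipped and "axial slide" local
  optima whose fit can match the correct one. The identity-initialised
  template build avoids the flipped basin via the co-orientation prior but
  a few percent of strongly deformed subjects can still settle several
  degrees from their true pose.

For this reason the package's mode-recovery benchmark
(`sample_corresponded` + `fit_pca`) evaluates the atlas stage on the
generator's exact correspondence, where the recovered variance fractions
match 16:4:1 to within ~1 percentage point and score–truth correlations
exceed 0.99, while alignment is validated separately on rigid-copy
populations (exact recovery) and the end-to-end pipeline is exercised by
the sampling-convergence study and the risk-model ordering experiment.

## Numerical choices

* Mesh validation rejects < 4 vertices, non-finite coordinates,
  out-of-range face indices, and triangles with area ≤ 10⁻⁹ mm² (reported
  by face index).
* ICP stops when the RMSD improvement falls below 10⁻⁹ mm (or a looser
  multiple inside template rounds, which only need to out-resolve the
  template stopping rule); candidate starts are ranked at a loose relative
  tolerance and only the winner is polished.
* PCA retains modes with eigenvalue > 10⁻¹² × the largest; a rank-0
  population is flagged degenerate.
* Tie-breaks are deterministic everywhere (lexicographic subject ids for
  the reference; first-nonzero-component rule for mode signs), and every
  stochastic operation takes a seed, so a run is reproducible bit-for-bit
  from (config, seed).
* Problem sizes in the test-suite benchmarks: 20 clouds × 1,500 points for
  alignment recovery; 10 subjects × 50 points for the PCA oracle; 80
  subjects × 2,000 points for mode recovery; resolutions 1,000–8,000 for
  the convergence study; 50 replicates of 200 subjects for the risk-model
  ordering. These are the package's benchmark conditions; larger cohorts
  and the 15,000-point default only change runtime.

## Known limitations

* Closest-point correspondence is not a diffeomorphic registration: it
  allows many-to-one matches and tangential sliding, with the variance
  effects quantified above.
* The dilatation-pattern rule is a configurable stand-in for phenotype
  classification schemes whose exact criteria are not published.
* Wall shear stress is consumed as an externally supplied per-subject
  scalar; no hemodynamics are computed.
* The risk model's AUC is in-sample, mirroring a single-cohort
  retrospective analysis; it overstates out-of-sample discrimination, and
  users who need a generalisation estimate should wrap `fit_risk_model` in
  their own resampling loop.
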