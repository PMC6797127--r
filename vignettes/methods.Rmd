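---
title: "Quantifying acetabular bone defects: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acetabular bone defects: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Revision hip surgery must cope with acetabular bone defects that plain
radiograph-based classifications (Paprosky and relatives) describe only
qualitatively. Given a CT-derived solid model of a defect hemipelvis and a
reconstruction of its native (pre-defect) counterpart, the defect can be
quantified instead: how much bone is missing, where, and what has changed
about the acetabular geometry. `acetquant` implements that quantification as
six parameters per case

1. bone volume loss per periacetabular sector (absolute and relative),
2. new bone formation per sector,
3. ovality of the defect acetabulum,
4. lateral center-edge (LCE, Wiberg) angle,
5. implant migration (total and by anatomical direction),
6. wall-defect flags per sector,

followed by a rule-based assignment to one of 17 defect groups. The package
deliberately starts *after* image segmentation and anatomical
reconstruction: its inputs are watertight surface meshes (STL/PLY) plus a
landmark file. How the native pelvis is reconstructed (e.g. by a statistical
shape model fitted to the intact contralateral and periacetabular bone) is
out of scope; the native solid is an input.

## Anatomical frame and sectors

The anterior pelvic plane (APP) is the plane through both anterior superior
iliac spines (ASIS) and the pubic symphysis. Body axes are X along the ASIS
line pointing lateral for the analyzed side, Z cranial within the APP and
orthogonal to X, and Y = Z x X pointing anterior. The APP normal is oriented
anterior using the fact that the hip joint center lies posterior of the APP.
Left-side cases are mirrored across the sagittal plane (through the ASIS
midpoint and the symphysis, normal along the ASIS line) before any
computation, so the entire downstream pipeline is written for a canonical
right side. The acetabular plane and rim radius come from a least-squares
plane plus 2D circle fit to rim points (or are given explicitly); if the
native center of rotation (CoR) is not supplied as a landmark, the fitted
rim-circle center is used, which is exact for a hemispherical socket whose
rim is its equator.

Around the native CoR a spherical region of interest (ROI) of radius
`roi_radius_factor` x acetabular radius (default 2.0) is partitioned into
four disjoint sectors: a **Medial** cap on the medial side of a plane
parallel to the acetabular plane (offset `medial_offset`, default 0 mm,
medial of the CoR), and three azimuthal wedges of 120 degrees each in the
remaining lateral shell — **Cranial** centered on the projected cranial
direction, **Anterior** and **Posterior** adjacent. The literature this
sector scheme descends from does not publish the cutting planes, so the
cap-plus-three-wedges construction here is the package's own, chosen to
reproduce the published sector topology; every report embeds the resolved
sector configuration so results are reproducible and comparable. The sectors
are enforced to be volumetrically disjoint and to partition the ROI exactly
(each point receives exactly one label; azimuthal gaps, possible only with
non-default wedge widths, are closed by nearest-center assignment).

## Voxel Boolean volumetry

Bone volume loss in a sector is the volume of (native minus defect)
restricted to the sector; new bone formation is (defect minus native),
symmetrically. Volumes are computed with a voxel Boolean engine:

* both meshes are rasterized onto one common grid by parity counting of
  z-ray crossings at voxel-column centers (the grid origin carries an
  irrational jitter so mesh features cannot sit exactly on the ray lattice);
* occupancies are combined voxel-wise;
* results are re-meshed, when a mesh is needed, as the voxel boundary
  surface, whose enclosed volume equals the voxel count times pitch cubed
  exactly.

There is no exact mesh-Boolean kernel in the package; requesting
`method = "exact"` falls back to the voxel method with a warning, so the
operation never fails on valid watertight input. Correctness is instead
established against independent closed-form oracles (box overlap volumes,
the sphere-sphere lens) in the test suite: the volume error of the voxel
method is bounded by O(pitch x shared surface area) and in practice stays
well under 1% at the default analysis pitch.

The analysis pitch is 0.25 mm (configurable). At that pitch a typical
hemipelvis pair voxelizes into roughly 30 million cells and one case
analyzes in seconds; the per-sector loss recovered on phantoms is within
about 1% of ground truth. Connected components of the difference smaller
than `min_component_ml` (default 0.05 ml) are discarded: thin shell-like
sheets between the two surfaces are reconstruction artefacts, not bone
loss, and 0.05 ml is one to two orders of magnitude below any clinically
reported sector loss. Relative values always use the native bone volume of
the same sector as denominator; a sector with zero native volume reports
missing relative values with a warning rather than a division by zero.

Loss and formation are computed clip-then-subtract (native occupancy AND
NOT defect occupancy, tallied per sector) rather than subtract-then-clip;
for a disjoint partition the two orders are equivalent and the occupancy
formulation performs both in one pass.

## Morphometrics

**Ovality.** Defect rim points are projected onto the native acetabular
plane and an ellipse is fitted with the direct least-squares (Halir-Flusser)
method, which is numerically stable and ellipse-specific. Ovality is the
major/minor diameter ratio; 1 means circular. The fit is exact on noiseless
conics and recovers the ratio within 2% under 0.2 mm point noise.

**LCE angle.** The vector from the native CoR to the most lateral edge of
the cranial roof is projected into the APP; the LCE angle is the signed
angle between that projection and the body Z-axis, positive lateral. The
lateral edge is an input landmark: on heavily eroded roofs its identification
is a clinical judgement the package does not automate. Angles between 25 and
39 degrees (inclusive) are classified as normal roof coverage, below as
reduced, above as increased. The sign convention (negative when the edge
lies medial of the CoR) extends the classic definition to severe defects.

**Implant migration.** The implant CoR is a linear least-squares sphere fit
to points on the implant's articulating sphere — either supplied sample
points or all mesh vertices with iterative residual trimming (so rim and
backside vertices do not bias the fit). Migration is the vector from native
to implant CoR decomposed onto the body axes; components are signed
(lateral/medial, anterior/posterior, cranial/caudal), the total is the
Euclidean norm, and the predominant direction is the largest absolute
component with exact ties broken by a fixed clinical-frequency order
(cranial, posterior, medial, lateral, anterior, caudal). A fitted radius
outside 15-45 mm warns as implausible. On noiseless data the sphere fit is
exact to machine precision; with 0.1 mm point noise and hemispherical
coverage the center is recovered within 0.1 mm.

**Wall defects.** A wall defect is a hole of at least `min_dim` (default
5 mm) in length and width, or a rim segment where native and defect
surfaces are at least `min_dim` apart. Two detectors are OR-combined per
sector, both driven by the bone-loss occupancy near the rim:

* *hole detector* — loss components restricted to a band around the native
  rim circle (width `band_width`, default 10 mm); a component flags its
  sector when its two **smallest** principal extents both reach `min_dim`.
  The rationale: for a through-hole the largest extent is the wall
  thickness, and the two smaller ones are the hole's length and width. A
  boundary-loop construction on the defect surface was rejected because a
  through-hole in a watertight solid has no boundary loop; occupancy
  components measure the same quantity robustly.
* *absent-rim detector* — the native rim circle is sampled at 1 degree
  steps; a contiguous arc of at least 5 degrees whose distance to the
  defect surface reaches `min_dim` flags the sectors it spans. The 5 degree
  minimum arc suppresses single-sample speckle; both parameters are
  configurable.

The rim circle lies exactly on the Medial/wedge boundary plane, so rim
findings are attributed to Medial only when they lie at least 1.5 mm
(configurable dead-band) medial of it, otherwise to the azimuthal wedge.

## Defect groups

A sector shows clinically relevant bone loss when its relative loss
strictly exceeds its threshold: 25% in Cranial, Anterior and Medial, 15% in
Posterior (the posterior column is the most critical for implant
stability). The inequality is strict by definition — boundary values are
not relevant. The flagged subset, in fixed Cranial-Anterior-
Posterior-Medial order, names the group; no flags give "All intact", all
four "All sectors"; together with the separate "Pelvic discontinuity" group
there are exactly 17. Pelvic discontinuity is an image-based diagnosis and
enters as an input flag that overrides the sector label while the
underlying flags stay in the record. Five groups carry a Paprosky
correspondence (All intact to 1/2A, Cranial to 2B, Medial to 2C,
Cranial-Medial to 3A, All sectors to 3B); the others have none. Spider-plot
data serialize the per-case profile: the case polyline holds the four
relative losses, the group polygon extends to 100% on flagged sectors and 0
elsewhere, so "All intact" has zero area.

## Cohort statistics

Descriptives are reported as median with 25th/75th percentiles (linear
interpolation) plus min/max/mean/sd, excluding and counting missing values
(migration is missing for cases without a segmentable implant). Normality
is tested per column with Shapiro-Wilk; differences between the relative
sector-loss distributions with the two-sided Mann-Whitney U test, exact by
enumeration when both groups have at most 8 observations and no ties,
otherwise via the normal approximation with tie and continuity correction.
Correlations are pairwise-complete Pearson by default (Spearman optional)
and banded on the absolute coefficient: moderate for 0.5 <= |R| < 0.7, high
for 0.7 <= |R| < 0.9, very high above. Pairs of an absolute value with its
own relative counterpart are flagged as trivial. No multiple-testing
correction is applied by default, matching standard practice in this
literature; the p-values are reported so any correction can be applied
downstream. Standard test internals are delegated to base R
(`shapiro.test`, `wilcox.test` for the exact path); the independent check
in the test suite is brute-force enumeration over all group assignments.

Cohort tables are read and written as CSV in the layout of published
supplementary raw-data files: a volumetry table (per-sector native/defect
volumes in mm^3, absolute and relative loss and formation), a
morphometrics table (length, width, ovality, LCE, total migration plus six
non-negative direction columns, wall flags as 0/1) and a long-form banded
correlation table.

## The phantom generator

Clinical CT cohorts in this domain are not publicly deposited as images, so
validation runs on a parametric hemipelvis phantom with exact ground truth.
The phantom is deliberately stylized: a spherical bone shell (outer radius =
acetabular radius + shell thickness, default 26 + 7 mm) around a
hemispherical acetabular cavity with a cylindrical lateral opening; the
outer sphere is shifted 6 mm laterally so the medial wall is thin and the
lateral columns thick, echoing real periacetabular bone distribution.
Defects are carved constructively: sphere "bites" (volume loss), capsule
punches through the rim wall and swept erosion arcs along the rim (wall
defects), and surface blobs added to the defect model (new bone formation).
The implant is a hemispherical cup displaced by a known migration vector;
rim geometry (a seeded ellipse for ovality), the lateral-edge landmark (a
chosen LCE angle) and sampled implant-surface points (0.1 mm noise,
emulating segmentation jitter) complete the case.

Meshes are extracted from the constructive geometry by marching tetrahedra
(Kuhn 6-tetrahedra cube subdivision, watertight by construction) at 0.5 mm
sampling; node values exactly on the iso level are consistently nudged so no
degenerate triangles arise. Ground-truth volumes do **not** come from the
meshes: an independent voxel oracle samples the constructive geometry
itself at 0.1 mm pitch over the carved regions (verified to change by less
than 0.5% against 0.05 mm), with per-sector native volumes from a 0.2 mm
full-domain pass shared across a cohort. Truth is therefore independent of
the mesh pipeline under test; what the phantom cannot show is robustness to
anatomically realistic shape variation, segmentation artefacts or real SSM
reconstruction error — passing recovery tests demonstrates correctness of
the geometry pipeline, not clinical validity.

The cohort generator draws per-sector relative-loss targets well clear of
the relevance thresholds (flagged sectors roughly 28-38%, unflagged 3-13%)
and solves bite radii against the oracle by bisection at fixed in-sector
sites, so every generated case realizes its intended group; in coverage
mode the first 17 cases span all 17 groups. Wall patterns use 7 mm punches
(or erosion arcs) on flagged sectors and occasional 3.5 mm punches — below
the 5 mm criterion — on unflagged ones; site azimuths keep medial and
lateral features from merging into one loss component. About two thirds of
cases carry an implant and 40% are left-sided. These design constants were
fixed while building the generator so the labeled conditions are actually
realized, and they are part of the generator's definition.

## Numerical choices and limitations

* Analysis pitch 0.25 mm, Boolean default pitch 0.5 mm, phantom mesh pitch
  0.5 mm, truth oracle 0.1 mm, cohort native-volume pass 0.2 mm; the
  validation suite uses a 20-case cohort. These sizes keep a full cohort
  validation in minutes on one CPU while leaving volumetric errors an order
  of magnitude under the 2% recovery target.
* Mesh loading merges duplicate vertices at 1e-6 mm, drops degenerate
  triangles, fan-fills boundary loops under 1 mm diameter and fixes global
  orientation; larger holes are a validation error with an open-edge count
  — heavily damaged meshes should be repaired upstream.
* Watertightness is defined as directed-edge balance (no surface
  boundary), which admits the balanced non-manifold edges of voxel-boundary
  meshes; their enclosed volume is still exact.
* On recovery tolerances: relative 2% bands are meaningful only above the
  voxel surface-dither scale; for formation volumes below ~1 ml the
  validation uses an absolute 0.025 ml floor instead, which at 0.25 mm
  pitch is the honest resolution statement.
* XLSX ingestion is not provided; supplementary-style tables are exchanged
  as CSV with identical column semantics.
* Thresholds (25/25/15/25) mark the grouping concept, not a validated
  definition of clinical relevance; they are configurable, and boundary
  behaviour (strict inequality) is fixed and tested.
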