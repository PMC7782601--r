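---
title: "Planar four-bar knee models and femoral rollback: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planar four-bar knee models and femoral rollback: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`kneefourbar` models sagittal tibiofemoral motion with the classical
crossed four-bar idealisation of the cruciate ligaments: the femur is
the ground link carrying the two femoral insertions, the tibia is the
coupler carrying the two tibial insertions, and the anterior and
posterior cruciate ligaments are the two moving links.  The assumptions
this buys and costs are worth stating explicitly:

* motion is **planar** — all kinematics live in one "main plane", which
  the package estimates from data as the total-least-squares plane of
  the tibia-tracker-centre trajectory;
* bones and ligaments are **rigid**; ligament elongation, laxity and
  out-of-plane coupling (tibial internal rotation, condylar lift-off)
  are outside the model;
* the femorotibial **contact** is a geometric minimal-clearance point
  between two sagittal outlines (condyle polyline against a
  single-valued plateau polyline), measured along the plateau normal,
  with a 0.1&nbsp;mm contact tolerance.  Whether the bodies actually
  touch does not change the reported point: if the surfaces separate or
  interpenetrate (the mechanism, not the contact, guides the motion),
  the minimal-clearance / deepest-penetration point is still the
  natural reading of "the contact point" on a video frame.

**Femoral rollback** is the anterior-posterior (AP) displacement of
that contact point on the tibial plateau, normalised to 0&nbsp;mm at
the extended position and positive posteriorly.  The model's extended
position sits at a flexion angle of 20&deg; in the reporting
convention, so curves are normalised there by default
(`extension_angle = 20`) and evaluated on a 20&ndash;90&deg; grid.

One planar-kinematics identity organises everything.  Let `y_IC(f)` be
the height of the mechanism's instant centre (the crossing point of the
two ligament links) above the plateau, and `y_c(f)` the height of the
centre of the condylar arc currently in contact.  For a circular arc on
a flat plateau the contact lies directly below the arc centre, so

    d(rollback)/d(flexion) = (pi/180) * (y_c - y_IC)   [mm per degree]

The natural condyle is modelled with two tangent-continuous arcs whose
radius decreases posteriorly (distal radius 58&nbsp;mm, posterior
21&nbsp;mm, handover at 36&deg;): in early flexion the high distal
centre rolls back quickly; once the posterior arc takes over and the
instant centre climbs, the curve flattens and gently declines.  A
single-arc implant profile (radius 30&nbsp;mm) has its centre between
the two, producing roughly half the excursion.

## From markers to a mechanism

* **Pose estimation** is SVD-based least-squares rigid registration
  (Kabsch) of each 4-marker cluster against the extended-leg reference
  frame; the tracker centre is the cluster centroid.
* **Flexion angle** is the rotation of the tibia-relative pose with
  respect to the extension reference, projected on the main-plane
  normal: with axis-angle pair `(a, u)`,
  `atan2(sin(a) * dot(u, n), cos(a))`.  Samples whose rotation axis is
  nearly orthogonal to the normal are flagged rather than dropped.
* **Plane fitting** minimises orthogonal distances (smallest principal
  direction); the sign and in-plane axes are fixed by configuration
  hints (lateral direction, AP direction), and the normal is flipped if
  necessary so that flexion comes out positive.
* **Path interpolation** pools all flexion-extension cycles, averages
  duplicate angles, and fits one smoothing spline per in-plane
  coordinate parameterised by flexion angle (generalised
  cross-validation by default; `smoothing = 0` gives exact
  interpolation).

## Two synthesis routes, and why both exist

`synthesize_fourbar()` implements *path synthesis*: it minimises the
squared distances between the coupler point and the target path, with
the input angle an affine function of flexion, by bounded multi-start
Levenberg-Marquardt.  The search is coarse-to-fine: every seeded start
is explored briefly on both elbow branches (30 iterations), the most
promising candidates are polished to convergence, and if the best
polished solution still misses the early-exit tolerance a short series
of jittered restarts (alternating elbow branches) attempts to escape
shallow local minima — in practice the persistent near-miss basin is
the mirrored elbow of the true mechanism.  Starts are drawn half from
the full bound box and half from a scale-aware prior (link lengths
commensurate with the target-path diagonal, pivots preferentially near
the path), which is what a mechanism designer would sketch by hand.
Non-assemblable configurations are handled smoothly: the elbow height
is clamped at zero and the transmission-triangle violation enters the
residual vector as a penalty.  A candidate is rejected unless it
assembles over the whole flexion range, on one branch, at three times
the target sampling density.

Path synthesis is the right tool when only a traced curve is known, but
it has two intrinsic limits.  First, linkages admit *cognates* —
different mechanisms tracing the same coupler curve with different
coupler rotations — so the tibia orientation is not identifiable from
the path alone (`lock_orientation` adds the measured coupler-rotation
constraint when needed).  Second, the true flexion-to-crank
correspondence of a four-bar is not affine, so a perfect simultaneous
fit of path and timing is impossible in that parameterisation;
`refine_drive_map()` replaces the affine map with a monotone spline
after the fit.

The pipeline itself measures more than a path: it measures the full
planar pose of the tibia, and the tibia *is* the coupler.  That turns
dimensional synthesis into the classical Burmester problem with many
precision poses, solved in `synthesize_fourbar_poses()` by a
circle-point search: a moving pivot is a body-fixed point whose
trajectory under the measured poses is a circle, so the two best
distinct minimisers of the circle-fit residual (multi-start
Nelder-Mead over the body plane, algebraic circle fit inside) are the
tibial insertions, the fitted circle centres are the femoral
insertions, and the drive map and body attachment follow exactly.  For
noise-free motion generated by a true four-bar the recovery is exact to
numerical precision, which is what makes the end-to-end round trip
(simulate &rarr; fit &rarr; rollback) reproduce the generator's curves
to well below 0.1&nbsp;mm.

Frames are closed by two registrations that a CT provides in practice:
the 3D pose of the femur sagittal frame relative to the femur tracker
at the extended reference (projected into the fitted plane), and the
extension pose of the tibia sagittal frame relative to the femur
sagittal frame (both bones are imaged in extension in the same CT).

## The synthetic knee and its calibration

The generator's defaults are one-time calibration constants, chosen
once and then frozen.  The calibration used **only the natural
(pre-operative) curve** as its objective — peak displacement 10&nbsp;mm
in early-to-mid flexion, a gentle decline to about 7&nbsp;mm at
90&deg;, contact clearance within 2.5&nbsp;mm over the grid, and
assembly over 0&ndash;120&deg; — over the ligament lengths, insertion
geometry, distal radius and transition angle, followed by rounding to
the values below.  The implant curve was *not* part of the objective;
that the single-arc profile then produces about half the rollback is an
emergent property of the frozen geometry, not a fitted one.

| parameter | default | units | role |
|---|---|---|---|
| `acl_length`, `pcl_length` | 41, 38 | mm | moving link lengths |
| `femoral_insertion_sep` | 11 | mm | ground link length |
| `tibial_insertion_sep` | 27 | mm | coupler link length |
| `acl_elevation` | 54 | deg | ACL inclination at extension |
| `insertion_frac` | 0.265 | &ndash; | tibial insertion split about the plateau centre |
| `distal_radius`, `posterior_radius` | 58, 21 | mm | natural condyle arcs |
| `arc_transition_angle` | 36 | deg | distal-to-posterior handover |
| `implant_radius` | 30 | mm | single-arc implant |
| `plateau_length` | 50 | mm | flat plateau extent |
| `flexion_max` | 120 | deg | required assembly range |

Two placement decisions deserve their rationale:

* **Implant placement is posterior-referenced**: the implant arc is
  tangent to the natural posterior arc at its posterior-most point,
  mirroring measured-resection practice in which the posterior cut
  thickness equals the implant's posterior condyle thickness.  The
  alternative (tangency at the distal-most point) was rejected on
  kinematic grounds: a condyle centre placed on the distal vertical
  swings high in the tibia frame at deep flexion (`y_c` grows with
  `cos f` lost), the post-operative curve then keeps rising and
  eventually exceeds the pre-operative one — the opposite of the
  flattened post-operative behaviour the comparison is meant to show.
* **Natural-vs-implant ordering is a neighbourhood property.**  The
  suite asserts `max rollback(natural) > max rollback(implant)` over
  seeded draws with `posterior_radius < implant_radius <
  distal_radius`, drawn within roughly &plusmn;10% of the calibrated
  geometry (distal 55&ndash;62, posterior 18&ndash;24, implant
  26&ndash;31&nbsp;mm, transition 34&ndash;38&deg;).  Far outside that
  neighbourhood — a much smaller distal radius with a near-distal
  implant radius — the implant behaves like the distal arc and the
  ordering can invert; the linkage, after all, was calibrated for one
  knee, not a population.

The **noise model** is isotropic Gaussian jitter per marker plus a slow
sinusoidal drift of each whole cluster (a stand-in for shell/skin
motion).  It emulates magnitudes, not mechanisms: real soft-tissue
artefact is correlated with flexion, direction-dependent and
non-stationary, and real recordings drop markers.  Passing the
noise-robustness tests therefore shows the pipeline tolerates
realistic *amounts* of perturbation, not that it is validated against
real skin-mounted trackers.

## Numerical choices

* Geometry tolerances are absolute `1e-9` (orthonormality, link-length
  conservation, volume conservation); contact tolerance 0.1&nbsp;mm;
  contact argmin refined by a parabola through the three neighbouring
  clearance samples so the contact trajectory is smooth despite the
  0.2&deg; profile discretisation.
* Mesh cutting nudges vertices lying exactly on the plane to the kept
  side by `1e-12` of the mesh scale; this keeps the crossing topology
  generic (watertight output) at a volume cost far below the `1e-9`
  relative conservation bound.  Cap polygons are triangulated by ear
  clipping with a fan fallback for degenerate rings.
* Monotone (Hyman) splines are used for every drive map; if a refined
  correspondence is non-monotone the code falls back to the affine map
  (path synthesis) or linear interpolation (pose synthesis).
* Branch selection is explicit everywhere: the elbow sign is part of
  the linkage, synthesis searches both, and a candidate whose
  transmission triangle degenerates inside the flexion range is
  rejected (branch-switch rejection).
* Degenerate inputs are first-class: equal condylar radii collapse the
  natural profile to a single arc (and are accepted), collinear marker
  or point sets raise errors naming the defect, identical target
  points or sub-5-point paths refuse synthesis.

## Problem sizes

The reference experiment simulates three 0&ndash;120&deg;
flexion-extension cycles at 2&deg; steps (362 frames, two 4-marker
clusters), fits the linkage to 41 interpolated path samples, and
evaluates rollback on a 71-point grid; the property suites use 20
seeded synthesis repetitions, 1000 random linkages against a
3600-angle assembly sweep, 100 random convex meshes, and 40 seeded
generator draws.  These sizes were chosen so the whole suite documents
the behaviour of every stage while remaining pleasant to run
interactively.

## Known limitations

* The model is strictly planar: no tibial internal-external rotation,
  no medial/lateral condyle asymmetry, no lift-off — a single sagittal
  contact is tracked.
* The plateau is flat by default and must be single-valued in AP; a
  dished plateau is representable as a polyline, but the contact
  clearance is still measured vertically.
* The implant is a profile substitution, not an implanted component:
  malposition studies would need the implant profile re-posed relative
  to the resected femur.
* Path synthesis on short, low-curvature arcs is a sloppy inverse
  problem; many mechanisms fit almost as well as the true one.  When
  poses are available, use the pose route; when not, treat the fitted
  parameters as one representative of an equivalence class whose
  coupler curve — not whose dimensions — is trustworthy.

```{r}
library(kneefourbar)
report <- run_demo(seed = 1)
report
plot_rollback(report$rollback_pre, report$rollback_post)
```
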