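# kneefourbar

Patient-specific planar four-bar models of knee flexion, and the femoral
rollback they predict before and after a simulated total knee
arthroplasty (TKA).

`kneefourbar` is aimed at biomechanics and orthopaedic-engineering work
that models tibiofemoral kinematics with a mechanism rather than a
musculoskeletal simulation: the two cruciate ligaments are idealised as
the moving links of a crossed four-bar whose ground link is the femur
and whose coupler is the tibia.  The package covers the whole chain from
raw optical-tracker marker streams to the clinical quantity of interest:

* **motion** — SVD-based (Kabsch) rigid pose estimation from marker
  clusters, tibia-relative-to-femur poses, signed flexion angles about
  the normal of a total-least-squares *main (sagittal) plane*, and
  smoothing-spline interpolation of the tracker-centre path over flexion;
* **fourbar** — planar four-bar kinematics (assembly by circle-circle
  intersection, both elbow branches, coupler points and curves, Grashof
  classification `s + l <= p + q`) and *dimensional synthesis*: a
  multi-start bounded Levenberg-Marquardt fit of the linkage to a target
  path, plus an exact Burmester-style circle-point search when full body
  poses are measured (the tibia is the coupler, so its two moving pivots
  are body-fixed points whose trajectories are circles);
* **resection** — measured-resection cutting planes from the anatomical
  axes (mechanical axis, TEA, AP, PCA) with the standard angles
  (6&deg; valgus, 3&deg; external rotation, 6&deg; posterior slope),
  applied to watertight triangle meshes with capped plane cuts, removed
  volumes, and planar section contours; ASCII STL I/O;
* **rollback** — the sagittal femorotibial contact point (minimal
  clearance between the posed condyle outline and the tibial plateau)
  tracked over a flexion grid, normalised to 0 mm at the extended
  position, averaged over trials, and compared pre vs post TKA;
* **synthetic_knee** — a fully synthetic, frozen reference knee
  (crossed cruciate four-bar, two-arc natural condyle whose radius
  decreases posteriorly, single-arc posterior-referenced implant
  condyle, flat plateau) plus a tracker-stream simulator with Gaussian
  marker noise and slow cluster drift, so every stage is testable with
  no external data.

The kinematic heart of the rollback prediction is one line of planar
kinematics: the anterior-posterior velocity of the contact point equals
`omega * (y_c - y_IC)`, where `y_c` is the height of the active condylar
arc centre above the plateau and `y_IC` the height of the mechanism's
instant centre (the crossing point of the two ligament links).  A large
distal arc rolls back fast in early flexion; the smaller posterior arc
and the climbing instant centre flatten the curve; a single-arc implant
centred near the posterior condylar centre rolls back roughly half as
far.

## Worked example

```r
library(kneefourbar)
report <- run_demo(seed = 1)   # simulate -> fit -> resect -> rollback
report
#> <knee_demo_report>
#>   synthesis rms 0.0005422 mm (path), attachment rms 0.0005422 mm
#>   pre-op  max rollback 10.02 mm at 37 deg
#>   post-op max rollback 4.84 mm at 90 deg
#>   post/pre ratio 0.483
#>   femoral resection removed 243553 mm^3 in 5 cuts
#>   seed 1, config 7236f426
plot_rollback(report$rollback_pre, report$rollback_post)
```

`run_demo()` generates the frozen synthetic knee, simulates noise-free
tracker streams over three flexion-extension cycles (0-120&deg;),
recovers the flexion samples and main plane from the markers, fits the
four-bar to the measured tibia poses, re-expresses it in the femur bone
frame through the CT-style registration, applies the measured-resection
plan to the synthetic femur solid, and computes the normalised rollback
curves on a 20-90&deg; grid (extension reference 20&deg;, the model's
extended position).  The printed lines mean:

* *synthesis rms* — coupler-path residual of the fitted linkage against
  the measured tracker-centre path (here: exact recovery);
* *pre-op max rollback 10.02 mm at 37&deg;* — the natural two-arc
  condyle rolls back about 10 mm shortly after extension;
* *post-op max rollback 4.84 mm, ratio 0.483* — substituting the
  single-arc implant profile, with nothing else changed, halves the
  rollback;
* *removed volumes* — per-cut bone volume of the five femoral cuts.

The same machinery runs from files: `run_pipeline("config.json")`, or
the thin command-line front end `exec/kneefourbar`
(`simulate | demo | pipeline` subcommands).

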