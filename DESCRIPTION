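Package: kneefourbar
Title: Planar Four-Bar Knee Models and Femoral Rollback Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds patient-specific planar four-bar models of tibiofemoral
    motion from optical marker-cluster recordings: rigid pose estimation
    from marker sets, total-least-squares fitting of the main (sagittal)
    motion plane, dimensional synthesis of a four-bar linkage whose coupler
    path follows the measured tibia trajectory, measured-resection cutting
    planes applied to triangle meshes, and quantification of femoral
    rollback (sagittal femorotibial contact-point displacement) before and
    after a simulated total knee arthroplasty.  A synthetic-knee generator
    (crossed cruciate-ligament four-bar, two-arc natural condyle,
    single-arc implant condyle) provides fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
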