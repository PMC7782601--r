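test_that("the frozen default knee assembles over the full flexion range", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  th <- linkage_input_angle(k$linkage, seq(0, 120, by = 1))
  s <- kneefourbar:::fourbar_solve(k$linkage, th)
  expect_true(all(s$ok))
  ## the drive map reproduces flexion: coupler rotation equals the angle
  for (f in c(0, 30, 60, 90, 120))
    expect_equal(k$tibia_pose(f)$theta, f, tolerance = 1e-6)
})

test_that("equal radii degenerate the natural profile to a single arc", {
  p <- synthetic_knee_params(distal_radius = 38, posterior_radius = 38,
                             implant_radius = 38)
  k <- make_ground_truth_knee(p)
  nat <- k$natural_profile$polyline
  r <- sqrt(rowSums(nat^2))        # distal arc centre is the origin
  expect_lt(max(abs(r - 38)), 1e-9)
  ## and it coincides with a same-radius implant profile
  imp <- k$implant_profile$polyline
  ri <- sqrt(rowSums(imp^2))
  expect_lt(max(abs(ri - 38)), 1e-9)
  expect_error(synthetic_knee_params(posterior_radius = 60,
                                     distal_radius = 58), "exceed")
})

test_that("scaling all lengths scales the rollback curve", {
  p1 <- synthetic_knee_params()
  s <- 2
  p2 <- synthetic_knee_params(
    acl_length = p1$acl_length * s, pcl_length = p1$pcl_length * s,
    femoral_insertion_sep = p1$femoral_insertion_sep * s,
    tibial_insertion_sep = p1$tibial_insertion_sep * s,
    distal_radius = p1$distal_radius * s,
    posterior_radius = p1$posterior_radius * s,
    plateau_length = p1$plateau_length * s,
    implant_radius = p1$implant_radius * s)
  k1 <- make_ground_truth_knee(p1)
  k2 <- make_ground_truth_knee(p2)
  ang <- seq(20, 90, 2)
  c1 <- rollback_curve(k1$linkage, k1$natural_profile, k1$plateau,
                       k1$tibia_attachment, ang)
  c2 <- rollback_curve(k2$linkage, k2$natural_profile, k2$plateau,
                       k2$tibia_attachment, ang)
  expect_equal(c2$displacement, s * c1$displacement, tolerance = 1e-3)
})

test_that("non-constructible ligament geometry raises a parameter error", {
  expect_error(make_ground_truth_knee(
    synthetic_knee_params(femoral_insertion_sep = 1, pcl_length = 150)),
    "not constructible|crossed")
})

test_that("tracker streams are deterministic and noise-free round trips", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  prof <- c(seq(0, 120, 4), seq(116, 4, -4))
  nz <- noise_model(marker_sd = 0.3, shell_drift_amp = 1, seed = 42)
  s1 <- simulate_tracker_stream(k, prof, nz)
  s2 <- simulate_tracker_stream(k, prof, nz)
  expect_identical(s1$frames, s2$frames)

  s3 <- simulate_tracker_stream(k, prof, noise_model(0.3, 1, seed = 43))
  expect_false(identical(s1$frames, s3$frames))

  clean <- simulate_tracker_stream(k, prof, noise_model(0, 0, seed = 1))
  mo <- analyze_motion(clean$frames,
                       lateral_hint = clean$registration$ez,
                       ap_hint = clean$registration$ex)
  expect_lt(max(abs(sort(mo$samples$flexion_deg) - sort(prof))), 1e-6)
  expect_lt(mo$plane_rms_mm, 1e-9)

  expect_error(simulate_tracker_stream(k, c(5, 10, 20)), "reference")
  expect_error(simulate_tracker_stream(k, c(0, 100, 150)), "range")
})

test_that("plane recovery stays within a degree under realistic noise", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  prof <- rep(c(seq(0, 120, 2), seq(118, 2, -2)), 3)
  prof <- c(0, prof[-1])
  sim <- simulate_tracker_stream(k, prof,
                                 noise_model(marker_sd = 0.3,
                                             shell_drift_amp = 0,
                                             seed = 7))
  mo <- analyze_motion(sim$frames, lateral_hint = sim$registration$ez,
                       ap_hint = sim$registration$ex)
  ang <- acos(min(1, abs(sum(mo$plane$normal * sim$registration$ez)))) *
    180 / pi
  expect_lt(ang, 1)
})

test_that("natural rollback exceeds implant rollback across parameter draws", {
  ## draw convention: radii within ~10 percent of the calibrated
  ## geometry (far smaller distal radii with near-distal implant radii
  ## make the implant behave like the distal arc and can invert the
  ## ordering; see the methods vignette)
  set.seed(123)
  n_ok <- 0
  for (i in 1:40) {
    p <- synthetic_knee_params(
      distal_radius = stats::runif(1, 55, 62),
      posterior_radius = stats::runif(1, 18, 24),
      implant_radius = stats::runif(1, 26, 31),
      arc_transition_angle = stats::runif(1, 34, 38))
    k <- make_ground_truth_knee(p)
    ang <- seq(20, 90, 2)
    nat <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                          k$tibia_attachment, ang)
    imp <- rollback_curve(k$linkage, k$implant_profile, k$plateau,
                          k$tibia_attachment, ang)
    expect_gt(max(nat$displacement), max(imp$displacement))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 40)
})

test_that("the synthetic femur solid is watertight with the stated volume", {
  m <- make_synthetic_femur_mesh()
  expect_true(is_watertight(m))
  va <- attr(m, "analytic_volume_mm3")
  expect_lt(abs(mesh_volume(m) - va) / va, 0.01)

  ## mid-condyle section reproduces the generating profile
  p <- synthetic_knee_params()
  pl <- motion_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  sec <- sagittal_profile(m, pl)
  P <- sec$contours[[sec$primary]]
  ## distal-most section point lies on the distal arc radius
  low <- P[which.min(P[, 2]), ]
  expect_equal(sqrt(sum(low^2)), p$distal_radius, tolerance = 0.05)
  ## all section points on the condylar arcs match the generating profile
  prof <- make_ground_truth_knee(p)$natural_profile$polyline
  arc <- P[P[, 2] < -30 & P[, 1] < 20, , drop = FALSE]
  d <- vapply(seq_len(nrow(arc)), function(i)
    min(sqrt(rowSums(sweep(prof, 2, arc[i, ])^2))),
    numeric(1))
  expect_lt(max(d), 0.2)
})
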