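flat_plateau <- function(len = 60)
  plateau_profile(cbind(seq(-len / 2, len / 2, length.out = 13), 0))

circle_condyle <- function(r = 20, center = c(0, 0), kind = "implant") {
  a <- seq(-120, 120, by = 0.25) * pi / 180
  condyle_profile(cbind(center[1] + r * sin(a), center[2] - r * cos(a)),
                  kind)
}

test_that("circle-on-line contact follows the closed form", {
  plat <- flat_plateau()
  cond <- circle_condyle(r = 20)   # centred at the profile-frame origin
  ## condyle centre posed at (x0, y0): contact under the centre,
  ## clearance y0 - r
  pose <- se2_pose(0, c(7, 24.5))
  cp <- contact_point(cond, pose, plat)
  expect_equal(cp$contact[1], 7, tolerance = 1e-6)
  expect_equal(cp$clearance, 4.5, tolerance = 1e-4)
  expect_false(cp$in_contact)

  pose2 <- se2_pose(0, c(-4, 20.05))
  cp2 <- contact_point(cond, pose2, plat)
  expect_true(cp2$in_contact)
  expect_equal(cp2$clearance, 0.05, tolerance = 1e-4)

  ## rotation about the centre does not move the contact of a circle
  pose3 <- se2_pose(35, c(-4, 20.05))
  cp3 <- contact_point(cond, pose3, plat)
  expect_equal(cp3$contact[1], cp2$contact[1], tolerance = 1e-6)
})

test_that("a circle rolling without slip advances the contact by r*theta", {
  plat <- flat_plateau(200)
  r <- 20
  cond <- circle_condyle(r = r)
  for (th in c(10, 25, 40)) {
    ## rolling pose: centre advances r*theta while the body spins -theta
    x <- r * th * pi / 180
    pose <- se2_pose(-th, c(x, r))
    cp <- contact_point(cond, pose, plat)
    expect_equal(cp$contact[1], x, tolerance = 1e-6)
    expect_lt(abs(cp$clearance), 1e-6)
  }
})

test_that("contact requires anterior-posterior overlap", {
  plat <- flat_plateau(20)
  cond <- circle_condyle(r = 5)
  expect_error(contact_point(cond, se2_pose(0, c(500, 10)), plat),
               "overlap")
})

test_that("contact_point is equivariant under a shared AP shift", {
  plat0 <- flat_plateau(120)
  cond <- circle_condyle(r = 18, center = c(3, 1))
  pose <- se2_pose(12, c(5, 18))
  cp0 <- contact_point(cond, pose, plat0)
  dx <- 14
  plat1 <- plateau_profile(cbind(plat0$polyline[, 1] + dx,
                                 plat0$polyline[, 2]),
                           center_ap = dx)
  pose1 <- se2_pose(12, c(5 + dx, 18))
  cp1 <- contact_point(cond, pose1, plat1)
  expect_equal(cp1$contact[1] - dx, cp0$contact[1], tolerance = 1e-9)
  expect_equal(cp1$clearance, cp0$clearance, tolerance = 1e-9)
})

test_that("rollback curves are normalised exactly at the extension angle", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  cv <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                       k$tibia_attachment, seq(20, 90, 5))
  expect_identical(cv$displacement[cv$flexion == 20], 0)
  ## normalisation is idempotent
  cv2 <- kneefourbar:::renormalize_rollback(cv)
  expect_equal(cv2$displacement, cv$displacement)
  ## an off-grid extension reference subtracts the raw value at that
  ## angle: normalized = raw - raw(extension)
  raw <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                        k$tibia_attachment, seq(20, 91, 0.5),
                        normalize = FALSE)
  cv3 <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                        k$tibia_attachment, seq(21, 91, 7),
                        extension_angle = 20)
  raw20 <- raw$displacement[raw$flexion == 20]
  raw21 <- raw$displacement[raw$flexion == 21]
  expect_equal(cv3$displacement[cv3$flexion == 21], raw21 - raw20,
               tolerance = 1e-9)
})

test_that("a condyle spinning about its own arc centre produces no rollback", {
  plat <- flat_plateau(120)
  cond <- circle_condyle(r = 22)
  x <- vapply(seq(0, 60, 5), function(th) {
    contact_point(cond, se2_pose(-th, c(4, 22.0)), plat)$contact[1]
  }, numeric(1))
  expect_lt(max(abs(x - x[1])), 1e-6)
})

test_that("average_trials implements the mean-of-three-flexions protocol", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  base <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                         k$tibia_attachment, seq(20, 90, 2))
  m <- average_trials(list(base, base, base))
  expect_equal(m$displacement, base$displacement, tolerance = 1e-12)

  shift <- function(cv, d) { cv$displacement <- cv$displacement + d; cv }
  m2 <- average_trials(list(shift(base, 1), base, shift(base, -1)))
  expect_equal(m2$displacement, base$displacement, tolerance = 1e-12)

  ## averaging reduces the error of noisy realizations
  set.seed(19)
  noisy <- lapply(1:3, function(i) {
    cv <- base
    cv$displacement <- cv$displacement + stats::rnorm(length(cv$flexion),
                                                      sd = 0.4)
    kneefourbar:::renormalize_rollback(cv)
  })
  mm <- average_trials(noisy)
  rms <- function(cv) sqrt(mean((cv$displacement - base$displacement)^2))
  expect_lt(rms(mm), min(vapply(noisy, rms, numeric(1))))
  expect_error(average_trials(list()), "no rollback")
})

test_that("compare_rollback reports maxima, angles and the ratio", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  pre <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                        k$tibia_attachment, seq(20, 90, 1))
  same <- compare_rollback(pre, pre)
  expect_equal(same$ratio, 1)
  expect_equal(max(abs(same$pointwise_delta$displacement)), 0)

  half <- pre
  half$displacement <- pre$displacement / 2
  cmp <- compare_rollback(pre, half)
  expect_equal(cmp$ratio, 0.5, tolerance = 1e-12)

  ## grid-max oracle: brute force over the sampled grid
  post <- rollback_curve(k$linkage, k$implant_profile, k$plateau,
                         k$tibia_attachment, seq(20, 90, 1))
  cmp2 <- compare_rollback(pre, post)
  expect_equal(cmp2$max_pre, max(pre$displacement))
  expect_equal(cmp2$angle_at_max_pre,
               pre$flexion[which.max(pre$displacement)])
  expect_equal(cmp2$max_post, max(post$displacement))

  far <- pre; far$flexion <- far$flexion + 500
  expect_error(compare_rollback(pre, far), "disjoint")
})

test_that("rollback CSV export keeps trial structure", {
  k <- make_ground_truth_knee(synthetic_knee_params())
  cv <- rollback_curve(k$linkage, k$natural_profile, k$plateau,
                       k$tibia_attachment, seq(20, 90, 10))
  f <- tempfile(fileext = ".csv")
  write_rollback_csv(list(pre = cv, post = cv), f)
  d <- utils::read.csv(f)
  expect_named(d, c("flexion_deg", "displacement_mm", "trial_id"))
  expect_equal(nrow(d), 2L * length(cv$flexion))
  unlink(f)
})
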