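test_that("pose_from_markers handles identity and pure translation", {
  ref <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  r <- pose_from_markers(ref, ref)
  expect_equal(r$pose$rotation, diag(3), tolerance = 1e-12)
  expect_equal(r$pose$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(r$rms, 1e-12)

  t0 <- c(10, -5, 3)
  r2 <- pose_from_markers(ref, sweep(ref, 2, t0, "+"))
  expect_equal(r2$pose$rotation, diag(3), tolerance = 1e-12)
  expect_equal(r2$pose$translation, t0, tolerance = 1e-12)
})

test_that("pose_from_markers recovers random rigid transforms exactly", {
  set.seed(11)
  ref <- rbind(c(0, 0, 0), c(80, 5, -10), c(10, 90, 20), c(-30, 40, 70))
  for (i in 1:20) {
    R <- random_rotation()
    t0 <- stats::rnorm(3, sd = 200)
    obs <- sweep(ref %*% t(R), 2, t0, "+")
    r <- pose_from_markers(ref, obs)
    expect_lt(max(abs(r$pose$rotation - R)), 1e-9)
    expect_lt(max(abs(r$pose$translation - t0)), 1e-9)
    expect_lt(r$rms, 1e-9)
  }
})

test_that("pose_from_markers rejects degenerate marker sets", {
  ref <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  expect_error(pose_from_markers(ref[1:2, ], ref[1:2, ]), "3 markers")
  expect_error(pose_from_markers(ref, ref[1:2, ]), "differ")
  col <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(pose_from_markers(col, col), "collinear")
})

test_that("relative_pose composes and round-trips", {
  set.seed(5)
  mk <- function() rigid_pose(random_rotation(), stats::rnorm(3, sd = 100))
  f <- mk(); t0 <- mk()
  expect_equal(relative_pose(f, f)$rotation, diag(3), tolerance = 1e-12)
  id <- rigid_pose()
  expect_equal(relative_pose(id, t0)$rotation, t0$rotation)
  rel <- relative_pose(f, t0)
  back <- pose_compose(f, rel)
  expect_lt(max(abs(back$rotation - t0$rotation)), 1e-9)
  expect_lt(max(abs(back$translation - t0$translation)), 1e-9)
})

test_that("flexion_angle is zero at the reference and exact in-plane", {
  pl <- motion_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  ref <- rigid_pose(random_rotation(), c(1, 2, 3))
  expect_equal(as.numeric(flexion_angle(ref, ref, pl)), 0)
  rot90 <- rigid_pose(kneefourbar:::rotation_about_axis(c(0, 0, 1), 90))
  rel <- pose_compose(ref, rot90)
  ## rotation applied in the reference frame, about the plane normal
  rel2 <- rigid_pose(ref$rotation %*% rot90$rotation, ref$translation)
  expect_equal(as.numeric(flexion_angle(rel2, ref, pl)), 90,
               tolerance = 1e-9)
})

test_that("flexion_angle matches an independent axis-angle oracle", {
  pl <- motion_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  ## axis 10 degrees off the plane normal, rotation 37 degrees
  ax <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  R <- kneefourbar:::rotation_about_axis(ax, 37)
  ref <- rigid_pose()
  rel <- rigid_pose(R)
  got <- as.numeric(flexion_angle(rel, ref, pl))
  ## oracle: eigen decomposition for the axis, trace for the angle,
  ## then the same signed projection definition computed independently
  ev <- eigen(R)
  i <- which.min(abs(ev$values - 1))
  axis <- Re(ev$vectors[, i]); axis <- axis / sqrt(sum(axis^2))
  ang <- acos((sum(diag(R)) - 1) / 2)
  ## orient the eigen axis to agree with the rotation sense
  test <- (R - t(R)) / 2
  w <- c(test[3, 2], test[1, 3], test[2, 1])
  if (sum(w * axis) < 0) axis <- -axis
  oracle <- atan2(sin(ang) * sum(axis * pl$normal), cos(ang)) * 180 / pi
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("fit_main_plane recovers exact and noisy planes", {
  set.seed(21)
  pts <- cbind(stats::runif(50, -40, 40), stats::runif(50, -40, 40), 5)
  pl <- fit_main_plane(pts)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(attr(pl, "rms_mm"), 1e-9)

  tri <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 10))
  pl3 <- fit_main_plane(tri)
  d <- as.numeric(sweep(tri, 2, pl3$origin) %*% pl3$normal)
  expect_lt(max(abs(d)), 1e-9)

  ## Monte-Carlo recovery: known random plane + isotropic noise sd 1 mm
  n_true <- c(1, 2, 3) / sqrt(14)
  basis <- kneefourbar:::plane_basis(n_true)
  uv <- cbind(stats::runif(500, -60, 60), stats::runif(500, -60, 60))
  cloud <- uv[, 1] %o% basis$ex + uv[, 2] %o% basis$ey +
    matrix(stats::rnorm(1500, sd = 1), 500, 3)
  plf <- fit_main_plane(cloud, lateral_hint = n_true)
  ang <- acos(min(1, abs(sum(plf$normal * n_true)))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("fit_main_plane errors on degenerate input and keeps frames orthonormal", {
  expect_error(fit_main_plane(rbind(c(0, 0, 0), c(1, 0, 0))), "3 points")
  col <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_main_plane(col), "collinear")
  set.seed(3)
  pts <- matrix(stats::rnorm(60, sd = 30), 20, 3)
  pl <- fit_main_plane(pts)
  M <- cbind(pl$in_plane_x, pl$in_plane_y, pl$normal)
  expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
  expect_gt(det(M), 0)
})

test_that("fit_main_plane is equivariant under rigid transformation", {
  set.seed(13)
  pts <- cbind(stats::rnorm(40, sd = 30), stats::rnorm(40, sd = 30),
               stats::rnorm(40, sd = 0.5))
  pl0 <- fit_main_plane(pts)
  R <- random_rotation(); t0 <- stats::rnorm(3, sd = 50)
  pl1 <- fit_main_plane(sweep(pts %*% t(R), 2, t0, "+"),
                        lateral_hint = as.numeric(R %*% pl0$normal))
  expect_lt(max(abs(pl1$normal - as.numeric(R %*% pl0$normal))), 1e-9)
})

test_that("project_trajectory round-trips through embedding", {
  pl <- fit_main_plane(rbind(c(0, 0, 5), c(10, 0, 5), c(0, 10, 5),
                             c(7, 9, 5)))
  p0 <- rbind(pl$origin)
  pr <- project_trajectory(p0, pl)
  expect_equal(as.numeric(pr$uv), c(0, 0), tolerance = 1e-12)
  expect_equal(pr$residual, 0, tolerance = 1e-12)
  p1 <- rbind(pl$origin + 7 * pl$in_plane_x + 2 * pl$normal)
  pr1 <- project_trajectory(p1, pl)
  expect_equal(as.numeric(pr1$uv), c(7, 0), tolerance = 1e-12)
  expect_equal(pr1$residual, 2, tolerance = 1e-12)

  set.seed(9)
  cloud <- matrix(stats::rnorm(90, sd = 40), 30, 3)
  pr2 <- project_trajectory(cloud, pl)
  back <- embed_trajectory(pr2$uv, pl, pr2$residual)
  expect_lt(max(abs(back - cloud)), 1e-9)
  expect_error(project_trajectory(cloud[0, , drop = FALSE], pl), "no traj")
})

test_that("interpolate_flexion_path is exact on clean arcs and robust to noise", {
  ang <- seq(0, 90, by = 1)
  pts <- cbind(50 * cos(ang * pi / 180), 50 * sin(ang * pi / 180))
  ip <- interpolate_flexion_path(pts, ang, n_out = 181, smoothing = 0)
  r <- sqrt(rowSums(ip$points^2))
  expect_lt(max(abs(r - 50)), 1e-6)

  ## duplicate angles from repeated cycles are pooled without error
  ip2 <- interpolate_flexion_path(rbind(pts, pts), c(ang, ang),
                                  n_out = 91, smoothing = 0)
  expect_equal(nrow(ip2$points), 91L)

  set.seed(31)
  noisy <- pts + matrix(stats::rnorm(length(pts), sd = 0.5), ncol = 2)
  ip3 <- interpolate_flexion_path(noisy, ang, n_out = 91)
  truth <- cbind(50 * cos(ip3$angle * pi / 180),
                 50 * sin(ip3$angle * pi / 180))
  rmse <- sqrt(mean(rowSums((ip3$points - truth)^2) / 2))
  expect_lt(rmse, 0.5)

  expect_error(interpolate_flexion_path(pts[1:10, ], ang[1:10],
                                        min_span = 20), "span")
})
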