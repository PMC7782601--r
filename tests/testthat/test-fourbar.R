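test_that("parallelogram linkage follows the closed form", {
  ## len_input = len_follower, len_coupler = ground length: the coupler
  ## stays parallel to ground, follower tip = ground_b + input vector
  ga <- c(0, 0); gb <- c(40, 0)
  lk <- fourbar_linkage(ga, gb, 15, 40, 15, branch = 1)
  for (th in c(10, 45, 80, 130)) {
    st <- assembly_state(lk, th)
    expect_equal(st$follower_tip,
                 gb + 15 * c(cos(th * pi / 180), sin(th * pi / 180)),
                 tolerance = 1e-9)
  }
  ## coupler point with offset (d, h) traces a circle of radius len_input
  ## about ground_a + R(0)(d, h)  (coupler rotation is constant)
  lk2 <- fourbar_linkage(ga, gb, 15, 40, 15, coupler_offset = c(12, 7),
                         branch = 1)
  th <- seq(5, 170, by = 15)
  cp <- t(vapply(th, function(a) coupler_point(lk2, a), numeric(2)))
  ctr <- c(12, 7)  # coupler frame parallel to ground: offset in ground axes
  r <- sqrt(rowSums(sweep(cp, 2, ctr)^2))
  expect_lt(max(abs(r - 15)), 1e-9)
})

test_that("broken linkage reports the not-assemblable angle", {
  lk <- fourbar_linkage(c(0, 0), c(100, 0), 10, 20, 10, branch = 1)
  expect_error(assembly_state(lk, 0), "not assemblable")
  expect_error(assembly_state(lk, 0), "0.000")
})

test_that("assembly matches an independent circle-circle construction", {
  lk <- demo_crank_rocker()
  th <- 37
  st <- assembly_state(lk, th)
  ## independent oracle: explicit circle-circle intersection formula
  P <- c(0, 0) + 22 * c(cos(th * pi / 180), sin(th * pi / 180))
  gb <- c(60, 5)
  d <- sqrt(sum((gb - P)^2))
  a <- (55^2 - 45^2 + d^2) / (2 * d)
  h <- sqrt(55^2 - a^2)
  u <- (gb - P) / d
  sol1 <- P + a * u + h * c(-u[2], u[1])
  expect_equal(st$input_tip, P, tolerance = 1e-12)
  expect_equal(st$follower_tip, sol1, tolerance = 1e-9)
})

test_that("assembly conserves all three link lengths", {
  set.seed(41)
  for (i in 1:25) {
    lk <- fourbar_linkage(stats::runif(2, -20, 20), stats::runif(2, 20, 60),
                          stats::runif(1, 10, 50), stats::runif(1, 10, 50),
                          stats::runif(1, 10, 50),
                          branch = sample(c(-1, 1), 1))
    th <- seq(0, 359, by = 7)
    s <- kneefourbar:::fourbar_solve(lk, th)
    if (!any(s$ok)) next
    it <- s$input_tip[s$ok, , drop = FALSE]
    ft <- s$follower_tip[s$ok, , drop = FALSE]
    expect_lt(max(abs(sqrt(rowSums(sweep(it, 2, lk$ground_a)^2)) -
                        lk$len_input)), 1e-9)
    expect_lt(max(abs(sqrt(rowSums(sweep(ft, 2, lk$ground_b)^2)) -
                        lk$len_follower)), 1e-9)
    expect_lt(max(abs(sqrt(rowSums((ft - it)^2)) - lk$len_coupler)), 1e-9)
  }
})

test_that("coupler point offsets reproduce the joint positions", {
  lk <- demo_crank_rocker(offset = c(0, 0))
  st <- assembly_state(lk, 25)
  expect_equal(coupler_point(lk, 25), st$input_tip, tolerance = 1e-12)
  lk2 <- demo_crank_rocker(offset = c(55, 0))
  expect_equal(coupler_point(lk2, 25), st$follower_tip, tolerance = 1e-9)
})

test_that("coupler curve closes for a crank-rocker and respects reversal", {
  lk <- demo_crank_rocker()
  cc <- coupler_curve(lk, c(0, 360), 721)
  expect_true(all(cc$assemblable))
  expect_lt(sqrt(sum((cc$points[1, ] - cc$points[721, ])^2)), 1e-9)

  two <- coupler_curve(lk, c(10, 50), 2)
  expect_equal(nrow(two$points), 2L)
  expect_equal(two$points[1, ], coupler_point(lk, 10), tolerance = 1e-12)

  fwd <- coupler_curve(lk, c(10, 80), 36)
  bwd <- coupler_curve(lk, c(80, 10), 36)
  expect_equal(fwd$points, bwd$points[36:1, ], tolerance = 1e-12)

  broken <- fourbar_linkage(c(0, 0), c(100, 0), 10, 20, 10)
  expect_error(coupler_curve(broken, c(0, 360), 100), "not assemblable")
})

test_that("coupler curve is continuous on the primary branch", {
  lk <- demo_crank_rocker()
  cc <- coupler_curve(lk, c(0, 90), 901)  # 0.1 degree spacing
  d <- sqrt(rowSums(diff(cc$points)^2))
  ## bound: input tip moves len_input * dtheta, coupler point amplified by
  ## the offset geometry; generous constant-factor tolerance
  bound <- (lk$len_input + sqrt(sum(lk$coupler_offset^2))) *
    0.1 * pi / 180 * 3 + 1e-6
  expect_lt(max(d), bound)
})

test_that("classify_grashof reproduces the textbook cases", {
  ## ground 3.5, input 1, coupler 2, follower 3: crank-rocker
  lk <- fourbar_linkage(c(0, 0), c(3.5, 0), 1, 2, 3)
  g <- classify_grashof(lk)
  expect_true(g$grashof)
  expect_equal(g$class, "crank-rocker")
  expect_true(g$input_is_crank)
  ## 1, 2, 3, 4 in any placement: s + l = p + q, change point
  lk2 <- fourbar_linkage(c(0, 0), c(1, 0), 2, 3, 4)
  expect_equal(classify_grashof(lk2)$class, "change-point")
  ## shortest link grounded: double crank
  lk3 <- fourbar_linkage(c(0, 0), c(1, 0), 4, 3.5, 4.2)
  expect_equal(classify_grashof(lk3)$class, "double-crank")
})

test_that("classification agrees with an exhaustive assemblability sweep", {
  set.seed(97)
  n_cases <- 200
  for (i in seq_len(n_cases)) {
    len <- stats::runif(4, 1, 10)
    ## avoid the change-point measure-zero boundary
    s <- min(len); l <- max(len)
    if (abs(s + l - (sum(len) - s - l)) < 1e-3) next
    lk <- fourbar_linkage(c(0, 0), c(len[1], 0), len[2], len[3], len[4])
    sweep_ok <- all(kneefourbar:::fourbar_solve(lk, seq(0, 359.9, 0.5))$ok)
    expect_identical(classify_grashof(lk)$input_is_crank, sweep_ok)
  }
})

test_that("tibia_pose_from_linkage is consistent with the coupler geometry", {
  lk <- demo_crank_rocker()
  st <- assembly_state(lk, 40)
  ## attachment coincident with the coupler frame
  p0 <- tibia_pose_from_linkage(lk, 40, se2_pose())
  expect_equal(p0$t, st$input_tip, tolerance = 1e-12)
  ## transforming the attachment origin equals coupler_point with the
  ## matching offset
  att <- se2_pose(30, c(12, -8))
  p1 <- tibia_pose_from_linkage(lk, 40, att)
  lk2 <- demo_crank_rocker(offset = c(12, -8))
  expect_equal(p1$t, coupler_point(lk2, 40), tolerance = 1e-9)
  ## parallelogram: constant coupler rotation for all angles
  para <- fourbar_linkage(c(0, 0), c(40, 0), 15, 40, 15)
  th <- seq(10, 150, by = 10)
  rot <- vapply(th, function(a)
    tibia_pose_from_linkage(para, a, se2_pose())$theta, numeric(1))
  expect_lt(max(abs(rot - rot[1])), 1e-9)
})

test_that("linkage JSON round-trips", {
  lk <- demo_crank_rocker()
  lk$drive <- c(10, 1)
  f <- tempfile(fileext = ".json")
  write_linkage_json(lk, f)
  lk2 <- read_linkage_json(f)
  expect_equal(lk2$ground_b, lk$ground_b)
  expect_equal(lk2$len_coupler, lk$len_coupler)
  expect_equal(linkage_input_angle(lk2, 25), linkage_input_angle(lk, 25))
  unlink(f)
})
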