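#' Configuration for four-bar dimensional synthesis
#'
#' @param n_starts number of random multi-start initialisations (>= 1).
#' @param seed integer RNG seed (mandatory: identical seed and inputs give
#'   identical results).
#' @param angle_range input-angle range searched (degrees) -- used to
#'   bound the affine flexion-to-input map.
#' @param bounds optional named list of length-2 numeric boxes for
#'   `pivot` (mm, added around the target bounding box), `length` (mm) and
#'   `offset` (mm).  Defaults: lengths in [5, 200] mm, pivots in the
#'   target bounding box +/- 100 mm, offsets in [-200, 200] mm.
#' @param correspondence `"ordered-by-angle"` (the input angle is an
#'   affine function of the flexion angle, its two parameters free) or
#'   `"closest-point"` (each target matched to the nearest point of the
#'   sampled coupler curve).
#' @param tolerance early-exit RMS tolerance (mm): starts stop once a
#'   feasible solution at least this good is found.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param lock_orientation also constrain the coupler-link rotation to
#'   follow the flexion angle (up to a free constant offset).  Path
#'   synthesis alone admits cognate linkages that trace the same coupler
#'   curve with a different coupler rotation; when the coupler is the
#'   tibia itself its rotation is measured, and locking it selects the
#'   kinematically correct solution.
#' @return object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_starts = 50L, seed = 1L,
                             angle_range = c(-180, 180), bounds = NULL,
                             correspondence = c("ordered-by-angle",
                                                "closest-point"),
                             tolerance = 1e-4, max_iter = 400L,
                             lock_orientation = FALSE) {
  correspondence <- match.arg(correspondence)
  stopifnot(n_starts >= 1L, length(angle_range) == 2L, tolerance >= 0)
  b <- list(length = c(5, 200), pivot = c(-100, 100), offset = c(-200, 200))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 angle_range = angle_range, bounds = b,
                 correspondence = correspondence, tolerance = tolerance,
                 max_iter = as.integer(max_iter),
                 lock_orientation = isTRUE(lock_orientation)),
            class = "synthesis_config")
}

## parameter vector layout for the optimiser:
## p = (gax, gay, gbx, gby, L1, L2, L3, ox, oy, m0, m1); theta = m0 + m1*f
par_to_linkage <- function(p, branch) {
  fourbar_linkage(ground_a = p[1:2], ground_b = p[3:4], len_input = p[5],
                  len_coupler = p[6], len_follower = p[7],
                  coupler_offset = p[8:9], branch = branch,
                  drive = c(p[10], p[11]))
}

## smooth residuals: coupler-point errors with the triangle inequality
## relaxed (elbow height clamped at 0) plus a penalty on the violation;
## with `lock` the coupler rotation must follow flexion up to the free
## offset p[12] (residual scaled by the coupler length as moment arm)
synth_residuals <- function(p, flexion, target, branch, penalty_w = 10,
                            lock = FALSE) {
  theta <- deg2rad(p[10] + p[11] * flexion)
  px <- p[1] + p[5] * cos(theta)
  py <- p[2] + p[5] * sin(theta)
  dx <- p[3] - px; dy <- p[4] - py
  d <- sqrt(dx^2 + dy^2)
  d <- pmax(d, 1e-9)
  a <- (p[6]^2 - p[7]^2 + d^2) / (2 * d)
  h2 <- p[6]^2 - a^2
  viol <- sqrt(pmax(-h2, 0))
  h <- sqrt(pmax(h2, 0))
  ux <- dx / d; uy <- dy / d
  fx <- px + a * ux - branch * h * uy
  fy <- py + a * uy + branch * h * ux
  ex <- (fx - px) / p[6]; ey <- (fy - py) / p[6]
  cx <- px + p[8] * ex - p[9] * ey
  cy <- py + p[8] * ey + p[9] * ex
  out <- c(cx - target[, 1], cy - target[, 2], penalty_w * viol)
  if (lock) {
    da <- atan2(ey, ex) - deg2rad(flexion + p[12])
    out <- c(out, atan2(sin(da), cos(da)) * p[6])
  }
  out
}

## nearest-point residuals for correspondence = "closest-point"
synth_residuals_cp <- function(p, flexion, target, branch, penalty_w = 10) {
  fr <- range(flexion)
  fgrid <- seq(fr[1], fr[2], length.out = 181L)
  theta <- deg2rad(p[10] + p[11] * fgrid)
  px <- p[1] + p[5] * cos(theta)
  py <- p[2] + p[5] * sin(theta)
  dx <- p[3] - px; dy <- p[4] - py
  d <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  a <- (p[6]^2 - p[7]^2 + d^2) / (2 * d)
  h2 <- p[6]^2 - a^2
  viol <- sqrt(pmax(-h2, 0))
  h <- sqrt(pmax(h2, 0))
  ux <- dx / d; uy <- dy / d
  fx <- px + a * ux - branch * h * uy
  fy <- py + a * uy + branch * h * ux
  ex <- (fx - px) / p[6]; ey <- (fy - py) / p[6]
  cx <- px + p[8] * ex - p[9] * ey
  cy <- py + p[8] * ey + p[9] * ex
  dmin <- vapply(seq_len(nrow(target)), function(i)
    min(sqrt((cx - target[i, 1])^2 + (cy - target[i, 2])^2)),
    numeric(1))
  c(dmin, penalty_w * mean(viol) * sqrt(length(dmin)))
}

## feasibility: assemblable (with margin) over the whole flexion range at
## 3x the target sampling, no branch fold (elbow height stays positive)
synth_feasible <- function(linkage, flexion) {
  fr <- range(flexion)
  dense <- seq(fr[1], fr[2], length.out = max(3L * length(flexion), 61L))
  s <- fourbar_solve(linkage, linkage_input_angle(linkage, dense))
  all(s$ok) && all(s$h > 1e-6 * linkage$len_coupler)
}

#' Dimensional synthesis of a four-bar from a target path
#'
#' Finds linkage dimensions, a coupler-point offset and an affine
#' flexion-to-input-angle map such that the coupler point tracks the
#' target path: bounded multi-start local least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}), both elbow branches
#' searched, infeasible assemblies handled by a smooth penalty on the
#' transmission-triangle violation.  A candidate is rejected if the
#' mechanism does not assemble over the whole flexion range on one branch.
#'
#' @param target_path n x 2 matrix of target points (mm), n >= 5.
#' @param flexion flexion angle per target point (degrees).
#' @param cfg a [synthesis_config()].
#' @return list with `linkage` (a [fourbar_linkage()] carrying the fitted
#'   affine drive map), `rms_mm`, `max_mm`, `n_starts_converged`,
#'   `starts` (per-start log data.frame).
#' @export
synthesize_fourbar <- function(target_path, flexion, cfg = synthesis_config()) {
  target <- as.matrix(target_path)
  stopifnot(ncol(target) == 2L, nrow(target) == length(flexion))
  if (nrow(target) < 5L)
    stop("at least 5 target points are required for synthesis")
  span <- max(dist(target[c(1L, round(nrow(target) / 2), nrow(target)), ]))
  if (max(dist(target)) < 1e-9)
    stop("degenerate target path: all points identical")
  if (diff(range(flexion)) < 1e-9)
    stop("degenerate flexion range")
  lock <- isTRUE(cfg$lock_orientation)
  if (lock && cfg$correspondence != "ordered-by-angle")
    stop("lock_orientation requires the ordered-by-angle correspondence")
  resfun <- if (cfg$correspondence == "ordered-by-angle") synth_residuals
            else synth_residuals_cp
  bb <- apply(target, 2L, range)
  lo <- c(bb[1, 1] + cfg$bounds$pivot[1], bb[1, 2] + cfg$bounds$pivot[1],
          bb[1, 1] + cfg$bounds$pivot[1], bb[1, 2] + cfg$bounds$pivot[1],
          rep(cfg$bounds$length[1], 3L),
          rep(cfg$bounds$offset[1], 2L), -360, -6)
  if (lock) lo <- c(lo, -360)
  hi <- c(bb[2, 1] + cfg$bounds$pivot[2], bb[2, 2] + cfg$bounds$pivot[2],
          bb[2, 1] + cfg$bounds$pivot[2], bb[2, 2] + cfg$bounds$pivot[2],
          rep(cfg$bounds$length[2], 3L),
          rep(cfg$bounds$offset[2], 2L), 360, 6)
  if (lock) hi <- c(hi, 360)
  set.seed(cfg$seed)
  n <- nrow(target)
  best <- NULL
  log_rows <- vector("list", cfg$n_starts)
  ## scale-aware start prior: half the starts draw link lengths
  ## commensurate with the target path size and pivots near the path,
  ## the other half cover the full bound box
  dg <- max(sqrt(sum((bb[2, ] - bb[1, ])^2)), 1e-6)
  ctr <- colMeans(bb)
  rlog <- function(k, a, b) exp(stats::runif(k, log(a), log(b)))
  rand_start <- function(scaled) {
    if (scaled) {
      ang <- stats::runif(2, 0, 2 * pi)
      rad <- rlog(2, 0.3 * dg, 6 * dg)
      ga <- ctr + rad[1] * c(cos(ang[1]), sin(ang[1]))
      gb <- ctr + rad[2] * c(cos(ang[2]), sin(ang[2]))
      lens <- rlog(3, 0.5 * dg, 8 * dg)
      offs <- rlog(2, 0.2 * dg, 6 * dg) * sample(c(-1, 1), 2, TRUE)
      m1 <- sample(c(-1, 1), 1) * rlog(1, 0.25, 3)
      p0 <- c(ga, gb, lens, offs, stats::runif(1, -360, 360), m1)
    } else {
      p0 <- lo[1:11] + stats::runif(11L) * (hi[1:11] - lo[1:11])
      if (abs(p0[11]) < 0.2) p0[11] <- sign(p0[11] + 1e-12) * 0.2
    }
    if (length(lo) > 11L) p0 <- c(p0, stats::runif(1, -360, 360))
    pmin(pmax(p0, lo), hi)
  }
  extra <- if (identical(resfun, synth_residuals)) list(lock = lock)
           else list()
  run_lm <- function(p0, branch, maxit) {
    fit <- try(suppressWarnings(do.call(minpack.lm::nls.lm, c(list(
      par = pmin(pmax(p0, lo), hi), lower = lo, upper = hi, fn = resfun,
      flexion = flexion, target = target, branch = branch,
      control = minpack.lm::nls.lm.control(maxiter = maxit,
                                           ptol = 1e-13, ftol = 1e-13)),
      extra))), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    p <- fit$par
    r <- synth_residuals(p[1:11], flexion, target, branch, penalty_w = 0)
    rms <- sqrt(mean(r[seq_len(2L * n)]^2) * 2)  # per-point 2D rms
    if (lock) {
      ro <- synth_residuals(p, flexion, target, branch, penalty_w = 0,
                            lock = TRUE)
      rms <- sqrt(rms^2 + mean(ro[2L * n + seq_len(n)]^2))
    }
    lk <- try(par_to_linkage(p[1:11], branch), silent = TRUE)
    feas <- !inherits(lk, "try-error") && synth_feasible(lk, flexion)
    list(par = p, branch = branch, rms = rms, feasible = feas,
         converged = fit$info %in% 1:4)
  }
  ## screening pass: every seeded start is explored briefly on both
  ## elbow branches, then the most promising candidates are polished to
  ## full convergence (coarse-to-fine multi-start)
  cands <- vector("list", 2L * cfg$n_starts)
  ci <- 0L
  for (s in seq_len(cfg$n_starts)) {
    p0 <- rand_start(s %% 2L == 0L)
    for (branch in c(1, -1)) {
      r <- run_lm(p0, branch, 30L)
      if (!is.null(r)) {
        ci <- ci + 1L
        r$start <- s
        cands[[ci]] <- r
      }
    }
  }
  cands <- cands[seq_len(ci)]
  log_rows <- lapply(cands, function(z)
    data.frame(start = z$start, branch = z$branch, rms_mm = z$rms,
               feasible = z$feasible, converged = z$converged))
  best <- NULL
  ord <- order(vapply(cands, function(z) z$rms, numeric(1)))
  n_polish <- min(16L, length(ord))
  for (i in ord[seq_len(n_polish)]) {
    r <- run_lm(cands[[i]]$par, cands[[i]]$branch, cfg$max_iter)
    if (!is.null(r) && r$feasible && (is.null(best) || r$rms < best$rms))
      best <- r
    if (!is.null(best) && best$rms <= cfg$tolerance) break
  }
  starts <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  ## refinement: polish the incumbent and, while it misses the tolerance,
  ## escape shallow local minima by restarting from jittered copies
  if (!is.null(best)) {
    try_from <- function(p0, maxit, branch) {
      fit <- try(suppressWarnings(do.call(minpack.lm::nls.lm, c(list(
        par = pmin(pmax(p0, lo), hi), lower = lo, upper = hi, fn = resfun,
        flexion = flexion, target = target, branch = branch,
        control = minpack.lm::nls.lm.control(maxiter = maxit,
                                             ptol = 1e-15, ftol = 1e-15)),
        if (identical(resfun, synth_residuals)) list(lock = lock)
        else list()))), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      lk2 <- try(par_to_linkage(fit$par[1:11], branch), silent = TRUE)
      if (inherits(lk2, "try-error") || !synth_feasible(lk2, flexion))
        return(NULL)
      r2 <- synth_residuals(fit$par[1:11], flexion, target, branch,
                            penalty_w = 0)
      list(par = fit$par, branch = branch,
           rms = sqrt(mean(r2[seq_len(2L * n)]^2) * 2))
    }
    cand <- try_from(best$par, 500L, best$branch)
    if (!is.null(cand) && cand$rms < best$rms) best <- cand
    ## a near-miss basin is often the mirrored elbow of the true
    ## mechanism, so the restarts alternate branches
    jit <- 0L
    while (best$rms > cfg$tolerance && jit < 12L) {
      jit <- jit + 1L
      p0 <- best$par * (1 + 0.08 * stats::rnorm(length(best$par))) +
        0.5 * stats::rnorm(length(best$par))
      cand <- try_from(p0, 300L,
                       if (jit %% 2L) -best$branch else best$branch)
      if (!is.null(cand) && cand$rms < best$rms) best <- cand
    }
  }
  if (is.null(best))
    stop("four-bar synthesis failed: no feasible assemblable solution ",
         "among ", cfg$n_starts, " starts (best infeasible rms ",
         signif(min(starts$rms_mm, na.rm = TRUE), 4), " mm)")
  linkage <- par_to_linkage(best$par[1:11], best$branch)
  pts <- coupler_points(linkage,
                        linkage_input_angle(linkage, flexion))$points
  err <- sqrt(rowSums((pts - target)^2))
  list(linkage = linkage, rms_mm = sqrt(mean(err^2)), max_mm = max(err),
       n_starts_converged = sum(starts$converged & starts$feasible,
                                na.rm = TRUE),
       starts = starts)
}

#' Refine the flexion-to-input-angle map by projection
#'
#' After path synthesis the affine drive map is only an approximation to
#' the true, generally non-linear correspondence.  This refits it: each
#' sample's input angle is adjusted (1D minimisation near the affine
#' prediction) so the coupler point is nearest the sample, and a monotone
#' spline through the refined pairs replaces the affine map.
#'
#' @param linkage a synthesised [fourbar_linkage()] with an affine drive.
#' @param target_path n x 2 matrix of measured points (mm).
#' @param flexion flexion angles of the samples (degrees).
#' @param window half-width (degrees) of the search window around the
#'   affine prediction.
#' @return the linkage with `drive` replaced by a monotone spline
#'   function (falls back to the affine map if the refined pairs are not
#'   monotone).
#' @export
refine_drive_map <- function(linkage, target_path, flexion, window = 15) {
  stopifnot(is.numeric(linkage$drive), length(linkage$drive) == 2L)
  target <- as.matrix(target_path)
  th0 <- linkage_input_angle(linkage, flexion)
  th <- vapply(seq_along(flexion), function(i) {
    f <- function(t) {
      r <- coupler_points(linkage, t)
      if (!r$ok) return(1e6)
      sum((r$points - target[i, ])^2)
    }
    stats::optimize(f, c(th0[i] - window, th0[i] + window))$minimum
  }, numeric(1))
  o <- order(flexion)
  fo <- flexion[o]; tho <- th[o]
  if (all(diff(tho) > 0) || all(diff(tho) < 0)) {
    sp <- stats::splinefun(fo, tho, method = "hyman")
    linkage$drive <- sp
  }
  linkage
}

#' Fit the coupler attachment of the tibia frame
#'
#' Estimates the fixed planar transform from the coupler-link frame to
#' the measured tibia frame: for each sample the measured planar tibia
#' pose is pulled back through the coupler pose and the per-sample
#' transforms are averaged (rotation via the circular mean, translation
#' via the arithmetic mean).
#'
#' @param linkage a [fourbar_linkage()] with a drive map.
#' @param flexion flexion angles of the samples (degrees).
#' @param tibia_poses list of measured [se2_pose()] (tibia frame in the
#'   plane frame).
#' @return list with `attachment` (an [se2_pose()]) and `rms` (residual:
#'   RMS of the per-sample pose deviations, mm-equivalent with rotation
#'   weighted by the coupler length).
#' @export
fit_tibia_attachment <- function(linkage, flexion, tibia_poses) {
  stopifnot(length(flexion) == length(tibia_poses))
  th <- linkage_input_angle(linkage, flexion)
  As <- lapply(seq_along(flexion), function(i) {
    s <- fourbar_solve(linkage, th[i])
    if (!s$ok) stop("linkage not assemblable at flexion ", flexion[i])
    cf <- se2_pose(coupler_angle_deg(s), as.numeric(s$input_tip))
    se2_compose(se2_inverse(cf), tibia_poses[[i]])
  })
  ang <- vapply(As, function(a) a$theta, numeric(1))
  tx <- vapply(As, function(a) a$t[1], numeric(1))
  ty <- vapply(As, function(a) a$t[2], numeric(1))
  mang <- rad2deg(atan2(mean(sin(deg2rad(ang))), mean(cos(deg2rad(ang)))))
  att <- se2_pose(mang, c(mean(tx), mean(ty)))
  dev2 <- vapply(seq_along(As), function(i) {
    da <- deg2rad(wrap180(ang[i] - mang)) * linkage$len_coupler
    sum((c(tx[i], ty[i]) - att$t)^2) + da^2
  }, numeric(1))
  list(attachment = att, rms = sqrt(mean(dev2)))
}

## algebraic (Kasa) circle fit; returns centre, radius and geometric rms
circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(list(center = c(NA, NA), r = NA, rms = Inf))
  c0 <- sol[1:2]
  r <- sqrt(max(sol[3] + sum(c0^2), 0))
  d <- sqrt((x - c0[1])^2 + (y - c0[2])^2) - r
  list(center = c0, r = r, rms = sqrt(mean(d^2)))
}

#' Dimensional synthesis from measured body poses (circle-point search)
#'
#' When the full planar pose of the guided body is measured (the tibia is
#' the coupler link itself), the two moving pivots are body-fixed points
#' whose trajectories are circles about the fixed pivots.  This routine
#' searches the moving plane for the two best circle-points (multi-start
#' Nelder-Mead over the body frame, algebraic circle fit inside), builds
#' the four-bar from them, and derives the exact sample-wise drive map
#' and the body attachment.  For noise-free motion generated by a true
#' four-bar the recovery is exact.
#'
#' @param poses list of measured [se2_pose()] (body frame in the fixed
#'   frame), one per flexion sample.
#' @param flexion flexion angles of the samples (degrees, strictly
#'   monotone after sorting).
#' @param cfg a [synthesis_config()] (`n_starts` and `seed` control the
#'   circle-point search; `bounds$offset` bounds the moving-pivot
#'   coordinates in the body frame).
#' @return list with `linkage` (drive map = monotone spline through the
#'   sample-wise input angles), `attachment` (the measured body frame on
#'   the coupler, an [se2_pose()]), `rms_mm` (coupler-point path rms
#'   against the measured origins), `pivot_rms_mm` (circle-fit rms of the
#'   two moving pivots), `moving_pivots` (2 x 2, body frame).
#' @export
synthesize_fourbar_poses <- function(poses, flexion,
                                     cfg = synthesis_config()) {
  n <- length(poses)
  stopifnot(n == length(flexion), n >= 5L)
  o <- order(flexion)
  poses <- poses[o]; flexion <- flexion[o]
  R <- lapply(poses, function(p) rot2(p$theta))
  Tt <- do.call(rbind, lapply(poses, function(p) p$t))
  traj <- function(m) {
    M <- do.call(rbind, lapply(R, function(r) as.numeric(r %*% m)))
    M + Tt
  }
  objective <- function(m) {
    X <- traj(m)
    circle_fit(X[, 1], X[, 2])$rms
  }
  set.seed(cfg$seed)
  lim <- cfg$bounds$offset
  grid0 <- as.matrix(expand.grid(seq(lim[1], lim[2], length.out = 7),
                                 seq(lim[1], lim[2], length.out = 7)))
  extra <- matrix(stats::runif(2L * cfg$n_starts, lim[1], lim[2]),
                  ncol = 2L)
  starts <- rbind(grid0, extra)
  sols <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    op <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-14))
    sols[[i]] <- list(m = op$par, rms = op$value)
  }
  rms_all <- vapply(sols, function(s) s$rms, numeric(1))
  ord <- order(rms_all)
  ## two best well-separated circle points
  m1 <- sols[[ord[1]]]$m
  m2 <- NULL
  min_sep <- 1  # mm, distinct-pivot threshold
  for (i in ord[-1]) {
    if (sqrt(sum((sols[[i]]$m - m1)^2)) > min_sep) {
      m2 <- sols[[i]]$m
      pivot_rms <- c(sols[[ord[1]]]$rms, sols[[i]]$rms)
      break
    }
  }
  if (is.null(m2))
    stop("circle-point search found no second distinct moving pivot")
  X1 <- traj(m1); X2 <- traj(m2)
  cf1 <- circle_fit(X1[, 1], X1[, 2])
  cf2 <- circle_fit(X2[, 1], X2[, 2])
  theta <- unwrap_deg(rad2deg(atan2(X1[, 2] - cf1$center[2],
                                    X1[, 1] - cf1$center[1])))
  lc <- sqrt(sum((m2 - m1)^2))
  ## branch: reproduce the follower tip at the mid sample
  mid <- ceiling(n / 2)
  lk_try <- function(br)
    fourbar_linkage(cf1$center, cf2$center, cf1$r, lc, cf2$r, branch = br)
  br <- 1L
  for (b in c(1L, -1L)) {
    s <- fourbar_solve(lk_try(b), theta[mid])
    if (s$ok && sqrt(sum((as.numeric(s$follower_tip) - X2[mid, ])^2)) <
          1e-3 * lc + 0.5) { br <- b; break }
  }
  drive <- if (all(diff(theta) > 0) || all(diff(theta) < 0))
    stats::splinefun(flexion, theta, method = "hyman")
  else stats::approxfun(flexion, theta, rule = 2)
  linkage <- fourbar_linkage(cf1$center, cf2$center, cf1$r, lc, cf2$r,
                             branch = br, drive = drive,
                             angle_range = range(theta))
  ## coupler frame in the body frame, and the attachment (its inverse)
  phi <- rad2deg(atan2(m2[2] - m1[2], m2[1] - m1[1]))
  attachment <- se2_inverse(se2_pose(phi, m1))
  linkage$coupler_offset <- as.numeric(se2_apply(attachment, c(0, 0)))
  cp <- coupler_points(linkage, linkage_input_angle(linkage, flexion))
  err <- sqrt(rowSums((cp$points - Tt)^2))
  list(linkage = linkage, attachment = attachment,
       rms_mm = sqrt(mean(err^2)), max_mm = max(err),
       pivot_rms_mm = pivot_rms, moving_pivots = rbind(m1, m2))
}
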