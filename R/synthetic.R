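#' Parameters of the synthetic knee generator
#'
#' The generator emulates the tibiofemoral joint as a crossed four-bar
#' mechanism whose two moving links are the cruciate ligaments (the classic
#' Menschik-style sagittal model): the femur is the ground link carrying
#' the two femoral insertions, the tibia is the coupler carrying the two
#' tibial insertions.  The femoral articulating outline is a two-arc
#' profile whose sagittal radius decreases posteriorly; the implant profile
#' is a single arc.  All lengths in mm, angles in degrees.
#'
#' Defaults are one-time calibration constants of the package's reference
#' synthetic knee and are frozen; see the methods vignette for how they
#' were chosen.
#'
#' @param acl_length,pcl_length ligament (moving link) lengths.
#' @param femoral_insertion_sep distance between the femoral insertions
#'   (ground link length).
#' @param tibial_insertion_sep distance between the tibial insertions
#'   (coupler link length).
#' @param distal_radius,posterior_radius radii of the distal and posterior
#'   condylar arcs (`posterior_radius < distal_radius`).
#' @param arc_transition_angle angle (from the distal-most point of the
#'   condyle, posteriorly positive) where the distal arc hands over to the
#'   posterior arc.
#' @param plateau_length AP length of the flat tibial plateau.
#' @param implant_radius radius of the single-arc implant profile.
#' @param flexion_max largest flexion angle the mechanism must reach.
#' @param seed integer seed for anything stochastic downstream.
#' @param acl_elevation elevation of the ACL above the tibial plateau at
#'   extension (degrees from the posterior x axis).
#' @param insertion_frac fraction of `tibial_insertion_sep` lying anterior
#'   to the plateau centre.
#' @param arc_start,arc_end angular extent of the condyle profiles
#'   (degrees from the distal-most point, posterior positive).
#' @return object of class `synthetic_knee_params`.
#' @export
synthetic_knee_params <- function(acl_length = 41, pcl_length = 38,
                                  femoral_insertion_sep = 11,
                                  tibial_insertion_sep = 27,
                                  distal_radius = 58, posterior_radius = 21,
                                  arc_transition_angle = 36,
                                  plateau_length = 50, implant_radius = 30,
                                  flexion_max = 120, seed = 1L,
                                  acl_elevation = 54, insertion_frac = 0.265,
                                  arc_start = -15, arc_end = 115) {
  p <- list(acl_length = acl_length, pcl_length = pcl_length,
            femoral_insertion_sep = femoral_insertion_sep,
            tibial_insertion_sep = tibial_insertion_sep,
            distal_radius = distal_radius,
            posterior_radius = posterior_radius,
            arc_transition_angle = arc_transition_angle,
            plateau_length = plateau_length,
            implant_radius = implant_radius, flexion_max = flexion_max,
            seed = as.integer(seed), acl_elevation = acl_elevation,
            insertion_frac = insertion_frac, arc_start = arc_start,
            arc_end = arc_end)
  lens <- c(p$acl_length, p$pcl_length, p$femoral_insertion_sep,
            p$tibial_insertion_sep, p$distal_radius, p$posterior_radius,
            p$plateau_length, p$implant_radius)
  stopifnot(all(lens > 0), all(is.finite(lens)))
  if (p$posterior_radius > p$distal_radius)
    stop("posterior_radius must not exceed distal_radius ",
         "(natural condyle curvature decreases posteriorly); equal radii ",
         "degenerate to a single-arc profile")
  structure(p, class = "synthetic_knee_params")
}

#' Marker noise model for the tracker simulator
#'
#' Isotropic per-marker Gaussian noise plus a slow sinusoidal drift of the
#' whole marker cluster, standing in for skin/shell motion artefact.
#'
#' @param marker_sd isotropic Gaussian noise s.d. per marker (mm).
#' @param shell_drift_amp amplitude of the low-frequency cluster drift (mm).
#' @param drift_period_s drift period (seconds).
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(marker_sd = 0.3, shell_drift_amp = 1.0,
                        drift_period_s = 8, seed = 1L) {
  stopifnot(marker_sd >= 0, shell_drift_amp >= 0, drift_period_s > 0)
  structure(list(marker_sd = marker_sd, shell_drift_amp = shell_drift_amp,
                 drift_period_s = drift_period_s, seed = as.integer(seed)),
            class = "noise_model")
}

## circle-circle intersection; returns 2 x 2 matrix (rows = solutions) or
## NULL when the circles do not intersect
circ_circ <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  if (d < 1e-12 || d > r1 + r2 || d < abs(r1 - r2)) return(NULL)
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  h <- sqrt(max(h2, 0))
  u <- (c2 - c1) / d
  m <- c1 + a * u
  rbind(m + h * c(-u[2], u[1]), m - h * c(-u[2], u[1]))
}

## do open segments p1-p2 and q1-q2 properly intersect?
segments_cross <- function(p1, p2, q1, q2) {
  cr <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cr(q1, q2, p1); d2 <- cr(q1, q2, p2)
  d3 <- cr(p1, p2, q1); d4 <- cr(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

## arc polyline about centre `c`, radius r, angles alpha (deg, measured
## from the downward vertical, posterior/x positive)
arc_points <- function(c, r, alpha_deg) {
  a <- deg2rad(alpha_deg)
  cbind(c[1] + r * sin(a), c[2] - r * cos(a))
}

#' Build the ground-truth synthetic knee
#'
#' Constructs the crossed four-bar from the ligament lengths and insertion
#' separations, the natural two-arc and single-arc implant condyle
#' profiles, the flat tibial plateau, the coupler attachment of the tibia
#' frame, and the exact drive map relating flexion angle to the mechanism
#' input angle.
#'
#' Frames: the femur sagittal frame has its origin at the distal condylar
#' arc centre, x pointing posteriorly and y proximally; the tibia sagittal
#' frame has its origin at the plateau centre with the same orientation at
#' full extension (flexion 0).
#'
#' @param params a [synthetic_knee_params()].
#' @return object of class `synthetic_knee`: list with `params`, `linkage`
#'   (a [fourbar_linkage()] in the femur frame, drive map included),
#'   `natural_profile`, `implant_profile` ([condyle_profile()]),
#'   `plateau` ([plateau_profile()]), `tibia_attachment` ([se2_pose()]),
#'   `tibia_pose` (function: flexion degrees -> [se2_pose()] of the tibia
#'   frame in the femur frame), `flexion_range`, and the 3D embedding used
#'   by [simulate_tracker_stream()].
#' @export
make_ground_truth_knee <- function(params = synthetic_knee_params()) {
  stopifnot(inherits(params, "synthetic_knee_params"))
  p <- params
  rd <- p$distal_radius
  ## tibial insertions (tibia frame: plateau centre at origin, y = 0)
  C_t <- c(-p$insertion_frac * p$tibial_insertion_sep, 0)
  D_t <- c((1 - p$insertion_frac) * p$tibial_insertion_sep, 0)
  ## femur frame at extension: tibia frame sits at (0, -rd)
  C0 <- C_t + c(0, -rd)
  D0 <- D_t + c(0, -rd)
  g1 <- deg2rad(p$acl_elevation)
  A <- C0 + p$acl_length * c(cos(g1), sin(g1))
  sols <- circ_circ(A, p$femoral_insertion_sep, D0, p$pcl_length)
  if (is.null(sols))
    stop("femoral insertions not constructible: the circles of radius ",
         "femoral_insertion_sep about the ACL insertion and pcl_length ",
         "about the tibial PCL insertion do not intersect")
  crossed <- apply(sols, 1L, function(B) segments_cross(A, C0, B, D0))
  if (!any(crossed))
    stop("no crossed ligament configuration exists for these parameters")
  B <- sols[which(crossed)[1L], ]
  ## linkage: input link = ACL (A -> C), follower = PCL (B -> D)
  lc <- sqrt(sum((D0 - C0)^2))
  ## branch sign reproducing D0 at the extension input angle
  d <- sqrt(sum((B - C0)^2)); u <- (B - C0) / d
  a <- (lc^2 - p$pcl_length^2 + d^2) / (2 * d)
  m <- C0 + a * u
  s <- sign(sum((D0 - m) * c(-u[2], u[1])))
  if (s == 0) s <- 1
  theta0 <- rad2deg(atan2(C0[2] - A[2], C0[1] - A[1]))
  linkage <- fourbar_linkage(ground_a = A, ground_b = B,
                             len_input = p$acl_length, len_coupler = lc,
                             len_follower = p$pcl_length, branch = s)
  ## extension coupler frame and the tibia attachment on the coupler
  cf0 <- {
    sol0 <- fourbar_solve(linkage, theta0)
    se2_pose(coupler_angle_deg(sol0), as.numeric(sol0$input_tip))
  }
  attach_t <- se2_compose(se2_inverse(cf0), se2_pose(0, c(0, -rd)))

  ## exact drive map by sweeping the input angle in both directions
  sweep_dir <- function(dir) {
    step <- 0.05 * dir
    theta <- theta0 + seq(0, 175 * dir, by = step)
    sol <- fourbar_solve(linkage, theta)
    ok <- sol$ok & sol$h > 1e-9   # stop before a branch fold
    nstop <- which(!ok)
    last <- if (length(nstop)) min(nstop) - 1L else length(theta)
    if (last < 2L) return(NULL)
    idx <- seq_len(last)
    psi <- unwrap_deg(coupler_angle_deg(
      lapply(sol, function(z) if (is.matrix(z)) z[idx, , drop = FALSE]
             else z[idx])))
    list(theta = theta[idx], dpsi = psi - psi[1])
  }
  dirs <- list(sweep_dir(+1), sweep_dir(-1))
  ## flexion = magnitude of tibia rotation relative to extension; pick the
  ## sweep direction that reaches flexion_max with posterior contact drift
  pick <- NULL
  for (sw in dirs) {
    if (is.null(sw)) next
    f <- abs(sw$dpsi)
    keep <- seq_len(max(which(cummax(f) == f)))   # monotone part
    f <- f[keep]; th <- sw$theta[keep]
    if (max(f) < p$flexion_max) next
    drive <- stats::splinefun(f, th, method = "hyman")
    pose_f <- function(fl)
      se2_compose({
        so <- fourbar_solve(linkage, drive(fl))
        se2_pose(coupler_angle_deg(so), as.numeric(so$input_tip))
      }, attach_t)
    ## posterior drift of the distal arc centre over early flexion
    x0 <- se2_apply(se2_inverse(pose_f(0)), c(0, 0))[1]
    x30 <- se2_apply(se2_inverse(pose_f(30)), c(0, 0))[1]
    cand <- list(drive = drive, flexion = f, theta = th,
                 drift = x30 - x0)
    if (is.null(pick) || cand$drift > pick$drift) pick <- cand
  }
  if (is.null(pick))
    stop("four-bar not assemblable over [0, ", p$flexion_max,
         "] deg flexion for these parameters")
  linkage$drive <- pick$drive
  linkage$angle_range <- range(pick$drive(c(0, p$flexion_max)))

  tibia_pose <- function(flexion) {
    th <- linkage_input_angle(linkage, flexion)
    tibia_pose_from_linkage(linkage, th, attach_t)
  }

  ## condyle profiles (femur frame, distal arc centre at the origin)
  da <- 0.2
  a1 <- seq(p$arc_start, p$arc_transition_angle, by = da)
  nat1 <- arc_points(c(0, 0), rd, a1)
  cp_post <- arc_points(c(0, 0), rd - p$posterior_radius,
                        p$arc_transition_angle)[1, ]
  a2 <- seq(p$arc_transition_angle + da, p$arc_end, by = da)
  nat2 <- arc_points(cp_post, p$posterior_radius, a2)
  natural <- condyle_profile(rbind(nat1, nat2), "natural")
  ## single-arc implant, posterior-referenced: tangent to the natural
  ## posterior arc at its posterior-most point, as in measured resection
  ## where the posterior cut thickness equals the implant's posterior
  ## condyle thickness (the posterior joint line is restored)
  ci <- cp_post + (p$posterior_radius - p$implant_radius) * c(1, 0)
  implant <- condyle_profile(
    arc_points(ci, p$implant_radius, seq(p$arc_start, p$arc_end, by = da)),
    "implant")
  plat_x <- seq(-p$plateau_length / 2, p$plateau_length / 2, length.out = 11)
  plateau <- plateau_profile(cbind(plat_x, 0), center_ap = 0)

  ## 3D embedding of the sagittal plane and the tracker clusters
  emb <- default_embedding()
  structure(list(params = p, linkage = linkage,
                 natural_profile = natural, implant_profile = implant,
                 plateau = plateau, tibia_attachment = attach_t,
                 tibia_pose = tibia_pose,
                 flexion_range = c(0, p$flexion_max),
                 embedding = emb),
            class = "synthetic_knee")
}

#' @export
print.synthetic_knee <- function(x, ...) {
  cat("<synthetic_knee>\n")
  cat(sprintf("  ligaments: ACL %.1f mm, PCL %.1f mm; insertions %.1f / %.1f mm\n",
              x$params$acl_length, x$params$pcl_length,
              x$params$femoral_insertion_sep, x$params$tibial_insertion_sep))
  cat(sprintf("  condyle arcs: distal r=%.1f, posterior r=%.1f (transition %.0f deg); implant r=%.1f mm\n",
              x$params$distal_radius, x$params$posterior_radius,
              x$params$arc_transition_angle, x$params$implant_radius))
  cat(sprintf("  flexion range [0, %.0f] deg\n", x$params$flexion_max))
  invisible(x)
}

## fixed 3D pose of the sagittal (main) plane in camera coordinates, plus
## tracker marker clusters expressed in the bone sagittal frames
## (x, y in-plane mm, z out-of-plane mm)
default_embedding <- function() {
  ## a generic oblique orientation: plane normal not aligned with any axis
  ax <- deg2rad(c(18, -32, 64))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax[1]), -sin(ax[1])),
              c(0, sin(ax[1]), cos(ax[1])))
  Ry <- rbind(c(cos(ax[2]), 0, sin(ax[2])), c(0, 1, 0),
              c(-sin(ax[2]), 0, cos(ax[2])))
  Rz <- rbind(c(cos(ax[3]), -sin(ax[3]), 0),
              c(sin(ax[3]), cos(ax[3]), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  origin <- c(142, -61, 1480)
  femur_markers <- rbind(c(-45, 95, 52), c(5, 120, 44),
                         c(-10, 80, 78), c(-48, 128, 66))
  tibia_markers <- rbind(c(24, -95, 55), c(62, -132, 47),
                         c(18, -140, 76), c(55, -88, 70))
  list(origin = origin, ex = R[, 1], ey = R[, 2], ez = R[, 3],
       femur_markers = femur_markers, tibia_markers = tibia_markers)
}

## embed sagittal-frame 3D coords (x, y in-plane, z out-of-plane) into
## camera coordinates
embed3 <- function(emb, xyz) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, 1L) else as.matrix(xyz)
  t(apply(xyz, 1L, function(v)
    emb$origin + v[1] * emb$ex + v[2] * emb$ey + v[3] * emb$ez))
}

#' Simulate optical tracker marker streams
#'
#' Plays the ground-truth knee through a flexion profile and renders the
#' two 4-marker tracker clusters (tracker 1 = femur, static; tracker 2 =
#' tibia, rigid with the four-bar coupler) in camera coordinates, with
#' Gaussian marker noise and a slow cluster drift.  Frame 0 must be the
#' extended-leg reference (flexion 0).
#'
#' @param knee a [make_ground_truth_knee()] result.
#' @param flexion_profile numeric vector of flexion angles per frame
#'   (degrees); the first element must be 0.
#' @param noise a [noise_model()]; use `marker_sd = 0` and
#'   `shell_drift_amp = 0` for noise-free streams.
#' @param dt frame period in seconds (default 1/30).
#' @return list with `frames` (data.frame with columns
#'   `frame,time_s,tracker_id,marker_index,x_mm,y_mm,z_mm`), `truth`
#'   (data.frame `frame,time_s,flexion_deg`), and `registration`: the
#'   synthetic stand-in for the CT-to-tracker registration -- the 3D pose
#'   of the femur sagittal frame (`origin`, `ex`, `ey`, `ez`, camera
#'   coordinates at the reference frame) plus `tibia_extension_pose2d`,
#'   the tibia sagittal frame expressed in the femur sagittal frame at
#'   the extended reference position (both bone frames come from the same
#'   CT, imaged in extension).
#' @export
simulate_tracker_stream <- function(knee, flexion_profile,
                                    noise = noise_model(), dt = 1 / 30) {
  stopifnot(inherits(knee, "synthetic_knee"), length(flexion_profile) >= 2L)
  if (abs(flexion_profile[1]) > 1e-12)
    stop("frame 0 must be the extended-leg reference (flexion 0)")
  fr <- knee$flexion_range
  if (any(flexion_profile < fr[1] - 1e-9 | flexion_profile > fr[2] + 1e-9))
    stop("flexion profile leaves the assemblable range [", fr[1], ", ",
         fr[2], "] deg")
  emb <- knee$embedding
  n <- length(flexion_profile)
  t_s <- (seq_len(n) - 1L) * dt
  set.seed(noise$seed)
  drift_dir <- matrix(stats::rnorm(6), 2L)
  drift_dir <- drift_dir / sqrt(rowSums(drift_dir^2))
  drift_phase <- stats::runif(2L, 0, 2 * pi)
  mk_noise <- function(nm) {
    if (noise$marker_sd == 0) matrix(0, nm, 3L)
    else matrix(stats::rnorm(nm * 3L, sd = noise$marker_sd), nm, 3L)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- flexion_profile[i]
    Bp <- knee$tibia_pose(f)
    tib2d <- se2_apply(Bp, emb$tibia_markers[, 1:2, drop = FALSE])
    tib3 <- embed3(emb, cbind(tib2d, emb$tibia_markers[, 3]))
    fem3 <- embed3(emb, emb$femur_markers)
    drift <- function(k)
      noise$shell_drift_amp *
        sin(2 * pi * t_s[i] / noise$drift_period_s + drift_phase[k]) *
        drift_dir[k, ]
    fem3 <- sweep(fem3 + mk_noise(4L), 2L, drift(1L), "+")
    tib3 <- sweep(tib3 + mk_noise(4L), 2L, drift(2L), "+")
    pts <- rbind(fem3, tib3)
    out[[i]] <- data.frame(frame = i - 1L, time_s = t_s[i],
                           tracker_id = rep(c(1L, 2L), each = 4L),
                           marker_index = rep(1:4, 2L),
                           x_mm = pts[, 1], y_mm = pts[, 2],
                           z_mm = pts[, 3])
  }
  frames <- do.call(rbind, out)
  rownames(frames) <- NULL
  B0 <- knee$tibia_pose(0)
  reg <- list(origin = as.numeric(embed3(emb, c(0, 0, 0))),
              ex = emb$ex, ey = emb$ey, ez = emb$ez,
              tibia_extension_pose2d = list(theta = B0$theta, t = B0$t))
  list(frames = frames,
       truth = data.frame(frame = seq_len(n) - 1L, time_s = t_s,
                          flexion_deg = flexion_profile),
       registration = reg)
}

#' Synthetic femur solid mesh
#'
#' A watertight stand-in for the CT-derived distal femur: the natural
#' two-arc condyle outline closed by a rectangular metaphyseal block and
#' extruded across the condylar width.  Purely synthetic geometry for
#' exercising the resection operations; its exact prism volume (polygon
#' area with circular-segment corrections times width) is attached as
#' attribute `analytic_volume_mm3`.
#'
#' @param params a [synthetic_knee_params()].
#' @param width extrusion width (mm, default 55).
#' @param top_y proximal extent of the shaft block (mm, default 50).
#' @param arc_step arc discretisation step (degrees, default 1.5).
#' @return a [trimesh()] in femur sagittal coordinates (x posterior,
#'   y proximal, z lateral).
#' @export
make_synthetic_femur_mesh <- function(params = synthetic_knee_params(),
                                      width = 55, top_y = 50,
                                      arc_step = 1.5) {
  p <- params
  rd <- p$distal_radius; rp <- p$posterior_radius
  at <- p$arc_transition_angle
  cp_post <- (rd - rp) * c(sin(deg2rad(at)), -cos(deg2rad(at)))
  a1 <- seq(p$arc_start, at, by = arc_step)
  a2 <- seq(at, p$arc_end, by = arc_step)[-1]
  ring <- rbind(arc_points(c(0, 0), rd, a1),
                arc_points(cp_post, rp, a2))
  S <- ring[1, ]; E <- ring[nrow(ring), ]
  ring <- rbind(ring, c(E[1], top_y), c(S[1], top_y))
  n <- nrow(ring)
  ## exact area: corner polygon + circular segments of the two arcs
  Tpt <- arc_points(c(0, 0), rd, at)[1, ]
  shoelace <- function(P)
    sum(P[, 1] * P[c(2:nrow(P), 1), 2] - P[c(2:nrow(P), 1), 1] * P[, 2]) / 2
  corners <- rbind(S, Tpt, E, c(E[1], top_y), c(S[1], top_y))
  seg <- function(r, d_deg) {
    d <- deg2rad(d_deg); r^2 / 2 * (d - sin(d))
  }
  area <- shoelace(corners) + seg(rd, at - p$arc_start) +
    seg(rp, p$arc_end - at)
  z0 <- -width / 2; z1 <- width / 2
  verts <- rbind(cbind(ring, z0), cbind(ring, z1))
  side <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(c(i, j, n + j), c(i, n + j, n + i))
  }))
  capt <- earclip(ring)
  faces <- rbind(side,
                 capt[, c(1L, 3L, 2L), drop = FALSE],        # bottom (-z)
                 capt + n)                                    # top (+z)
  m <- trimesh(verts, faces)
  attr(m, "analytic_volume_mm3") <- area * width
  m
}
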