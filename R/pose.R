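#' Rigid 3D pose
#'
#' A proper rigid transform: `x |-> R x + t` with `R` a 3x3 proper
#' orthogonal matrix and `t` a 3-vector (mm).
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric (mm).
#' @return object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation is not proper (det != +1)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  aa <- rotation_axis_angle(x$rotation)
  cat(sprintf("<rigid_pose> angle %.3f deg about (%.3f, %.3f, %.3f), t = (%.2f, %.2f, %.2f) mm\n",
              aa$angle, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose rigid poses
#' @param a,b `rigid_pose` objects; the result applies `b` first, then `a`.
#' @return a [rigid_pose()].
#' @export
pose_compose <- function(a, b)
  rigid_pose(a$rotation %*% b$rotation,
             as.numeric(a$rotation %*% b$translation) + a$translation)

#' Invert a rigid pose
#' @param a a [rigid_pose()].
#' @return the inverse [rigid_pose()].
#' @export
pose_inverse <- function(a)
  rigid_pose(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))

#' Apply a rigid pose to points
#' @param a a [rigid_pose()].
#' @param pts n x 3 matrix or length-3 vector (mm).
#' @return transformed points.
#' @export
pose_apply <- function(a, pts) {
  if (is.null(dim(pts))) return(as.numeric(a$rotation %*% pts) + a$translation)
  sweep(pts %*% t(a$rotation), 2L, a$translation, "+")
}

## axis-angle decomposition of a rotation matrix (degrees)
rotation_axis_angle <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  sa <- sqrt(sum(w^2))
  angle <- rad2deg(atan2(sa, ca))
  axis <- if (sa > 1e-12) w / sa else c(0, 0, 1)
  list(angle = angle, axis = axis)
}

## rotation about a unit axis by an angle in degrees (Rodrigues)
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg)
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Least-squares rigid pose from matched marker sets
#'
#' SVD-based rigid registration (Kabsch) of two ordered marker sets:
#' returns the proper rigid transform mapping the reference markers onto
#' the observed markers with minimal sum of squared distances, plus the
#' RMS residual.
#'
#' @param reference_markers,observed_markers n x 3 matrices (n >= 3,
#'   matched ordering, reference not collinear), mm.
#' @return list with `pose` (a [rigid_pose()]) and `rms` (RMS residual,
#'   mm).
#' @export
pose_from_markers <- function(reference_markers, observed_markers) {
  X <- as.matrix(reference_markers); Y <- as.matrix(observed_markers)
  if (ncol(X) != 3L || ncol(Y) != 3L)
    stop("marker sets must be n x 3 matrices")
  if (nrow(X) < 3L) stop("at least 3 markers are required")
  if (nrow(X) != nrow(Y))
    stop("reference and observed marker counts differ")
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  ## collinearity of the reference cluster
  sv_ref <- svd(X0)$d
  if (sv_ref[2] < 1e-9 * max(sv_ref[1], 1))
    stop("reference markers are collinear; the pose is not determined")
  H <- crossprod(X0, Y0)               # sum x_i y_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  res <- sweep(X %*% t(R), 2L, t, "+") - Y
  list(pose = rigid_pose(R, t), rms = sqrt(mean(rowSums(res^2))))
}

#' Pose of the tibia tracker relative to the femur tracker
#'
#' @param femur_pose,tibia_pose [rigid_pose()] objects of the two trackers
#'   in camera coordinates.
#' @return [rigid_pose()]: tibia frame expressed in the femur frame
#'   (`femur_pose^-1 o tibia_pose`).
#' @export
relative_pose <- function(femur_pose, tibia_pose)
  pose_compose(pose_inverse(femur_pose), tibia_pose)

#' Fitted main (sagittal) plane
#'
#' @param origin 3-vector (mm).
#' @param normal unit 3-vector.
#' @param in_plane_x,in_plane_y unit 3-vectors completing a right-handed
#'   orthonormal triad `{x, y, normal}`.
#' @return object of class `motion_plane`.
#' @export
motion_plane <- function(origin, normal, in_plane_x, in_plane_y) {
  origin <- as.numeric(origin)
  M <- cbind(in_plane_x, in_plane_y, normal)
  stopifnot(length(origin) == 3L, all(dim(M) == c(3L, 3L)))
  if (max(abs(crossprod(M) - diag(3))) > 1e-9)
    stop("plane axes are not orthonormal")
  if (det(M) < 0) stop("plane axes are not right-handed")
  structure(list(origin = origin, normal = as.numeric(normal),
                 in_plane_x = as.numeric(M[, 1]),
                 in_plane_y = as.numeric(M[, 2])),
            class = "motion_plane")
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances to
#' the points (smallest principal direction of the centred cloud).  The
#' normal sign is chosen to have a positive dot product with
#' `lateral_hint`; the in-plane x axis is the projection of `ap_hint`
#' (anterior-posterior direction), y completes the right-handed triad.
#'
#' @param points n x 3 matrix (n >= 3, not collinear), mm.
#' @param lateral_hint approximate lateral direction (sign convention for
#'   the normal).
#' @param ap_hint approximate anterior-posterior direction (in-plane x).
#' @return a [motion_plane()] with attribute `rms_mm` (out-of-plane RMS).
#' @export
fit_main_plane <- function(points, lateral_hint = c(0, 0, 1),
                           ap_hint = c(1, 0, 0)) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 3L)
  if (nrow(P) < 3L) stop("at least 3 points are required to fit a plane")
  ctr <- colMeans(P)
  P0 <- sweep(P, 2L, ctr)
  s <- svd(P0, nu = 0)
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop("points are collinear; the plane is degenerate")
  n <- s$v[, 3]
  if (sum(n * lateral_hint) < 0) n <- -n
  ex <- ap_hint - n * sum(ap_hint * n)
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9)
    stop("ap_hint is parallel to the plane normal; cannot fix in-plane axes")
  ex <- ex / nx
  ey <- c(n[2] * ex[3] - n[3] * ex[2],
          n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])
  pl <- motion_plane(ctr, n, ex, ey)
  attr(pl, "rms_mm") <- sqrt(mean((P0 %*% n)^2))
  pl
}

#' Signed flexion angle of a relative pose
#'
#' Extracts the rotation of `rel` with respect to the extension reference
#' (`extension_ref^-1 o rel`), decomposes it as axis-angle, and projects
#' the rotation onto the main-plane normal: `atan2(sin(a) u.n, cos(a))`
#' with `(a, u)` the axis-angle pair.  Zero at the extension reference;
#' the sign follows the plane normal (right-hand rule).
#'
#' @param rel,extension_ref [rigid_pose()] objects (tibia relative to
#'   femur).
#' @param plane a [motion_plane()].
#' @param min_projection warn threshold: if the rotation axis is nearly
#'   orthogonal to the plane normal (|u.n| below this), the sample is
#'   flagged.
#' @return flexion angle in degrees, with attribute `off_plane` (logical
#'   warning flag).
#' @export
flexion_angle <- function(rel, extension_ref, plane, min_projection = 0.5) {
  Q <- t(extension_ref$rotation) %*% rel$rotation
  ca <- (sum(diag(Q)) - 1) / 2
  w <- c(Q[3, 2] - Q[2, 3], Q[1, 3] - Q[3, 1], Q[2, 1] - Q[1, 2]) / 2
  sn <- sum(w * plane$normal)          # sin(angle) * (axis . normal)
  ang <- rad2deg(atan2(sn, ca))
  sa <- sqrt(sum(w^2))
  off <- sa > 1e-9 && abs(sum(w / sa * plane$normal)) < min_projection &&
    rad2deg(atan2(sa, ca)) > 1
  structure(ang, off_plane = off)
}

#' Project 3D trajectory points into the main plane
#'
#' @param points n x 3 matrix of tracker-centre positions (mm, femur
#'   frame).
#' @param plane a [motion_plane()].
#' @return list with `uv` (n x 2 in-plane coordinates, mm) and `residual`
#'   (signed out-of-plane distance along the normal, mm).
#' @export
project_trajectory <- function(points, plane) {
  P <- as.matrix(points)
  if (!nrow(P)) stop("no trajectory points supplied")
  stopifnot(ncol(P) == 3L)
  P0 <- sweep(P, 2L, plane$origin)
  list(uv = cbind(P0 %*% plane$in_plane_x, P0 %*% plane$in_plane_y),
       residual = as.numeric(P0 %*% plane$normal))
}

#' Re-embed projected points into 3D
#'
#' Inverse of [project_trajectory()]: maps in-plane coordinates plus the
#' out-of-plane residual back to 3D.
#' @param uv n x 2 in-plane coordinates (mm).
#' @param plane a [motion_plane()].
#' @param residual out-of-plane distances (mm, default 0).
#' @return n x 3 matrix.
#' @export
embed_trajectory <- function(uv, plane, residual = 0) {
  uv <- as.matrix(uv)
  outer(rep(1, nrow(uv)), plane$origin) +
    uv[, 1] %o% plane$in_plane_x + uv[, 2] %o% plane$in_plane_y +
    residual %o% plane$normal
}

#' Interpolate the tracker path over flexion angle
#'
#' Fits a smooth path `(u(angle), v(angle))` through possibly repeated
#' flexion-extension cycles: samples are pooled, duplicate angles
#' averaged, each coordinate fitted with a smoothing spline (or an
#' interpolating spline when `smoothing = 0`), and the path is resampled
#' at `n_out` uniformly spaced angles.
#'
#' @param points2d n x 2 in-plane coordinates (mm).
#' @param angles flexion angles per sample (degrees).
#' @param n_out number of output samples.
#' @param smoothing `NULL` for generalised cross-validation, `0` for exact
#'   interpolation, or a `spar` value in (0, 1] passed to
#'   [stats::smooth.spline()].
#' @param min_span minimal flexion span (degrees) required of the input.
#' @return list with `angle` (length `n_out`) and `points` (`n_out` x 2).
#' @export
interpolate_flexion_path <- function(points2d, angles, n_out = 101,
                                     smoothing = NULL, min_span = 20) {
  P <- as.matrix(points2d)
  stopifnot(ncol(P) == 2L, nrow(P) == length(angles))
  if (nrow(P) < 4L) stop("at least 4 samples are required")
  if (diff(range(angles)) < min_span)
    stop("flexion range ", signif(diff(range(angles)), 4),
         " deg is below the minimal span of ", min_span, " deg")
  ## pool cycles: average duplicate angles
  key <- round(angles, 9)
  u <- tapply(P[, 1], key, mean)
  v <- tapply(P[, 2], key, mean)
  a <- as.numeric(names(u))
  o <- order(a)
  a <- a[o]; u <- as.numeric(u)[o]; v <- as.numeric(v)[o]
  grid <- seq(min(a), max(a), length.out = n_out)
  fit1 <- function(y) {
    if (!is.null(smoothing) && smoothing == 0)
      return(stats::spline(a, y, xout = grid, method = "fmm")$y)
    if (length(a) < 10L)
      return(stats::spline(a, y, xout = grid, method = "fmm")$y)
    f <- if (is.null(smoothing)) stats::smooth.spline(a, y)
         else stats::smooth.spline(a, y, spar = smoothing)
    stats::predict(f, grid)$y
  }
  list(angle = grid, points = cbind(fit1(u), fit1(v)))
}

#' Marker streams to flexion samples
#'
#' The front half of the pipeline: per-frame tracker poses (Kabsch against
#' the extension-reference frame), tibia-relative-to-femur poses, tracker
#' centres (cluster centroid) in the femur frame, total-least-squares main
#' plane through the centres, signed flexion angles about the plane
#' normal, and the projected 2D trajectory.
#'
#' @param frames data.frame with columns
#'   `frame,time_s,tracker_id,marker_index,x_mm,y_mm,z_mm` (tracker 1 =
#'   femur, tracker 2 = tibia); the reference (extended leg) frame is
#'   `frame == reference_frame`.
#' @param reference_frame id of the extension reference frame (default 0).
#' @param lateral_hint,ap_hint direction hints passed to
#'   [fit_main_plane()], in femur-frame coordinates.
#' @return list of class `motion_analysis`: `samples` (data.frame with
#'   `frame,time_s,flexion_deg,u_mm,v_mm,residual_mm,pose_rms_mm,
#'   off_plane`), `plane` (a [motion_plane()]), `rel_poses` (list of
#'   [rigid_pose()]), `centers` (n x 3), `plane_rms_mm`.
#' @export
analyze_motion <- function(frames, reference_frame = 0L,
                           lateral_hint = c(0, 0, 1), ap_hint = c(1, 0, 0)) {
  need <- c("frame", "time_s", "tracker_id", "marker_index",
            "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(frames)))
    stop("marker stream must have columns ", paste(need, collapse = ","))
  get_markers <- function(fr, tr) {
    d <- frames[frames$frame == fr & frames$tracker_id == tr, ]
    d <- d[order(d$marker_index), ]
    as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
  }
  ids <- sort(unique(frames$frame))
  if (!reference_frame %in% ids)
    stop("reference frame ", reference_frame, " not present in the stream")
  ref_fem <- get_markers(reference_frame, 1L)
  ref_tib <- get_markers(reference_frame, 2L)
  n <- length(ids)
  rel <- vector("list", n)
  centers <- matrix(NA_real_, n, 3L)
  rms <- numeric(n)
  tib_centroid_ref <- colMeans(ref_tib)
  for (i in seq_len(n)) {
    pf <- pose_from_markers(ref_fem, get_markers(ids[i], 1L))
    pt <- pose_from_markers(ref_tib, get_markers(ids[i], 2L))
    rel[[i]] <- relative_pose(pf$pose, pt$pose)
    rms[i] <- sqrt((pf$rms^2 + pt$rms^2) / 2)
    centers[i, ] <- pose_apply(rel[[i]], tib_centroid_ref)
  }
  plane <- fit_main_plane(centers, lateral_hint, ap_hint)
  iref <- match(reference_frame, ids)
  ang <- numeric(n); off <- logical(n)
  for (i in seq_len(n)) {
    a <- flexion_angle(rel[[i]], rel[[iref]], plane)
    ang[i] <- as.numeric(a); off[i] <- attr(a, "off_plane")
  }
  ## flexion should be predominantly positive; flip the normal (and the
  ## in-plane y axis, keeping the frame right-handed) if not
  if (sum(ang) < 0) {
    plane <- motion_plane(plane$origin, -plane$normal,
                          plane$in_plane_x, -plane$in_plane_y)
    ang <- -ang
  }
  pr <- project_trajectory(centers, plane)
  tms <- frames$time_s[match(ids, frames$frame)]
  samples <- data.frame(frame = ids, time_s = tms, flexion_deg = ang,
                        u_mm = pr$uv[, 1], v_mm = pr$uv[, 2],
                        residual_mm = pr$residual, pose_rms_mm = rms,
                        off_plane = off)
  structure(list(samples = samples, plane = plane, rel_poses = rel,
                 centers = centers,
                 plane_rms_mm = attr(plane, "rms_mm"),
                 reference_frame = reference_frame),
            class = "motion_analysis")
}

#' Read / write marker stream CSV
#'
#' Columns `frame,time_s,tracker_id,marker_index,x_mm,y_mm,z_mm`; frame 0
#' is the extension reference by convention.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_marker_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "time_s", "tracker_id", "marker_index",
            "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d)))
    stop("marker CSV must have columns ", paste(need, collapse = ","))
  d
}

#' @rdname read_marker_csv
#' @param frames data.frame of marker positions.
#' @export
write_marker_csv <- function(frames, path) {
  utils::write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted plane to JSON
#' @param plane a [motion_plane()].
#' @param path output path.
#' @export
write_plane_json <- function(plane, path) {
  jsonlite::write_json(list(origin = plane$origin, normal = plane$normal,
                            in_plane_x = plane$in_plane_x,
                            in_plane_y = plane$in_plane_y,
                            rms_mm = attr(plane, "rms_mm")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
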