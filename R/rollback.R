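#' Sagittal condyle profile
#'
#' An ordered open polyline describing the articulating sagittal outline of
#' the femoral condyle (natural bone or implant), in a femur-fixed sagittal
#' frame (x anterior-to-posterior positive, y proximal positive, mm).
#'
#' @param polyline n x 2 numeric matrix (mm).
#' @param kind `"natural"` or `"implant"`.
#' @return object of class `condyle_profile`.
#' @export
condyle_profile <- function(polyline, kind = c("natural", "implant")) {
  kind <- match.arg(kind)
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2L, nrow(polyline) >= 2L,
            all(is.finite(polyline)))
  structure(list(polyline = polyline, kind = kind),
            class = "condyle_profile")
}

#' Sagittal tibial plateau profile
#'
#' A single-valued polyline y(x) in the tibia-fixed sagittal frame
#' (x posterior positive, mm); `center_ap` is the anterior-posterior
#' coordinate of the plateau centre used as the rollback zero reference.
#'
#' @param polyline n x 2 numeric matrix, strictly increasing in x.
#' @param center_ap plateau-centre AP coordinate (mm).
#' @return object of class `plateau_profile`.
#' @export
plateau_profile <- function(polyline, center_ap = 0) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2L, nrow(polyline) >= 2L,
            all(is.finite(polyline)), all(diff(polyline[, 1]) > 0))
  structure(list(polyline = polyline, center_ap = as.numeric(center_ap)),
            class = "plateau_profile")
}

#' Femorotibial contact point in the sagittal plane
#'
#' Poses the condyle polyline into the tibia-fixed frame and finds the
#' point of minimal signed clearance above the plateau, measured along the
#' plateau normal (vertical for the flat default plateau).  Clearance below
#' `tol` means contact; negative clearance (discretisation overlap) selects
#' the deepest-penetration point.
#'
#' @param femur_profile a [condyle_profile()].
#' @param femur_pose2d an [se2_pose()]: femur sagittal frame expressed in
#'   the tibia sagittal frame.
#' @param plateau a [plateau_profile()].
#' @param tol contact tolerance (mm, default 0.1).
#' @return list with `contact` (2-vector, tibia frame, mm), `clearance`
#'   (mm) and `in_contact` (logical).
#' @export
contact_point <- function(femur_profile, femur_pose2d, plateau, tol = 0.1) {
  stopifnot(inherits(femur_profile, "condyle_profile"),
            inherits(femur_pose2d, "se2_pose"),
            inherits(plateau, "plateau_profile"))
  posed <- se2_apply(femur_pose2d, femur_profile$polyline)
  px <- plateau$polyline[, 1]; py <- plateau$polyline[, 2]
  sel <- posed[, 1] >= px[1] & posed[, 1] <= px[length(px)]
  if (!any(sel))
    stop("no anterior-posterior overlap between posed condyle and plateau")
  x <- posed[sel, 1]; y <- posed[sel, 2]
  base <- stats::approx(px, py, xout = x, rule = 2)$y
  clr <- y - base
  i <- which.min(clr)
  cx <- x[i]; cy <- base[i] + clr[i]; cmin <- clr[i]
  ## parabolic refinement over the argmin neighbourhood for a smooth
  ## contact trajectory despite polyline discretisation
  if (i > 1L && i < length(x)) {
    x3 <- x[(i - 1L):(i + 1L)]; c3 <- clr[(i - 1L):(i + 1L)]
    den <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
    if (abs(den) > 1e-12) {
      a <- (x3[3] * (c3[2] - c3[1]) + x3[2] * (c3[1] - c3[3]) +
              x3[1] * (c3[3] - c3[2])) / den
      b <- (x3[3]^2 * (c3[1] - c3[2]) + x3[2]^2 * (c3[3] - c3[1]) +
              x3[1]^2 * (c3[2] - c3[3])) / den
      if (a > 1e-12) {
        xv <- -b / (2 * a)
        if (xv >= x3[1] && xv <= x3[3]) {
          cc <- (x3[1] - xv) * (x3[2] - xv) * a +
            ((c3[2] - c3[1]) / (x3[2] - x3[1])) * (xv - x3[1]) + c3[1]
          ## evaluate the fitted parabola at its vertex
          cv <- a * xv^2 + b * xv +
            (c3[1] - a * x3[1]^2 - b * x3[1])
          cx <- xv
          cmin <- cv
          cy <- stats::approx(px, py, xout = xv, rule = 2)$y + cv
        }
      }
    }
  }
  list(contact = c(cx, cy), clearance = cmin, in_contact = cmin < tol)
}

#' Femoral rollback curve
#'
#' For each flexion angle, poses the femur relative to the tibia through
#' the four-bar (the tibia frame is the reference because the plateau and
#' its AP axis are tibia-fixed), finds the femorotibial contact point, and
#' records its anterior-posterior coordinate relative to the plateau
#' centre.  The curve is normalised to 0 mm at the extension reference
#' angle.  Positive displacement is posterior (rollback).
#'
#' @param linkage a [fourbar_linkage()] with a drive map (see
#'   [linkage_input_angle()]), expressed in the femur sagittal frame.
#' @param femur_profile a [condyle_profile()] in the femur sagittal frame.
#' @param plateau a [plateau_profile()] in the tibia sagittal frame.
#' @param tibia_attachment an [se2_pose()]: tibia sagittal frame in
#'   coupler-link coordinates.
#' @param angles flexion angles (degrees, strictly increasing).
#' @param extension_angle flexion angle of the extension reference used for
#'   normalisation (degrees; default 20, the model's extended position).
#' @param normalize normalise to 0 at `extension_angle` (default TRUE).
#' @param contact_tol contact tolerance passed to [contact_point()].
#' @return object of class `rollback_curve`: list with `flexion`,
#'   `displacement` (mm), `clearance`, `normalized`, `extension_angle`.
#' @export
rollback_curve <- function(linkage, femur_profile, plateau, tibia_attachment,
                           angles, extension_angle = 20, normalize = TRUE,
                           contact_tol = 0.1) {
  stopifnot(all(diff(angles) > 0))
  eval_angles <- angles
  if (normalize && !extension_angle %in% angles)
    eval_angles <- sort(unique(c(angles, extension_angle)))
  disp <- clear <- numeric(length(eval_angles))
  for (i in seq_along(eval_angles)) {
    th <- linkage_input_angle(linkage, eval_angles[i])
    tp <- tibia_pose_from_linkage(linkage, th, tibia_attachment)
    cp <- contact_point(femur_profile, se2_inverse(tp), plateau,
                        tol = contact_tol)
    disp[i] <- cp$contact[1] - plateau$center_ap
    clear[i] <- cp$clearance
  }
  if (normalize) {
    ref <- disp[match(extension_angle, eval_angles)]
    disp <- disp - ref
  }
  keep <- match(angles, eval_angles)
  structure(list(flexion = angles, displacement = disp[keep],
                 clearance = clear[keep], normalized = normalize,
                 extension_angle = extension_angle),
            class = "rollback_curve")
}

#' @export
print.rollback_curve <- function(x, ...) {
  i <- which.max(x$displacement)
  cat(sprintf(paste0("<rollback_curve> %d angles [%g, %g] deg, %s, ",
                     "max %.2f mm at %.0f deg\n"),
              length(x$flexion), min(x$flexion), max(x$flexion),
              if (x$normalized) "normalized" else "raw",
              x$displacement[i], x$flexion[i]))
  invisible(x)
}

## re-normalise a curve at its extension reference (linear interpolation if
## the reference is off-grid)
renormalize_rollback <- function(curve) {
  ref <- stats::approx(curve$flexion, curve$displacement,
                       xout = curve$extension_angle, rule = 2)$y
  curve$displacement <- curve$displacement - ref
  ## exact zero at an on-grid reference
  j <- match(curve$extension_angle, curve$flexion)
  if (!is.na(j)) curve$displacement[j] <- 0
  curve$normalized <- TRUE
  curve
}

#' Average rollback trials
#'
#' Pointwise mean of several rollback curves (the final value is the mean
#' of the measured flexions).  Curves are resampled by linear interpolation
#' onto the flexion grid of the first curve restricted to the common range,
#' then the normalisation is re-applied.
#'
#' @param curves list of [rollback_curve()] objects.
#' @return a [rollback_curve()].
#' @export
average_trials <- function(curves) {
  if (!length(curves)) stop("no rollback curves supplied")
  stopifnot(all(vapply(curves, inherits, TRUE, "rollback_curve")))
  lo <- max(vapply(curves, function(cv) min(cv$flexion), 0))
  hi <- min(vapply(curves, function(cv) max(cv$flexion), 0))
  if (lo >= hi) stop("rollback curves have disjoint flexion ranges")
  grid <- curves[[1]]$flexion
  grid <- grid[grid >= lo & grid <= hi]
  m <- vapply(curves, function(cv)
    stats::approx(cv$flexion, cv$displacement, xout = grid)$y,
    numeric(length(grid)))
  out <- structure(list(flexion = grid,
                        displacement = rowMeans(as.matrix(m)),
                        clearance = NULL,
                        normalized = curves[[1]]$normalized,
                        extension_angle = curves[[1]]$extension_angle),
                   class = "rollback_curve")
  renormalize_rollback(out)
}

#' Compare pre- and post-operative rollback
#'
#' @param pre,post normalised [rollback_curve()] objects with overlapping
#'   flexion ranges.
#' @return list with `max_pre`, `angle_at_max_pre`, `max_post`,
#'   `angle_at_max_post`, `ratio` (max_post / max_pre) and
#'   `pointwise_delta` (a [rollback_curve()] of post - pre on the common
#'   grid, not re-normalised).
#' @export
compare_rollback <- function(pre, post) {
  stopifnot(inherits(pre, "rollback_curve"), inherits(post, "rollback_curve"))
  if (!isTRUE(pre$normalized) || !isTRUE(post$normalized))
    stop("both curves must be normalized before comparison")
  lo <- max(min(pre$flexion), min(post$flexion))
  hi <- min(max(pre$flexion), max(post$flexion))
  if (lo >= hi) stop("rollback curves have disjoint flexion ranges")
  grid <- sort(unique(c(pre$flexion[pre$flexion >= lo & pre$flexion <= hi],
                        post$flexion[post$flexion >= lo & post$flexion <= hi])))
  a <- stats::approx(pre$flexion, pre$displacement, xout = grid)$y
  b <- stats::approx(post$flexion, post$displacement, xout = grid)$y
  ia <- which.max(a); ib <- which.max(b)
  delta <- structure(list(flexion = grid, displacement = b - a,
                          clearance = NULL, normalized = FALSE,
                          extension_angle = pre$extension_angle),
                     class = "rollback_curve")
  list(max_pre = a[ia], angle_at_max_pre = grid[ia],
       max_post = b[ib], angle_at_max_post = grid[ib],
       ratio = b[ib] / a[ia], pointwise_delta = delta)
}

#' Write rollback curves to CSV
#'
#' Columns `flexion_deg,displacement_mm,trial_id`.
#' @param curves a [rollback_curve()] or a named list of them (names become
#'   trial ids).
#' @param path output CSV path.
#' @export
write_rollback_csv <- function(curves, path) {
  if (inherits(curves, "rollback_curve")) curves <- list(trial1 = curves)
  df <- do.call(rbind, lapply(names(curves), function(id) {
    cv <- curves[[id]]
    data.frame(flexion_deg = cv$flexion, displacement_mm = cv$displacement,
               trial_id = id)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
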