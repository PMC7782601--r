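#' Planar rigid transform (SE(2))
#'
#' A planar pose is a rotation by `theta` (degrees, counter-clockwise)
#' followed by a translation `t` (mm).  Poses act on row-wise 2D point sets
#' as `p |-> R(theta) p + t`.  These are the frames used for the four-bar
#' coupler, the tibia attachment and the sagittal bone frames.
#'
#' @param theta rotation angle in degrees (counter-clockwise).
#' @param t numeric length-2 translation (mm).
#' @return an object of class `se2_pose`.
#' @export
se2_pose <- function(theta = 0, t = c(0, 0)) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(t), length(t) == 2L, all(is.finite(t)))
  structure(list(theta = theta, t = as.numeric(t)), class = "se2_pose")
}

#' @export
print.se2_pose <- function(x, ...) {
  cat(sprintf("<se2_pose> theta = %.4f deg, t = (%.4f, %.4f) mm\n",
              x$theta, x$t[1], x$t[2]))
  invisible(x)
}

rot2 <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

#' Compose two planar poses
#'
#' `se2_compose(a, b)` is the pose "first apply `b`, then `a`".
#' @param a,b `se2_pose` objects.
#' @return an `se2_pose`.
#' @export
se2_compose <- function(a, b) {
  se2_pose(a$theta + b$theta, as.numeric(rot2(a$theta) %*% b$t) + a$t)
}

#' Invert a planar pose
#' @param a an `se2_pose`.
#' @return the inverse `se2_pose`.
#' @export
se2_inverse <- function(a) {
  se2_pose(-a$theta, as.numeric(-(rot2(-a$theta) %*% a$t)))
}

#' Apply a planar pose to points
#' @param a an `se2_pose`.
#' @param pts numeric matrix (n x 2) or length-2 vector.
#' @return transformed points, same shape as the input.
#' @export
se2_apply <- function(a, pts) {
  if (is.null(dim(pts))) {
    stopifnot(length(pts) == 2L)
    return(as.numeric(rot2(a$theta) %*% pts) + a$t)
  }
  stopifnot(ncol(pts) == 2L)
  sweep(pts %*% t(rot2(a$theta)), 2L, a$t, "+")
}

## angle helpers -------------------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap an angle difference into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

## unwrap a sampled angle sequence so it is continuous (degrees)
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- wrap180(diff(x))
  x[1] + c(0, cumsum(d))
}
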