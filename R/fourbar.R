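#' Planar four-bar linkage
#'
#' Defines a planar four-bar mechanism in a ground (femur-fixed) frame.
#' The input link rotates about `ground_a`, the follower about `ground_b`;
#' the coupler (tibia-fixed link) joins the two moving pivots.  A coupler
#' point is given in the coupler-link frame whose origin is the input-link
#' tip and whose x axis points along the coupler towards the follower tip.
#'
#' @param ground_a,ground_b length-2 numeric, fixed pivot positions (mm).
#' @param len_input,len_coupler,len_follower positive link lengths (mm).
#' @param coupler_offset length-2 numeric, coupler-point coordinates in the
#'   coupler-link frame (mm).
#' @param branch `+1` or `-1`: which circle-circle intersection (elbow side)
#'   the follower tip takes.  `+1` selects the intersection to the left of
#'   the directed segment input-tip -> `ground_b`.
#' @param angle_range optional length-2 numeric, declared input-angle range
#'   in degrees.
#' @param drive optional drive map relating flexion angle to input angle:
#'   either a length-2 numeric `c(offset, scale)` (input = offset +
#'   scale * flexion, degrees) or a function `function(flexion_deg)` that
#'   returns input angles in degrees.
#' @return an object of class `fourbar_linkage`.
#' @export
fourbar_linkage <- function(ground_a, ground_b, len_input, len_coupler,
                            len_follower, coupler_offset = c(0, 0),
                            branch = 1L, angle_range = NULL, drive = NULL) {
  ground_a <- as.numeric(ground_a); ground_b <- as.numeric(ground_b)
  stopifnot(length(ground_a) == 2L, length(ground_b) == 2L,
            all(is.finite(c(ground_a, ground_b))),
            is.numeric(len_input), len_input > 0,
            is.numeric(len_coupler), len_coupler > 0,
            is.numeric(len_follower), len_follower > 0,
            length(coupler_offset) == 2L, branch %in% c(-1, 1))
  if (sqrt(sum((ground_a - ground_b)^2)) < 1e-9)
    stop("ground pivots must be distinct")
  structure(list(ground_a = ground_a, ground_b = ground_b,
                 len_input = as.numeric(len_input),
                 len_coupler = as.numeric(len_coupler),
                 len_follower = as.numeric(len_follower),
                 coupler_offset = as.numeric(coupler_offset),
                 branch = as.integer(branch),
                 angle_range = angle_range, drive = drive),
            class = "fourbar_linkage")
}

#' @export
print.fourbar_linkage <- function(x, ...) {
  cat("<fourbar_linkage>\n")
  cat(sprintf("  ground_a  (%.3f, %.3f) mm   ground_b (%.3f, %.3f) mm\n",
              x$ground_a[1], x$ground_a[2], x$ground_b[1], x$ground_b[2]))
  cat(sprintf("  lengths   input %.3f  coupler %.3f  follower %.3f  (ground %.3f) mm\n",
              x$len_input, x$len_coupler, x$len_follower,
              sqrt(sum((x$ground_b - x$ground_a)^2))))
  cat(sprintf("  coupler offset (%.3f, %.3f) mm, branch %+d\n",
              x$coupler_offset[1], x$coupler_offset[2], x$branch))
  g <- classify_grashof(x)
  cat(sprintf("  class: %s\n", g$class))
  invisible(x)
}

## Vectorised position solve over input angles (degrees).
## Returns input tip, follower tip, elbow height h, assemblability flags.
fourbar_solve <- function(linkage, theta_deg) {
  th <- deg2rad(theta_deg)
  ax <- linkage$ground_a[1]; ay <- linkage$ground_a[2]
  bx <- linkage$ground_b[1]; by <- linkage$ground_b[2]
  px <- ax + linkage$len_input * cos(th)
  py <- ay + linkage$len_input * sin(th)
  dx <- bx - px; dy <- by - py
  d <- sqrt(dx^2 + dy^2)
  l2 <- linkage$len_coupler; l3 <- linkage$len_follower
  ## triangle on the coupler/follower pair about P and ground_b
  a <- (l2^2 - l3^2 + d^2) / (2 * d)
  h2 <- l2^2 - a^2
  ok <- h2 >= 0 & d > 1e-12
  h <- sqrt(pmax(h2, 0))
  ux <- dx / d; uy <- dy / d
  s <- linkage$branch
  fx <- px + a * ux - s * h * uy
  fy <- py + a * uy + s * h * ux
  list(theta = theta_deg,
       input_tip = cbind(px, py, deparse.level = 0),
       follower_tip = cbind(fx, fy, deparse.level = 0),
       ok = ok, h = h, h2 = h2, d = d)
}

#' Joint positions of a four-bar at one input angle
#'
#' @param linkage a [fourbar_linkage()].
#' @param input_angle input-link angle in degrees (measured from the ground
#'   x axis at `ground_a`).
#' @return list with 2-vectors `ground_a`, `input_tip`, `follower_tip`,
#'   `ground_b` (mm).
#' @export
assembly_state <- function(linkage, input_angle) {
  stopifnot(inherits(linkage, "fourbar_linkage"),
            is.numeric(input_angle), length(input_angle) == 1L)
  s <- fourbar_solve(linkage, input_angle)
  if (!s$ok)
    stop(sprintf(paste0("four-bar not assemblable at input angle %.3f deg ",
                        "(transmission triangle violated: d = %.3f, ",
                        "coupler %.3f, follower %.3f)"),
                 input_angle, s$d, linkage$len_coupler,
                 linkage$len_follower))
  list(ground_a = linkage$ground_a,
       input_tip = as.numeric(s$input_tip),
       follower_tip = as.numeric(s$follower_tip),
       ground_b = linkage$ground_b)
}

## coupler frame angles (deg) for a solved state
coupler_angle_deg <- function(sol) {
  rad2deg(atan2(sol$follower_tip[, 2] - sol$input_tip[, 2],
                sol$follower_tip[, 1] - sol$input_tip[, 1]))
}

## Vectorised coupler points; returns n x 2 with NA where not assemblable.
coupler_points <- function(linkage, theta_deg) {
  s <- fourbar_solve(linkage, theta_deg)
  ex <- (s$follower_tip[, 1] - s$input_tip[, 1]) / linkage$len_coupler
  ey <- (s$follower_tip[, 2] - s$input_tip[, 2]) / linkage$len_coupler
  ox <- linkage$coupler_offset[1]; oy <- linkage$coupler_offset[2]
  cp <- cbind(s$input_tip[, 1] + ox * ex - oy * ey,
              s$input_tip[, 2] + ox * ey + oy * ex)
  cp[!s$ok, ] <- NA_real_
  list(points = cp, ok = s$ok, sol = s)
}

#' Coupler point at one input angle
#'
#' @inheritParams assembly_state
#' @return length-2 numeric (mm).
#' @export
coupler_point <- function(linkage, input_angle) {
  stopifnot(length(input_angle) == 1L)
  r <- coupler_points(linkage, input_angle)
  if (!r$ok) stop(sprintf("four-bar not assemblable at %.3f deg", input_angle))
  as.numeric(r$points)
}

#' Coupler curve over an input-angle range
#'
#' Evaluates the coupler point at `n` uniformly spaced input angles.  The
#' contiguous assemblable run containing the start of the range is the
#' primary branch.
#'
#' @inheritParams assembly_state
#' @param angle_range length-2 numeric, input-angle range in degrees.
#' @param n number of samples (>= 2).
#' @return list with `theta` (deg), `points` (n x 2, NA outside assembly),
#'   `assemblable` (logical), `primary` (logical, the contiguous assemblable
#'   run containing the range start).
#' @export
coupler_curve <- function(linkage, angle_range, n) {
  stopifnot(length(angle_range) == 2L, n >= 2)
  theta <- seq(angle_range[1], angle_range[2], length.out = n)
  r <- coupler_points(linkage, theta)
  if (!any(r$ok))
    stop("four-bar not assemblable anywhere in the requested angle range")
  primary <- logical(n)
  if (r$ok[1]) {
    stop_at <- which(!r$ok)
    last <- if (length(stop_at)) min(stop_at) - 1L else n
    primary[seq_len(last)] <- TRUE
  } else {
    runs <- rle(r$ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    i <- which(runs$values)[1]
    primary[starts[i]:ends[i]] <- TRUE
  }
  list(theta = theta, points = r$points, assemblable = r$ok,
       primary = primary)
}

#' Grashof classification of a four-bar
#'
#' Applies the Grashof test `s + l <= p + q` on the four link lengths
#' (including the ground link) and names the mobility class from the
#' position of the shortest link.
#'
#' @inheritParams assembly_state
#' @return list with `grashof` (logical), `class` (character), `lengths`
#'   (named numeric), and `input_is_crank` (logical: the input link can make
#'   a full revolution).
#' @export
classify_grashof <- function(linkage) {
  g <- sqrt(sum((linkage$ground_b - linkage$ground_a)^2))
  len <- c(ground = g, input = linkage$len_input,
           coupler = linkage$len_coupler, follower = linkage$len_follower)
  s <- min(len); l <- max(len)
  pq <- sum(len) - s - l
  tol <- 1e-9 * max(len)
  shortest <- names(len)[which.min(len)]
  if (abs(s + l - pq) <= tol) {
    cls <- "change-point"; grashof <- TRUE
  } else if (s + l < pq) {
    grashof <- TRUE
    cls <- switch(shortest,
                  ground = "double-crank",
                  coupler = "double-rocker",
                  input = , follower = "crank-rocker")
  } else {
    grashof <- FALSE
    cls <- "non-grashof-triple-rocker"
  }
  input_is_crank <- grashof && shortest %in% c("ground", "input")
  list(grashof = grashof, class = cls, lengths = len,
       input_is_crank = input_is_crank)
}

#' Planar pose of a coupler-fixed (tibia) frame
#'
#' Returns the rigid planar pose, in the ground (femur) frame, of a frame
#' rigidly attached to the coupler link.  The attachment is given as an
#' [se2_pose()] expressed in the coupler-link frame (origin at the input
#' tip, x axis along the coupler).
#'
#' @inheritParams assembly_state
#' @param tibia_attachment an [se2_pose()]: the tibia frame in coupler-link
#'   coordinates.
#' @return an [se2_pose()] (tibia frame in ground frame).
#' @export
tibia_pose_from_linkage <- function(linkage, input_angle, tibia_attachment) {
  stopifnot(inherits(tibia_attachment, "se2_pose"), length(input_angle) == 1L)
  s <- fourbar_solve(linkage, input_angle)
  if (!s$ok) stop(sprintf("four-bar not assemblable at %.3f deg", input_angle))
  cf <- se2_pose(coupler_angle_deg(s), as.numeric(s$input_tip))
  se2_compose(cf, tibia_attachment)
}

#' Input angle for a given flexion angle
#'
#' Evaluates the linkage's drive map (affine pair or function) relating
#' knee flexion angle to the mechanism input angle.
#'
#' @inheritParams assembly_state
#' @param flexion numeric vector of flexion angles (degrees).
#' @return numeric vector of input angles (degrees).
#' @export
linkage_input_angle <- function(linkage, flexion) {
  d <- linkage$drive
  if (is.null(d))
    stop("linkage has no drive map relating flexion to input angle")
  if (is.function(d)) return(d(flexion))
  stopifnot(is.numeric(d), length(d) == 2L)
  d[1] + d[2] * flexion
}

## -------------------------------------------------------------------------
## JSON I/O

#' Write a linkage to JSON
#' @param linkage a [fourbar_linkage()].
#' @param path output file path.
#' @export
write_linkage_json <- function(linkage, path) {
  drive <- linkage$drive
  x <- list(ground_a = linkage$ground_a, ground_b = linkage$ground_b,
            len_input = linkage$len_input, len_coupler = linkage$len_coupler,
            len_follower = linkage$len_follower,
            coupler_offset = linkage$coupler_offset,
            branch = linkage$branch, angle_range = linkage$angle_range,
            drive_affine = if (is.numeric(drive)) drive else NULL)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linkage from JSON
#' @param path JSON file written by [write_linkage_json()].
#' @return a [fourbar_linkage()].
#' @export
read_linkage_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fourbar_linkage(x$ground_a, x$ground_b, x$len_input, x$len_coupler,
                  x$len_follower, x$coupler_offset, x$branch,
                  angle_range = x$angle_range, drive = x$drive_affine)
}
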