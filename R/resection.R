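#' Anatomical reference axes of the knee
#'
#' The femoral rotational references used by measured resection: the
#' mechanical axis (pointing proximally along the femur), the
#' transepicondylar axis (TEA), the anterior-posterior (Whiteside) axis
#' and the posterior condylar axis (PCA), with the knee centre as origin.
#' Vectors are normalised on construction.
#'
#' @param mechanical_axis,tea,ap_axis,pca 3-vectors (any length, will be
#'   normalised).  `ap_axis` points anteriorly, `mechanical_axis`
#'   proximally.
#' @param origin knee centre (mm).
#' @return object of class `anatomical_axes`.
#' @export
anatomical_axes <- function(mechanical_axis = c(0, 0, 1),
                            tea = c(1, 0, 0),
                            ap_axis = c(0, 1, 0),
                            pca = c(1, 0, 0),
                            origin = c(0, 0, 0)) {
  nz <- function(v) {
    v <- as.numeric(v); l <- sqrt(sum(v^2))
    if (l < 1e-9) stop("degenerate (zero) anatomical axis")
    v / l
  }
  m <- nz(mechanical_axis); te <- nz(tea); ap <- nz(ap_axis); pc <- nz(pca)
  if (abs(sum(ap * te)) > cos(deg2rad(10)))
    stop("ap_axis and tea are nearly parallel (angle < 10 deg)")
  structure(list(mechanical_axis = m, tea = te, ap_axis = ap, pca = pc,
                 origin = as.numeric(origin)),
            class = "anatomical_axes")
}

#' Measured-resection plan
#'
#' Cut angles and depths for a measured-resection total knee
#' arthroplasty.  Angle defaults follow the standard technique: 6 degrees
#' of femoral valgus, neutral femoral flexion, 3 degrees of external
#' rotation referenced to the posterior condylar axis, neutral tibial
#' coronal angle and 6 degrees of posterior tibial slope.
#'
#' @param femoral_valgus,femoral_flexion,external_rotation,tibial_coronal,posterior_slope
#'   angles in degrees, each within [-15, 15].
#' @param resection_depths named numeric (mm > 0): `distal`, `posterior`,
#'   `anterior`, `tibial` (defaults 9, 9, 9, 8).
#' @return object of class `resection_plan`.
#' @export
resection_plan <- function(femoral_valgus = 6, femoral_flexion = 0,
                           external_rotation = 3, tibial_coronal = 0,
                           posterior_slope = 6,
                           resection_depths = c(distal = 9, posterior = 9,
                                                anterior = 9, tibial = 8)) {
  ang <- c(femoral_valgus, femoral_flexion, external_rotation,
           tibial_coronal, posterior_slope)
  if (any(abs(ang) > 15))
    stop("resection angles must lie within [-15, 15] degrees")
  if (any(resection_depths <= 0)) stop("resection depths must be positive")
  structure(list(femoral_valgus = femoral_valgus,
                 femoral_flexion = femoral_flexion,
                 external_rotation = external_rotation,
                 tibial_coronal = tibial_coronal,
                 posterior_slope = posterior_slope,
                 resection_depths = resection_depths),
            class = "resection_plan")
}

#' Cutting plane
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal, pointing towards the kept (bone) side.
#' @param label one of `distal-femoral`, `posterior-femoral`,
#'   `anterior-femoral`, `chamfer-anterior`, `chamfer-posterior`,
#'   `tibial`.
#' @return object of class `cutting_plane`.
#' @export
cutting_plane <- function(point, normal, label = "cut") {
  n <- as.numeric(normal); l <- sqrt(sum(n^2))
  if (l < 1e-12) stop("degenerate cutting-plane normal")
  structure(list(point = as.numeric(point), normal = n / l,
                 label = label),
            class = "cutting_plane")
}

## rotate vector v by ang (deg) about `axis` orthogonalised against v's
## plane: the component of axis parallel to v is removed first so the
## stated angle is realised exactly even for slightly non-orthogonal
## anatomical axes
rotate_exact <- function(v, axis, ang) {
  if (abs(ang) < 1e-15) return(v)
  a <- axis - v * sum(axis * v) / sum(v * v)
  l <- sqrt(sum(a^2))
  if (l < 1e-9) stop("rotation axis parallel to the rotated vector")
  as.numeric(rotation_about_axis(a / l, ang) %*% v)
}

#' Build measured-resection cutting planes
#'
#' Constructs the femoral (distal, posterior, anterior, two chamfers) and
#' tibial cutting planes from the anatomical axes and the plan:
#' \itemize{
#'   \item distal femoral: normal = mechanical axis tilted by the valgus
#'     angle about the AP axis, then by the femoral flexion angle about
#'     the TEA;
#'   \item posterior femoral: normal = the PCA-orthogonal direction
#'     (anterior) rotated by the external rotation about the mechanical
#'     axis -- femoral component rotation referenced to the posterior
#'     condyles;
#'   \item anterior femoral and chamfers: an implant-box template at the
#'     configured chamfer angle;
#'   \item tibial: normal = mechanical axis tilted posteriorly by the
#'     slope about a TEA-parallel axis, then by the tibial coronal angle
#'     about the AP axis, flipped distally (the tibia keeps its distal
#'     side).
#' }
#' Plane points lie at the configured resection depths from the origin
#' along the respective cut directions.
#'
#' @param axes an [anatomical_axes()].
#' @param plan a [resection_plan()].
#' @param chamfer_angle chamfer obliquity of the implant box (degrees,
#'   default 45).
#' @return list of [cutting_plane()] objects, in surgical order: distal,
#'   posterior, anterior, chamfer-posterior, chamfer-anterior, tibial.
#' @export
build_resection_planes <- function(axes, plan, chamfer_angle = 45) {
  stopifnot(inherits(axes, "anatomical_axes"),
            inherits(plan, "resection_plan"))
  m <- axes$mechanical_axis; ap <- axes$ap_axis
  dd <- plan$resection_depths
  ## distal femoral cut: valgus about AP, then flexion about TEA
  nd <- rotate_exact(m, ap, plan$femoral_valgus)
  nd <- rotate_exact(nd, axes$tea, plan$femoral_flexion)
  distal <- cutting_plane(axes$origin - dd[["distal"]] * nd, nd,
                          "distal-femoral")
  ## posterior femoral cut: anterior direction (orthogonal to PCA and to
  ## the mechanical axis) rotated by the external rotation about the
  ## mechanical axis
  ant <- ap - axes$pca * sum(ap * axes$pca)
  ant <- ant - m * sum(ant * m)
  ant <- ant / sqrt(sum(ant^2))
  np <- rotate_exact(ant, m, plan$external_rotation)
  posterior <- cutting_plane(axes$origin - dd[["posterior"]] * np, np,
                             "posterior-femoral")
  ## anterior femoral cut: opposite the posterior cut direction
  na <- -np
  anterior <- cutting_plane(axes$origin - dd[["anterior"]] * na, na,
                            "anterior-femoral")
  ## chamfers: between distal and posterior/anterior at the box angle
  mix <- function(n1, n2, ang) {
    v <- cos(deg2rad(ang)) * n1 + sin(deg2rad(ang)) * n2
    v / sqrt(sum(v^2))
  }
  ncp <- mix(nd, np, chamfer_angle)
  ncA <- mix(nd, na, chamfer_angle)
  ## chamfer planes pass inside the corner left between the primary cuts
  ## (implant-box template: chamfer_frac of both depths)
  cf <- 0.75
  champ <- cutting_plane(axes$origin - cf * (dd[["distal"]] * nd +
                                               dd[["posterior"]] * np),
                         ncp, "chamfer-posterior")
  chama <- cutting_plane(axes$origin - cf * (dd[["distal"]] * nd +
                                               dd[["anterior"]] * na),
                         ncA, "chamfer-anterior")
  ## tibial cut: posterior slope about a TEA-parallel axis, coronal tilt
  ## about AP; the tibia keeps the distal side
  nt <- rotate_exact(m, axes$tea, -plan$posterior_slope)
  nt <- rotate_exact(nt, ap, plan$tibial_coronal)
  tibial <- cutting_plane(axes$origin - dd[["tibial"]] * nt, -nt, "tibial")
  list(distal, posterior, anterior, champ, chama, tibial)
}
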