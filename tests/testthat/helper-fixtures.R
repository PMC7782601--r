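## shared fixtures, built in code

## a unit cube trimesh with outward orientation
unit_cube <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  trimesh(v, f)
}

## random affinely deformed convex solid (image of the cube)
random_convex_mesh <- function() {
  A <- matrix(stats::rnorm(9), 3)
  while (abs(det(A)) < 0.2) A <- matrix(stats::rnorm(9), 3)
  m <- unit_cube()
  v <- m$vertices %*% t(A)
  v <- sweep(v, 2, stats::rnorm(3, sd = 2), "+")
  f <- m$faces
  if (det(A) < 0) f <- f[, c(1, 3, 2)]
  trimesh(v, f)
}

## sphere mesh by octahedron subdivision (vertices exactly on the sphere)
sphere_mesh <- function(radius = 20, n_subdiv = 4) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(n_subdiv)) {
    env <- new.env(parent = emptyenv())
    midpt <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- env[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      env[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpt(a, b); bc <- midpt(b, c_); ca <- midpt(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(ab, b, bc), c(ca, bc, c_),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  trimesh(v * radius, f)
}

## random proper rotation matrix
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  kneefourbar:::rotation_about_axis(ax, stats::runif(1, 0, 360))
}

## a comfortable Grashof crank-rocker used across tests
demo_crank_rocker <- function(offset = c(25, 18))
  fourbar_linkage(c(0, 0), c(60, 5), 22, 55, 45,
                  coupler_offset = offset, branch = 1)

## sample the demo crank-rocker coupler curve as a synthesis target
crank_rocker_target <- function(n = 40) {
  lk <- demo_crank_rocker()
  fl <- seq(0, 100, length.out = n)
  theta <- 10 + 1.0 * fl
  pts <- t(vapply(theta, function(th) coupler_point(lk, th), numeric(2)))
  list(linkage = lk, flexion = fl, theta = theta, points = pts)
}
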