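#' Triangle mesh
#'
#' A plain indexed triangle mesh (mm).  Volume operations (cutting with
#' capping, volume) require a watertight, consistently outward-oriented
#' mesh.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise seen from outside.
#' @return object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, all(is.finite(vertices)),
            all(faces >= 1L), all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces, volume %.3f mm^3, %s\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x),
              if (is_watertight(x)) "watertight" else "NOT watertight"))
  invisible(x)
}

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem volume: positive for a watertight mesh with outward
#' orientation.
#' @param mesh a [trimesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Is a mesh watertight?
#'
#' Every undirected edge must be shared by exactly two faces, once in each
#' direction (consistent orientation).
#' @param mesh a [trimesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  de <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  fwd <- paste(de[, 1], de[, 2])
  rev <- paste(de[, 2], de[, 1])
  !anyDuplicated(fwd) && all(fwd %in% rev)
}

## ear-clipping triangulation of a simple 2D polygon (n x 2, open, any
## orientation); returns k x 3 index triples in the input order
earclip <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(matrix(integer(0), 0L, 3L))
  area2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  idx <- seq_len(n)
  if (area2 < 0) idx <- rev(idx)          # make CCW
  tris <- matrix(integer(0), 0L, 3L)
  guard <- 0L
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  while (length(idx) > 3L && guard < 10000L) {
    m <- length(idx); clipped <- FALSE
    for (i in seq_len(m)) {
      ia <- idx[if (i == 1L) m else i - 1L]
      ib <- idx[i]
      ic <- idx[if (i == m) 1L else i + 1L]
      a <- poly[ia, ]; b <- poly[ib, ]; c_ <- poly[ic, ]
      if (cross2(a, b, c_) <= 1e-12 * max(abs(poly)) ^ 2) next  # reflex/degenerate
      others <- setdiff(idx, c(ia, ib, ic))
      inside <- FALSE
      for (j in others) {
        p <- poly[j, ]
        if (cross2(a, b, p) >= 0 && cross2(b, c_, p) >= 0 &&
            cross2(c_, a, p) >= 0) { inside <- TRUE; break }
      }
      if (inside) next
      tris <- rbind(tris, c(ia, ib, ic))
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) {                        # fallback: fan (degenerate ring)
      for (i in 2L:(length(idx) - 1L))
        tris <- rbind(tris, c(idx[1L], idx[i], idx[i + 1L]))
      idx <- integer(0)
      break
    }
    guard <- guard + 1L
  }
  if (length(idx) == 3L) tris <- rbind(tris, idx)
  tris
}

## orthonormal in-plane basis for a unit normal
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- a - n * sum(a * n)
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(n[2] * ex[3] - n[3] * ex[2], n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])
  list(ex = ex, ey = ey, n = n)
}

## chain directed edges (two-column index matrix) into closed loops
chain_loops <- function(edges) {
  loops <- list()
  nxt <- split(edges[, 2], edges[, 1])
  used <- rep(FALSE, nrow(edges))
  emap <- split(seq_len(nrow(edges)), edges[, 1])
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    loop <- edges[e0, 1]
    cur <- edges[e0, 2]
    used[e0] <- TRUE
    repeat {
      loop <- c(loop, cur)
      cand <- emap[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      used[cand[1L]] <- TRUE
      cur <- edges[cand[1L], 2]
      if (cur == loop[1L]) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Cut a mesh with a plane
#'
#' Clips the mesh to the half-space on the side of `plane$normal`
#' (the normal points towards the kept side) and, for watertight input,
#' caps the cross-section so the result is watertight again.
#'
#' @param mesh a [trimesh()].
#' @param plane a [cutting_plane()] or list with `point` (3-vector) and
#'   `normal` (3-vector, towards the kept side).
#' @param cap cap the cross-section (default TRUE; requires watertight
#'   input).
#' @return a [trimesh()].
#' @export
cut_mesh <- function(mesh, plane, cap = TRUE) {
  stopifnot(inherits(mesh, "trimesh"))
  n <- plane$normal / sqrt(sum(plane$normal^2))
  if (cap && !is_watertight(mesh))
    stop("capping a cut requires a watertight input mesh")
  v <- mesh$vertices
  sd <- as.numeric(sweep(v, 2L, plane$point) %*% n)
  ## vertices exactly on the plane break the generic crossing topology
  ## (duplicate seam vertices); nudge them to the kept side by a distance
  ## far below any geometric tolerance
  eps <- 1e-12 * max(max(abs(sd)), 1)
  sd[abs(sd) < eps] <- eps
  keep <- sd >= 0
  if (all(keep)) return(mesh)
  if (!any(keep)) return(trimesh(matrix(numeric(0), 0L, 3L),
                                 matrix(integer(0), 0L, 3L)))
  newv <- list(); newvi <- new.env(parent = emptyenv())
  verts <- v
  cut_vertex <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- newvi[[key]]
    if (!is.null(hit)) return(hit)
    t <- sd[i] / (sd[i] - sd[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    verts <<- rbind(verts, p)
    id <- nrow(verts)
    newvi[[key]] <- id
    id
  }
  faces <- list(); capedges <- list()
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[k, ]
    kp <- keep[tri]
    nk <- sum(kp)
    if (nk == 3L) { faces[[length(faces) + 1L]] <- tri; next }
    if (nk == 0L) next
    ## rotate so the pattern starts with the kept vertex (nk = 1) or the
    ## dropped vertex is last (nk = 2)
    if (nk == 1L) {
      r <- which(kp)
      tri <- tri[((r - 1L + 0:2) %% 3L) + 1L]     # kept first
      a <- tri[1L]; b <- tri[2L]; c_ <- tri[3L]
      iab <- cut_vertex(a, b); ica <- cut_vertex(c_, a)
      faces[[length(faces) + 1L]] <- c(a, iab, ica)
      capedges[[length(capedges) + 1L]] <- c(iab, ica)
    } else {
      r <- which(!kp)
      tri <- tri[((r - 1L + 1:3) %% 3L) + 1L]     # dropped last
      a <- tri[1L]; b <- tri[2L]; c_ <- tri[3L]
      ibc <- cut_vertex(b, c_); ica <- cut_vertex(c_, a)
      faces[[length(faces) + 1L]] <- c(a, b, ibc)
      faces[[length(faces) + 1L]] <- c(a, ibc, ica)
      capedges[[length(capedges) + 1L]] <- c(ibc, ica)
    }
  }
  if (cap && length(capedges)) {
    E <- do.call(rbind, capedges)
    loops <- chain_loops(E)
    bs <- plane_basis(n)
    for (lp in loops) {
      if (lp[1L] == lp[length(lp)]) lp <- lp[-length(lp)]
      if (length(lp) < 3L) next
      p2 <- cbind(verts[lp, , drop = FALSE] %*% bs$ex,
                  verts[lp, , drop = FALSE] %*% bs$ey)
      tris <- earclip(p2)
      ## earclip returns CCW triangles in the right-handed (ex, ey, n)
      ## basis; the cap must face away from the kept side (-n), so flip
      for (r in seq_len(nrow(tris)))
        faces[[length(faces) + 1L]] <- lp[tris[r, c(1L, 3L, 2L)]]
    }
  }
  out <- trimesh(verts, do.call(rbind, faces))
  drop_unused_vertices(out)
}

## compact a mesh to its referenced vertices
drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(map[mesh$faces], ncol = 3L))
}

#' Apply a sequence of resection cuts
#'
#' Cuts the mesh with each plane in the given (surgical) order and logs
#' the volume removed by each cut.
#'
#' @param mesh a watertight [trimesh()].
#' @param planes list of [cutting_plane()] objects.
#' @return list with `mesh` (the resected [trimesh()]) and `removed`
#'   (named numeric, mm^3 per cut).
#' @export
apply_resection <- function(mesh, planes) {
  removed <- numeric(length(planes))
  labs <- vapply(seq_along(planes), function(i) {
    lb <- planes[[i]]$label
    if (is.null(lb)) paste0("cut", i) else lb
  }, character(1))
  cur <- mesh
  for (i in seq_along(planes)) {
    v0 <- mesh_volume(cur)
    cur <- cut_mesh(cur, planes[[i]])
    removed[i] <- v0 - mesh_volume(cur)
  }
  names(removed) <- labs
  list(mesh = cur, removed = removed)
}

#' Planar cross-section contours of a mesh
#'
#' Intersects the mesh with a plane and returns the closed contour(s)
#' expressed in the plane's 2D frame; the largest-area contour is flagged
#' as primary.
#'
#' @param mesh a [trimesh()].
#' @param plane a [motion_plane()] (origin, normal, in-plane axes).
#' @return list of class `mesh_section`: `contours` (list of closed k x 2
#'   polylines, first point repeated last), `areas` (mm^2, absolute) and
#'   `primary` (index of the largest contour).
#' @export
sagittal_profile <- function(mesh, plane) {
  stopifnot(inherits(mesh, "trimesh"))
  v <- mesh$vertices
  sd <- as.numeric(sweep(v, 2L, plane$origin) %*% plane$normal)
  segs <- list(); keys <- list()
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  for (k in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[k, ]
    s <- sd[tri]
    pos <- s > 0
    if (all(pos) || all(!pos)) next
    ## the two crossing edges, oriented consistently with the face
    pts <- list(); kk <- character(0)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      i <- tri[e[1L]]; j <- tri[e[2L]]
      if ((sd[i] > 0) == (sd[j] > 0)) next
      t <- sd[i] / (sd[i] - sd[j])
      pts[[length(pts) + 1L]] <- v[i, ] + t * (v[j, ] - v[i, ])
      kk <- c(kk, ekey(i, j))
    }
    if (length(pts) == 2L) {
      segs[[length(segs) + 1L]] <- rbind(pts[[1L]], pts[[2L]])
      keys[[length(keys) + 1L]] <- kk
    }
  }
  if (!length(segs))
    stop("the plane does not intersect the mesh (empty section)")
  ## chain segments into loops via shared edge keys
  K <- do.call(rbind, keys)
  loops2d <- list(); areas <- numeric(0)
  used <- rep(FALSE, length(segs))
  to2d <- function(p) c(sum((p - plane$origin) * plane$in_plane_x),
                        sum((p - plane$origin) * plane$in_plane_y))
  adj <- split(seq_len(length(segs)), K[, 1])
  adj2 <- split(seq_len(length(segs)), K[, 2])
  find_next <- function(key, self) {
    cand <- c(adj[[key]], adj2[[key]])
    cand <- cand[!used[cand] & cand != self]
    if (length(cand)) cand[1L] else NA_integer_
  }
  for (s0 in seq_len(length(segs))) {
    if (used[s0]) next
    used[s0] <- TRUE
    pts <- list(segs[[s0]][1L, ], segs[[s0]][2L, ])
    key <- K[s0, 2L]
    cur <- s0
    repeat {
      nx <- find_next(key, cur)
      if (is.na(nx)) break
      used[nx] <- TRUE
      if (K[nx, 1L] == key) { pts[[length(pts) + 1L]] <- segs[[nx]][2L, ]; key <- K[nx, 2L] }
      else { pts[[length(pts) + 1L]] <- segs[[nx]][1L, ]; key <- K[nx, 1L] }
      cur <- nx
    }
    P <- do.call(rbind, lapply(pts, to2d))
    ## drop the duplicated closing point if present, then close explicitly
    if (nrow(P) > 2L && sqrt(sum((P[1L, ] - P[nrow(P), ])^2)) < 1e-9)
      P <- P[-nrow(P), , drop = FALSE]
    if (nrow(P) < 3L) next
    a2 <- sum(P[, 1] * P[c(2:nrow(P), 1L), 2] -
                P[c(2:nrow(P), 1L), 1] * P[, 2]) / 2
    loops2d[[length(loops2d) + 1L]] <- rbind(P, P[1L, ])
    areas <- c(areas, abs(a2))
  }
  if (!length(loops2d))
    stop("the plane only touches the mesh (degenerate section)")
  structure(list(contours = loops2d, areas = areas,
                 primary = which.max(areas)),
            class = "mesh_section")
}

## -------------------------------------------------------------------------
## ASCII STL I/O

#' Read an ASCII STL file
#' @param path STL file path.
#' @return a [trimesh()] (vertices deduplicated exactly).
#' @export
read_stl <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("not a valid ASCII STL file: ", path)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(z)
    as.numeric(z[2:4])))
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  trimesh(xyz[uk, , drop = FALSE], matrix(vid, ncol = 3L, byrow = TRUE))
}

#' Write an ASCII STL file
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, name = "kneefourbar") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c_ <- v[f[k, 3], ]
    nrm <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
             (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
             (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                 sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                 sprintf("      vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}
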