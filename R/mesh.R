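#' Triangulated surface mesh
#'
#' A closed triangulated boundary in world mm coordinates: the final
#' segmentation, the phantom ground truth and the training contours are all
#' carried in this form.
#'
#' @param vertices an n x 3 matrix of vertex positions (mm).
#' @param faces an m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || !all(is.finite(vertices)))
    se_stop("se_invalid_argument", "vertices must be a finite n x 3 matrix")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    se_stop("se_invalid_argument", "face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, volume %.1f mm^3%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; positive for outward
#' face orientation.
#' @param mesh a [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Is the mesh watertight?
#'
#' Every edge must be shared by exactly two faces with opposite
#' orientation.
#' @param mesh a [surface_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices) + 1
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- sort(pmin(e[, 1], e[, 2]) * nv + pmax(e[, 1], e[, 2]))
  n <- length(key)
  if (n %% 2 != 0) return(FALSE)
  odd <- seq(1, n, by = 2)
  # sorted keys must come in exact pairs
  if (!all(key[odd] == key[odd + 1])) return(FALSE)
  if (anyDuplicated(key[odd])) return(FALSE)
  !anyDuplicated(e[, 1] * nv + e[, 2])
}

# flip faces if the signed volume is negative so normals point outward
orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# loft a watertight tube through an ordered stack of rings (equal point
# counts, consistent angular parameterisation); ends are closed with caps
# subdivided into concentric rings (about cap_spacing mm apart) so the mesh
# has no long thin triangles, plus an apex fan
loft_mesh <- function(rings, cap_spacing = 2) {
  k <- length(rings)
  if (k < 2) se_stop("se_invalid_argument", "need at least 2 rings to loft")
  n <- nrow(rings[[1]])
  cap_rings <- function(ring) {
    ctr <- colMeans(ring)
    rad <- max(sqrt(rowSums(sweep(ring, 2, ctr)^2)))
    nk <- max(1L, ceiling(rad / cap_spacing))
    if (nk == 1L) return(list())
    ss <- seq_len(nk - 1L) / nk            # scale factors, small -> large
    lapply(ss, function(s) sweep(sweep(ring, 2, ctr) * s, 2, ctr, `+`))
  }
  allrings <- c(cap_rings(rings[[1]]), rings, rev(cap_rings(rings[[k]])))
  m <- length(allrings)
  verts <- do.call(rbind, allrings)
  idx <- function(i, j) (i - 1L) * n + ((j - 1L) %% n) + 1L
  side <- vector("list", m - 1L)
  js <- seq_len(n)
  for (i in seq_len(m - 1L)) {
    a <- idx(i, js); b <- idx(i, js + 1L)
    cc <- idx(i + 1L, js + 1L); d <- idx(i + 1L, js)
    side[[i]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  c1 <- nrow(verts) + 1L
  c2 <- nrow(verts) + 2L
  verts <- rbind(verts, colMeans(rings[[1]]), colMeans(rings[[k]]))
  cap1 <- cbind(c1, idx(1L, js + 1L), idx(1L, js))
  cap2 <- cbind(c2, idx(m, js), idx(m, js + 1L))
  orient_outward(surface_mesh(verts, rbind(do.call(rbind, side), cap1, cap2)))
}

#' 3-D convex hull
#'
#' Incremental convex hull of a 3-D point set. Returned faces are oriented
#' outward.
#'
#' @param pts an n x 3 matrix, n >= 4, not all coplanar.
#' @return A [surface_mesh()] of the hull.
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) se_stop("se_invalid_argument", "convex hull needs >= 4 points")
  scale <- max(apply(pts, 2, function(cc) diff(range(cc))))
  eps <- 1e-10 * max(scale, 1)
  # initial simplex: extreme pair, farthest from line, farthest from plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  d12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossn <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
                  rel[, 3] * d12[1] - rel[, 1] * d12[3],
                  rel[, 1] * d12[2] - rel[, 2] * d12[1])
  i3 <- which.max(rowSums(crossn^2))
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  if (vnorm(nrm) < eps) se_stop("se_invalid_argument", "degenerate (collinear) point set")
  h <- as.vector(rel %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < eps) se_stop("se_invalid_argument", "degenerate (coplanar) point set")
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  # preallocated face store (grown by doubling): triangle indices, outward
  # normals, plane offsets, live flag
  cap <- 256L
  tri <- matrix(0L, cap, 3)
  nrm2 <- matrix(0, cap, 3)
  off <- numeric(cap)
  nlen <- numeric(cap)
  live <- logical(cap)
  nf <- 0L
  add_face <- function(a, b, cc) {
    nn <- cross3(pts[b, ] - pts[a, ], pts[cc, ] - pts[a, ])
    l <- vnorm(nn)
    if (l < eps^2) return(invisible(NULL))
    if (sum(nn * (interior - pts[a, ])) > 0) {
      tmp <- b; b <- cc; cc <- tmp
      nn <- -nn
    }
    if (nf == nrow(tri)) {
      grow <- nrow(tri)
      tri <<- rbind(tri, matrix(0L, grow, 3))
      nrm2 <<- rbind(nrm2, matrix(0, grow, 3))
      off <<- c(off, numeric(grow))
      nlen <<- c(nlen, numeric(grow))
      live <<- c(live, logical(grow))
    }
    nf <<- nf + 1L
    tri[nf, ] <<- c(a, b, cc)
    nrm2[nf, ] <<- nn
    off[nf] <<- sum(nn * pts[a, ])
    nlen[nf] <<- l
    live[nf] <<- TRUE
    invisible(NULL)
  }
  add_face(i1, i2, i3); add_face(i1, i2, i4)
  add_face(i1, i3, i4); add_face(i2, i3, i4)
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    q <- pts[p, ]
    act <- which(live[seq_len(nf)])
    vis <- act[(nrm2[act, , drop = FALSE] %*% q - off[act]) >
                 eps * pmax(1, nlen[act])]
    if (length(vis) == 0) next
    vf <- tri[vis, , drop = FALSE]
    live[vis] <- FALSE
    edges <- rbind(vf[, 1:2], vf[, 2:3], vf[, c(3, 1)])
    # horizon = directed edges whose reverse is not among the visible faces
    ekey <- edges[, 1] * (n + 1) + edges[, 2]
    rkey <- edges[, 2] * (n + 1) + edges[, 1]
    horizon <- edges[!(rkey %in% ekey), , drop = FALSE]
    for (e in seq_len(nrow(horizon))) add_face(horizon[e, 1], horizon[e, 2], p)
  }
  keep <- which(live[seq_len(nf)])
  used <- sort(unique(as.vector(tri[keep, ])))
  remap <- integer(n); remap[used] <- seq_along(used)
  faces_out <- matrix(remap[tri[keep, ]], ncol = 3)
  orient_outward(surface_mesh(pts[used, , drop = FALSE], faces_out))
}

# exit parameter t of rays origin + t*dir (t > 0) through the convex hull,
# treating the hull as an intersection of halfspaces; ray origins must be
# inside the hull
hull_ray_exit <- function(hull, origins, dirs) {
  v <- hull$vertices; f <- hull$faces
  a <- v[f[, 1], , drop = FALSE]
  nrm <- cbind((v[f[, 2], 2] - a[, 2]) * (v[f[, 3], 3] - a[, 3]) -
                 (v[f[, 2], 3] - a[, 3]) * (v[f[, 3], 2] - a[, 2]),
               (v[f[, 2], 3] - a[, 3]) * (v[f[, 3], 1] - a[, 1]) -
                 (v[f[, 2], 1] - a[, 1]) * (v[f[, 3], 3] - a[, 3]),
               (v[f[, 2], 1] - a[, 1]) * (v[f[, 3], 2] - a[, 2]) -
                 (v[f[, 2], 2] - a[, 2]) * (v[f[, 3], 1] - a[, 1]))
  off <- rowSums(nrm * a)
  num <- off - tcrossprod(nrm, origins)   # nf x np
  den <- tcrossprod(nrm, dirs)
  tt <- num / den
  tt[den <= 1e-12] <- Inf
  apply(tt, 2, function(col) min(col[col > 0], Inf))
}

#' Intersect a mesh with a plane
#'
#' Exact triangle-plane intersection with segment chaining into closed
#' polygons.
#'
#' @param mesh a [surface_mesh()].
#' @param point,normal the plane (3-D mm point and normal).
#' @return A list of closed 3-D polygons (k x 3 matrices), possibly empty.
#' @export
mesh_section <- function(mesh, point, normal) {
  normal <- unitize(normal)
  v <- mesh$vertices; f <- mesh$faces
  d <- as.vector(sweep(v, 2, point) %*% normal)
  segs <- list()
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    dd <- d[tri]
    pos <- dd > 0
    if (all(pos) || all(!pos)) next
    # the two edges crossing the plane
    pts <- matrix(NA_real_, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dd[e[1]]; d2 <- dd[e[2]]
      if ((d1 > 0) != (d2 > 0)) {
        t <- d1 / (d1 - d2)
        pts <- rbind(pts, v[tri[e[1]], ] + t * (v[tri[e[2]], ] - v[tri[e[1]], ]))
      }
    }
    if (nrow(pts) == 2) segs[[length(segs) + 1L]] <- pts
  }
  if (length(segs) == 0) return(list())
  chain_segments(segs)
}

# chain a set of 3-D segments into closed polylines by endpoint matching
chain_segments <- function(segs, tol = 1e-6) {
  ends <- do.call(rbind, lapply(segs, function(s) rbind(s[1, ], s[2, ])))
  key <- apply(round(ends / tol), 1, paste, collapse = ",")
  n <- length(segs)
  used <- rep(FALSE, n)
  # map endpoint key -> segment indices
  lookup <- split(seq_len(2 * n), key)
  polys <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    used[s0] <- TRUE
    poly <- segs[[s0]]
    repeat {
      lastp <- poly[nrow(poly), ]
      k <- paste(round(lastp / tol), collapse = ",")
      cand <- lookup[[k]]
      nxt <- NULL
      for (ci in cand) {
        si <- ((ci - 1L) %/% 2L) + 1L
        if (used[si]) next
        endi <- ((ci - 1L) %% 2L) + 1L
        nxt <- list(si = si, other = segs[[si]][3 - endi, ])
        break
      }
      if (is.null(nxt)) break
      used[nxt$si] <- TRUE
      poly <- rbind(poly, nxt$other)
    }
    # closed if last point meets first
    if (nrow(poly) >= 3 &&
        vnorm(poly[1, ] - poly[nrow(poly), ]) < 10 * tol) {
      polys[[length(polys) + 1L]] <- poly[-nrow(poly), , drop = FALSE]
    } else if (nrow(poly) >= 3) {
      polys[[length(polys) + 1L]] <- poly
    }
  }
  polys
}

#' Sample points densely over a mesh surface
#'
#' Deterministic barycentric-lattice sampling of every triangle at
#' approximately the requested spacing (used for surface-distance
#' computations).
#'
#' @param mesh a [surface_mesh()].
#' @param spacing target sample spacing in mm.
#' @return An n x 3 matrix of surface points (includes all vertices).
#' @export
sample_mesh_points <- function(mesh, spacing = 0.5) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- sqrt(rowSums((b - a)^2))
  e2 <- sqrt(rowSums((cc - b)^2))
  e3 <- sqrt(rowSums((a - cc)^2))
  k <- pmax(1L, ceiling(pmax(e1, e2, e3) / spacing))
  E1 <- b - a
  E2 <- cc - a
  pts <- list(v)  # all vertices once
  for (kk in sort(unique(k))) {
    if (kk == 1L) next
    rows <- which(k == kk)
    # interior + edge lattice points (i, j >= 0, i + j <= kk), excluding the
    # three corners which are already present as vertices
    ij <- expand.grid(i = 0:kk, j = 0:kk)
    ij <- ij[ij$i + ij$j <= kk, ]
    corners <- (ij$i == 0 & ij$j == 0) | (ij$i == kk & ij$j == 0) |
      (ij$i == 0 & ij$j == kk)
    ij <- ij[!corners, ]
    w1 <- ij$i / kk; w2 <- ij$j / kk
    nr <- length(rows); L <- nrow(ij)
    ri <- rep(rows, times = L)
    wi1 <- rep(w1, each = nr)
    wi2 <- rep(w2, each = nr)
    pts[[length(pts) + 1L]] <-
      a[ri, , drop = FALSE] + wi1 * E1[ri, , drop = FALSE] +
      wi2 * E2[ri, , drop = FALSE]
  }
  do.call(rbind, pts)
}

#' Read or write a surface mesh
#'
#' ASCII PLY and STL formats.
#'
#' @param path file path (`.ply` or `.stl`).
#' @param mesh a [surface_mesh()] (for writing).
#' @return `read_mesh` returns a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) return(read_stl(path))
  lines <- readLines(path)
  if (lines[1] != "ply") se_stop("se_io_error", "not a PLY file: %s", path)
  end_hdr <- which(lines == "end_header")[1]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", lines, value = TRUE)[1]))
  vdat <- do.call(rbind, lapply(strsplit(lines[(end_hdr + 1):(end_hdr + nv)], "\\s+"),
                                function(x) as.numeric(x[1:3])))
  fdat <- do.call(rbind, lapply(strsplit(lines[(end_hdr + nv + 1):(end_hdr + nv + nf)], "\\s+"),
                                function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(vdat, fdat)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (grepl("\\.stl$", path, ignore.case = TRUE)) return(write_stl(mesh, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 9), 1, paste,
                   collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

read_stl <- function(path) {
  lines <- trimws(readLines(path))
  vl <- grep("^vertex ", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  # deduplicate vertices
  key <- apply(round(v, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  remap <- match(key, key[uniq])
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  surface_mesh(v[uniq, , drop = FALSE], faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid stackedellipse", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- cross3(b - a, cc - a)
    nl <- vnorm(n); if (nl > 0) n <- n / nl
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("    vertex %g %g %g", cc[1], cc[2], cc[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid stackedellipse", con)
  invisible(path)
}
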