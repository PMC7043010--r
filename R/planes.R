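#' Manual mid-sagittal initialisation
#'
#' The single manual input of the segmentation: a closed contour drawn on a
#' (near) mid-sagittal slice plus four ordered landmark points that split the
#' contour into the top surface (fundus-top to cervix-top), the cervix end
#' cap, the bottom surface (cervix-bottom to fundus-bottom) and the fundus
#' end cap. Anchor pairs used to build the semi-axial slicing planes connect
#' the top and bottom surfaces at matching fundus-to-cervix stations.
#'
#' @param point a point on the sagittal plane (3-D mm).
#' @param normal the plane normal, along the anatomical LR direction.
#' @param axis1,axis2 in-plane orthonormal basis (3-D unit vectors); contour
#'   coordinates are expressed in this basis.
#' @param contour an n x 2 matrix of in-plane (mm) points forming a simple
#'   closed polyline (last point connects to first).
#' @param landmarks 4 distinct indices into `contour`, in cyclic order:
#'   fundus-top, cervix-top, cervix-bottom, fundus-bottom.
#' @param check_simple verify that the contour does not self-intersect
#'   (O(n^2); disable for very dense contours you already trust).
#' @return An object of class `sagittal_init`.
#' @export
sagittal_init <- function(point, normal, axis1, axis2, contour, landmarks,
                          check_simple = TRUE) {
  contour <- as.matrix(contour)
  if (ncol(contour) != 2 || nrow(contour) < 8)
    se_stop("se_invalid_argument", "contour must be an n x 2 matrix with n >= 8")
  if (!all(is.finite(contour)))
    se_stop("se_invalid_argument", "contour contains non-finite points")
  normal <- unitize(normal); axis1 <- unitize(axis1); axis2 <- unitize(axis2)
  if (abs(sum(axis1 * axis2)) > 1e-9 || abs(sum(axis1 * normal)) > 1e-9 ||
      abs(sum(axis2 * normal)) > 1e-9)
    se_stop("se_invalid_argument", "plane basis must be orthonormal")
  landmarks <- as.integer(landmarks)
  if (length(landmarks) != 4 || anyDuplicated(landmarks) ||
      any(landmarks < 1) || any(landmarks > nrow(contour)))
    se_stop("se_invalid_argument", "landmarks must be 4 distinct contour indices")
  # cyclic order: walking from landmark 1 the other three appear in order
  rel <- (landmarks - landmarks[1]) %% nrow(contour)
  if (is.unsorted(rel[-1]) || any(rel[-1] == 0))
    se_stop("se_invalid_argument", "landmarks must be in cyclic order along the contour")
  if (check_simple && !polygon_is_simple(contour))
    se_stop("se_invalid_argument", "contour must be simple (non-self-intersecting)")
  structure(list(point = as.numeric(point), normal = normal,
                 axis1 = axis1, axis2 = axis2,
                 contour = contour, landmarks = landmarks),
            class = "sagittal_init")
}

#' @export
print.sagittal_init <- function(x, ...) {
  cat(sprintf("<sagittal_init> %d contour points, landmarks at %s\n",
              nrow(x$contour), paste(x$landmarks, collapse = ", ")))
  invisible(x)
}

#' Read or write a sagittal initialisation as JSON
#' @param path file path.
#' @param init a [sagittal_init()] (for writing).
#' @return `read_init` returns a [sagittal_init()].
#' @export
read_init <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sagittal_init(point = j$plane$point, normal = j$plane$normal,
                axis1 = j$plane$axis1, axis2 = j$plane$axis2,
                contour = matrix(unlist(j$contour), ncol = 2, byrow = FALSE),
                landmarks = j$landmarks)
}

#' @rdname read_init
#' @export
write_init <- function(init, path) {
  stopifnot(inherits(init, "sagittal_init"))
  jsonlite::write_json(list(
    plane = list(point = init$point, normal = init$normal,
                 axis1 = init$axis1, axis2 = init$axis2),
    contour = unname(init$contour),
    landmarks = init$landmarks), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# extract the open polyline of the contour from landmark index i1 to i2
# (walking forward cyclically, endpoints included)
contour_segment <- function(contour, i1, i2) {
  n <- nrow(contour)
  idx <- if (i1 <= i2) i1:i2 else c(i1:n, 1:i2)
  contour[idx, , drop = FALSE]
}

#' Build top-bottom anchor pairs from a sagittal initialisation
#'
#' Places arclength-uniform anchor points on the top surface segment
#' (fundus-top landmark to cervix-top landmark) and matching points on the
#' bottom surface segment (matched by arclength fraction measured from the
#' fundus end), yielding one anchor pair per future semi-axial slicing
#' plane. The number of pairs is `ceiling(top arclength / slice_spacing)`,
#' with a minimum of one.
#'
#' @param init a [sagittal_init()].
#' @param slice_spacing target spacing between slicing planes in mm.
#' @return A list of anchor pairs, each `list(top = c(x, y), bottom = c(x, y))`
#'   in sagittal in-plane mm coordinates, ordered fundus to cervix.
#' @export
build_anchor_pairs <- function(init, slice_spacing) {
  stopifnot(inherits(init, "sagittal_init"))
  if (!is.finite(slice_spacing) || slice_spacing <= 0)
    se_stop("se_invalid_argument", "slice_spacing must be positive")
  lm <- init$landmarks
  top <- contour_segment(init$contour, lm[1], lm[2])      # fundus-top -> cervix-top
  bottom <- contour_segment(init$contour, lm[3], lm[4])   # cervix-bottom -> fundus-bottom
  len_top <- sum(sqrt(rowSums((top[-1, , drop = FALSE] -
                                 top[-nrow(top), , drop = FALSE])^2)))
  n <- max(1L, ceiling(len_top / slice_spacing))
  frac <- (seq_len(n) - 0.5) / n                          # fundus -> cervix stations
  len_bot <- sum(sqrt(rowSums((bottom[-1, , drop = FALSE] -
                                 bottom[-nrow(bottom), , drop = FALSE])^2)))
  top_pts <- interp_polyline(top, frac * len_top)
  bot_pts <- interp_polyline(bottom, (1 - frac) * len_bot) # measured from fundus end
  lapply(seq_len(n), function(i)
    list(top = as.numeric(top_pts[i, ]), bottom = as.numeric(bot_pts[i, ])))
}

#' Semi-axial slicing plane
#'
#' A plane through an anchor-pair midpoint spanned by the anchor line
#' (`u_axis`, pointing top to bottom) and the anatomical LR direction
#' (`v_axis`). In-plane coordinates are `(x, y)` with x the LR (`v_axis`)
#' component and y the `u_axis` component, so that the ellipse semi-axis `a`
#' lies along x.
#'
#' @param origin plane origin in world mm (anchor midpoint).
#' @param u_axis unit vector along the anchor top-to-bottom line.
#' @param v_axis unit vector along anatomical LR.
#' @param grid optional sampling grid: `list(extent = c(Ex, Ey), spacing = s)`
#'   in mm, centred on the origin.
#' @param seed_b,centroid minor-axis seed (half the anchor distance, mm) and
#'   world centroid recorded for the downstream first-guess ellipse.
#' @return An object of class `slicing_plane` with unit `normal = u x v`.
#' @export
slicing_plane <- function(origin, u_axis, v_axis, grid = NULL,
                          seed_b = NA_real_, centroid = origin) {
  u_axis <- unitize(u_axis); v_axis <- unitize(v_axis)
  if (abs(sum(u_axis * v_axis)) > 1e-9)
    se_stop("se_invalid_argument", "u_axis and v_axis must be orthogonal")
  if (!is.null(grid)) {
    if (is.null(grid$extent) || is.null(grid$spacing) || any(grid$spacing <= 0))
      se_stop("se_invalid_argument", "grid must have positive extent and spacing")
  }
  structure(list(origin = as.numeric(origin), u_axis = u_axis, v_axis = v_axis,
                 normal = unitize(cross3(u_axis, v_axis)),
                 grid = grid, seed_b = seed_b, centroid = as.numeric(centroid)),
            class = "slicing_plane")
}

#' Slicing planes from anchor pairs
#'
#' Each anchor pair defines one semi-axial plane: origin at the pair
#' midpoint, `u_axis` along the top-to-bottom anchor line, `v_axis` along
#' LR (the sagittal-plane normal). The minor-axis seed `b` (half the anchor
#' distance) and the world centroid are recorded on the plane for the
#' first-guess ellipse. Zero-length anchor lines are rejected; the returned
#' list carries a `"warnings"` attribute describing any rejections.
#'
#' @param pairs anchor pairs from [build_anchor_pairs()].
#' @param init the [sagittal_init()] whose in-plane frame the pairs live in.
#' @param grid optional sampling grid spec applied to every plane (see
#'   [slicing_plane()]).
#' @return A list of [slicing_plane()] objects (attribute `"warnings"`:
#'   character vector of rejection records).
#' @export
planes_from_pairs <- function(pairs, init, grid = NULL) {
  stopifnot(inherits(init, "sagittal_init"))
  if (length(pairs) == 0) se_stop("se_invalid_argument", "no anchor pairs supplied")
  to_world <- function(p) init$point + p[1] * init$axis1 + p[2] * init$axis2
  planes <- list()
  warns <- character()
  for (i in seq_along(pairs)) {
    top <- to_world(pairs[[i]]$top)
    bottom <- to_world(pairs[[i]]$bottom)
    d <- bottom - top
    if (vnorm(d) < 1e-9) {
      warns <- c(warns, sprintf("pair %d rejected: zero-length anchor line", i))
      next
    }
    planes[[length(planes) + 1L]] <-
      slicing_plane(origin = (top + bottom) / 2, u_axis = d / vnorm(d),
                    v_axis = init$normal, grid = grid,
                    seed_b = vnorm(d) / 2, centroid = (top + bottom) / 2)
  }
  attr(planes, "warnings") <- warns
  planes
}

#' Map in-plane points to world coordinates (and back)
#'
#' `plane_to_world(plane, pts)` maps in-plane `(x, y)` mm coordinates to 3-D
#' world points `origin + x * v_axis + y * u_axis` (x along LR). The round
#' trip through `world_to_plane` is the identity for points on the plane.
#'
#' @param plane a [slicing_plane()].
#' @param pts an n x 2 matrix of in-plane points (or n x 3 world points for
#'   `world_to_plane`).
#' @return An n x 3 matrix of world points (or n x 2 in-plane coordinates).
#' @export
plane_to_world <- function(plane, pts) {
  pts <- matrix(pts, ncol = 2)
  sweep(pts[, 1, drop = FALSE] %*% rbind(plane$v_axis) +
          pts[, 2, drop = FALSE] %*% rbind(plane$u_axis),
        2, plane$origin, `+`)
}

#' @rdname plane_to_world
#' @export
world_to_plane <- function(plane, pts) {
  pts <- matrix(pts, ncol = 3)
  rel <- sweep(pts, 2, plane$origin, `-`)
  cbind(x = as.vector(rel %*% plane$v_axis),
        y = as.vector(rel %*% plane$u_axis))
}

# grid node coordinates of a plane's sampling grid (centred on the origin)
plane_grid_axes <- function(plane) {
  g <- plane$grid
  if (is.null(g)) se_stop("se_invalid_argument", "plane carries no sampling grid")
  s <- g$spacing
  nx <- max(2L, floor(g$extent[1] / s) + 1L)
  ny <- max(2L, floor(g$extent[2] / s) + 1L)
  list(x = (seq_len(nx) - (nx + 1) / 2) * s,
       y = (seq_len(ny) - (ny + 1) / 2) * s,
       spacing = s)
}

#' Resample a volume onto a slicing plane
#'
#' Trilinear interpolation of the volume at every node of the plane's
#' sampling grid. Nodes falling outside the volume take the sentinel
#' `fill` value and are flagged in the validity mask, so a field of view
#' that does not fully cover the organ degrades gracefully rather than
#' failing.
#'
#' @param vol a [volume3d()].
#' @param plane a [slicing_plane()] carrying a sampling grid.
#' @param fill sentinel value for out-of-volume nodes.
#' @return A `planar_image`: list with `pixels` (nx x ny matrix), `valid`
#'   (logical mask), `x`, `y` (node coordinates, mm), `spacing` and `plane`.
#' @export
resample_plane <- function(vol, plane, fill = 0) {
  stopifnot(inherits(vol, "volume3d"), inherits(plane, "slicing_plane"))
  ax <- plane_grid_axes(plane)
  nodes <- as.matrix(expand.grid(x = ax$x, y = ax$y, KEEP.OUT.ATTRS = FALSE))
  world <- plane_to_world(plane, nodes)
  res <- .trilinear_sample_cpp(vol$intensities, dim(vol$intensities),
                               vol$spacing, vol$origin, world, fill)
  if (!any(res$inside)) se_stop("se_empty_overlap", "plane grid does not overlap the volume")
  structure(list(pixels = matrix(res$values, nrow = length(ax$x)),
                 valid = matrix(res$inside, nrow = length(ax$x)),
                 x = ax$x, y = ax$y, spacing = ax$spacing, plane = plane),
            class = "planar_image")
}
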