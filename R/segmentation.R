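#' Edge-map parameters
#'
#' The three user-tuneable parameters of the boundary-detection step, with
#' the defaults used for all segmentations: `sigma` (standard deviation of
#' the Gaussian smoothing kernel, in pixels of the resampled semi-axial
#' grid), `k` (edge-preservation exponent of the distance weighting) and
#' `r` (total length of the radial search window used for peak detection,
#' in pixels; rounded to the nearest odd integer >= 3).
#'
#' @param sigma Gaussian smoothing std in pixels (> 0).
#' @param k distance-weighting exponent (> 0); smaller k penalises
#'   boundaries far from the initialisation more heavily.
#' @param r radial search length in pixels.
#' @param fill sentinel intensity for out-of-volume pixels.
#' @return An object of class `edge_map_params`.
#' @export
edge_map_params <- function(sigma = 4, k = 1, r = 29, fill = 0) {
  if (sigma <= 0) se_stop("se_invalid_argument", "sigma must be positive")
  if (k <= 0) se_stop("se_invalid_argument", "k must be positive")
  r <- 2 * round((r - 1) / 2) + 1  # nearest odd
  if (r < 3) se_stop("se_invalid_argument", "r must round to an odd integer >= 3")
  structure(list(sigma = sigma, k = k, r = as.integer(r), fill = fill),
            class = "edge_map_params")
}

#' First-guess elliptical contours
#'
#' Segmentation step 1: every anchor pair contributes one semi-axial plane
#' with a first-guess ellipse on it. The minor semi-axis is half the anchor
#' distance, the centroid is the anchor midpoint, the major (LR) semi-axis
#' comes from the population axis model, and the rotation is zero. Slices
#' whose predicted major axis is non-positive are skipped with a warning
#' record.
#'
#' @param init a [sagittal_init()].
#' @param model an [axis_model()].
#' @param slice_spacing spacing between slicing planes in mm.
#' @param pixel_spacing sampling spacing of the semi-axial grids in mm.
#' @param params an [edge_map_params()]; together with `pixel_spacing` it
#'   sets the margin of each slice's sampling grid.
#' @return A list of `list(plane, ellipse)` ordered fundus to cervix, with
#'   attribute `"warnings"`.
#' @export
initialize_ellipses <- function(init, model, slice_spacing = 1.16,
                                pixel_spacing = 0.58,
                                params = edge_map_params()) {
  stopifnot(inherits(init, "sagittal_init"), inherits(model, "axis_model"))
  pairs <- build_anchor_pairs(init, slice_spacing)
  planes <- planes_from_pairs(pairs, init)
  warns <- attr(planes, "warnings")
  margin <- (floor(params$r / 2) + ceiling(3 * params$sigma) + 2) * pixel_spacing
  out <- list()
  for (i in seq_along(planes)) {
    pl <- planes[[i]]
    b <- pl$seed_b
    a <- tryCatch(predict_major_axis(model, b), se_error = function(e) NA_real_)
    if (!is.finite(a) || a <= 0) {
      warns <- c(warns, sprintf("slice %d skipped: non-positive predicted major axis", i))
      next
    }
    pl$grid <- list(extent = c(2 * a + 2 * margin, 2 * b + 2 * margin),
                    spacing = pixel_spacing)
    out[[length(out) + 1L]] <- list(plane = pl,
                                    ellipse = ellipse2d(0, 0, a = a, b = b, phi = 0))
  }
  attr(out, "warnings") <- warns
  out
}

#' Signed distance map of a closed contour
#'
#' For every node of a planar grid, the minimum Euclidean distance (mm) to
#' the nearest contour point, negative inside the contour and positive
#' outside.
#'
#' @param contour an n x 2 matrix of in-plane mm points (closed by
#'   convention, n >= 3).
#' @param grid a `planar_image` or a list with node coordinate vectors `x`
#'   and `y` (mm).
#' @return A `length(x)` x `length(y)` matrix of signed distances.
#' @export
signed_distance <- function(contour, grid) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) se_stop("se_invalid_argument", "contour needs >= 3 points")
  if (any(!is.finite(contour))) se_stop("se_invalid_argument", "contour must be finite")
  nodes <- as.matrix(expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE))
  d <- .min_dist2d_cpp(nodes, contour)
  inside <- .point_in_polygon_cpp(nodes, contour)
  matrix(ifelse(inside, -d, d), nrow = length(grid$x))
}

#' Direction field of a signed distance map
#'
#' The unit gradient ("phase") of the signed distance map: at every pixel a
#' unit vector pointing away from the contour interior, which models the
#' expected intensity-gradient direction of a hypoechoic (dark) target on a
#' brighter background. Pixels with a (numerically) vanishing gradient,
#' e.g. on the medial axis, get the zero vector.
#'
#' @param sdm signed distance matrix from [signed_distance()].
#' @return A list with matrices `Jx`, `Jy` (unit components).
#' @export
direction_field <- function(sdm) {
  if (any(!is.finite(sdm))) se_stop("se_invalid_argument", "distance map must be finite")
  g <- central_diff(sdm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ok <- mag >= 1e-6
  Jx <- ifelse(ok, g$gx / pmax(mag, 1e-300), 0)
  Jy <- ifelse(ok, g$gy / pmax(mag, 1e-300), 0)
  list(Jx = Jx, Jy = Jy)
}

#' Distance weighting of edge strength
#'
#' The weight \eqn{R = (1 - (d/d_{max})^k) \exp(-(d/d_{max})^k)} applied to
#' the directional edge map, penalising boundaries far from the
#' initialisation contour; `d_max` is the largest distance on the slice's
#' grid, so R is 1 on the contour and 0 at the farthest pixel.
#'
#' @param d matrix of non-negative distances (mm).
#' @param k positive exponent controlling how fast the weight falls off.
#' @return A matrix of weights in `[0, 1]`.
#' @export
distance_weight <- function(d, k = 1) {
  if (any(d < 0)) se_stop("se_invalid_argument", "distances must be non-negative")
  dmax <- max(d)
  if (dmax <= 0) se_stop("se_degenerate_grid", "all distances are zero")
  u <- (d / dmax)^k
  (1 - u) * exp(-u)
}

#' Directional edge map of a semi-axial image
#'
#' Combines image gradients with two priors: the target is darker than its
#' surroundings (gradient direction must agree with the outward direction
#' field of the initialisation ellipse), and the true boundary is near the
#' initialisation contour (distance weighting). The image is smoothed with
#' a Gaussian of std `sigma` pixels; the squared positive part of the
#' agreement (gradient dotted with the direction field) is weighted by the
#' distance term. Out-of-volume pixels contribute zero.
#'
#' @param img a `planar_image` from [resample_plane()].
#' @param init the initialisation [ellipse2d()] in the image's in-plane mm
#'   coordinates.
#' @param params an [edge_map_params()].
#' @param n_contour number of points used to discretise the initialisation
#'   contour for the distance map.
#' @return An object of class `directional_edge_map`: list with `values`
#'   (non-negative matrix aligned with `img`), plus the inputs used.
#' @export
directional_edge_map <- function(img, init, params = edge_map_params(),
                                 n_contour = 360L) {
  stopifnot(inherits(img, "planar_image"), inherits(init, "ellipse2d"),
            inherits(params, "edge_map_params"))
  # normalised convolution: out-of-volume pixels are excluded from the
  # smoothing support rather than blurred in as the sentinel value, so the
  # edge of the field of view does not manufacture boundaries
  px <- img$pixels
  px[!img$valid] <- 0
  w <- gauss_blur2(img$valid + 0, params$sigma)
  V1 <- gauss_blur2(px, params$sigma) / pmax(w, 1e-12)
  V1[w < 1e-6] <- params$fill
  g <- central_diff(V1)  # pixel units; only relative magnitude matters
  contour <- ellipse_points(init, n_contour)
  # as the initialisation contour is an exact ellipse, the inside test can
  # use the implicit equation rather than the generic polygon test
  nodes <- as.matrix(expand.grid(x = img$x, y = img$y, KEEP.OUT.ATTRS = FALSE))
  d <- .min_dist2d_cpp(nodes, contour)
  inside <- ellipse_residual(init, nodes) < 0
  sdm <- matrix(ifelse(inside, -d, d), nrow = length(img$x))
  J <- direction_field(sdm)
  agreement <- g$gx * J$Jx + g$gy * J$Jy
  R <- distance_weight(abs(sdm), params$k)
  # noise floor: gradients at the level of convolution round-off (~1e-10 of
  # the intensity scale) are not edges
  eps <- 1e-10 * max(abs(V1))
  f <- ifelse(agreement > eps, agreement^2 * R, 0)
  f[!img$valid] <- 0
  structure(list(values = f, image = img, init = init, params = params,
                 sdm = sdm), class = "directional_edge_map")
}

# indices of strict local maxima with positive value; a plateau of equal
# values higher than both neighbouring runs peaks at its centre sample
find_peaks <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer()
  for (i in 2:(k - 1)) {
    if (r$values[i] <= 0) next
    if (r$values[i - 1] < r$values[i] && r$values[i + 1] < r$values[i])
      peaks <- c(peaks, as.integer(floor((starts[i] + ends[i]) / 2)))
  }
  peaks
}

#' Deform an initialisation contour towards edge-map peaks
#'
#' Segmentation step 2 (contour deformation): for each of `n_points`
#' initialisation points (uniform in parametric angle), a 1-D profile of
#' the directional edge map is sampled along the ray from the ellipse
#' centroid through the point, over a window of total length `r` pixels
#' centred on the point. The point moves to the local maximum nearest to
#' its initial position (ties broken towards the interior); if the window
#' contains no peak the point stays in place.
#'
#' @param edge a [directional_edge_map()].
#' @param init the initialisation [ellipse2d()].
#' @param r radial search length in pixels (defaults to the edge map's
#'   parameter).
#' @param n_points number of contour points (>= 16).
#' @return An `n_points` x 2 matrix: the provisional contour (mm).
#' @export
deform_contour <- function(edge, init, r = NULL, n_points = 180L) {
  stopifnot(inherits(edge, "directional_edge_map"), inherits(init, "ellipse2d"))
  if (n_points < 16) se_stop("se_invalid_argument", "n_points must be >= 16")
  r <- r %||% edge$params$r
  hw <- floor(r / 2)
  img <- edge$image
  pts <- ellipse_points(init, n_points)
  out <- .deform_cpp(edge$values, img$x[1], img$y[1], img$spacing,
                     pts, init$c1, init$c2, as.integer(hw))
  colnames(out) <- c("x", "y")
  out
}

#' Regularise a provisional contour by ellipse fitting
#'
#' Segmentation step 3 (boundary regularisation): a direct least-squares
#' ellipse is fitted to the provisional contour to smooth the boundary and
#' damp outliers. If the fit fails (degenerate points) and a fallback
#' ellipse is supplied, the fallback is returned with attribute
#' `"fallback"` set; without a fallback the fit error propagates.
#'
#' @param prov an n x 2 matrix of provisional contour points (n >= 5).
#' @param fallback optional [ellipse2d()] (typically the first-guess
#'   ellipse for the slice).
#' @return An [ellipse2d()].
#' @export
regularize_contour <- function(prov, fallback = NULL) {
  res <- tryCatch(fit_ellipse_direct(prov), se_fit_error = function(e) e)
  if (inherits(res, "ellipse2d")) return(res)
  if (is.null(fallback)) stop(res)
  attr(fallback, "fallback") <- TRUE
  fallback
}

#' Assemble final 2-D ellipses into a 3-D surface
#'
#' Segmentation step 4: each final ellipse is sampled and mapped into world
#' coordinates, and a single closed triangulated boundary is built around
#' all surface points. `shrink_factor` controls concavity: 1 gives the
#' fully conforming surface through the stacked ellipses, 0 gives the
#' convex hull of all surface points, intermediate values interpolate
#' radially between the two.
#'
#' @param slices list of `list(plane, ellipse)` (>= 3, ordered along the
#'   organ).
#' @param n_points points sampled per ellipse.
#' @param shrink_factor concavity parameter in `[0, 1]`.
#' @return A watertight [surface_mesh()].
#' @export
assemble_3d <- function(slices, n_points = 180L, shrink_factor = 1) {
  if (length(slices) < 3) se_stop("se_invalid_argument", "need at least 3 slices")
  if (shrink_factor < 0 || shrink_factor > 1)
    se_stop("se_invalid_argument", "shrink_factor must be in [0, 1]")
  rings <- lapply(slices, function(s)
    plane_to_world(s$plane, ring_points(s$ellipse, n_points)))
  if (shrink_factor < 1) {
    allpts <- do.call(rbind, rings)
    hull <- convex_hull_3d(allpts)
    rings <- lapply(rings, function(rg) {
      ctr <- colMeans(rg)
      rel <- sweep(rg, 2, ctr)
      tv <- sqrt(rowSums(rel^2))
      dirs <- rel / tv
      texit <- hull_ray_exit(hull, matrix(ctr, nrow(rg), 3, byrow = TRUE), dirs)
      texit <- pmax(texit, tv)  # guard against numerical undershoot
      tnew <- shrink_factor * tv + (1 - shrink_factor) * texit
      sweep(dirs * tnew, 2, ctr, `+`)
    })
  }
  loft_mesh(rings)
}

#' Segment a volume with the stacked-ellipse pipeline
#'
#' Runs the full segmentation phase: first-guess ellipses from the manual
#' sagittal initialisation and the axis model, then per slice resampling,
#' directional edge map, radial peak deformation and elliptical
#' regularisation, and finally 3-D assembly. Per-slice failures (empty
#' overlap, degenerate fits, implausible fits) degrade to the first-guess
#' ellipse for that slice rather than aborting, so a 3-D contour is always
#' produced. The pipeline is deterministic given its inputs.
#'
#' @param vol a [volume3d()].
#' @param init a [sagittal_init()].
#' @param model an [axis_model()]; default the built-in population model.
#' @param params an [edge_map_params()].
#' @param shrink_factor concavity of the 3-D assembly (see [assemble_3d()]).
#' @param slice_spacing spacing of slicing planes in mm; default twice the
#'   smallest voxel spacing.
#' @param n_points contour points per slice.
#' @param pixel_spacing semi-axial grid spacing in mm; default the smallest
#'   voxel spacing.
#' @return An object of class `segmentation_result`: list with `mesh`
#'   (watertight [surface_mesh()]), `slices` (per-slice list of
#'   `plane`, `first_guess`, `provisional`, `final`) and `warnings`.
#' @export
segment_volume <- function(vol, init, model = default_axis_model(),
                           params = edge_map_params(), shrink_factor = 1,
                           slice_spacing = NULL, n_points = 180L,
                           pixel_spacing = NULL) {
  stopifnot(inherits(vol, "volume3d"), inherits(init, "sagittal_init"))
  pixel_spacing <- pixel_spacing %||% min(vol$spacing)
  slice_spacing <- slice_spacing %||% (2 * min(vol$spacing))
  ies <- initialize_ellipses(init, model, slice_spacing, pixel_spacing, params)
  warns <- attr(ies, "warnings")
  slices <- vector("list", length(ies))
  for (i in seq_along(ies)) {
    pl <- ies[[i]]$plane
    e0 <- ies[[i]]$ellipse
    rec <- list(plane = pl, first_guess = e0,
                provisional = ellipse_points(e0, n_points), final = e0)
    res <- tryCatch({
      img <- resample_plane(vol, pl, fill = params$fill)
      edge <- directional_edge_map(img, e0, params)
      prov <- deform_contour(edge, e0, params$r, n_points)
      fin <- regularize_contour(prov, fallback = e0)
      if (isTRUE(attr(fin, "fallback"))) {
        warns <<- c(warns, sprintf("slice %d: degenerate fit, first-guess kept", i))
      } else if (!plausible_fit(fin, e0)) {
        warns <<- c(warns, sprintf("slice %d: implausible fit, first-guess kept", i))
        fin <- e0
      }
      list(provisional = prov, final = fin)
    }, se_error = function(e) {
      warns <<- c(warns, sprintf("slice %d: %s; first-guess kept", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      rec$provisional <- res$provisional
      rec$final <- res$final
    }
    slices[[i]] <- rec
  }
  mesh <- assemble_3d(lapply(slices, function(s)
    list(plane = s$plane, ellipse = s$final)), n_points, shrink_factor)
  structure(list(mesh = mesh, slices = slices, warnings = warns),
            class = "segmentation_result")
}

# ellipse boundary points with a parameterization-independent start: the
# first point is the one nearest the +x (LR) direction from the centroid, so
# stacked rings stay angularly aligned regardless of the fitted rotation
# (phi is only defined modulo pi and may swap the parametric axes)
ring_points <- function(e, n) {
  p <- ellipse_points(e, n)
  ang <- atan2(p[, 2] - e$c2, p[, 1] - e$c1)
  j0 <- which.min(abs(ang))
  if (j0 > 1) p <- p[c(j0:n, 1:(j0 - 1)), , drop = FALSE]
  p
}

# loose sanity check that a regularised ellipse stays commensurate with its
# first guess (wild fits arise only from degenerate provisional contours)
plausible_fit <- function(fit, guess) {
  lim <- max(guess$a, guess$b)
  fit$a <= 3 * guess$a && fit$b <= 3 * guess$b &&
    fit$a >= guess$a / 3 && fit$b >= guess$b / 3 &&
    vnorm(c(fit$c1 - guess$c1, fit$c2 - guess$c2)) <= lim
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d slices, mesh volume %.1f cm^3, %d warning(s)\n",
              length(x$slices), mesh_volume(x$mesh) / 1000, length(x$warnings)))
  invisible(x)
}
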