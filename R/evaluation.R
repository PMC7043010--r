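#' Binary voxel mask
#'
#' @param bits logical 3-D array (TRUE inside the segmentation).
#' @param spacing voxel spacing in mm (length 3).
#' @param origin centre of voxel (1,1,1) in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(bits, spacing, origin) {
  if (!is.logical(bits) || length(dim(bits)) != 3)
    se_stop("se_invalid_argument", "bits must be a logical 3-D array")
  structure(list(bits = bits, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "binary_mask")
}

# common evaluation grid: bounding box of the meshes padded by `pad` mm
eval_grid <- function(meshes, spacing, pad = 5) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  lo <- apply(allv, 2, min) - pad
  hi <- apply(allv, 2, max) + pad
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, spacing = spacing, n = n)
}

#' Voxelize a watertight mesh
#'
#' Marks every grid voxel whose centre lies inside (or on) the mesh, by
#' parity counting of surface crossings along grid-aligned rays.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param grid a list with `origin` (mm), `spacing` (mm, length 3) and `n`
#'   (voxel counts), e.g. from the evaluation-grid helper; or a
#'   [volume3d()] whose grid should be reused.
#' @return A [binary_mask()]. A mesh entirely outside the grid yields an
#'   all-`FALSE` mask with a warning.
#' @export
voxelize <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is_watertight(mesh))
    se_stop("se_invalid_argument", "mesh must be watertight for voxelization")
  if (inherits(grid, "volume3d"))
    grid <- list(origin = grid$origin, spacing = grid$spacing,
                 n = dim(grid$intensities))
  bits <- .voxelize_cpp(mesh$vertices, mesh$faces - 1L, as.integer(grid$n),
                        grid$spacing, grid$origin)
  bits <- array(bits, dim = grid$n)
  if (!any(bits)) warning("mesh does not cover any voxel centre of the grid")
  binary_mask(bits, grid$spacing, grid$origin)
}

#' Dice similarity coefficient
#'
#' Volumetric overlap `2|A n B| / (|A| + |B|)`: 1 for perfect overlap, 0
#' for disjoint masks. Two empty masks compare as 1 by convention (logged
#' as a message).
#'
#' @param A,B [binary_mask()] objects on the same grid.
#' @return The DSC in `[0, 1]`.
#' @export
dice <- function(A, B) {
  stopifnot(inherits(A, "binary_mask"), inherits(B, "binary_mask"))
  if (!identical(dim(A$bits), dim(B$bits)) ||
      max(abs(A$spacing - B$spacing)) > 1e-9 ||
      max(abs(A$origin - B$origin)) > 1e-9)
    se_stop("se_grid_mismatch", "masks must share an identical grid")
  na <- sum(A$bits); nb <- sum(B$bits)
  if (na + nb == 0) {
    message("both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(A$bits & B$bits) / (na + nb)
}

#' Mean absolute surface-to-surface distance (MSSD)
#'
#' The mean distance from every surface point of A to its nearest
#' neighbour on the surface of B. The directed measure is asymmetric; the
#' default symmetric mode returns the mean of the two directed values.
#' Mesh inputs are densified to approximately `spacing` mm surface samples
#' before the nearest-neighbour search.
#'
#' @param A,B [surface_mesh()] objects or n x 3 point matrices.
#' @param symmetric if `TRUE` (default) average the two directed values.
#' @param spacing surface sampling density in mm for mesh inputs.
#' @return The MSSD in mm.
#' @export
mssd <- function(A, B, symmetric = TRUE, spacing = 0.5) {
  as_pts <- function(x) {
    if (inherits(x, "surface_mesh")) sample_mesh_points(x, spacing) else as.matrix(x)
  }
  pa <- as_pts(A); pb <- as_pts(B)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    se_stop("se_invalid_argument", "surfaces must be non-empty")
  dab <- mean(.nn_dist3d_cpp(pa, pb))
  if (!symmetric) return(dab)
  dba <- mean(.nn_dist3d_cpp(pb, pa))
  (dab + dba) / 2
}

#' Median and IQR summaries per group and overall
#'
#' Linear-interpolation (type-7) quantiles of per-case metric values,
#' grouped (e.g. per patient) and pooled, mirroring the usual
#' median-with-IQR reporting of segmentation studies.
#'
#' @param values numeric vector of per-case values.
#' @param group optional grouping factor (same length).
#' @return A data.frame with columns `group`, `n`, `median`, `iqr`; the
#'   pooled row is labelled `"overall"`.
#' @export
cohort_summary <- function(values, group = NULL) {
  if (length(values) < 1) se_stop("se_invalid_argument", "need at least one value")
  one <- function(v, g) data.frame(
    group = g, n = length(v),
    median = unname(median(v)),
    iqr = unname(quantile(v, 0.75, type = 7) - quantile(v, 0.25, type = 7)))
  out <- list()
  if (!is.null(group)) {
    stopifnot(length(group) == length(values))
    sp <- split(values, group)
    out <- lapply(names(sp), function(g) one(sp[[g]], g))
  }
  rows <- do.call(rbind, c(out, list(one(values, "overall"))))
  rownames(rows) <- NULL
  rows
}

#' Compare two segmentations
#'
#' Convenience wrapper computing the DSC (on a common voxel grid) and the
#' symmetric MSSD between two watertight meshes.
#'
#' @param pred,truth [surface_mesh()] objects.
#' @param spacing evaluation voxel size in mm (default 0.58).
#' @param pad grid padding around the joint bounding box in mm.
#' @param mssd_spacing surface sampling density for the MSSD in mm.
#' @return A list with `dsc` and `mssd_mm`.
#' @export
evaluate_meshes <- function(pred, truth, spacing = 0.58, pad = 5,
                            mssd_spacing = 0.5) {
  g <- eval_grid(list(pred, truth), spacing, pad)
  list(dsc = dice(voxelize(pred, g), voxelize(truth, g)),
       mssd_mm = mssd(pred, truth, symmetric = TRUE, spacing = mssd_spacing))
}
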