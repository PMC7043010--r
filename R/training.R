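#' Population axis model a = m * b + K
#'
#' Linear relationship between the major (LR) and minor semi-axes of
#' elliptical uterine cross-sections, fitted across all slices of all
#' training patients and used during segmentation to predict the LR
#' semi-axis from the manually initialised minor semi-axis.
#'
#' @param m dimensionless slope.
#' @param K intercept in mm.
#' @param r_squared coefficient of determination of the fit (may be `NA`
#'   for externally supplied models).
#' @param n_points number of (a, b) samples behind the fit.
#' @return An object of class `axis_model`.
#' @export
axis_model <- function(m, K, r_squared = NA_real_, n_points = NA_integer_) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    se_stop("se_invalid_argument", "r_squared must be in [0, 1]")
  structure(list(m = m, K = K, r_squared = r_squared,
                 n_points = as.integer(n_points)), class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  cat(sprintf("<axis_model> a = %.3f * b + %.3f mm (R^2 = %s, n = %s)\n",
              x$m, x$K,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.2f", x$r_squared)),
              ifelse(is.na(x$n_points), "NA", x$n_points)))
  invisible(x)
}

#' Built-in default axis model
#'
#' The shipped population model (slope 1.01, intercept 11.3 mm,
#' R-squared 0.60) so segmentation is usable without retraining.
#' @return An [axis_model()].
#' @export
default_axis_model <- function() {
  axis_model(m = 1.01, K = 11.3, r_squared = 0.60, n_points = NA_integer_)
}

#' Read or write an axis model as JSON
#' @param path file path.
#' @param model an [axis_model()] (for writing).
#' @return `read_axis_model` returns an [axis_model()].
#' @export
read_axis_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  axis_model(m = j$m, K = j$K, r_squared = j$r_squared %||% NA_real_,
             n_points = j$n_points %||% NA_integer_)
}

#' @rdname read_axis_model
#' @export
write_axis_model <- function(model, path) {
  stopifnot(inherits(model, "axis_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Parameterise a 3-D contour surface as stacked ellipses
#'
#' Training-phase step: the gold-standard 3-D contour is cut by the
#' semi-axial slicing planes derived from the sagittal initialisation, and
#' a direct least-squares ellipse is fitted to each cross-section polygon.
#' Slices whose cross-section has fewer than 5 points, misses the surface
#' entirely, or fails the ellipse fit are dropped with a warning record.
#'
#' @param surface a closed [surface_mesh()].
#' @param init a [sagittal_init()] placed near the surface's mid-sagittal
#'   section.
#' @param slice_spacing spacing between slicing planes in mm.
#' @return A list with elements `slices` (list of `list(plane, ellipse)`),
#'   `samples` (data.frame with columns `slice`, `a_mm`, `b_mm`) and
#'   `warnings` (character).
#' @export
parameterize_contour <- function(surface, init, slice_spacing = 1.16) {
  stopifnot(inherits(surface, "surface_mesh"), inherits(init, "sagittal_init"))
  pairs <- build_anchor_pairs(init, slice_spacing)
  planes <- planes_from_pairs(pairs, init)
  warns <- attr(planes, "warnings")
  slices <- list()
  rows <- list()
  for (i in seq_along(planes)) {
    pl <- planes[[i]]
    polys <- mesh_section(surface, pl$origin, pl$normal)
    if (length(polys) == 0) {
      warns <- c(warns, sprintf("slice %d: plane misses the surface", i))
      next
    }
    # take the section component whose centroid is nearest the anchor midpoint
    d <- vapply(polys, function(p) vnorm(colMeans(p) - pl$origin), numeric(1))
    poly <- polys[[which.min(d)]]
    if (nrow(poly) < 5) {
      warns <- c(warns, sprintf("slice %d: cross-section has < 5 points", i))
      next
    }
    pts2 <- world_to_plane(pl, poly)
    e <- tryCatch(fit_ellipse_direct(pts2), se_fit_error = function(err) NULL)
    if (is.null(e)) {
      warns <- c(warns, sprintf("slice %d: ellipse fit failed", i))
      next
    }
    slices[[length(slices) + 1L]] <- list(plane = pl, ellipse = e)
    rows[[length(rows) + 1L]] <- data.frame(slice = i, a_mm = e$a, b_mm = e$b)
  }
  samples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(), a_mm = numeric(), b_mm = numeric())
  list(slices = slices, samples = samples, warnings = warns)
}

#' Fit the population axis model
#'
#' Unweighted ordinary least squares of the major semi-axis `a` on the
#' minor semi-axis `b`, pooling every slice from every patient. Per-patient
#' fits (diagnostic only) are returned when a `patient` column is present.
#'
#' @param samples a data.frame with numeric columns `a_mm` and `b_mm`
#'   (optionally `patient`).
#' @return An [axis_model()]; when `patient` is present, attribute
#'   `"per_patient"` holds a data.frame of per-patient slopes/intercepts.
#' @export
fit_axis_model <- function(samples) {
  if (!all(c("a_mm", "b_mm") %in% names(samples)))
    se_stop("se_invalid_argument", "samples must have columns a_mm and b_mm")
  a <- samples$a_mm; b <- samples$b_mm
  if (length(a) < 2) se_stop("se_degenerate_fit", "need at least 2 samples")
  if (any(a <= 0) || any(b <= 0))
    se_stop("se_invalid_argument", "axis samples must be positive")
  if (max(b) - min(b) < .Machine$double.eps * max(1, max(abs(b))))
    se_stop("se_degenerate_fit", "all minor axes identical; slope is unidentifiable")
  fit <- lm(a ~ b)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  model <- axis_model(m = unname(coef(fit)[2]), K = unname(coef(fit)[1]),
                      r_squared = max(0, min(1, r2)), n_points = length(a))
  if ("patient" %in% names(samples)) {
    per <- do.call(rbind, lapply(split(samples, samples$patient), function(s) {
      if (nrow(s) < 2 || max(s$b_mm) - min(s$b_mm) < 1e-12) return(NULL)
      cf <- coef(lm(a_mm ~ b_mm, data = s))
      data.frame(patient = s$patient[1], m = unname(cf[2]), K = unname(cf[1]),
                 n = nrow(s))
    }))
    attr(model, "per_patient") <- per
  }
  model
}

#' Predict the major (LR) semi-axis from the minor semi-axis
#'
#' @param model an [axis_model()].
#' @param b minor semi-axis in mm (positive).
#' @return Predicted major semi-axis `m * b + K` in mm. A non-positive
#'   prediction (no valid ellipse) signals an error of class
#'   `se_invalid_model`.
#' @export
predict_major_axis <- function(model, b) {
  stopifnot(inherits(model, "axis_model"))
  if (any(b <= 0)) se_stop("se_invalid_argument", "b must be positive")
  a <- model$m * b + model$K
  if (any(a <= 0))
    se_stop("se_invalid_model", "axis model predicts a non-positive major axis")
  a
}

#' Train an axis model from contour meshes and initialisations
#'
#' Convenience wrapper over [parameterize_contour()] and [fit_axis_model()]
#' for a set of training patients.
#'
#' @param meshes list of [surface_mesh()] (or paths readable by
#'   [read_mesh()]).
#' @param inits list of [sagittal_init()] (or paths readable by
#'   [read_init()]).
#' @param slice_spacing spacing between slicing planes in mm.
#' @param patients optional patient identifiers (default sequential).
#' @return A list with `model` (an [axis_model()]), `samples` (pooled
#'   data.frame with `patient`, `slice`, `a_mm`, `b_mm`) and `warnings`.
#' @export
train_axis_model <- function(meshes, inits, slice_spacing = 1.16,
                             patients = NULL) {
  if (length(meshes) != length(inits))
    se_stop("se_invalid_argument", "meshes and inits must have equal length")
  patients <- patients %||% sprintf("P%02d", seq_along(meshes))
  all_samples <- list()
  warns <- character()
  for (i in seq_along(meshes)) {
    mesh <- if (is.character(meshes[[i]])) read_mesh(meshes[[i]]) else meshes[[i]]
    init <- if (is.character(inits[[i]])) read_init(inits[[i]]) else inits[[i]]
    p <- parameterize_contour(mesh, init, slice_spacing)
    if (nrow(p$samples)) {
      p$samples$patient <- patients[i]
      all_samples[[length(all_samples) + 1L]] <- p$samples
    }
    if (length(p$warnings))
      warns <- c(warns, paste0(patients[i], ": ", p$warnings))
  }
  samples <- do.call(rbind, all_samples)
  list(model = fit_axis_model(samples), samples = samples, warnings = warns)
}
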