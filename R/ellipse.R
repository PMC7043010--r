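#' Planar ellipse
#'
#' The shape prior of the stacked-ellipse segmentation: an axis-aligned or
#' rotated ellipse \eqn{(x-c_1)^2/a^2 + (y-c_2)^2/b^2 = 1} (rotated by
#' \eqn{\phi} about its centroid). On semi-axial slicing planes the in-plane
#' x axis is the anatomical left-right (LR) direction, so `a` is the LR
#' semi-axis and `b` the semi-axis along the anchor (top-bottom) line.
#'
#' @param c1,c2 centroid coordinates in mm.
#' @param a,b semi-axis lengths in mm, both positive.
#' @param phi in-plane rotation in radians; first-guess ellipses use 0.
#' @return An object of class `ellipse2d`.
#' @export
ellipse2d <- function(c1, c2, a, b, phi = 0) {
  stopifnot(is.finite(c1), is.finite(c2), is.finite(a), is.finite(b), is.finite(phi))
  if (a <= 0 || b <= 0) se_stop("se_invalid_argument", "ellipse semi-axes must be positive")
  structure(list(c1 = c1, c2 = c2, a = a, b = b, phi = phi), class = "ellipse2d")
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf("<ellipse2d> centre (%.3f, %.3f) mm, a = %.3f, b = %.3f mm, phi = %.4f rad\n",
              x$c1, x$c2, x$a, x$b, x$phi))
  invisible(x)
}

#' Sample points on an ellipse
#'
#' Returns `n` points uniformly spaced in parametric angle. Every returned
#' point satisfies the (rotated) implicit ellipse equation to machine
#' precision.
#'
#' @param e an [ellipse2d()].
#' @param n number of points, at least 5 (4 allowed only for internal use is
#'   not supported; the closed contour convention requires >= 5).
#' @param theta0 starting parametric angle in radians.
#' @return An `n` x 2 matrix of (x, y) points in mm; closed by convention
#'   (the last point connects back to the first).
#' @export
ellipse_points <- function(e, n = 180L, theta0 = 0) {
  stopifnot(inherits(e, "ellipse2d"))
  if (n < 5) se_stop("se_invalid_argument", "at least 5 points are required (got %d)", n)
  th <- theta0 + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cx <- cos(th) * e$a
  cy <- sin(th) * e$b
  cp <- cos(e$phi); sp <- sin(e$phi)
  cbind(x = e$c1 + cx * cp - cy * sp,
        y = e$c2 + cx * sp + cy * cp)
}

# implicit-equation residual of points against an ellipse (0 on the ellipse)
ellipse_residual <- function(e, pts) {
  dx <- pts[, 1] - e$c1
  dy <- pts[, 2] - e$c2
  cp <- cos(e$phi); sp <- sin(e$phi)
  u <- dx * cp + dy * sp
  v <- -dx * sp + dy * cp
  (u / e$a)^2 + (v / e$b)^2 - 1
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct least-squares fitting of an ellipse to 2-D
#' points (Halir-Flusser formulation of the Fitzgibbon ellipse-specific
#' fit): the conic minimising the algebraic distance subject to the
#' ellipse constraint \eqn{4AC - B^2 = 1}. The conic is converted to
#' geometric parameters with `a >= b` and `phi` reduced modulo pi.
#' The fit is non-iterative, which is what makes it cheap enough to run on
#' every semi-axial slice.
#'
#' @param points an n x 2 matrix of (x, y) points, n >= 5, not collinear.
#' @return An [ellipse2d()]. Degenerate input (fewer than 5 points,
#'   collinear points, or a non-elliptical conic) signals an error of class
#'   `se_fit_error`, distinct from ordinary success.
#' @export
fit_ellipse_direct <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5) se_stop("se_fit_error", "ellipse fit needs >= 5 points (got %d)", nrow(points))
  if (!all(is.finite(points))) se_stop("se_fit_error", "ellipse fit input contains non-finite points")
  # centre and scale for conditioning
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  sc <- max(abs(points[, 1] - mx), abs(points[, 2] - my))
  if (sc < .Machine$double.eps) se_stop("se_fit_error", "degenerate (coincident) points")
  x <- (points[, 1] - mx) / sc
  y <- (points[, 2] - my) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    se_stop("se_fit_error", "degenerate point configuration (singular scatter matrix)"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) se_stop("se_fit_error", "no ellipse solution (collinear or hyperbolic input)")
  a1 <- V[, ok[1]]
  conic <- c(a1, as.vector(Tm %*% a1))  # A B C D E F in scaled coords
  e <- conic_to_ellipse(conic)
  if (is.null(e)) se_stop("se_fit_error", "fitted conic is not an ellipse")
  # undo the normalisation
  ellipse2d(c1 = mx + sc * e$c1, c2 = my + sc * e$c2,
            a = sc * e$a, b = sc * e$b, phi = e$phi)
}

# convert conic coefficients (A,B,C,D,E,F), Ax^2+Bxy+Cy^2+Dx+Ey+F=0, to
# geometric ellipse parameters with a >= b, phi in [0, pi); NULL if not an
# ellipse
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- 4 * A * C - B^2
  if (den <= 0) return(NULL)
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  F0 <- F + (D * x0 + E * y0) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values  # decreasing
  if (any(-F0 / lam <= 0)) return(NULL)
  axes <- sqrt(-F0 / lam)
  # eigen() returns decreasing eigenvalues; the smaller eigenvalue's
  # eigenvector is the major-axis direction
  major_idx <- which.max(axes)
  vec <- eg$vectors[, major_idx]
  phi <- atan2(vec[2], vec[1]) %% pi
  list(c1 = x0, c2 = y0, a = max(axes), b = min(axes), phi = phi)
}
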