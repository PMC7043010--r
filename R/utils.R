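# Internal helpers shared across modules. All physical quantities are in mm,
# world frame is right-handed with axes (LR, AP, SI) unless stated otherwise.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

se_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "se_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# cumulative arclength of an open polyline given as an n x 2 (or n x 3) matrix
cum_arclength <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# point at arclength s along an open polyline (linear interpolation)
interp_polyline <- function(pts, s) {
  cs <- cum_arclength(pts)
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(i, nrow(pts) - 1)
  t <- (s - cs[i]) / pmax(cs[i + 1] - cs[i], .Machine$double.eps)
  pts[i, , drop = FALSE] * (1 - t) + pts[i + 1, , drop = FALSE] * t
}

# does any pair of non-adjacent edges of the closed polygon intersect?
polygon_is_simple <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < tol) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > tol && t < 1 - tol && u > tol && u < 1 - tol
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    for (j in js) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

# central differences of a matrix in pixel units; returns list(gx, gy) where
# gx differentiates along rows (first index) and gy along columns
central_diff <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  gx <- m; gy <- m
  gx[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / 2
  gx[1, ] <- m[2, ] - m[1, ]
  gx[nx, ] <- m[nx, ] - m[nx - 1, ]
  gy[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / 2
  gy[, 1] <- m[, 2] - m[, 1]
  gy[, ny] <- m[, ny] - m[, ny - 1]
  list(gx = gx, gy = gy)
}

# bilinear sampling of a matrix at fractional (0-based) pixel coordinates;
# out-of-range samples return `fill`
bilinear_sample <- function(m, fx, fy, fill = 0) {
  nx <- nrow(m); ny <- ncol(m)
  out <- rep(fill, length(fx))
  ok <- fx >= 0 & fy >= 0 & fx <= nx - 1 & fy <= ny - 1
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based
  v00 <- m[cbind(i0, j0)]; v10 <- m[cbind(i0 + 1, j0)]
  v01 <- m[cbind(i0, j0 + 1)]; v11 <- m[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
    v01 * (1 - tx) * ty + v11 * tx * ty
  out
}

# 1-D Gaussian kernel, truncated at 4 sigma and renormalised
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a 3-D array, sigma in voxels per axis.
# Edge handling: the truncated kernel is renormalised over the in-bounds
# support (equivalent to normalised convolution), so flat fields are preserved.
gauss_blur3 <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  blur_matrix <- function(n, s) {
    if (s <= 0) return(NULL)
    k <- gauss_kernel(s)
    r <- (length(k) - 1L) / 2L
    idx <- outer(seq_len(n), (-r):r, `+`)
    w <- matrix(rep(k, each = n), nrow = n)
    w[idx < 1 | idx > n] <- 0
    idx <- pmin(pmax(idx, 1L), n)
    B <- matrix(0, n, n)
    for (col in seq_len(ncol(idx))) {
      B[cbind(seq_len(n), idx[, col])] <- B[cbind(seq_len(n), idx[, col])] + w[, col]
    }
    B / rowSums(B)
  }
  B1 <- blur_matrix(d[1], sigma[1])
  B2 <- blur_matrix(d[2], sigma[2])
  B3 <- blur_matrix(d[3], sigma[3])
  x <- arr
  if (!is.null(B1)) {
    x <- array(B1 %*% matrix(x, d[1]), d)
  }
  if (!is.null(B2)) {
    x <- aperm(array(B2 %*% matrix(aperm(x, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
               c(2, 1, 3))
  }
  if (!is.null(B3)) {
    x <- aperm(array(B3 %*% matrix(aperm(x, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
               c(2, 3, 1))
  }
  x
}

# 2-D Gaussian smoothing with replicate boundary (EBImage convolution)
gauss_blur2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k1 <- gauss_kernel(sigma)
  kern <- outer(k1, k1)
  EBImage::filter2(m, kern, boundary = "replicate")
}
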