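# Independent oracles used to check the package's implementations.

# geometric-distance ellipse fit: Nelder-Mead over the 5 parameters
# minimising summed squared orthogonal distances (distances measured
# against a dense sampling of the candidate ellipse)
oracle_geometric_fit <- function(pts, start) {
  dist_to_ellipse <- function(par) {
    e <- ellipse2d(par[1], par[2], abs(par[3]), abs(par[4]), par[5])
    samp <- ellipse_points(e, 720)
    d2 <- outer(pts[, 1], samp[, 1], `-`)^2 + outer(pts[, 2], samp[, 2], `-`)^2
    sum(apply(d2, 1, min))
  }
  fit <- optim(start, dist_to_ellipse, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  ellipse2d(fit$par[1], fit$par[2], abs(fit$par[3]), abs(fit$par[4]), fit$par[5])
}

# closed-form simple linear regression (normal equations)
oracle_ols <- function(y, x) {
  sxx <- sum((x - mean(x))^2)
  m <- sum((x - mean(x)) * (y - mean(y))) / sxx
  K <- mean(y) - m * mean(x)
  ss_res <- sum((y - (m * x + K))^2)
  r2 <- 1 - ss_res / sum((y - mean(y))^2)
  list(m = m, K = K, r_squared = r2)
}

# O(n*m) brute-force directed mean nearest-neighbour distance
oracle_mssd_directed <- function(A, B) {
  mean(apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2)))))
}

# brute-force min distance from each query to a 2-D point set
oracle_min_dist2d <- function(query, pts) {
  apply(query, 1, function(p) sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)))
}

# sort-based median and IQR (type-7 interpolation re-derived by hand)
oracle_median_iqr <- function(v) {
  s <- sort(v)
  n <- length(s)
  qat <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(median = qat(0.5), iqr = qat(0.75) - qat(0.25))
}

# brute-force arclength parameterisation of an open polyline: point at
# fraction f of total length
oracle_point_at_fraction <- function(pts, f) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  s <- f * cs[length(cs)]
  i <- max(which(cs <= s + 1e-12)[1], findInterval(s, cs))
  i <- min(i, nrow(pts) - 1)
  t <- (s - cs[i]) / seg[i]
  pts[i, ] * (1 - t) + pts[i + 1, ] * t
}
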