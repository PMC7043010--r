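#' Synthetic uterus phantom specification
#'
#' Describes a speckled 3-D B-mode-like test volume containing a curved,
#' hypoechoic, tubular target with elliptical cross-sections and known
#' ground truth. The default geometry mimics an anteverted uterus: a
#' quadratic mid-sagittal centerline bending from the inferior cervix
#' towards an anteriorly tipped fundus, a minor-axis profile that is widest
#' in the uterine body and tapers towards the cervix, and major axes
#' generated from the default axis law with per-slice jitter. Intensities
#' make the target darker than the speckled background (`mu_in < mu_out`).
#'
#' @param centerline control points (3 x 2 matrix, mm) of a quadratic
#'   Bezier in the mid-sagittal (AP, SI) plane, ordered fundus to cervix.
#' @param b_profile function of arclength fraction `s` in `[0, 1]` (fundus
#'   to cervix) returning the minor semi-axis in mm.
#' @param axis_law list `(m, K, sigma_a)`: major axis `a = m*b + K` plus
#'   Gaussian jitter of std `sigma_a` mm.
#' @param intensity list `(mu_in, mu_out, sigma_psf)`: interior and
#'   exterior mean intensities (`mu_in < mu_out`) and the Gaussian
#'   point-spread blur in mm.
#' @param speckle list `(enabled, weight)`: multiplicative unit-mean
#'   Rayleigh speckle; `weight` in `[0, 1]` blends it with the noiseless
#'   field (1 = fully developed speckle).
#' @param shadow optional list `(apex, from_deg, to_deg, factor)` defining
#'   an attenuated angular sector in the sagittal plane, or `NULL`.
#' @param spacing voxel spacing of the rendered volume in mm (isotropic).
#' @param ring_spacing spacing of the ground-truth ellipse stack in mm.
#' @param n_ring_points points per ground-truth ring.
#' @param pad volume padding around the target in mm.
#' @param seed integer seed; all phantom randomness derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(centerline = rbind(c(30, 12), c(0, 2), c(-2, -34)),
                         b_profile = function(s) 8 + 8 * exp(-((s - 0.25) / 0.35)^2),
                         axis_law = list(m = 1.01, K = 11.3, sigma_a = 1.0),
                         intensity = list(mu_in = 45, mu_out = 90, sigma_psf = 1.2),
                         speckle = list(enabled = TRUE, weight = 1),
                         shadow = NULL,
                         spacing = 0.58, ring_spacing = 1.16,
                         n_ring_points = 180L, pad = 10, seed = 1L) {
  if (intensity$mu_in >= intensity$mu_out)
    se_stop("se_invalid_argument", "target must be hypoechoic (mu_in < mu_out)")
  if (intensity$sigma_psf <= 0 || spacing <= 0 || ring_spacing <= 0)
    se_stop("se_invalid_argument", "spacing, ring_spacing and sigma_psf must be positive")
  s <- seq(0, 1, length.out = 64)
  if (any(b_profile(s) <= 0))
    se_stop("se_invalid_argument", "b_profile must be positive on [0, 1]")
  structure(list(centerline = centerline, b_profile = b_profile,
                 axis_law = axis_law, intensity = intensity, speckle = speckle,
                 shadow = shadow, spacing = spacing, ring_spacing = ring_spacing,
                 n_ring_points = as.integer(n_ring_points), pad = pad,
                 seed = as.integer(seed)), class = "phantom_spec")
}

# evaluate the quadratic Bezier centerline and (unit) tangent at parameter t
bezier2 <- function(cp, t) {
  p <- outer((1 - t)^2, cp[1, ]) + outer(2 * t * (1 - t), cp[2, ]) +
    outer(t^2, cp[3, ])
  d <- outer(2 * (1 - t), cp[2, ] - cp[1, ]) + outer(2 * t, cp[3, ] - cp[2, ])
  list(p = p, d = d)
}

#' Ground-truth ellipse stack and mesh
#'
#' Builds the phantom's true boundary: ring stations every `ring_spacing`
#' mm along the centerline, each carrying an ellipse orthogonal to the
#' centerline tangent (and containing the LR direction) with minor
#' semi-axis from `b_profile` and major semi-axis from the axis law plus
#' seeded jitter. The mesh is the fully conforming loft through the rings.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `mesh` (watertight [surface_mesh()]), `slices`
#'   (list of `list(plane, ellipse)`) and `centers` (ring centres, world
#'   mm).
#' @export
make_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tt <- seq(0, 1, length.out = 512)
  bz <- bezier2(spec$centerline, tt)
  cs <- cum_arclength(bz$p)
  total <- cs[length(cs)]
  n <- max(3L, ceiling(total / spec$ring_spacing))
  s_st <- (seq_len(n) - 0.5) / n
  t_st <- approx(cs / total, tt, xout = s_st, rule = 2)$y
  st <- bezier2(spec$centerline, t_st)
  b <- spec$b_profile(s_st)
  a <- withr::with_seed(spec$seed, {
    spec$axis_law$m * b + spec$axis_law$K + rnorm(n, 0, spec$axis_law$sigma_a)
  })
  a <- pmax(a, 0.5 * b)  # jitter must never collapse the ellipse
  slices <- vector("list", n)
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tan2 <- unitize(st$d[i, ])            # sagittal tangent, fundus -> cervix
    up2 <- c(-tan2[2], tan2[1])           # rotate +90 deg: the "top" side
    # keep "top" pointing to the anterior-superior side consistently
    if (i == 1 && up2[2] < 0) up2 <- -up2
    if (i > 1) {
      up2_prev <- -slices[[i - 1]]$plane$u_axis[2:3]
      if (sum(up2 * up2_prev) < 0) up2 <- -up2
    }
    center <- c(0, st$p[i, 1], st$p[i, 2])
    u3 <- unitize(c(0, -up2[1], -up2[2])) # u_axis: top -> bottom
    plane <- slicing_plane(origin = center, u_axis = u3, v_axis = c(1, 0, 0),
                           seed_b = b[i], centroid = center)
    slices[[i]] <- list(plane = plane,
                        ellipse = ellipse2d(0, 0, a = a[i], b = b[i], phi = 0))
    centers[i, ] <- center
  }
  rings <- lapply(slices, function(s)
    plane_to_world(s$plane, ellipse_points(s$ellipse, spec$n_ring_points)))
  list(mesh = loft_mesh(rings), slices = slices, centers = centers)
}

#' Render a phantom volume
#'
#' Rasterises the truth mesh into a piecewise-constant intensity field
#' (`mu_in` inside, `mu_out` outside), blurs it with the Gaussian PSF,
#' multiplies by unit-mean Rayleigh speckle and applies the optional shadow
#' sector. Deterministic given the spec's seed.
#'
#' @param truth output of [make_truth()].
#' @param spec the [phantom_spec()].
#' @return A [volume3d()].
#' @export
render_volume <- function(truth, spec) {
  mesh <- truth$mesh
  lo <- apply(mesh$vertices, 2, min) - spec$pad
  hi <- apply(mesh$vertices, 2, max) + spec$pad
  sp <- rep(spec$spacing, 3)
  n <- as.integer(ceiling((hi - lo) / sp)) + 1L
  mask <- .voxelize_cpp(mesh$vertices, mesh$faces - 1L, n, sp, lo)
  img <- array(ifelse(mask, spec$intensity$mu_in, spec$intensity$mu_out), dim = n)
  img <- gauss_blur3(img, spec$intensity$sigma_psf / spec$spacing)
  if (isTRUE(spec$speckle$enabled) && spec$speckle$weight > 0) {
    w <- spec$speckle$weight
    ray <- withr::with_seed(spec$seed + 1L, {
      sqrt(2 / pi) * sqrt(-2 * log(pmax(runif(length(img)), 1e-300)))
    })
    img <- img * ((1 - w) + w * ray)
  }
  if (!is.null(spec$shadow)) {
    ax <- lapply(1:3, function(k) lo[k] + (seq_len(n[k]) - 1) * sp[k])
    yz <- expand.grid(y = ax[[2]], z = ax[[3]])
    ang <- atan2(yz$z - spec$shadow$apex[2], yz$y - spec$shadow$apex[1]) * 180 / pi
    hit <- ang >= spec$shadow$from_deg & ang <= spec$shadow$to_deg
    fac <- ifelse(hit, spec$shadow$factor, 1)
    img <- img * array(rep(fac, each = n[1]), dim = n)
  }
  volume3d(img, spacing = sp, origin = lo)
}

#' Simulated manual initialisation of a phantom
#'
#' Extracts the mid-sagittal cross-section of the truth as the manual
#' contour, places the four landmarks at the fundus-top, cervix-top,
#' cervix-bottom and fundus-bottom extremes, and optionally perturbs the
#' contour with a smooth random displacement of maximum amplitude `jitter`
#' mm (emulating observer variability).
#'
#' @param truth output of [make_truth()].
#' @param jitter maximum contour perturbation in mm (0 = exact section).
#' @param seed seed for the perturbation.
#' @return A [sagittal_init()].
#' @export
make_initialization <- function(truth, jitter = 0, seed = 1L) {
  slices <- truth$slices
  n <- length(slices)
  top <- t(vapply(slices, function(s)
    as.numeric(plane_to_world(s$plane, cbind(0, -s$ellipse$b))), numeric(3)))
  bottom <- t(vapply(slices, function(s)
    as.numeric(plane_to_world(s$plane, cbind(0, s$ellipse$b))), numeric(3)))
  # contour in sagittal (AP, SI) coordinates: top run fundus->cervix, then
  # bottom run cervix->fundus; closed by convention
  contour <- rbind(top[, 2:3], bottom[n:1, 2:3])
  landmarks <- c(1L, n, n + 1L, 2L * n)
  if (jitter > 0) {
    # smooth low-frequency radial perturbation, max amplitude = jitter
    m <- nrow(contour)
    t01 <- (seq_len(m) - 1) / m
    coefs <- withr::with_seed(seed, rnorm(6))
    delta <- coefs[1] * cos(2 * pi * t01) + coefs[2] * sin(2 * pi * t01) +
      coefs[3] * cos(4 * pi * t01) + coefs[4] * sin(4 * pi * t01) +
      coefs[5] * cos(6 * pi * t01) + coefs[6] * sin(6 * pi * t01)
    delta <- delta / max(abs(delta)) * jitter
    nxt <- contour[c(2:m, 1), ]
    prv <- contour[c(m, 1:(m - 1)), ]
    tang <- nxt - prv
    nrm <- cbind(tang[, 2], -tang[, 1])
    nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
    ctr <- colMeans(contour)
    outward <- rowSums(nrm * sweep(contour, 2, ctr)) > 0
    nrm[!outward, ] <- -nrm[!outward, ]
    contour <- contour + delta * nrm
  }
  sagittal_init(point = c(0, 0, 0), normal = c(1, 0, 0),
                axis1 = c(0, 1, 0), axis2 = c(0, 0, 1),
                contour = contour, landmarks = landmarks,
                check_simple = FALSE)
}

#' Generate a complete phantom case
#'
#' One call producing the rendered volume, ground-truth mesh and slices,
#' and the simulated manual initialisation.
#'
#' @param spec a [phantom_spec()].
#' @param jitter initialisation perturbation in mm.
#' @return A list with `volume`, `truth_mesh`, `truth_slices`, `init` and
#'   `seed`.
#' @export
phantom_case <- function(spec = phantom_spec(), jitter = 0) {
  truth <- make_truth(spec)
  vol <- render_volume(truth, spec)
  init <- make_initialization(truth, jitter = jitter, seed = spec$seed + 2L)
  list(volume = vol, truth_mesh = truth$mesh, truth_slices = truth$slices,
       init = init, seed = spec$seed)
}
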