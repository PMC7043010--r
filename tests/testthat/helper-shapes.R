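# Geometric fixtures built in code.

unitize_test <- function(v) v / sqrt(sum(v^2))

# rectangle initialisation: width x height mm, corner landmarks in the
# fundus-top, cervix-top, cervix-bottom, fundus-bottom convention, points
# per edge chosen dense enough for arclength interpolation
rect_init <- function(width = 40, height = 10, n_edge = 81) {
  top <- cbind(seq(0, width, length.out = n_edge), height)
  right <- cbind(width, seq(height, 0, length.out = n_edge))
  bottom <- cbind(seq(width, 0, length.out = n_edge), 0)
  left <- cbind(0, seq(0, height, length.out = n_edge))
  contour <- rbind(top[-n_edge, ], right[-n_edge, ], bottom[-n_edge, ], left[-n_edge, ])
  sagittal_init(point = c(0, 0, 0), normal = c(1, 0, 0),
                axis1 = c(0, 1, 0), axis2 = c(0, 0, 1),
                contour = contour,
                landmarks = c(1L, n_edge, 2L * (n_edge - 1L) + 1L,
                              3L * (n_edge - 1L) + 1L))
}

# circle initialisation with landmarks at N, E, S, W
circle_init <- function(radius = 10, n = 360) {
  th <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n  # start at N, clockwise
  contour <- cbind(radius * cos(th), radius * sin(th))
  sagittal_init(point = c(0, 0, 0), normal = c(1, 0, 0),
                axis1 = c(0, 1, 0), axis2 = c(0, 0, 1),
                contour = contour,
                landmarks = as.integer(c(1, n / 4 + 1, n / 2 + 1, 3 * n / 4 + 1)),
                check_simple = FALSE)
}

# axis-aligned ellipsoid mesh (semi-axes along LR, AP, SI), built as a loft
# of elliptical rings stacked along SI
ellipsoid_mesh <- function(a_lr, a_ap, a_si, n_rings = 60, n_pts = 120) {
  zs <- a_si * cos(seq(pi - 0.04, 0.04, length.out = n_rings))
  rings <- lapply(zs, function(z) {
    s <- sqrt(max(1 - (z / a_si)^2, 1e-6))
    th <- 2 * pi * (seq_len(n_pts) - 1) / n_pts
    cbind(a_lr * s * cos(th), a_ap * s * sin(th), z)
  })
  stackedellipse:::loft_mesh(rings)
}

# UV-sphere mesh of given radius
sphere_mesh <- function(radius = 10, n_rings = 60, n_pts = 90) {
  ellipsoid_mesh(radius, radius, radius, n_rings, n_pts)
}

# straight stack of identical circles along SI (cylinder)
cylinder_slices <- function(radius = 10, length = 40, n_slices = 21) {
  zs <- seq(0, length, length.out = n_slices)
  lapply(zs, function(z)
    list(plane = slicing_plane(origin = c(0, 0, z), u_axis = c(0, 1, 0),
                               v_axis = c(1, 0, 0)),
         ellipse = ellipse2d(0, 0, radius, radius)))
}

# small, fast phantom used by unit tests (coarser grid and slicing than the
# full-size study phantom exercised in the acceptance suite)
tiny_phantom_spec <- function(seed = 1L, speckle = TRUE) {
  phantom_spec(centerline = rbind(c(18, 8), c(0, 2), c(-2, -20)),
               b_profile = function(s) 6 + 4 * exp(-((s - 0.25) / 0.35)^2),
               spacing = 1.0, ring_spacing = 2.0, pad = 8,
               speckle = list(enabled = speckle, weight = 1),
               seed = as.integer(seed))
}

# planar grid helper for edge-map tests: square image of constant value
flat_image <- function(n = 81, spacing = 1, value = 0) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  structure(list(pixels = matrix(value, n, n),
                 valid = matrix(TRUE, n, n),
                 x = ax, y = ax, spacing = spacing, plane = NULL),
            class = "planar_image")
}

# blurred disk image: dark disk (mu_in) on bright background (mu_out)
disk_image <- function(n = 161, spacing = 1, radius = 40, mu_in = 20,
                       mu_out = 100, sigma = 4) {
  img <- flat_image(n, spacing)
  rr <- sqrt(outer(img$x^2, img$y^2, `+`))
  img$pixels <- ifelse(rr <= radius, mu_in, mu_out)
  img$pixels <- stackedellipse:::gauss_blur2(img$pixels, sigma)
  img
}
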