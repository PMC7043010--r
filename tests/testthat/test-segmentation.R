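test_that("signed distance maps have correct magnitude and sign", {
  img <- flat_image(n = 81, spacing = 1)
  circ <- ellipse_points(ellipse2d(0, 0, 10, 10), 720)
  sdm <- signed_distance(circ, img)
  ctr <- which(img$x == 0)
  expect_equal(sdm[ctr, ctr], -10, tolerance = 1e-3)
  at15 <- which(img$x == 15)
  expect_equal(sdm[at15, ctr], 5, tolerance = 1e-3)

  # star-shaped contour against the brute-force min-over-points oracle
  set.seed(14)
  th <- sort(runif(40, 0, 2 * pi))
  rad <- 8 + 4 * sin(3 * th) + runif(40, -0.5, 0.5)
  star <- cbind(rad * cos(th), rad * sin(th))
  sdm2 <- signed_distance(star, img)
  pix <- cbind(sample(seq_along(img$x), 500, replace = TRUE),
               sample(seq_along(img$y), 500, replace = TRUE))
  got <- abs(sdm2[pix])
  want <- oracle_min_dist2d(cbind(img$x[pix[, 1]], img$y[pix[, 2]]), star)
  expect_lt(max(abs(got - want)), 1e-9)

  expect_error(signed_distance(star[1:2, ], img), class = "se_invalid_argument")
})

test_that("direction field is the outward unit gradient with a singular-pixel rule", {
  img <- flat_image(n = 101, spacing = 1)
  circ <- ellipse_points(ellipse2d(0, 0, 12, 12), 720)
  sdm <- signed_distance(circ, img)
  J <- direction_field(sdm)
  mag <- sqrt(J$Jx^2 + J$Jy^2)
  expect_true(all(abs(mag) < 1e-6 | abs(mag - 1) < 1e-6))

  # exterior pixels: J within 0.02 of the outward radial direction
  xs <- img$x
  for (p in list(c(30, 0), c(0, -35), c(25, 25), c(-28, 10))) {
    i <- which(xs == p[1]); j <- which(xs == p[2])
    rhat <- p / sqrt(sum(p^2))
    expect_lt(sqrt((J$Jx[i, j] - rhat[1])^2 + (J$Jy[i, j] - rhat[2])^2), 0.02)
  }

  # the circle centre lies on the medial axis: gradient vanishes there
  ctr <- which(xs == 0)
  expect_equal(J$Jx[ctr, ctr], 0)
  expect_equal(J$Jy[ctr, ctr], 0)
})

test_that("distance weighting matches its closed form and decreases strictly", {
  d <- matrix(seq(0, 12, length.out = 1001), ncol = 1)
  R <- distance_weight(d, k = 1)
  expect_equal(R[1], 1)
  expect_equal(R[length(R)], 0)
  u <- which(abs(d / max(d) - 0.5) < 1e-9)
  expect_equal(R[u], 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_true(all(diff(R[, 1]) < 0))
  expect_true(all(R >= 0 & R <= 1))
  expect_error(distance_weight(matrix(0, 3, 3), 1), class = "se_degenerate_grid")
  expect_error(distance_weight(matrix(-1, 2, 2), 1), class = "se_invalid_argument")
})

test_that("directional edge map applies the contrast-polarity case split", {
  params <- edge_map_params()
  init <- ellipse2d(0, 0, 40, 40)

  # uniform image: no gradient, identically zero edge map
  f0 <- directional_edge_map(flat_image(161, value = 55), init, params)
  expect_true(all(f0$values == 0))

  # dark disk: the edge-map ridge sits on the maximal-gradient circle
  img <- disk_image(161, radius = 40, mu_in = 20, mu_out = 100, sigma = 4)
  fmap <- directional_edge_map(img, init, params)
  expect_true(all(fmap$values >= 0))
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  for (t in th) {
    rr <- seq(30, 50, by = 0.25)
    prof <- stackedellipse:::bilinear_sample(
      fmap$values, (rr * cos(t) - img$x[1]) / img$spacing,
      (rr * sin(t) - img$y[1]) / img$spacing)
    expect_lt(abs(rr[which.max(prof)] - 40), 1)
  }

  # inverted contrast (bright disk on dark): agreement <= 0 is zeroed on the ring
  inv <- disk_image(161, radius = 40, mu_in = 100, mu_out = 20, sigma = 4)
  finv <- directional_edge_map(inv, init, params)
  ring <- abs(sqrt(outer(inv$x^2, inv$y^2, `+`)) - 40) < 6
  expect_true(all(finv$values[ring] == 0))

  # random image: f = 0 exactly where the agreement term is non-positive
  set.seed(77)
  rimg <- flat_image(61)
  rimg$pixels <- matrix(runif(61^2), 61, 61)
  small <- ellipse2d(0, 0, 15, 12)
  fr <- directional_edge_map(rimg, small, params)
  V1 <- stackedellipse:::gauss_blur2(rimg$pixels, params$sigma)
  g <- stackedellipse:::central_diff(V1)
  sdm <- signed_distance(ellipse_points(small, 360), rimg)
  J <- direction_field(sdm)
  agree <- g$gx * J$Jx + g$gy * J$Jy
  expect_true(all(fr$values[agree <= 0] == 0))
  expect_true(all(fr$values >= 0))
})

test_that("radial peak search moves points to the nearest peak and stays put otherwise", {
  params <- edge_map_params(r = 29)
  img <- flat_image(161, spacing = 1)
  mk_edge <- function(values) {
    structure(list(values = values, image = img,
                   init = NULL, params = params, sdm = NULL),
              class = "directional_edge_map")
  }
  rr <- sqrt(outer(img$x^2, img$y^2, `+`))

  # single bright circular ridge at radius 35, init at 40: all points pull in
  ridge <- exp(-(rr - 35)^2 / 2)
  init <- ellipse2d(0, 0, 40, 40)
  prov <- deform_contour(mk_edge(ridge), init, n_points = 90)
  rads <- sqrt(rowSums(prov^2))
  expect_true(all(abs(rads - 35) <= 1))

  # zero edge map: the contour stays exactly in place
  prov0 <- deform_contour(mk_edge(matrix(0, 161, 161)), init, n_points = 90)
  expect_equal(unname(prov0), unname(ellipse_points(init, 90)), tolerance = 1e-12)

  # two concentric ridges at 37 and 48, init at 40: the nearer (inner) wins
  ridge2 <- exp(-(rr - 37)^2 / 2) + exp(-(rr - 48)^2 / 2)
  prov2 <- deform_contour(mk_edge(ridge2), init, n_points = 90)
  rads2 <- sqrt(rowSums(prov2^2))
  expect_true(all(abs(rads2 - 37) <= 1))

  # window containment: never farther than r/2 pixels from the start
  set.seed(99)
  noisy <- matrix(runif(161^2), 161, 161)
  provn <- deform_contour(mk_edge(noisy), init, n_points = 90)
  moved <- sqrt(rowSums((provn - ellipse_points(init, 90))^2))
  expect_true(all(moved <= params$r / 2 + 1e-9))
})

test_that("elliptical regularisation smooths outliers and falls back on degeneracy", {
  e <- ellipse2d(1, 2, 20, 12, 0.2)
  pts <- ellipse_points(e, 100)
  f <- regularize_contour(pts)
  expect_equal(c(f$c1, f$c2, f$a, f$b, f$phi), c(1, 2, 20, 12, 0.2),
               tolerance = 1e-6)

  # clinically sized contour (pixels): 10% of points displaced 10 px
  # outward still leave the fitted axes within 5% of the true ellipse
  ec <- ellipse2d(1, 2, 43, 26, 0.2)
  ptsc <- ellipse_points(ec, 180)
  set.seed(55)
  out <- ptsc
  bad <- sample(180, 18)
  dirs <- sweep(ptsc[bad, , drop = FALSE], 2, c(1, 2))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  out[bad, ] <- out[bad, ] + 10 * dirs
  f2 <- regularize_contour(out)
  expect_lt(abs(f2$a - 43) / 43, 0.05)
  expect_lt(abs(f2$b - 26) / 26, 0.05)

  # collinear degenerate points: first-guess fallback, flagged
  line <- cbind(1:20, 2 * (1:20))
  fb <- regularize_contour(line, fallback = e)
  expect_true(isTRUE(attr(fb, "fallback")))
  expect_equal(fb$a, e$a)
  expect_error(regularize_contour(line), class = "se_fit_error")
})

test_that("first-guess ellipses follow the axis model and anchor geometry", {
  init <- rect_init(width = 40, height = 20)
  ies <- initialize_ellipses(init, axis_model(1, 0), slice_spacing = 10,
                             pixel_spacing = 1)
  expect_length(ies, 4)
  for (s in ies) {
    expect_equal(s$ellipse$a, 10)   # identity model on b = 10
    expect_equal(s$ellipse$b, 10)
    expect_equal(s$ellipse$phi, 0)
  }
  ies2 <- initialize_ellipses(init, axis_model(1.01, 11.3), slice_spacing = 10,
                              pixel_spacing = 1)
  expect_equal(ies2[[1]]$ellipse$a, 21.4)
  expect_equal(ies2[[1]]$ellipse$b, 10)

  # phantom centerline: first-guess centroids lie on the centerline
  spec <- tiny_phantom_spec(seed = 6, speckle = FALSE)
  truth <- make_truth(spec)
  pinit <- make_initialization(truth, jitter = 0)
  ies3 <- initialize_ellipses(pinit, axis_model(1.01, 11.3),
                              slice_spacing = spec$ring_spacing,
                              pixel_spacing = spec$spacing)
  ctrs <- t(vapply(ies3, function(s) s$plane$centroid, numeric(3)))
  truth_ctrs <- t(vapply(truth$slices, function(s) s$plane$origin, numeric(3)))
  for (i in seq_len(nrow(ctrs))) {
    d <- min(sqrt(colSums((t(truth_ctrs) - ctrs[i, ])^2)))
    expect_lt(d, spec$ring_spacing)
  }
})

test_that("full pipeline reproduces the first-guess stack on edge-free volumes and is deterministic", {
  spec <- tiny_phantom_spec(seed = 9, speckle = FALSE)
  truth <- make_truth(spec)
  init <- make_initialization(truth, jitter = 0)
  flat <- render_volume(truth, spec)
  flat$intensities[] <- 50  # uniform: no edges anywhere

  seg <- segment_volume(flat, init)
  for (s in seg$slices) {
    expect_equal(s$final$a, s$first_guess$a, tolerance = 1e-9)
    expect_equal(s$final$b, s$first_guess$b, tolerance = 1e-9)
    expect_equal(c(s$final$c1, s$final$c2),
                 c(s$first_guess$c1, s$first_guess$c2), tolerance = 1e-9)
  }

  # determinism: bit-identical slice ellipses and meshes across reruns
  vol <- render_volume(truth, spec)
  s1 <- segment_volume(vol, init)
  s2 <- segment_volume(vol, init)
  expect_identical(lapply(s1$slices, `[[`, "final"),
                   lapply(s2$slices, `[[`, "final"))
  expect_identical(s1$mesh$vertices, s2$mesh$vertices)
  expect_true(is_watertight(s1$mesh))
})
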