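test_that("ellipse_points satisfies the implicit ellipse equation", {
  # unit circle sampled at multiples of pi/4 hits the four axis points
  p <- ellipse_points(ellipse2d(0, 0, 1, 1), 8)
  expect_equal(p[1, ], c(x = 1, y = 0), tolerance = 1e-12)
  expect_equal(p[3, ], c(x = 0, y = 1), tolerance = 1e-12)
  expect_equal(p[5, ], c(x = -1, y = 0), tolerance = 1e-12)
  expect_equal(p[7, ], c(x = 0, y = -1), tolerance = 1e-12)

  # every point of an axis-aligned ellipse satisfies the implicit equation
  e <- ellipse2d(2, 3, 5, 2)
  p <- ellipse_points(e, 123)
  expect_lt(max(abs((p[, 1] - 2)^2 / 25 + (p[, 2] - 3)^2 / 4 - 1)), 1e-9)

  # rotated ellipses too, and the point centroid is the ellipse centroid
  set.seed(11)
  for (i in 1:20) {
    e <- ellipse2d(runif(1, -50, 50), runif(1, -50, 50),
                   runif(1, 1, 30), runif(1, 1, 30), runif(1, 0, pi))
    p <- ellipse_points(e, 360)
    expect_lt(max(abs(stackedellipse:::ellipse_residual(e, p))), 1e-9)
    expect_equal(unname(colMeans(p)), c(e$c1, e$c2), tolerance = 1e-9)
  }
  expect_error(ellipse_points(e, 4), class = "se_invalid_argument")
})

test_that("direct ellipse fit round-trips noise-free input and flags degeneracy", {
  e <- ellipse2d(1, -2, 4, 2, 0.3)
  f <- fit_ellipse_direct(ellipse_points(e, 40))
  expect_equal(c(f$c1, f$c2, f$a, f$b, f$phi),
               c(1, -2, 4, 2, 0.3), tolerance = 1e-6)

  # five points on a circle pin down the circle
  th <- 2 * pi * (0:4) / 5
  f <- fit_ellipse_direct(cbind(3 * cos(th) + 1, 3 * sin(th) - 2))
  expect_equal(c(f$c1, f$c2, f$a, f$b), c(1, -2, 3, 3), tolerance = 1e-6)

  expect_error(fit_ellipse_direct(cbind(1:4, 1:4)), class = "se_fit_error")
  expect_error(fit_ellipse_direct(cbind(1:10, 2 * (1:10))), class = "se_fit_error")
})

test_that("direct fit agrees with a geometric-distance oracle under noise", {
  set.seed(21)
  for (i in 1:5) {
    e <- ellipse2d(runif(1, -5, 5), runif(1, -5, 5),
                   a = runif(1, 8, 15), b = runif(1, 3, 6), phi = runif(1, 0, pi))
    pts <- ellipse_points(e, 100)
    pts <- pts + matrix(rnorm(200, 0, 0.05 * e$b), ncol = 2)
    fit <- fit_ellipse_direct(pts)
    orc <- oracle_geometric_fit(pts, start = c(e$c1, e$c2, e$a, e$b, e$phi))
    expect_lt(abs(fit$a - orc$a) / orc$a, 0.02)
    expect_lt(abs(fit$b - orc$b) / orc$b, 0.02)
    expect_lt(sqrt((fit$c1 - orc$c1)^2 + (fit$c2 - orc$c2)^2) / orc$b, 0.02)
  }
})

test_that("anchor pairs are arclength-uniform, equal-count and correctly matched", {
  # rectangle with corner landmarks: the two long edges pair vertically
  init <- rect_init(width = 40, height = 10)
  pairs <- build_anchor_pairs(init, slice_spacing = 10)
  expect_length(pairs, 4)
  for (p in pairs) {
    expect_equal(p$top[1], p$bottom[1], tolerance = 1e-9)   # vertical
    expect_equal(abs(p$top[2] - p$bottom[2]), 10, tolerance = 1e-9)
  }
  expect_equal(sort(vapply(pairs, function(p) p$top[1], numeric(1))),
               c(5, 15, 25, 35), tolerance = 1e-9)

  # matched stations: brute-force arclength parameterisation oracle
  lm <- init$landmarks
  top_seg <- stackedellipse:::contour_segment(init$contour, lm[1], lm[2])
  bot_seg <- stackedellipse:::contour_segment(init$contour, lm[3], lm[4])
  for (i in seq_along(pairs)) {
    f <- (i - 0.5) / length(pairs)
    expect_equal(unname(pairs[[i]]$top),
                 unname(oracle_point_at_fraction(top_seg, f)), tolerance = 1e-9)
    expect_equal(unname(pairs[[i]]$bottom),
                 unname(oracle_point_at_fraction(bot_seg, 1 - f)), tolerance = 1e-9)
  }

  # equal counts on top and bottom for arbitrary landmark placements
  set.seed(5)
  ci <- circle_init(10)
  for (sp in c(3, 7, 50)) {
    pairs <- build_anchor_pairs(ci, sp)
    expect_gte(length(pairs), 1)
    # every anchor line spans the centre's x for the symmetric quadrants
    for (p in pairs) {
      expect_lte(min(p$top[1], p$bottom[1]), 1e-6)
      expect_gte(max(p$top[1], p$bottom[1]), -1e-6)
    }
  }
  expect_error(build_anchor_pairs(ci, -1), class = "se_invalid_argument")
})

test_that("slicing planes contain the LR direction and record seeds", {
  init <- rect_init()
  pairs <- build_anchor_pairs(init, 10)
  planes <- planes_from_pairs(pairs, init)
  for (pl in planes) {
    expect_lt(abs(sum(pl$normal * init$normal)), 1e-9)  # contains LR
    expect_lt(abs(sum(pl$u_axis * pl$v_axis)), 1e-9)
    expect_equal(vnorm <- sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)
  }

  # seed b and centroid from the anchor pair, in world coordinates
  man <- list(list(top = c(0, 0), bottom = c(0, -20)))
  pl <- planes_from_pairs(man, init)[[1]]
  expect_equal(pl$seed_b, 10)
  expect_equal(pl$centroid, c(0, 0, -10))  # sagittal (0,-10) in world

  # zero-length anchor line is rejected with a warning record
  man2 <- list(list(top = c(1, 1), bottom = c(1, 1)),
               list(top = c(0, 0), bottom = c(0, -20)))
  pls <- planes_from_pairs(man2, init)
  expect_length(pls, 1)
  expect_match(attr(pls, "warnings"), "zero-length")
})

test_that("plane resampling reproduces constant, linear and native-slice fields", {
  vol <- volume3d(array(7, dim = c(12, 14, 16)), spacing = 1)
  pl <- slicing_plane(origin = c(5, 6, 7), u_axis = c(0, 1, 0), v_axis = c(0, 0, 1),
                      grid = list(extent = c(8, 8), spacing = 0.5))
  img <- resample_plane(vol, pl)
  expect_true(all(img$pixels[img$valid] == 7))

  # trilinear interpolation reproduces a linear-in-x field exactly
  xs <- array(rep(0:11, 14 * 16), dim = c(12, 14, 16))
  volx <- volume3d(xs, spacing = 1)
  plx <- slicing_plane(origin = c(4.3, 6, 7), u_axis = c(0, 1, 0), v_axis = c(0, 0, 1),
                       grid = list(extent = c(6, 6), spacing = 1))
  imgx <- resample_plane(volx, plx)
  expect_lt(max(abs(imgx$pixels[imgx$valid] - 4.3)), 1e-9)

  # a plane aligned with a native slice returns those voxels exactly
  set.seed(3)
  rv <- array(runif(12 * 14 * 16), dim = c(12, 14, 16))
  volr <- volume3d(rv, spacing = 1)
  pln <- slicing_plane(origin = c(5, 6, 8), u_axis = c(0, 1, 0), v_axis = c(1, 0, 0),
                       grid = list(extent = c(4, 4), spacing = 1))
  imgn <- resample_plane(volr, pln)
  # node (x, y) -> world (5 + x, 6 + y, 8) -> voxel indices
  for (ix in seq_along(imgn$x)) {
    for (iy in seq_along(imgn$y)) {
      wx <- 5 + imgn$x[ix]; wy <- 6 + imgn$y[iy]
      expect_equal(imgn$pixels[ix, iy], rv[wx + 1, wy + 1, 9], tolerance = 1e-12)
    }
  }

  far <- slicing_plane(origin = c(1000, 0, 0), u_axis = c(0, 1, 0), v_axis = c(0, 0, 1),
                       grid = list(extent = c(4, 4), spacing = 1))
  expect_error(resample_plane(vol, far), class = "se_empty_overlap")
})

test_that("plane/world transforms round-trip to machine precision", {
  pl <- slicing_plane(origin = c(3, -2, 5),
                      u_axis = unitize_test(c(0, 1, 1)),
                      v_axis = c(1, 0, 0))
  expect_equal(as.numeric(plane_to_world(pl, cbind(0, 0))), pl$origin)
  expect_equal(as.numeric(plane_to_world(pl, cbind(0, 1))), pl$origin + pl$u_axis)
  expect_equal(as.numeric(plane_to_world(pl, cbind(1, 0))), pl$origin + pl$v_axis)
  set.seed(9)
  pts <- matrix(runif(2000, -50, 50), ncol = 2)
  back <- world_to_plane(pl, plane_to_world(pl, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})
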