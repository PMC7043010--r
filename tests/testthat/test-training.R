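test_that("contour parameterisation recovers analytic ellipsoid cross-sections", {
  em <- ellipsoid_mesh(15, 10, 20)  # LR 15, AP 10, SI 20
  # mid-sagittal initialisation: top/bottom arcs of the (AP, SI) section
  zs <- seq(19.3, -19.3, length.out = 80)
  bs <- 10 * sqrt(1 - (zs / 20)^2)
  contour <- rbind(cbind(bs, zs), cbind(-bs, rev(zs)))
  init <- sagittal_init(point = c(0, 0, 0), normal = c(1, 0, 0),
                        axis1 = c(0, 1, 0), axis2 = c(0, 0, 1),
                        contour = contour, landmarks = c(1L, 80L, 81L, 160L),
                        check_simple = FALSE)
  res <- parameterize_contour(em, init, slice_spacing = 2)
  expect_gt(length(res$slices), 10)
  # the slice nearest the equator recovers the analytic semi-axes
  mids <- vapply(res$slices, function(s) abs(s$plane$origin[3]), numeric(1))
  mid <- res$slices[[which.min(mids)]]
  expect_equal(mid$ellipse$a, 15, tolerance = 0.5 / 15)
  expect_equal(mid$ellipse$b, 10, tolerance = 0.5 / 10)
})

test_that("contour parameterisation round-trips the phantom generator", {
  # jitter-free straight-centerline stack: the generating axes are known
  # analytically at every station along the path
  bp <- function(s) 7 + 5 * exp(-((s - 0.3) / 0.3)^2)
  spec <- phantom_spec(centerline = rbind(c(0, 24), c(0, 0), c(0, -24)),
                       b_profile = bp,
                       axis_law = list(m = 1.01, K = 11.3, sigma_a = 0),
                       spacing = 1, ring_spacing = 1.5, seed = 2,
                       speckle = list(enabled = FALSE, weight = 0))
  truth <- make_truth(spec)
  init <- make_initialization(truth, jitter = 0)
  res <- parameterize_contour(truth$mesh, init, slice_spacing = 2)
  expect_gt(nrow(res$samples), 10)
  z0 <- 24; z1 <- -24
  for (s in res$slices) {
    frac <- (z0 - s$plane$origin[3]) / (z0 - z1)
    if (frac < 0.05 || frac > 0.95) next  # end caps are not full sections
    b_true <- bp(frac)
    a_true <- 1.01 * b_true + 11.3
    expect_lt(abs(s$ellipse$b - b_true) / b_true, 0.02)
    expect_lt(abs(s$ellipse$a - a_true) / a_true, 0.02)
  }

  # slicing wider than the organ still yields at least one valid slice
  res2 <- parameterize_contour(truth$mesh, init, slice_spacing = 60)
  expect_lte(length(res2$slices), length(build_anchor_pairs(init, 60)))
})

test_that("axis model fit matches closed-form least squares", {
  # exact line
  b <- seq(5, 30, length.out = 20)
  m <- fit_axis_model(data.frame(a_mm = 2 * b + 5, b_mm = b))
  expect_equal(m$m, 2, tolerance = 1e-12)
  expect_equal(m$K, 5, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  # constant response: zero slope, intercept at the mean, no variance explained
  mc <- fit_axis_model(data.frame(a_mm = rep(7, 10), b_mm = b[1:10]))
  expect_equal(mc$m, 0, tolerance = 1e-12)
  expect_equal(mc$K, 7, tolerance = 1e-12)
  expect_equal(mc$r_squared, 0, tolerance = 1e-12)

  # noisy fit equals the normal-equations oracle to 1e-9 and recovers truth
  set.seed(31)
  bb <- runif(200, 10, 35)
  aa <- 1.01 * bb + 11.3 + rnorm(200, 0, 3)
  fit <- fit_axis_model(data.frame(a_mm = aa, b_mm = bb))
  orc <- oracle_ols(aa, bb)
  expect_equal(fit$m, orc$m, tolerance = 1e-9)
  expect_equal(fit$K, orc$K, tolerance = 1e-9)
  expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-9)
  expect_lt(abs(fit$m - 1.01), 0.1)
  expect_lt(abs(fit$K - 11.3), 3)

  expect_error(fit_axis_model(data.frame(a_mm = c(3, 4), b_mm = c(2, 2))),
               class = "se_degenerate_fit")
  expect_error(fit_axis_model(data.frame(a_mm = 3, b_mm = 2)),
               class = "se_degenerate_fit")
})

test_that("major-axis prediction follows the linear model and rejects degenerate output", {
  expect_equal(predict_major_axis(axis_model(1.01, 11.3), 10), 21.4)
  expect_equal(predict_major_axis(axis_model(1, 0), 7), 7)
  expect_equal(predict_major_axis(axis_model(0, 5), 123), 5)
  expect_error(predict_major_axis(axis_model(-2, 1), 1), class = "se_invalid_model")
  expect_error(predict_major_axis(axis_model(1, 1), -3), class = "se_invalid_argument")
})

test_that("axis model serialises to JSON and ships a usable default", {
  d <- default_axis_model()
  expect_equal(d$m, 1.01)
  expect_equal(d$K, 11.3)
  p <- tempfile(fileext = ".json")
  write_axis_model(d, p)
  d2 <- read_axis_model(p)
  expect_equal(d2$m, d$m)
  expect_equal(d2$K, d$K)
  expect_equal(d2$r_squared, d$r_squared)
})

test_that("training over multiple phantoms pools samples and fits the population model", {
  meshes <- list(); inits <- list()
  for (sd in 1:3) {
    spec <- tiny_phantom_spec(seed = sd, speckle = FALSE)
    truth <- make_truth(spec)
    meshes[[sd]] <- truth$mesh
    inits[[sd]] <- make_initialization(truth, jitter = 0)
  }
  tr <- train_axis_model(meshes, inits, slice_spacing = 2)
  expect_s3_class(tr$model, "axis_model")
  expect_true(all(c("patient", "a_mm", "b_mm") %in% names(tr$samples)))
  # generating law is m = 1.01, K = 11.3 with 1 mm jitter: recovered nearby
  expect_lt(abs(tr$model$m - 1.01), 0.35)
  expect_lt(abs(tr$model$K - 11.3), 4)
})
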