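phi16 <- uniform_phi(16)

test_that("isotropic input gives zero anisotropy and undefined direction", {
  f <- fit_azimuthal_orientation(rep(5, 16), phi16)
  expect_equal(f$a_sym, 5)
  expect_equal(f$a_asym, 0, tolerance = 1e-12)
  expect_equal(f$degree, 0, tolerance = 1e-12)
  expect_true(is.na(f$theta_s))
})

test_that("a cosine profile in the model class is recovered exactly", {
  az <- 1 + 0.5 * cos(2 * (phi16 - 30) * pi / 180)
  f <- fit_azimuthal_orientation(az, phi16)
  expect_equal(f$a_sym, 1, tolerance = 1e-9)
  expect_equal(f$a_asym, 0.5, tolerance = 1e-9)
  expect_equal(f$theta_s, 30, tolerance = 1e-9)
  expect_equal(f$degree, 0.5, tolerance = 1e-9)
})

test_that("closed-form Fourier and least-squares cosine fits agree", {
  set.seed(77)
  for (rep in 1:50) {
    az <- runif(16, 0.1, 10)
    ff <- fit_azimuthal_orientation(az, phi16)
    # force the least-squares branch by faking one missing-then-restored run
    X <- cbind(1, cos(2 * phi16 * pi / 180), sin(2 * phi16 * pi / 180))
    cf <- stats::lsfit(X, az, intercept = FALSE)$coefficients
    expect_equal(ff$a_sym, unname(cf[1]), tolerance = 1e-9)
    expect_equal(ff$a_asym, unname(sqrt(cf[2]^2 + cf[3]^2)),
                 tolerance = 1e-9)
    th_ls <- (atan2(cf[3], cf[2]) / 2 * 180 / pi) %% 180
    if (ff$a_asym > 1e-8)
      expect_equal(ff$theta_s, unname(th_ls), tolerance = 1e-9)
  }
})

test_that("masked sectors fall back to least squares and recover the model", {
  az <- 2 + 0.8 * cos(2 * (phi16 - 117) * pi / 180)
  az[c(2, 9)] <- -1   # sentinels
  f <- fit_azimuthal_orientation(az, phi16)
  expect_equal(f$method, "lsq")
  expect_equal(f$a_sym, 2, tolerance = 1e-9)
  expect_equal(f$a_asym, 0.8, tolerance = 1e-9)
  expect_equal(f$theta_s, 117, tolerance = 1e-9)
  expect_true(is.na(
    fit_azimuthal_orientation(c(az[1:7], rep(-1, 9)), phi16)$a_sym))
})

test_that("rotation equivariance: shifting phi shifts theta_s, amplitudes fixed", {
  set.seed(5)
  for (rep in 1:20) {
    az <- runif(16, 0.5, 4) + 2 * pmax(cos(2 * (phi16 - 40) * pi / 180), 0)
    f0 <- fit_azimuthal_orientation(az, phi16)
    delta <- runif(1, 0, 180)
    f1 <- fit_azimuthal_orientation(az, phi16 + delta)
    expect_equal(f1$a_sym, f0$a_sym, tolerance = 1e-9)
    expect_equal(f1$a_asym, f0$a_asym, tolerance = 1e-9)
    d <- (f1$theta_s - f0$theta_s - delta) %% 180
    expect_lt(min(d, 180 - d), 1e-9)
  }
})

test_that("degree of orientation lies in [0, 1] for random nonnegative profiles", {
  set.seed(11)
  for (rep in 1:10000) {
    az <- runif(16, 0, 1)
    f <- fit_azimuthal_orientation(az, phi16)
    expect_true(f$degree >= 0 && f$degree <= 1)
  }
})

test_that("fiber axis mapping handles both scattering geometries", {
  expect_equal(fiber_axis(30, "meridional"), 30)
  expect_equal(fiber_axis(30, "equatorial"), 120)
  expect_equal(fiber_axis(170, "equatorial"), 80)
})

test_that("orientation maps render with the documented channel semantics", {
  ny <- 4; nx <- 4
  omap <- structure(list(
    theta_s = matrix(45, ny, nx),
    a_sym = matrix(2, ny, nx),
    a_asym = matrix(c(1, 0), ny, nx),
    degree = matrix(0.5, ny, nx),
    band = c(0.085, 0.11)), class = "orientation_map")
  img <- render_orientation_map(omap, "hv")
  # uniform theta -> single hue among lit pixels
  lit <- img[, , 1] + img[, , 2] + img[, , 3] > 0
  hues <- apply(img, c(1, 2), function(px)
    grDevices::rgb2hsv(px[1] * 255, px[2] * 255, px[3] * 255)[1])
  expect_equal(length(unique(round(hues[lit], 6))), 1)
  # zero anisotropy everywhere -> black image in hue-value mode
  omap$a_asym <- matrix(0, ny, nx)
  expect_true(all(render_orientation_map(omap, "hv") == 0))
})

test_that("two-orientation checkerboards map to two distinct hues", {
  ny <- 6; nx <- 6
  checker <- outer(1:ny, 1:nx, function(i, j) (i + j) %% 2)
  omap <- structure(list(
    theta_s = 30 + 90 * checker,
    a_sym = matrix(2, ny, nx),
    a_asym = matrix(1, ny, nx),
    degree = matrix(0.5, ny, nx),
    band = c(0.085, 0.11)), class = "orientation_map")
  img <- render_orientation_map(omap, "hv", percentiles = c(0, 1))
  hdeg <- 180 * apply(img, c(1, 2), function(px)
    grDevices::rgb2hsv(px[1] * 255, px[2] * 255, px[3] * 255)[1])
  # 8-bit RGB quantization jitters hues by a fraction of a degree
  near30 <- abs(hdeg - 30) < 1
  near120 <- abs(hdeg - 120) < 1
  expect_true(all(near30 | near120))
  expect_identical(near120, checker == 1)
})

test_that("band profiles average valid bins only", {
  g <- qaz_grid(q_min = 0.1, q_max = 0.2, n_q = 10, n_seg = 4)
  slab <- matrix(1, 4, 10)
  slab[2, ] <- 3
  slab[3, 1:5] <- -1
  slab[3, 6:10] <- 7
  bp <- band_profile(slab, g, c(0.1, 0.2))
  expect_equal(bp, c(1, 3, 7, 1))
  one_bin <- band_profile(slab, g, c(0.1, 0.112))
  expect_equal(one_bin, c(1, 3, -1, 1))
})

test_that("simulated orientation fields are recovered within half a sector", {
  tw <- tiny_scan(ny = 12, nx = 12, seed = 140)
  om <- orient_scan(tw$scan, c(0.085, 0.11))
  col <- tw$gt$label == "collagen"
  err <- abs(om$theta_s[col] - tw$gt$theta[col]) %% 180
  err <- pmin(err, 180 - err)
  expect_lt(median(err, na.rm = TRUE), 11.25 / 2)
})

test_that("degree of orientation rises strictly with the concentration kappa", {
  gt <- make_ground_truth("unprocessed", 10, 10, seed = 150)
  col <- gt$label == "collagen"
  degs <- sapply(c(0.2, 0.5, 1, 2), function(kap) {
    gt$kappa <- kap
    scan <- simulate_reduced_scan(gt, seed = 151)
    om <- orient_scan(scan, c(0.085, 0.11))
    median(om$degree[col], na.rm = TRUE)
  })
  expect_true(all(diff(degs) > 0))
})
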