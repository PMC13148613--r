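test_that("the preset library anchors its structural reference values", {
  lib <- preset_library()
  expect_gte(length(lib), 5)
  expect_true(all(c("unprocessed", "dehydrated", "tough_resin", "paraffin",
                    "cryo") %in% names(lib)))
  expect_equal(lib$unprocessed$x, 0.46)
  expect_equal(lib$unprocessed$d_offset_pct, 0)
  expect_equal(lib$dehydrated$x, 0.42)
  expect_equal(lib$dehydrated$d_offset_pct, -2)
  expect_false(lib$dehydrated$muscle_present)
  # tough-resin D is the reference shrunk by 3.64%
  D_tr <- 66.727 * (1 + lib$tough_resin$d_offset_pct / 100)
  expect_equal(D_tr, 66.727 * (1 - 0.0364))
  expect_gt(lib$cryo$i11_i10_mult, 1)
})

test_that("ground truth is reproducible from the seed", {
  g1 <- make_ground_truth("unprocessed", 12, 12, seed = 8)
  g2 <- make_ground_truth("unprocessed", 12, 12, seed = 8)
  expect_identical(g1, g2)
  g3 <- make_ground_truth("unprocessed", 12, 12, seed = 9)
  expect_false(identical(g1$label, g3$label))
  s1 <- simulate_reduced_scan(g1, qaz_grid(n_q = 300), seed = 4)
  s2 <- simulate_reduced_scan(g1, qaz_grid(n_q = 300), seed = 4)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("label mosaics respect the configured area fractions", {
  gt <- make_ground_truth("unprocessed", 40, 40, seed = 3,
                          fractions = c(0.5, 0.3, 0.2))
  lab <- gt$label
  expect_true(all(lab[1, ] == "background"))
  interior <- lab[2:39, 2:39]
  f_col <- mean(interior == "collagen")
  expect_gt(f_col, 0.35)
  expect_lt(f_col, 0.65)
  expect_true(all(c("muscle", "other") %in% interior))
})

test_that("kappa = 0 removes azimuthal anisotropy in expectation", {
  gt <- make_ground_truth("unprocessed", 8, 8, seed = 5)
  gt$kappa <- 0
  gt$kappa_m <- 0
  scan <- simulate_reduced_scan(gt, qaz_grid(n_q = 400), seed = 6,
                                poisson = FALSE)
  pt <- which(gt$label == "collagen", arr.ind = TRUE)[1, ]
  slab <- scan_point(scan, pt[1], pt[2])
  expect_lt(max(apply(slab, 2, function(col) diff(range(col)))), 1e-9)
})

test_that("x = 0.5 leaves only background in the even-order bins", {
  gt <- make_ground_truth("unprocessed", 8, 8, seed = 5)
  gt$x[] <- 0.5
  gt$order_mult <- rep(1, 10)   # no preset damping: suppression is the model's
  scan <- simulate_reduced_scan(gt, seed = 6, poisson = FALSE)
  pt <- which(gt$label == "collagen", arr.ind = TRUE)[1, ]
  slab <- scan_point(scan, pt[1], pt[2])
  q <- scan$grid$q_centers
  bg <- gt$bg_scale * q^-gt$beta + gt$floor
  for (n in c(2, 4, 6)) {
    sel <- abs(q - 2 * pi * n / gt$D[pt[1], pt[2]]) < 0.004
    # even-order windows: residual above background only from odd-order tails
    expect_lt(max(abs(slab[1, sel] - bg[sel])), 1e-6)
  }
})

test_that("expected bin values match an independent evaluation of the formula", {
  gt <- make_ground_truth("tough_resin", 10, 10, seed = 17)
  grid <- qaz_grid(n_q = 600)
  scan <- simulate_reduced_scan(gt, grid, seed = 18, poisson = FALSE)
  set.seed(77)
  q <- grid$q_centers
  phi <- grid$phi_centers
  for (rep in 1:5) {
    i <- sample(nrow(gt$label), 1); j <- sample(ncol(gt$label), 1)
    k <- sample(grid$n_seg, 1); b <- sample(grid$n_q, 1)
    lab <- gt$label[i, j]
    expected <- if (lab == "background") gt$floor else
      gt$bg_scale * q[b]^(-gt$beta) + gt$floor
    if (lab == "collagen") {
      K <- exp(gt$kappa * (cos(2 * (phi[k] - gt$theta[i, j]) * pi / 180) - 1))
      for (n in 1:10) {
        s <- gt$sigma_c * sqrt(n)
        expected <- expected + gt$amp_collagen * gt$order_mult[n] *
          sin(pi * n * gt$x[i, j])^2 / (pi * n)^2 *
          exp(-(q[b] - 2 * pi * n / gt$D[i, j])^2 / (2 * s^2)) /
          (s * sqrt(2 * pi)) * K
      }
    } else if (lab == "muscle") {
      K <- exp(gt$kappa_m *
                 (cos(2 * (phi[k] - gt$theta[i, j] - 90) * pi / 180) - 1))
      d10 <- gt$d10[i, j]; d11 <- d10 / sqrt(3); s <- gt$sigma_m
      expected <- expected + gt$amp_muscle * K *
        (exp(-(q[b] - 2 * pi / d10)^2 / (2 * s^2)) / (s * sqrt(2 * pi)) +
           gt$rho * exp(-(q[b] - 2 * pi / d11)^2 / (2 * s^2)) /
             (s * sqrt(2 * pi)))
    } else if (lab == "other") {
      for (m in seq_len(nrow(gt$other_peaks)))
        expected <- expected + gt$other_peaks$amp[m] *
          exp(-(q[b] - gt$other_peaks$center[m])^2 /
                (2 * gt$other_peaks$sigma[m]^2))
    }
    expect_equal(scan$intensity[i, j, k, b], expected, tolerance = 1e-12)
  }
})

test_that("reducing a simulated detector frame reproduces the forward model", {
  gt <- make_ground_truth("unprocessed", 8, 8, seed = 23)
  pt <- which(gt$label == "muscle", arr.ind = TRUE)[1, ]
  geom <- detector_geometry(dims = c(384, 384), pixel_size_um = 150,
                            sample_detector_distance_mm = 4000,
                            wavelength_nm = 0.1)
  grid <- qaz_grid(q_min = 0.06, q_max = 0.4, n_q = 60, n_seg = 8)
  fr <- simulate_detector_frame(gt, pt[1], pt[2], geom, seed = 2,
                                poisson = FALSE)
  red <- reduce_frame(fr, grid)
  ref <- simulate_reduced_scan(gt, grid, seed = 3, poisson = FALSE)
  ref_slab <- scan_point(ref, pt[1], pt[2])
  pop <- red >= 0
  # bin means of the pixel-sampled model vs bin-centre evaluation: agree to
  # a few percent where the model varies smoothly over a bin
  rel <- abs(red[pop] - ref_slab[pop]) / ref_slab[pop]
  expect_lt(median(rel), 0.05)
  # zero-amplitude ground truth gives a pure-background frame
  gt0 <- gt
  gt0$amp_muscle <- 0
  fr0 <- simulate_detector_frame(gt0, pt[1], pt[2], geom, seed = 2,
                                 poisson = FALSE)
  qp <- ssaxs:::pixel_q_phi(geom)
  expect_equal(as.numeric(fr0$counts),
               as.numeric(gt$bg_scale * pmax(qp$q, 1e-6)^-gt$beta + gt$floor),
               tolerance = 1e-12)
  # a masked ring propagates to sentinel bins
  mask <- abs(qp$q - 0.2) < 0.01
  geom_m <- detector_geometry(dims = c(384, 384), pixel_size_um = 150,
                              sample_detector_distance_mm = 4000,
                              wavelength_nm = 0.1, mask = mask)
  fr_m <- simulate_detector_frame(gt, pt[1], pt[2], geom_m, seed = 2)
  red_m <- reduce_frame(fr_m, grid)
  ring_bins <- which(grid$q_centers > 0.195 & grid$q_centers < 0.205)
  expect_true(all(red_m[, ring_bins] == -1))
})

test_that("preset orderings match the preservation-effect findings", {
  x_med <- i65_med <- ratio_med <- list()
  for (preset in c("unprocessed", "dehydrated", "cryo")) {
    tw <- tiny_scan(preset, ny = 12, nx = 12, seed = 120)
    res <- run_pipeline(tw$scan)
    x_med[[preset]] <- median(res$table$overlap_fraction, na.rm = TRUE)
    i65_med[[preset]] <- median(res$table$i6_over_i5, na.rm = TRUE)
    if (any(is.finite(res$table$i11_over_i10)))
      ratio_med[[preset]] <- median(res$table$i11_over_i10, na.rm = TRUE)
  }
  expect_lt(x_med$dehydrated, x_med$unprocessed)
  expect_gt(i65_med$dehydrated, i65_med$unprocessed)
  expect_gt(ratio_med$cryo, ratio_med$unprocessed)
  expect_null(ratio_med$dehydrated)   # doublet lost with dehydration
})
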