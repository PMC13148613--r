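# Fixtures are built in code at test time; nothing binary ships with the
# package.

# a small simulated scan (cached per test file through lazy evaluation)
tiny_scan <- function(preset = "unprocessed", ny = 12, nx = 12, seed = 42,
                      poisson = TRUE, grid = qaz_grid()) {
  gt <- make_ground_truth(preset, ny, nx, seed = seed)
  list(gt = gt,
       scan = simulate_reduced_scan(gt, grid, seed = seed + 1,
                                    poisson = poisson))
}

# noiseless meridional collagen profile with unit-area Gaussian orders at
# q_n = 2*pi*n/D weighted by the step-density model
collagen_profile <- function(grid, D, x = 0.46, amp = 3000,
                             sigma_c = 0.0025, orders = 1:6, bg = 0) {
  q <- grid$q_centers
  prof <- rep(bg, length(q))
  for (n in orders) {
    s <- sigma_c * sqrt(n)
    prof <- prof + amp * sin(pi * n * x)^2 / (pi * n)^2 *
      exp(-(q - 2 * pi * n / D)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  }
  prof
}

# order-n collagen fit window
order_window <- function(n, d_ref = 67, tol = 0.06) {
  2 * pi * n / d_ref * c(1 - tol, 1 + tol)
}

# brute-force per-pixel binning oracle for reduce_frame
brute_reduce <- function(frame, grid) {
  geom <- frame$geometry
  px_mm <- geom$pixel_size_um / 1000
  out_sum <- matrix(0, grid$n_seg, grid$n_q)
  out_n <- matrix(0L, grid$n_seg, grid$n_q)
  phi0 <- grid$phi_edges[1]
  w <- 360 / grid$n_seg
  for (i in seq_len(geom$dims[1])) {
    for (j in seq_len(geom$dims[2])) {
      if (geom$mask[i, j] || !is.finite(frame$counts[i, j])) next
      dy <- -(i - geom$beam_center_px[1]) * px_mm
      dx <- (j - geom$beam_center_px[2]) * px_mm
      r <- sqrt(dx^2 + dy^2)
      q <- (4 * pi / geom$wavelength_nm) *
        sin(0.5 * atan(r / geom$sample_detector_distance_mm))
      iq <- findInterval(q, grid$q_edges, rightmost.closed = TRUE)
      if (iq < 1 || iq > grid$n_q) next
      phi <- (atan2(dy, dx) * 180 / pi) %% 360
      is <- (floor(((phi - phi0) %% 360) / w) %% grid$n_seg) + 1
      out_sum[is, iq] <- out_sum[is, iq] + frame$counts[i, j]
      out_n[is, iq] <- out_n[is, iq] + 1L
    }
  }
  out <- matrix(-1, grid$n_seg, grid$n_q)
  out[out_n > 0] <- out_sum[out_n > 0] / out_n[out_n > 0]
  out
}

uniform_phi <- function(n_seg = 16) (seq_len(n_seg) - 0.5) * 360 / n_seg
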