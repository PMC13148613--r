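# Reference values anchoring the simulator: intact hydrated collagen has a
# ~67 nm D-period (measured unprocessed median 66.727 nm) and overlap
# fraction 0.46; vertebrate skeletal muscle d10 is taken as 38 nm.
D_REFERENCE <- 66.727
X_REFERENCE <- 0.46
D10_REFERENCE <- 38
RHO_REST <- 0.4

#' Library of preservation-method presets
#'
#' Each preset encodes the qualitative structural shifts a preparation
#' method imposes, as point values: the D-period offset (dehydration /
#' embedding shrinkage), the overlap fraction x (decreasing with
#' dehydration), per-order amplitude multipliers (staining amplification,
#' low-order damping), whether the muscle equatorial doublet survives, the
#' muscle d-spacing offset, the I11/I10 multiplier (rigor-like elevation)
#' and a relative noise level. Where source ranges exist, midpoints are
#' taken.
#'
#' @return named list of `preset` objects with fields `name`,
#'   `d_offset_pct`, `x`, `order_mult` (length 10), `muscle_present`,
#'   `muscle_d_offset_pct`, `i11_i10_mult`, `noise_level`.
#' @export
preset_library <- function() {
  mk <- function(name, d_offset_pct = 0, x = X_REFERENCE,
                 order_mult = rep(1, 10), muscle_present = TRUE,
                 muscle_d_offset_pct = 0, i11_i10_mult = 1,
                 noise_level = 1) {
    structure(list(name = name, d_offset_pct = d_offset_pct, x = x,
                   order_mult = order_mult, muscle_present = muscle_present,
                   muscle_d_offset_pct = muscle_d_offset_pct,
                   i11_i10_mult = i11_i10_mult, noise_level = noise_level),
              class = "ssaxs_preset")
  }
  # In fresh hydrated fibrils the low even orders (2, 4, ...) are nearly
  # extinct — more so than the crude two-phase step density predicts, since
  # the real axial electron density softens the gap/overlap contrast. The
  # multipliers encode that extra suppression; order 6, the upper member of
  # the I6/I5 diagnostic pair, is left on the step model so the O/D forward
  # and inverse chains stay consistent.
  even_damp <- c(1, 0.003, 1, 0.003, 1, 1, 1, 0.003, 1, 0.003)
  list(
    # fresh tissue: even orders suppressed, muscle doublet at rest
    unprocessed = mk("unprocessed", order_mult = even_damp),
    # drying-type fixation: D down 2%, x down to 0.42, even orders
    # re-emerge with dehydration, doublet lost
    dehydrated = mk("dehydrated", d_offset_pct = -2, x = 0.42,
                    muscle_present = FALSE),
    # osmium staining + epoxy: 3.64% shrinkage, all orders amplified,
    # modest lattice shortening, rigor-like intensity ratio
    tough_resin = mk("tough_resin", d_offset_pct = -3.64,
                     order_mult = rep(3, 10), muscle_d_offset_pct = -5,
                     i11_i10_mult = 3),
    # paraffin embedding: low-order damping, x ~ 0.43-0.44, d-spacings -30%
    paraffin = mk("paraffin", d_offset_pct = -2, x = 0.435,
                  order_mult = c(0.3, 0.3, rep(1, 8)),
                  muscle_d_offset_pct = -30),
    # cryopreservation: D-period kept, even orders stay suppressed,
    # elevated I11/I10, noisier signal
    cryo = mk("cryo", order_mult = even_damp, i11_i10_mult = 3,
              noise_level = 2)
  )
}

# standardized smooth random field (separable moving-average smoothing)
smooth_field <- function(ny, nx, smoothness = NULL) {
  if (is.null(smoothness)) smoothness <- max(3L, round(min(ny, nx) / 6))
  w <- rep(1 / smoothness, smoothness)
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  for (pass in 1:2) {
    z <- apply(z, 2, function(col) stats::filter(col, w, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, w, circular = TRUE)))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate ground-truth parameter fields for a synthetic scan
#'
#' Builds the label mosaic (a background frame around level bands of a
#' smooth random field: collagen / muscle / other), a smooth orientation
#' field and per-point structural parameter fields equal to the preset
#' values plus small spatial jitter (sigma = 0.2% of the value). Fully
#' reproducible from the seed.
#'
#' @param preset a preset from [preset_library()], or its name.
#' @param ny,nx scan dimensions (>= 8 each).
#' @param seed integer RNG seed.
#' @param fractions interior area fractions `c(collagen, muscle, other)`,
#'   summing to 1 (default `c(0.45, 0.35, 0.20)`).
#' @return object of class `ground_truth` with matrices `label`, `theta`
#'   (deg), `D` (nm), `x`, `d10` (nm), `transmission`, scalars describing
#'   the forward model (`beta`, `bg_scale`, `floor`, `amp_collagen`,
#'   `order_mult`, `amp_muscle`, `rho`, `kappa`, `kappa_m`, `sigma_c`,
#'   `sigma_m`, other-region peak table) and the `seed`.
#' @export
make_ground_truth <- function(preset, ny, nx, seed,
                              fractions = c(0.45, 0.35, 0.20)) {
  if (is.character(preset)) {
    lib <- preset_library()
    if (!preset %in% names(lib)) stop("unknown preset: ", preset)
    preset <- lib[[preset]]
  }
  stopifnot(inherits(preset, "ssaxs_preset"), ny >= 8, nx >= 8,
            abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  f <- smooth_field(ny, nx)
  cuts <- stats::quantile(f, cumsum(fractions[c(3, 2)]))
  label <- matrix("collagen", ny, nx)
  label[f <= cuts[2]] <- "muscle"
  label[f <= cuts[1]] <- "other"
  label[1, ] <- label[ny, ] <- "background"
  label[, 1] <- label[, nx] <- "background"
  theta <- (90 + 50 * smooth_field(ny, nx)) %% 180
  jit <- function(v) v * (1 + 0.002 * matrix(stats::rnorm(ny * nx), ny, nx))
  D0 <- D_REFERENCE * (1 + preset$d_offset_pct / 100)
  d10_0 <- D10_REFERENCE * (1 + preset$muscle_d_offset_pct / 100)
  transmission <- matrix(1, ny, nx)
  inner <- label != "background"
  transmission[inner] <- pmin(0.95, pmax(
    0.05, 0.82 + 0.04 * smooth_field(ny, nx)[inner]))
  gt <- list(
    preset = preset$name,
    label = label,
    theta = theta,
    D = jit(matrix(D0, ny, nx)),
    x = jit(matrix(preset$x, ny, nx)),
    d10 = jit(matrix(d10_0, ny, nx)),
    transmission = transmission,
    beta = 3, bg_scale = 0.1, floor = 0.5,
    amp_collagen = 3000 / preset$noise_level,
    order_mult = preset$order_mult,
    amp_muscle = 3 / preset$noise_level,
    muscle_present = preset$muscle_present,
    rho = RHO_REST * preset$i11_i10_mult,
    kappa = 1, kappa_m = 1,
    sigma_c = 0.0025, sigma_m = 0.006,
    other_peaks = data.frame(center = c(0.075, 0.16, 0.245),
                             sigma = 0.012,
                             amp = c(500, 300, 200) / preset$noise_level),
    seed = seed
  )
  class(gt) <- "ground_truth"
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> preset '%s', %d x %d points (seed %d)\n",
              x$preset, nrow(x$label), ncol(x$label), x$seed))
  invisible(x)
}

# pi-periodic von-Mises-style azimuthal kernel; reduces to the cosine model
# at small kappa and stays positive at large kappa
azimuthal_kernel <- function(phi_deg, theta_deg, kappa) {
  exp(kappa * (cos(2 * (phi_deg - theta_deg) * pi / 180) - 1))
}

# unit-area Gaussian in q, so peak areas equal their model weights exactly
gauss_density <- function(q, center, sigma) {
  exp(-(q - center)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

# expected intensity of one scan point on arbitrary (q, phi) arrays
point_expected_intensity <- function(gt, i, j, q, phi) {
  lab <- gt$label[i, j]
  if (lab == "background") return(rep(gt$floor, length(q)) + 0 * q)
  lam <- gt$bg_scale * q^(-gt$beta) + gt$floor
  if (lab == "collagen") {
    K <- azimuthal_kernel(phi, gt$theta[i, j], gt$kappa)
    radial <- 0
    for (n in 1:10)
      radial <- radial + gt$order_mult[n] * order_weight(n, gt$x[i, j]) *
        gauss_density(q, 2 * pi * n / gt$D[i, j], gt$sigma_c * sqrt(n))
    lam <- lam + gt$amp_collagen * K * radial
  } else if (lab == "muscle" && gt$muscle_present) {
    K <- azimuthal_kernel(phi, gt$theta[i, j] + 90, gt$kappa_m)
    d10 <- gt$d10[i, j]
    radial <- gauss_density(q, 2 * pi / d10, gt$sigma_m) +
      gt$rho * gauss_density(q, 2 * pi / (d10 / sqrt(3)), gt$sigma_m)
    lam <- lam + gt$amp_muscle * K * radial
  } else if (lab == "other") {
    for (k in seq_len(nrow(gt$other_peaks)))
      lam <- lam + gt$other_peaks$amp[k] *
        exp(-(q - gt$other_peaks$center[k])^2 /
              (2 * gt$other_peaks$sigma[k]^2))
  }
  lam
}

#' Forward-simulate a reduced scan from ground truth
#'
#' Per scan point, sector and q bin the expected intensity is a power-law
#' diffuse background plus, by region: collagen meridional Bragg orders at
#' `q_n = 2*pi*n/D` weighted by the two-phase step-density model
#' `w_n(x) = sin^2(pi*n*x)/(pi*n)^2` under a pi-periodic von-Mises-style
#' azimuthal kernel around theta; the muscle equatorial doublet at
#' `2*pi/d10` and `2*pi/(d10/sqrt(3))` (intensity ratio rho) around
#' theta + 90; or three broad isotropic peaks at q = 0.075, 0.16 and
#' 0.245 nm^-1 for the "other" connective structures. Counts are then
#' Poisson-sampled.
#'
#' @param gt a [make_ground_truth()] result.
#' @param grid a [qaz_grid()] covering at least 0.05-0.65 nm^-1.
#' @param seed integer seed for the Poisson sampling.
#' @param poisson sample counting noise? `FALSE` returns the expected
#'   (noiseless) intensities.
#' @return a [reduced_scan()].
#' @export
simulate_reduced_scan <- function(gt, grid = qaz_grid(), seed = 1,
                                  poisson = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  validate_qaz_grid(grid)
  ny <- nrow(gt$label); nx <- ncol(gt$label)
  q <- grid$q_centers
  phi <- grid$phi_centers
  set.seed(seed)
  intensity <- array(0, dim = c(ny, nx, grid$n_seg, grid$n_q))
  ones <- rep(1, grid$n_seg)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      lab <- gt$label[i, j]
      iso <- if (lab == "background") rep(gt$floor, grid$n_q)
             else gt$bg_scale * q^(-gt$beta) + gt$floor
      lam <- outer(ones, iso)
      if (lab == "collagen") {
        radial <- 0
        for (n in 1:10)
          radial <- radial + gt$order_mult[n] * order_weight(n, gt$x[i, j]) *
            gauss_density(q, 2 * pi * n / gt$D[i, j], gt$sigma_c * sqrt(n))
        K <- azimuthal_kernel(phi, gt$theta[i, j], gt$kappa)
        lam <- lam + gt$amp_collagen * outer(K, radial)
      } else if (lab == "muscle" && gt$muscle_present) {
        d10 <- gt$d10[i, j]
        radial <- gauss_density(q, 2 * pi / d10, gt$sigma_m) +
          gt$rho * gauss_density(q, 2 * pi / (d10 / sqrt(3)), gt$sigma_m)
        K <- azimuthal_kernel(phi, gt$theta[i, j] + 90, gt$kappa_m)
        lam <- lam + gt$amp_muscle * outer(K, radial)
      } else if (lab == "other") {
        radial <- 0
        for (k in seq_len(nrow(gt$other_peaks)))
          radial <- radial + gt$other_peaks$amp[k] *
            exp(-(q - gt$other_peaks$center[k])^2 /
                  (2 * gt$other_peaks$sigma[k]^2))
        lam <- lam + outer(ones, radial)
      }
      if (poisson) lam[] <- stats::rpois(length(lam), lam)
      intensity[i, j, , ] <- lam
    }
  }
  reduced_scan(intensity, grid, transmission = gt$transmission,
               exposure_s = 0.1, step_um = 25)
}

#' Forward-simulate a raw detector frame for one scan point
#'
#' Evaluates the same radial/azimuthal model as [simulate_reduced_scan()]
#' at every unmasked pixel's (q, phi) and Poisson-samples it; exercises the
#' reduction module.
#'
#' @param gt a [make_ground_truth()] result.
#' @param row,col scan-point indices.
#' @param geometry a [detector_geometry()].
#' @param seed integer seed.
#' @param poisson sample counting noise?
#' @return a [detector_frame()].
#' @export
simulate_detector_frame <- function(gt, row, col, geometry, seed = 1,
                                    poisson = TRUE) {
  stopifnot(inherits(gt, "ground_truth"),
            inherits(geometry, "detector_geometry"))
  qp <- pixel_q_phi(geometry)
  lam <- point_expected_intensity(gt, row, col, pmax(qp$q, 1e-6), qp$phi)
  dim(lam) <- geometry$dims
  set.seed(seed)
  counts <- if (poisson) {
    m <- matrix(stats::rpois(length(lam), lam), geometry$dims[1])
  } else lam
  counts[geometry$mask] <- 0
  detector_frame(counts, geometry)
}
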