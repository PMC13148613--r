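#' Azimuthal band profile of a scan point
#'
#' Per-sector mean intensity over the valid q bins of a band; the input to
#' the cosine orientation fit.
#'
#' @param slab one scan point's `[n_seg, n_q]` intensity matrix.
#' @param grid the scan's [qaz_grid()].
#' @param band q interval, nm^-1.
#' @return numeric vector length `n_seg`; sectors with no valid bin carry
#'   the sentinel. If more than half the sectors are sentinel the vector is
#'   returned with attribute `unfit = TRUE`.
#' @export
band_profile <- function(slab, grid, band) {
  idx <- q_window_bins(grid, band)
  sub <- slab[, idx, drop = FALSE]
  sub[!is_valid_bin(sub)] <- NA_real_
  v <- rowMeans(sub, na.rm = TRUE)
  v[!is.finite(v)] <- SENTINEL
  if (sum(v == SENTINEL) > length(v) / 2) attr(v, "unfit") <- TRUE
  v
}

#' Fit the pi-periodic cosine model to an azimuthal profile
#'
#' Model: `I(phi) = a_sym + a_asym * cos(2*(phi - theta_s))`. With all
#' sectors valid on a uniform grid the parameters are the discrete 2-phi
#' Fourier component, which the cosine basis reproduces exactly by
#' orthogonality: `a_sym = mean(I)`,
#' `c2 = (2/N) * sum(I_k * exp(2i*phi_k))`, `a_asym = |c2|`,
#' `theta_s = Arg(c2)/2` mapped to \[0, 180). With masked sectors the same
#' model is fitted by least squares on the basis
#' `{1, cos(2*phi), sin(2*phi)}`.
#'
#' @param az azimuthal intensity vector (length `n_seg`); sentinel entries
#'   are treated as missing.
#' @param phi_centers sector centres, degrees.
#' @param min_valid minimum number of valid sectors (default 8).
#' @return object of class `orientation_fit`: `a_sym`, `a_asym`, `theta_s`
#'   (degrees in \[0, 180), `NA` when isotropic), `degree`
#'   (`a_asym / a_sym`), `n_valid`, `method` ("fourier" or "lsq").
#' @export
fit_azimuthal_orientation <- function(az, phi_centers, min_valid = 8) {
  stopifnot(length(az) == length(phi_centers))
  ok <- is_valid_bin(az)
  out <- list(a_sym = NA_real_, a_asym = NA_real_, theta_s = NA_real_,
              degree = NA_real_, n_valid = sum(ok), method = NA_character_)
  class(out) <- "orientation_fit"
  if (sum(ok) < min_valid) return(out)
  phir <- phi_centers * pi / 180
  if (all(ok)) {
    a0 <- mean(az)
    c2 <- (2 / length(az)) * sum(az * exp(2i * phir))
    a2 <- Mod(c2)
    th <- (Arg(c2) / 2 * 180 / pi) %% 180
    out$method <- "fourier"
  } else {
    X <- cbind(1, cos(2 * phir[ok]), sin(2 * phir[ok]))
    cf <- stats::lsfit(X, az[ok], intercept = FALSE)$coefficients
    a0 <- cf[1]
    a2 <- sqrt(cf[2]^2 + cf[3]^2)
    th <- (atan2(cf[3], cf[2]) / 2 * 180 / pi) %% 180
    out$method <- "lsq"
  }
  if (!is.finite(a0) || a0 <= 0) return(out)
  out$a_sym <- unname(a0)
  out$a_asym <- unname(a2)
  out$degree <- unname(a2 / a0)
  # below ~1e-10 relative anisotropy the direction is numerical noise
  out$theta_s <- if (a2 > 1e-10 * a0) unname(th)
                 else NA_real_   # isotropic: direction undefined
  out
}

#' Fibre long-axis direction from the scattering-anisotropy direction
#'
#' Collagen scatters meridionally: the fibril long axis lies along the
#' anisotropy direction. Myofibril equatorial scattering is perpendicular to
#' the fibre axis, so in equatorial mode the axis is `theta_s + 90` mod 180.
#'
#' @param theta_s anisotropy direction, degrees.
#' @param mode `"meridional"` (collagen) or `"equatorial"` (myofibril).
#' @return fibre axis direction, degrees in \[0, 180).
#' @export
fiber_axis <- function(theta_s, mode = c("meridional", "equatorial")) {
  mode <- match.arg(mode)
  if (mode == "meridional") theta_s %% 180 else (theta_s + 90) %% 180
}

#' Orientation analysis of every scan point in a band
#'
#' @param scan a [reduced_scan()].
#' @param band q interval, nm^-1 (collagen first-order band
#'   `c(0.085, 0.11)`; myofibril band `c(0.231, 0.367)`).
#' @param min_valid minimum valid sectors per point.
#' @return object of class `orientation_map`: matrices `a_sym`, `a_asym`,
#'   `theta_s`, `degree` `[ny, nx]` and the `band`.
#' @export
orient_scan <- function(scan, band, min_valid = 8) {
  stopifnot(inherits(scan, "reduced_scan"))
  d <- dim(scan$intensity)
  idx <- q_window_bins(scan$grid, band)
  a_sym <- a_asym <- theta_s <- degree <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      az <- band_profile(scan$intensity[i, j, , ], scan$grid, band)
      f <- fit_azimuthal_orientation(az, scan$grid$phi_centers, min_valid)
      a_sym[i, j] <- f$a_sym
      a_asym[i, j] <- f$a_asym
      theta_s[i, j] <- f$theta_s
      degree[i, j] <- f$degree
    }
  }
  structure(list(a_sym = a_sym, a_asym = a_asym, theta_s = theta_s,
                 degree = degree, band = band), class = "orientation_map")
}

#' Render an orientation map as an RGB image
#'
#' Hue encodes the anisotropy direction `theta_s` on the 180-degree colour
#' wheel. In `"hv"` mode (saturation = 1) value encodes `a_asym`; in `"hsv"`
#' mode value encodes `a_sym` and saturation `a_asym`. Value/saturation
#' channels are rescaled to the stated percentiles.
#'
#' @param omap an [orient_scan()] result.
#' @param mode `"hv"` or `"hsv"`.
#' @param percentiles length-2 probabilities used to normalize the intensity
#'   channels (default `c(0.01, 0.99)`).
#' @return numeric array `[ny, nx, 3]` of RGB in \[0, 1\].
#' @export
render_orientation_map <- function(omap, mode = c("hv", "hsv"),
                                   percentiles = c(0.01, 0.99)) {
  mode <- match.arg(mode)
  h <- (omap$theta_s %% 180) / 180
  h[is.na(h)] <- 0
  rescale <- function(m) {
    v <- m
    v[is.na(v)] <- 0
    qs <- stats::quantile(v, percentiles, na.rm = TRUE)
    # constant positive channel: render at full scale, not black
    if (diff(qs) <= 0)
      return(matrix(as.numeric(v > 0), nrow(m), ncol(m)))
    pmin(pmax((v - qs[1]) / diff(qs), 0), 1)
  }
  if (mode == "hv") {
    s <- matrix(1, nrow(h), ncol(h))
    v <- rescale(omap$a_asym)
  } else {
    s <- rescale(omap$a_asym)
    v <- rescale(omap$a_sym)
  }
  col <- grDevices::hsv(as.vector(h), as.vector(s), as.vector(v))
  rgb <- grDevices::col2rgb(col) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim = c(nrow(h), ncol(h), 3))
}

#' Render a region map as an RGB image
#'
#' Colour scheme: collagen light gray/white, muscle orange, other green,
#' background black.
#' @param rmap a [segment_regions()] result.
#' @return numeric array `[ny, nx, 3]`.
#' @export
render_region_map <- function(rmap) {
  pal <- list(background = c(0, 0, 0), collagen = c(0.9, 0.9, 0.9),
              muscle = c(1, 0.55, 0), other = c(0.1, 0.7, 0.2))
  lab <- rmap$label
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (nm in names(pal))
    for (k in 1:3)
      out[, , k][lab == nm] <- pal[[nm]][k]
  out
}

#' Write an RGB (or grayscale) image array to PNG
#' @param img array `[ny, nx, 3]` or matrix in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
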