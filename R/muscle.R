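#' Extract the equatorial 1D profile of a muscle point
#'
#' Same nearest-opposite-sector-pair rule as the collagen meridional
#' extraction, applied along the equatorial scattering direction obtained
#' from the myofibril-band orientation fit.
#'
#' @param slab one scan point's `[n_seg, n_q]` intensity matrix.
#' @param grid the scan's [qaz_grid()].
#' @param theta_eq equatorial scattering direction, degrees.
#' @return numeric vector length `n_q`.
#' @export
extract_equatorial_profile <- function(slab, grid, theta_eq) {
  opposite_sector_profile(slab, grid, theta_eq)
}

#' Fit the (1,0)/(1,1) equatorial doublet
#'
#' Independent local-background Gaussian fits (the [fit_peak()] machinery)
#' in two non-overlapping windows bracketing the hexagonal-lattice
#' reflections.
#'
#' @param q,intensity the 1D equatorial profile.
#' @param window10 q window for the (1,0) peak, nm^-1 (default
#'   `c(0.14, 0.21)`).
#' @param window11 q window for the (1,1) peak (default `c(0.24, 0.34)`).
#' @param snr_min visibility threshold (default 3).
#' @return list with elements `fit10` and `fit11` ([fit_peak()] objects).
#' @export
fit_equatorial_doublet <- function(q, intensity, window10 = c(0.14, 0.21),
                                   window11 = c(0.24, 0.34), snr_min = 3) {
  if (window10[2] > window11[1]) stop("doublet windows must not overlap")
  list(fit10 = fit_peak(q, intensity, window10, snr_min = snr_min),
       fit11 = fit_peak(q, intensity, window11, snr_min = snr_min))
}

#' Myofilament lattice parameters from the equatorial peak positions
#'
#' Plane spacings `d = 2*pi/q` and the hexagonal lattice constant
#' `a = 2*d10/sqrt(3)`. For a geometrically consistent hexagonal lattice
#' `d10/d11 = sqrt(3)`; the `consistent` flag records whether the measured
#' pair is within 10% of that identity.
#'
#' @param q10,q11 peak centres, nm^-1 (`NA` when not visible).
#' @return list: `d10`, `d11` (nm), `a` (nm), `consistent` (logical, `NA`
#'   when either spacing is missing); `NULL` when both are missing.
#' @export
compute_lattice <- function(q10, q11) {
  h10 <- is.finite(q10) && q10 > 0
  h11 <- is.finite(q11) && q11 > 0
  if (!h10 && !h11) return(NULL)
  d10 <- if (h10) 2 * pi / q10 else NA_real_
  d11 <- if (h11) 2 * pi / q11 else NA_real_
  a <- if (h10) 2 * d10 / sqrt(3) else NA_real_
  consistent <- if (h10 && h11) abs(d10 / (d11 * sqrt(3)) - 1) < 0.1
                else NA
  list(d10 = d10, d11 = d11, a = a, consistent = consistent)
}

#' I11/I10 equatorial intensity ratio
#'
#' Ratio of integrated (1,1) to (1,0) intensities; low in resting muscle,
#' strongly elevated in rigor as myosin mass shifts toward the thin
#' filaments. `NULL` when either peak is not visible.
#'
#' @param fit10,fit11 [fit_peak()] results for the doublet.
#' @return numeric ratio, or `NULL`.
#' @export
compute_i11_over_i10 <- function(fit10, fit11) {
  if (!isTRUE(fit10$visible) || !isTRUE(fit11$visible)) return(NULL)
  fit11$area / fit10$area
}

#' Analyze all muscle points of a scan
#'
#' For every muscle-labelled point: extracts the equatorial profile along
#' the myofibril-band anisotropy direction, fits the (1,0)/(1,1) doublet and
#' derives spacings, lattice constant, widths and the I11/I10 ratio.
#'
#' @param scan a [reduced_scan()].
#' @param region a [segment_regions()] result.
#' @param orientation an [orient_scan()] result on the myofibril band
#'   (q = 0.231-0.367 nm^-1).
#' @param window10,window11 doublet fit windows, nm^-1.
#' @param snr_min visibility threshold.
#' @return data.frame, one row per muscle point: `row`, `col`, `theta_eq`,
#'   `q10`, `q11`, `d10`, `d11`, `a`, `fwhm10`, `fwhm11`, `i11_over_i10`,
#'   `vis10`, `vis11`, `consistent`.
#' @export
analyze_muscle_points <- function(scan, region, orientation,
                                  window10 = c(0.14, 0.21),
                                  window11 = c(0.24, 0.34), snr_min = 3) {
  stopifnot(inherits(scan, "reduced_scan"), inherits(region, "region_map"))
  pts <- which(region$label == "muscle", arr.ind = TRUE)
  qc <- scan$grid$q_centers
  n <- nrow(pts)
  out <- data.frame(row = integer(n), col = integer(n),
                    theta_eq = NA_real_, q10 = NA_real_, q11 = NA_real_,
                    d10 = NA_real_, d11 = NA_real_, a = NA_real_,
                    fwhm10 = NA_real_, fwhm11 = NA_real_,
                    i11_over_i10 = NA_real_, vis10 = FALSE, vis11 = FALSE,
                    consistent = NA)
  for (p in seq_len(n)) {
    i <- pts[p, 1]; j <- pts[p, 2]
    out$row[p] <- i; out$col[p] <- j
    th <- orientation$theta_s[i, j]
    prof <- if (is.finite(th))
      extract_equatorial_profile(scan$intensity[i, j, , ], scan$grid, th)
    else azimuthal_mean_profile(scan, i, j)
    out$theta_eq[p] <- th
    db <- fit_equatorial_doublet(qc, prof, window10, window11, snr_min)
    f10 <- db$fit10; f11 <- db$fit11
    out$vis10[p] <- f10$visible
    out$vis11[p] <- f11$visible
    if (f10$visible) { out$q10[p] <- f10$center; out$fwhm10[p] <- f10$fwhm }
    if (f11$visible) { out$q11[p] <- f11$center; out$fwhm11[p] <- f11$fwhm }
    lat <- compute_lattice(out$q10[p], out$q11[p])
    if (!is.null(lat)) {
      out$d10[p] <- lat$d10; out$d11[p] <- lat$d11; out$a[p] <- lat$a
      out$consistent[p] <- lat$consistent
    }
    rr <- compute_i11_over_i10(f10, f11)
    if (!is.null(rr)) out$i11_over_i10[p] <- rr
  }
  out
}
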