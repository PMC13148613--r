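# Shared sector-pair extraction: mean of the two opposite sectors whose
# centres lie nearest theta and theta + 180 (degrees).
opposite_sector_profile <- function(slab, grid, theta) {
  stopifnot(is.finite(theta))
  angdist <- function(a, b) {
    d <- abs((a - b) %% 360)
    pmin(d, 360 - d)
  }
  k1 <- which.min(angdist(grid$phi_centers, theta %% 360))
  # the exact opposite sector (n_seg is even, sectors tile the circle)
  k2 <- ((k1 - 1 + grid$n_seg / 2) %% grid$n_seg) + 1
  p1 <- slab[k1, ]
  p2 <- slab[k2, ]
  v1 <- is_valid_bin(p1)
  v2 <- is_valid_bin(p2)
  out <- rep(SENTINEL, length(p1))
  both <- v1 & v2
  out[both] <- (p1[both] + p2[both]) / 2
  out[v1 & !v2] <- p1[v1 & !v2]
  out[v2 & !v1] <- p2[v2 & !v1]
  if (!any(v1) || !any(v2)) attr(out, "single_sector") <- TRUE
  attr(out, "sectors") <- c(k1, k2)
  out
}

#' Extract the meridional 1D profile of a collagen point
#'
#' Averages the two opposite azimuth sectors whose centres are nearest the
#' meridional scattering direction `theta_s` and `theta_s + 180`. If one
#' sector is entirely invalid the other is used alone and the result is
#' flagged (`attr "single_sector"`).
#'
#' @param slab one scan point's `[n_seg, n_q]` intensity matrix.
#' @param grid the scan's [qaz_grid()].
#' @param theta_s meridional direction from the collagen-band orientation
#'   fit, degrees.
#' @return numeric vector length `n_q`.
#' @export
extract_meridional_profile <- function(slab, grid, theta_s) {
  opposite_sector_profile(slab, grid, theta_s)
}

#' Collagen D-period from a Bragg peak position
#'
#' Bragg's law for the order-n meridional reflection: `D = 2*pi*n / q_n`.
#'
#' @param n Bragg order (1-10).
#' @param q_n peak centre, nm^-1; must be positive.
#' @return D-period, nm.
#' @export
compute_d_period <- function(n, q_n) {
  stopifnot(n %in% 1:10)
  if (any(q_n <= 0)) stop("q_n must be > 0")
  2 * pi * n / q_n
}

#' Forward intensity ratio of consecutive meridional orders
#'
#' Two-phase (gap/overlap step-density) model of the axial electron
#' density: the integrated intensity of order n is proportional to
#' `sin^2(pi*n*x) / (pi*n)^2` with x the overlap fraction O/D. The ratio of
#' consecutive orders is then
#' `r(x) = [n/(n+1)]^2 * sin^2((n+1)*pi*x) / sin^2(n*pi*x)`.
#'
#' @param x overlap fraction in (0, 1).
#' @param n lower order (default 5: the I6/I5 pair).
#' @return the ratio `I_{n+1} / I_n`.
#' @export
order_intensity_ratio <- function(x, n = 5) {
  (n / (n + 1))^2 * sin((n + 1) * pi * x)^2 / sin(n * pi * x)^2
}

# per-order weight of the step-density model (used by the simulator too)
order_weight <- function(n, x) sin(pi * n * x)^2 / (pi * n)^2

#' Ratio of sixth- to fifth-order integrated peak intensities
#'
#' Dehydration damage raises this ratio. Uses the integrated areas of the
#' two Gaussian fits; `NULL` when either peak is not visible.
#'
#' @param fit5,fit6 [fit_peak()] results for orders 5 and 6.
#' @return numeric ratio, or `NULL`.
#' @export
compute_i6_over_i5 <- function(fit5, fit6) {
  if (!isTRUE(fit5$visible) || !isTRUE(fit6$visible)) return(NULL)
  fit6$area / fit5$area
}

#' Solve the overlap/D-period fraction from consecutive order intensities
#'
#' Inverts the two-phase step-density ratio
#' `r = [n/(n+1)]^2 * sin^2((n+1)*pi*x) / sin^2(n*pi*x)` for the overlap
#' fraction x by a dense grid scan over the bracket followed by bisection
#' refinement. The equation has multiple roots; the structurally reasonable
#' one is taken as the root closest to the intact hydrated-fibril reference
#' 0.46.
#'
#' Identifiability: the ratio r(x) for n = 5 has a pole at x = 0.4 (the
#' fifth order is extinct there) and is strictly decreasing on (0.4, 0.5],
#' so the inversion is exact on that branch. For a true x below 0.4 the
#' same ratio also occurs at a conjugate point above 0.4, which is closer
#' to the reference and is therefore the root returned: overlap fractions
#' below the fifth-order extinction are not identifiable from the I6/I5
#' ratio alone under the closest-to-reference rule.
#'
#' @param i_n integrated intensity of order n (> 0).
#' @param i_n1 integrated intensity of order n+1 (>= 0). Zero maps to
#'   x = 0.5 exactly (even orders vanish for a symmetric gap/overlap).
#' @param n lower order (default 5).
#' @param bracket search interval for x (default `c(0.35, 0.55)`).
#' @param reference root-selection anchor (default 0.46).
#' @param step grid-scan resolution (default 1e-4).
#' @return overlap fraction x, or `NULL` when no root lies in the bracket.
#' @export
solve_overlap_fraction <- function(i_n, i_n1, n = 5,
                                   bracket = c(0.35, 0.55),
                                   reference = 0.46, step = 1e-4) {
  if (i_n <= 0) stop("i_n must be > 0")
  if (i_n1 < 0) stop("i_n1 must be >= 0")
  r <- i_n1 / i_n
  if (r == 0) return(0.5)  # even orders vanish for symmetric gap/overlap
  f <- function(x) order_intensity_ratio(x, n) - r
  xs <- seq(bracket[1], bracket[2], by = step)
  # exclude the poles of r(x) where sin(n*pi*x) ~ 0 (e.g. x = 0.4 for n = 5)
  fin <- abs(sin(n * pi * xs)) > 1e-6
  fx <- rep(NA_real_, length(xs))
  fx[fin] <- f(xs[fin])
  roots <- c()
  for (k in seq_len(length(xs) - 1)) {
    if (!is.finite(fx[k]) || !is.finite(fx[k + 1])) next
    if (fx[k] == 0) roots <- c(roots, xs[k])
    else if (fx[k] * fx[k + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(xs[k], xs[k + 1]),
                                       tol = 1e-10)$root)
  }
  if (is.finite(fx[length(xs)]) && fx[length(xs)] == 0)
    roots <- c(roots, xs[length(xs)])
  if (length(roots) == 0) return(NULL)
  roots[which.min(abs(roots - reference))]
}

#' Analyze all collagen points of a scan
#'
#' For every collagen-labelled point: extracts the meridional profile along
#' the collagen-band anisotropy direction, fits a Gaussian per requested
#' Bragg order in a window `2*pi*n/d_ref * (1 +/- tol)`, and derives the
#' D-period (orders 5 and 6), FWHM, I6/I5 and overlap fraction O/D. Order 1
#' is fitted for normalized per-order intensities but excluded from
#' D estimation (too few bins on the rising edge), as is order 3 (overlap
#' with muscle equatorial peaks).
#'
#' @param scan a [reduced_scan()].
#' @param region a [segment_regions()] result.
#' @param orientation an [orient_scan()] result on the collagen band.
#' @param orders integer vector of Bragg orders to fit (default `c(1, 5, 6)`;
#'   use `1:10` for the full prevalence table).
#' @param d_ref reference D-period defining search windows, nm (default 67).
#' @param tol window half-width as fraction of the central q (default 0.06).
#' @param snr_min peak visibility threshold (default 3).
#' @return data.frame, one row per collagen point: `row`, `col`, `theta_s`,
#'   per-order `q_n`, `fwhm_n`, `area_n`, `vis_n`, plus `D5`, `D6`,
#'   `fwhm5`, `fwhm6`, `i6_over_i5`, `overlap_fraction`, `d_outlier`.
#' @export
analyze_collagen_points <- function(scan, region, orientation,
                                    orders = c(1, 5, 6), d_ref = 67,
                                    tol = 0.06, snr_min = 3) {
  stopifnot(inherits(scan, "reduced_scan"), inherits(region, "region_map"))
  pts <- which(region$label == "collagen", arr.ind = TRUE)
  qc <- scan$grid$q_centers
  rows <- vector("list", nrow(pts))
  for (p in seq_len(nrow(pts))) {
    i <- pts[p, 1]; j <- pts[p, 2]
    th <- orientation$theta_s[i, j]
    prof <- if (is.finite(th))
      extract_meridional_profile(scan$intensity[i, j, , ], scan$grid, th)
    else azimuthal_mean_profile(scan, i, j)
    rec <- list(row = i, col = j, theta_s = th)
    fits <- list()
    for (n in orders) {
      win <- 2 * pi * n / d_ref * c(1 - tol, 1 + tol)
      pf <- fit_peak(qc, prof, win, snr_min = snr_min, order = n)
      fits[[as.character(n)]] <- pf
      rec[[paste0("q_", n)]] <- if (pf$visible) pf$center else NA_real_
      rec[[paste0("fwhm_", n)]] <- if (pf$visible) pf$fwhm else NA_real_
      rec[[paste0("area_", n)]] <- if (pf$visible) pf$area else NA_real_
      rec[[paste0("vis_", n)]] <- pf$visible
    }
    for (n in intersect(c(5, 6), orders)) {
      qn <- rec[[paste0("q_", n)]]
      rec[[paste0("D", n)]] <- if (is.finite(qn)) compute_d_period(n, qn)
                               else NA_real_
    }
    f5 <- fits[["5"]]; f6 <- fits[["6"]]
    r65 <- if (!is.null(f5) && !is.null(f6)) compute_i6_over_i5(f5, f6)
           else NULL
    rec$i6_over_i5 <- if (is.null(r65)) NA_real_ else r65
    rec$overlap_fraction <- NA_real_
    if (!is.null(r65) && f5$area > 0) {
      x <- solve_overlap_fraction(f5$area, f6$area, n = 5)
      if (!is.null(x)) rec$overlap_fraction <- x
    }
    d5 <- rec$D5 %||% NA_real_; d6 <- rec$D6 %||% NA_real_
    rec$d_outlier <- (is.finite(d5) && (d5 < 55 || d5 > 75)) ||
                     (is.finite(d6) && (d6 < 55 || d6 > 75))
    if (1 %in% orders && isTRUE(rec$vis_1) && rec$area_1 > 0) {
      for (n in setdiff(orders, 1))
        rec[[paste0("rel_", n)]] <- if (isTRUE(rec[[paste0("vis_", n)]]))
          rec[[paste0("area_", n)]] / rec$area_1 else NA_real_
      rec$rel_1 <- 1
    }
    rows[[p]] <- rec
  }
  if (length(rows) == 0) return(data.frame())
  nms <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    r[setdiff(nms, names(r))] <- NA
    as.data.frame(r[nms])
  }))
}

#' Per-order prevalence and normalized-intensity table
#'
#' For orders n = 1..10: `A` is the median over collagen points (with both
#' order n and order 1 visible) of the order-n integrated intensity
#' normalized against the first-order intensity; `B` is the fraction of all
#' collagen points with a visible order-n peak.
#'
#' @param points data.frame from [analyze_collagen_points()] run with
#'   `orders = 1:10` (or any superset of interest).
#' @param orders orders to tabulate (default `1:10`).
#' @return data.frame with columns `order`, `A`, `B`.
#' @export
peak_prevalence_table <- function(points, orders = 1:10) {
  if (nrow(points) == 0) stop("no collagen points")
  out <- data.frame(order = orders, A = NA_real_, B = NA_real_)
  for (k in seq_along(orders)) {
    n <- orders[k]
    vcol <- paste0("vis_", n)
    if (!vcol %in% names(points)) next
    vis_n <- points[[vcol]] %in% TRUE
    out$B[k] <- sum(vis_n) / nrow(points)
    rcol <- paste0("rel_", n)
    if (rcol %in% names(points)) {
      vals <- points[[rcol]][vis_n & points$vis_1 %in% TRUE]
      vals <- vals[is.finite(vals)]
      if (length(vals) > 0) out$A[k] <- stats::median(vals)
    }
  }
  out
}
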