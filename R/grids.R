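# Sentinel marking missing / invalid intensity bins. Negative by construction:
# physical intensities are non-negative, so the mask survives serialization.
SENTINEL <- -1

#' Is a bin value valid (not the missing sentinel)?
#' @param x numeric vector or array of intensities.
#' @return logical of the same shape; `TRUE` where the value is finite and
#'   non-negative.
#' @export
is_valid_bin <- function(x) is.finite(x) & x >= 0

#' Construct a q/azimuth binning grid
#'
#' Defines the reduced-data geometry: `n_q` radial bins over a scattering
#' vector interval (nm^-1) and `n_seg` azimuth sectors tiling \[0, 360)
#' degrees. Azimuth is measured counterclockwise from the detector +x axis.
#'
#' @param q_min,q_max q range covered by the grid, nm^-1.
#' @param n_q number of radial bins (default 1200).
#' @param n_seg number of azimuth sectors (default 16); must be even so that
#'   sectors come in opposite pairs.
#' @param phi0 azimuth of the first sector's lower edge, degrees.
#' @return an object of class `qaz_grid` with fields `q_centers`, `q_edges`,
#'   `phi_centers`, `phi_edges`, `n_q`, `n_seg`.
#' @export
qaz_grid <- function(q_min = 0.05, q_max = 0.65, n_q = 1200, n_seg = 16,
                     phi0 = 0) {
  stopifnot(q_min > 0, q_max > q_min, n_q >= 2, n_seg >= 2)
  if (n_seg %% 2 != 0)
    stop("n_seg must be even: azimuth sectors must come in opposite pairs")
  q_edges <- seq(q_min, q_max, length.out = n_q + 1)
  phi_edges <- phi0 + seq(0, 360, length.out = n_seg + 1)
  g <- list(
    q_centers = (q_edges[-1] + q_edges[-(n_q + 1)]) / 2,
    q_edges = q_edges,
    phi_centers = ((phi_edges[-1] + phi_edges[-(n_seg + 1)]) / 2) %% 360,
    phi_edges = phi_edges %% 360,
    n_q = as.integer(n_q),
    n_seg = as.integer(n_seg)
  )
  class(g) <- "qaz_grid"
  g
}

validate_qaz_grid <- function(g) {
  stopifnot(inherits(g, "qaz_grid"))
  if (any(!is.finite(g$q_centers))) stop("NaN in q grid")
  if (any(diff(g$q_centers) <= 0)) stop("q_centers must be strictly increasing")
  if (length(g$q_centers) != g$n_q) stop("q grid length mismatch")
  if (length(g$phi_centers) != g$n_seg) stop("phi grid length mismatch")
  invisible(g)
}

#' @export
print.qaz_grid <- function(x, ...) {
  cat(sprintf("<qaz_grid> %d q bins on [%.4g, %.4g] nm^-1, %d azimuth sectors\n",
              x$n_q, min(x$q_edges), max(x$q_edges), x$n_seg))
  invisible(x)
}

# q-bin index for arbitrary q values; 0 / n_q+1 outside the grid
q_bin_index <- function(grid, q) findInterval(q, grid$q_edges,
                                              rightmost.closed = TRUE)

# azimuth sector index for angles in degrees (any real); sectors tile [0,360)
phi_bin_index <- function(grid, phi) {
  phi0 <- grid$phi_edges[1]
  w <- 360 / grid$n_seg
  (floor(((phi - phi0) %% 360) / w) %% grid$n_seg) + 1L
}

# smallest q-bin index range covering a q interval [lo, hi]
q_window_bins <- function(grid, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- which(grid$q_centers >= window[1] & grid$q_centers <= window[2])
  if (length(idx) == 0)
    stop(sprintf("q window [%g, %g] contains no grid bins", window[1], window[2]))
  idx
}
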