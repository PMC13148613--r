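#' Construct a reduced scan
#'
#' A `reduced_scan` is the pipeline's universal input: the azimuthally
#' segmented intensity of a raster scan, one `[n_seg, n_q]` slab per scan
#' point, stored as a 4D array `[ny, nx, n_seg, n_q]` together with the
#' transmission map and acquisition metadata. Row 1 is the top of rendered
#' maps. Invalid bins carry a negative sentinel and are excluded from all
#' fits.
#'
#' @param intensity numeric array `[ny, nx, n_seg, n_q]`; non-negative
#'   counts, or the negative sentinel for missing bins.
#' @param grid a [qaz_grid()] matching dims 3 and 4 of `intensity`.
#' @param transmission numeric matrix `[ny, nx]` in (0, 1]; defaults to 1.
#' @param exposure_s exposure per scan point, seconds (default 0.1).
#' @param step_um scan grid pitch, micrometres (default 25).
#' @param normalized has transmission/exposure normalization been applied?
#' @return an object of class `reduced_scan`.
#' @export
reduced_scan <- function(intensity, grid, transmission = NULL,
                         exposure_s = 0.1, step_um = 25,
                         normalized = FALSE) {
  validate_qaz_grid(grid)
  d <- dim(intensity)
  if (length(d) != 4)
    stop("intensity must be a 4D array [ny, nx, n_seg, n_q]")
  if (d[3] != grid$n_seg || d[4] != grid$n_q)
    stop(sprintf("intensity dims [%d, %d] do not match grid (%d segments, %d q bins)",
                 d[3], d[4], grid$n_seg, grid$n_q))
  if (is.null(transmission))
    transmission <- matrix(1, d[1], d[2])
  if (!all(dim(transmission) == d[1:2]))
    stop("transmission map not congruent with scan grid")
  if (any(!is.finite(transmission)) || any(transmission <= 0) ||
      any(transmission > 1))
    stop("transmission must be finite and in (0, 1]")
  bad <- !is.finite(intensity)
  if (any(bad)) intensity[bad] <- SENTINEL
  s <- list(intensity = intensity, grid = grid, transmission = transmission,
            exposure_s = exposure_s, step_um = step_um,
            normalized = isTRUE(normalized))
  class(s) <- "reduced_scan"
  s
}

#' @export
print.reduced_scan <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<reduced_scan> %d x %d points, %d sectors x %d q bins; %s\n",
              d[1], d[2], d[3], d[4],
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.reduced_scan <- function(x) dim(x$intensity)

#' Extract one scan point's [n_seg, n_q] intensity slab
#' @param scan a `reduced_scan`.
#' @param row,col 1-based scan-point indices.
#' @return numeric matrix `[n_seg, n_q]`.
#' @export
scan_point <- function(scan, row, col) {
  scan$intensity[row, col, , ]
}

#' Azimuthally averaged 1D profile of one scan point
#'
#' Mean over sectors per q bin, ignoring sentinel bins; bins invalid in all
#' sectors come back as the sentinel.
#' @inheritParams scan_point
#' @return numeric vector length `n_q`.
#' @export
azimuthal_mean_profile <- function(scan, row, col) {
  slab <- scan_point(scan, row, col)
  slab[!is_valid_bin(slab)] <- NA_real_
  p <- colMeans(slab, na.rm = TRUE)
  p[!is.finite(p)] <- SENTINEL
  p
}
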