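#' Flat-detector geometry
#'
#' @param sample_detector_distance_mm sample-to-detector distance along the
#'   beam, millimetres.
#' @param pixel_size_um square pixel pitch, micrometres.
#' @param beam_center_px direct-beam position `(row, col)` in pixel units
#'   (1-based, may be fractional).
#' @param wavelength_nm X-ray wavelength, nanometres.
#' @param dims frame dimensions `(rows, cols)`.
#' @param mask logical matrix `[rows, cols]`; `TRUE` pixels are excluded
#'   from every bin. Default: nothing masked.
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(sample_detector_distance_mm = 2000,
                              pixel_size_um = 172,
                              beam_center_px = NULL,
                              wavelength_nm = 0.1,
                              dims = c(192, 192),
                              mask = NULL) {
  stopifnot(sample_detector_distance_mm > 0, pixel_size_um > 0,
            wavelength_nm > 0, length(dims) == 2, all(dims >= 2))
  if (is.null(beam_center_px)) beam_center_px <- (dims + 1) / 2
  if (beam_center_px[1] < 1 || beam_center_px[1] > dims[1] ||
      beam_center_px[2] < 1 || beam_center_px[2] > dims[2])
    stop("beam center must lie inside the frame")
  if (is.null(mask)) mask <- matrix(FALSE, dims[1], dims[2])
  stopifnot(all(dim(mask) == dims))
  g <- list(sample_detector_distance_mm = sample_detector_distance_mm,
            pixel_size_um = pixel_size_um,
            beam_center_px = beam_center_px,
            wavelength_nm = wavelength_nm,
            dims = as.integer(dims),
            mask = mask)
  class(g) <- "detector_geometry"
  g
}

# per-pixel (q, phi): exact flat-detector relation
# q = (4*pi/lambda) * sin(0.5 * atan(r / L)); phi counterclockwise from +x,
# with detector row 1 at the top (+y up in lab frame means -row direction).
pixel_q_phi <- function(geometry) {
  px_mm <- geometry$pixel_size_um / 1000
  rows <- seq_len(geometry$dims[1])
  cols <- seq_len(geometry$dims[2])
  dy <- -(rows - geometry$beam_center_px[1]) * px_mm   # lab +y is up
  dx <- outer(rep(1, length(rows)), (cols - geometry$beam_center_px[2]) * px_mm)
  dym <- outer(dy, rep(1, length(cols)))
  r <- sqrt(dx^2 + dym^2)
  q <- (4 * pi / geometry$wavelength_nm) *
    sin(0.5 * atan(r / geometry$sample_detector_distance_mm))
  phi <- (atan2(dym, dx) * 180 / pi) %% 360
  list(q = q, phi = phi)
}

#' Construct a raw detector frame
#' @param counts non-negative integer-valued matrix `[rows, cols]`.
#' @param geometry a [detector_geometry()] with matching dims.
#' @return object of class `detector_frame`.
#' @export
detector_frame <- function(counts, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"),
            all(dim(counts) == geometry$dims))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  f <- list(counts = counts, geometry = geometry)
  class(f) <- "detector_frame"
  f
}

#' Azimuthally integrate a detector frame
#'
#' Bins every unmasked pixel by its scattering vector magnitude and azimuth
#' and returns the per-bin mean count — the `[n_seg, n_q]` slab of one scan
#' point. Bins receiving no pixel carry the missing sentinel. The mean (not
#' the sum) makes bins comparable across unequal solid-angle coverage.
#'
#' @param frame a [detector_frame()].
#' @param grid a [qaz_grid()]; if its q range extends beyond the detector's
#'   accessible range, out-of-range bins are sentinel and a warning is
#'   issued.
#' @return numeric matrix `[n_seg, n_q]`.
#' @export
reduce_frame <- function(frame, grid) {
  stopifnot(inherits(frame, "detector_frame"))
  validate_qaz_grid(grid)
  geom <- frame$geometry
  use <- !geom$mask & is.finite(frame$counts)
  if (!any(use)) stop("all detector pixels are masked")
  qp <- pixel_q_phi(geom)
  qmax_det <- max(qp$q[use])
  if (max(grid$q_edges) > qmax_det * 1.0000001)
    warning("q grid extends beyond the detector's accessible q range; ",
            "out-of-range bins set to sentinel")
  iq <- q_bin_index(grid, qp$q[use])
  inq <- iq >= 1 & iq <= grid$n_q
  is <- phi_bin_index(grid, qp$phi[use])
  cnt <- frame$counts[use]
  keep <- inq
  idx <- (iq[keep] - 1L) * grid$n_seg + is[keep]   # column-major [n_seg, n_q]
  sums <- rowsum(cnt[keep], idx)
  npix <- rowsum(rep(1, sum(keep)), idx)
  out <- matrix(SENTINEL, grid$n_seg, grid$n_q)
  out[as.integer(rownames(sums))] <- sums / npix
  out
}

#' Estimate transmission from beamstop scatter
#'
#' Transmission is proxied by the ratio of counts scattered off the beamstop
#' (summed over a fixed detector ROI) to the same quantity from an
#' empty-beam reference, clipped to (0, 1] because the scatter proxy can
#' exceed the reference through noise.
#'
#' @param frame a [detector_frame()].
#' @param beamstop_roi integer vector `c(row_min, row_max, col_min, col_max)`.
#' @param empty_reference ROI count sum of the empty-beam frame; must be > 0.
#' @return transmission in (0, 1].
#' @export
estimate_transmission <- function(frame, beamstop_roi, empty_reference) {
  stopifnot(inherits(frame, "detector_frame"), length(beamstop_roi) == 4)
  if (empty_reference <= 0) stop("empty_reference must be > 0")
  roi <- frame$counts[beamstop_roi[1]:beamstop_roi[2],
                      beamstop_roi[3]:beamstop_roi[4]]
  s <- sum(roi, na.rm = TRUE)
  if (s <= 0) stop("zero counts in beamstop ROI: beam off?")
  t <- s / empty_reference
  if (t > 1) {
    warning(sprintf("transmission %.4f > 1 clipped to 1", t))
    t <- 1
  }
  t
}

#' Normalize a scan by transmission and exposure
#'
#' Divides every scan point's intensity by `transmission * exposure_s`.
#' Idempotent: a second call is a no-op. Sentinel bins stay sentinel.
#'
#' @param scan a [reduced_scan()].
#' @return the normalized `reduced_scan`.
#' @export
normalize_scan <- function(scan) {
  stopifnot(inherits(scan, "reduced_scan"))
  if (scan$normalized) return(scan)
  d <- dim(scan$intensity)
  denom <- scan$transmission * scan$exposure_s
  scale <- array(rep(1 / denom, times = d[3] * d[4]), dim = d)
  valid <- is_valid_bin(scan$intensity)
  scan$intensity[valid] <- scan$intensity[valid] * scale[valid]
  scan$normalized <- TRUE
  scan
}
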