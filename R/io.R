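#' Write a reduced scan to the HDF5 scan container
#'
#' One self-describing HDF5 file per scan. Layout: datasets
#' `/scan/intensity` `[ny, nx, n_seg, n_q]`, `/scan/q` (bin centres, nm^-1),
#' `/scan/q_edges`, `/scan/phi` (sector centres, degrees), `/scan/phi_edges`,
#' `/scan/transmission` `[ny, nx]`; group attributes `exposure_s`, `step_um`,
#' `normalized`.
#'
#' @param scan a [reduced_scan()].
#' @param path output file path.
#' @param overwrite overwrite an existing file? Default `FALSE` (refused).
#' @param compress gzip compression level 0-9 (default 4). Compression never
#'   changes the stored values.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, overwrite = FALSE, compress = 4) {
  stopifnot(inherits(scan, "reduced_scan"))
  if (file.exists(path)) {
    if (!overwrite) stop("file exists and overwrite = FALSE: ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "scan")
  d <- dim(scan$intensity)
  rhdf5::h5createDataset(path, "scan/intensity", dims = d,
                         storage.mode = "double",
                         chunk = c(1, d[2], d[3], d[4]), level = compress)
  rhdf5::h5write(scan$intensity, path, "scan/intensity")
  rhdf5::h5write(scan$grid$q_centers, path, "scan/q")
  rhdf5::h5write(scan$grid$q_edges, path, "scan/q_edges")
  rhdf5::h5write(scan$grid$phi_centers, path, "scan/phi")
  rhdf5::h5write(scan$grid$phi_edges, path, "scan/phi_edges")
  rhdf5::h5write(scan$transmission, path, "scan/transmission")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "scan")
  rhdf5::h5writeAttribute(scan$exposure_s, gid, "exposure_s")
  rhdf5::h5writeAttribute(scan$step_um, gid, "step_um")
  rhdf5::h5writeAttribute(as.integer(scan$normalized), gid, "normalized")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a reduced scan from the HDF5 scan container
#'
#' Counterpart of [write_scan()]; validates the layout and array shapes and
#' rejects malformed files with an error naming the offending dataset.
#'
#' @param path HDF5 file written by [write_scan()] (or following its layout).
#' @return a [reduced_scan()].
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop("not an HDF5 scan container: ", path))
  present <- file.path(ls$group, ls$name)
  need <- c("/scan/intensity", "/scan/q", "/scan/phi", "/scan/transmission")
  for (ds in need)
    if (!ds %in% present)
      stop("scan container is missing dataset ", ds)
  intensity <- rhdf5::h5read(path, "scan/intensity")
  q <- as.numeric(rhdf5::h5read(path, "scan/q"))
  phi <- as.numeric(rhdf5::h5read(path, "scan/phi"))
  transmission <- rhdf5::h5read(path, "scan/transmission")
  if (any(!is.finite(q))) stop("NaN in q grid of /scan/q")
  if (any(diff(q) <= 0)) stop("/scan/q must be strictly increasing")
  d <- dim(intensity)
  if (length(d) != 4)
    stop("/scan/intensity must be 4D [ny, nx, n_seg, n_q]")
  if (d[4] != length(q))
    stop("/scan/intensity q dimension does not match /scan/q")
  if (d[3] != length(phi))
    stop("/scan/intensity segment dimension does not match /scan/phi")
  attrs <- rhdf5::h5readAttributes(path, "scan")
  grid <- if ("/scan/q_edges" %in% present) {
    rebuild_grid(q, phi,
                 as.numeric(rhdf5::h5read(path, "scan/q_edges")),
                 as.numeric(rhdf5::h5read(path, "scan/phi_edges")))
  } else {
    rebuild_grid(q, phi)
  }
  reduced_scan(intensity, grid, transmission = as.matrix(transmission),
               exposure_s = as.numeric(attrs$exposure_s %||% 0.1),
               step_um = as.numeric(attrs$step_um %||% 25),
               normalized = isTRUE(as.logical(attrs$normalized %||% 0L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reconstruct a qaz_grid from stored centres (and edges when present)
rebuild_grid <- function(q, phi, q_edges = NULL, phi_edges = NULL) {
  n_q <- length(q)
  n_seg <- length(phi)
  if (is.null(q_edges)) {
    dq <- diff(q)
    q_edges <- c(q[1] - dq[1] / 2, q + c(dq, dq[n_q - 1]) / 2)
  }
  g <- list(q_centers = q, q_edges = q_edges, phi_centers = phi,
            phi_edges = phi_edges %||%
              ((phi - 360 / n_seg / 2) %% 360),
            n_q = as.integer(n_q), n_seg = as.integer(n_seg))
  class(g) <- "qaz_grid"
  validate_qaz_grid(g)
}

#' Write a per-point result table to CSV
#'
#' One header row, one row per scan point, columns in the table's stored
#' order (`row`, `col`, `label`, then analysis outputs). Missing values are
#' written as empty fields.
#'
#' @param table data.frame with at least `row` and `col` columns; (row, col)
#'   pairs must be unique.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (!all(c("row", "col") %in% names(table)))
    stop("result table must have 'row' and 'col' columns")
  if (nrow(table) > 0 && anyDuplicated(table[, c("row", "col")]))
    stop("duplicate (row, col) scan points in result table")
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a result-table CSV written by [write_result_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
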