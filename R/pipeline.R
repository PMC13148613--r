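#' Default pipeline configuration
#'
#' All tunable q windows and thresholds in one place. The segmentation,
#' collagen-band and myofibril-band windows default to 0.085-0.095,
#' 0.085-0.11 and 0.231-0.367 nm^-1; per-order collagen windows are
#' `2*pi*n/d_ref * (1 +/- order_tol)`.
#'
#' @return nested named list; serializable to YAML with [write_config()].
#' @export
default_config <- function() {
  list(
    windows = list(
      segmentation = c(0.085, 0.095),
      collagen_band = c(0.085, 0.11),
      myofibril_band = c(0.231, 0.367),
      equatorial_10 = c(0.14, 0.21),
      equatorial_11 = c(0.24, 0.34)
    ),
    d_ref = 67,
    order_tol = 0.06,
    orders = c(1, 5, 6),
    thresholds = list(t_c = 0, t_o = -4, t_bg = 0.99, snr_min = 3),
    render = list(percentiles = c(0.01, 0.99)),
    seed = 1
  )
}

#' Write / read a pipeline configuration as YAML
#' @param config configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Run the full analysis pipeline on one scan
#'
#' Stages: transmission/exposure normalization, intensity-exponent
#' segmentation (with sixth-order fallback), orientation fits on the
#' collagen and myofibril bands, collagen meridional peak analysis, muscle
#' equatorial doublet analysis, and per-sample distribution summaries.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param scan a [reduced_scan()] or path to an HDF5 scan container.
#' @param config configuration list (default [default_config()]).
#' @param out_dir optional output directory; when given, writes the
#'   per-point CSV (`results.csv`), region/orientation/ratio PNG maps, the
#'   summary CSV and the configuration actually used.
#' @return list with `table` (per-point data.frame), `region`, `exponent`,
#'   `orient_collagen`, `orient_myofibril`, `collagen`, `muscle`,
#'   `summaries`, `config`.
#' @export
run_pipeline <- function(scan, config = default_config(), out_dir = NULL) {
  if (is.character(scan)) scan <- read_scan(scan)
  stopifnot(inherits(scan, "reduced_scan"))
  config <- utils::modifyList(default_config(), config)
  w <- config$windows
  th <- config$thresholds
  scan <- normalize_scan(scan)
  expmap <- compute_intensity_exponent(scan, w$segmentation)
  # sixth-order fallback is only consulted where the exponent rule did not
  # already call collagen (OR semantics, cheaper)
  need6 <- !is.na(expmap$alpha) & expmap$alpha < th$t_c &
    scan$transmission < th$t_bg
  sixth <- detect_sixth_order(scan, d_ref = config$d_ref,
                              tol = config$order_tol,
                              snr_min = th$snr_min, subset = need6)
  region <- segment_regions(expmap, sixth, scan$transmission, th)
  oc <- orient_scan(scan, w$collagen_band)
  om <- orient_scan(scan, w$myofibril_band)
  col_df <- analyze_collagen_points(scan, region, oc,
                                    orders = config$orders,
                                    d_ref = config$d_ref,
                                    tol = config$order_tol,
                                    snr_min = th$snr_min)
  mus_df <- analyze_muscle_points(scan, region, om,
                                  window10 = w$equatorial_10,
                                  window11 = w$equatorial_11,
                                  snr_min = th$snr_min)
  d <- dim(scan$intensity)
  tab <- data.frame(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    label = as.vector(region$label),
    alpha = as.vector(expmap$alpha),
    a_sym_col = as.vector(oc$a_sym), a_asym_col = as.vector(oc$a_asym),
    theta_col = as.vector(oc$theta_s), degree_col = as.vector(oc$degree),
    a_sym_myo = as.vector(om$a_sym), a_asym_myo = as.vector(om$a_asym),
    theta_myo = as.vector(om$theta_s), degree_myo = as.vector(om$degree)
  )
  if (nrow(col_df) > 0)
    tab <- merge(tab, col_df[, setdiff(names(col_df), "theta_s")],
                 by = c("row", "col"), all.x = TRUE, sort = FALSE)
  if (nrow(mus_df) > 0)
    tab <- merge(tab, mus_df[, setdiff(names(mus_df), "theta_eq")],
                 by = c("row", "col"), all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$col, tab$row), ]
  rownames(tab) <- NULL
  summaries <- summarize_sample(tab)
  res <- list(table = tab, region = region, exponent = expmap,
              orient_collagen = oc, orient_myofibril = om,
              collagen = col_df, muscle = mus_df, summaries = summaries,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# parameters summarized per sample (those present in the table)
PIPELINE_PARAMS <- c("D5", "D6", "fwhm_5", "fwhm_6", "i6_over_i5",
                     "overlap_fraction", "d10", "d11", "fwhm10", "fwhm11",
                     "i11_over_i10")

summarize_sample <- function(tab) {
  out <- list()
  for (p in intersect(PIPELINE_PARAMS, names(tab))) {
    v <- tab[[p]][is.finite(tab[[p]])]
    if (length(v) > 0) out[[p]] <- summarize_distribution(v)
  }
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_result_table(res$table, file.path(out_dir, "results.csv"))
  write_config(res$config, file.path(out_dir, "config.yaml"))
  write_map_png(render_region_map(res$region),
                file.path(out_dir, "region_map.png"))
  pct <- res$config$render$percentiles
  write_map_png(render_orientation_map(res$orient_collagen,
                                       percentiles = pct),
                file.path(out_dir, "orientation_collagen.png"))
  write_map_png(render_orientation_map(res$orient_myofibril,
                                       percentiles = pct),
                file.path(out_dir, "orientation_myofibril.png"))
  for (p in c("i6_over_i5", "i11_over_i10"))
    if (p %in% names(res$table)) {
      m <- matrix(NA_real_, nrow(res$region$label), ncol(res$region$label))
      m[cbind(res$table$row, res$table$col)] <- res$table[[p]]
      write_map_png(render_value_map(m, pct),
                    file.path(out_dir, paste0(p, "_map.png")))
    }
  if (length(res$summaries) > 0) {
    sm <- do.call(rbind, lapply(names(res$summaries), function(p)
      data.frame(parameter = p, as.data.frame(res$summaries[[p]]))))
    utils::write.csv(sm, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Render a scalar parameter map as a grayscale image
#' @param m numeric matrix (NA rendered black).
#' @param percentiles normalization probabilities.
#' @return matrix in \[0, 1\].
#' @export
render_value_map <- function(m, percentiles = c(0.01, 0.99)) {
  v <- m
  fin <- is.finite(v)
  if (!any(fin)) return(matrix(0, nrow(m), ncol(m)))
  qs <- stats::quantile(v[fin], percentiles)
  out <- matrix(0, nrow(m), ncol(m))
  if (diff(qs) > 0)
    out[fin] <- pmin(pmax((v[fin] - qs[1]) / diff(qs), 0), 1)
  out
}

#' Compare parameter distributions across samples
#'
#' For each parameter present in at least two samples: a distribution
#' summary per sample, the rank-sum comparison of every non-reference
#' sample against the declared reference, and the percent change of
#' medians.
#'
#' @param results named list of [run_pipeline()] results (or of their
#'   `table` data.frames).
#' @param reference name of the reference sample (must be in `results`).
#' @param parameters parameters to compare (default the pipeline's standard
#'   set).
#' @param min_n minimum finite values per sample for a comparison
#'   (default 2).
#' @return data.frame: `parameter`, `sample`, `n`, `median`, `q1`, `q3`,
#'   `median_pct_change`, `statistic`, `p_value`, `stars` (reference rows
#'   carry NA test fields).
#' @export
compare_samples <- function(results, reference,
                            parameters = PIPELINE_PARAMS, min_n = 2) {
  stopifnot(reference %in% names(results))
  tabs <- lapply(results, function(r) if (is.data.frame(r)) r else r$table)
  rows <- list()
  for (p in parameters) {
    vals <- lapply(tabs, function(t)
      if (p %in% names(t)) t[[p]][is.finite(t[[p]])] else numeric(0))
    if (length(vals[[reference]]) < min_n) next
    for (s in names(tabs)) {
      v <- vals[[s]]
      if (length(v) < min_n) next
      sm <- summarize_distribution(v)
      rec <- data.frame(parameter = p, sample = s, n = sm$n,
                        median = sm$median, q1 = sm$q1, q3 = sm$q3,
                        median_pct_change = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        stars = NA_character_)
      if (s != reference) {
        rec$median_pct_change <-
          percent_change(sm$median,
                         stats::median(vals[[reference]]))
        ct <- compare_distributions(v, vals[[reference]])
        rec$statistic <- ct$statistic
        rec$p_value <- ct$p_value
        rec$stars <- ct$stars
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
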