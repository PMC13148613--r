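#' Box-plot summary of a parameter distribution
#'
#' Linear-interpolation quartiles; whiskers at the most extreme data within
#' 1.5 IQR of the quartiles; everything beyond counts as an outlier.
#'
#' @param values numeric vector (NA dropped); must leave at least one value.
#' @return list: `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `n_outliers`.
#' @export
summarize_distribution <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values to summarize")
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_lim <- qs[1] - 1.5 * iqr
  hi_lim <- qs[3] + 1.5 * iqr
  inside <- v[v >= lo_lim & v <= hi_lim]
  list(n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       n_outliers = sum(v < lo_lim | v > hi_lim))
}

# significance stars per the conventional mapping
p_stars <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else "ns"
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Compares two unpaired samples of per-point parameters. For
#' `max(n_a, n_b) <= 8` the null distribution of U is enumerated exactly
#' over all assignments of the pooled ranks; for larger untied samples a
#' continuity-corrected Edgeworth (kurtosis-adjusted) normal approximation
#' is used, and with ties the tie-corrected normal approximation with
#' continuity correction.
#' Significance stars: `***` p <= 0.001, `**` p <= 0.01, `*` p <= 0.05,
#' `ns` otherwise.
#'
#' The named test in box-plot figures of this field is often "Wilcoxon";
#' for unpaired pixel populations of unequal size the rank-sum form is the
#' defined one, and is the default here. For equal-length paired inputs use
#' `paired = TRUE`, which applies the signed-rank test.
#'
#' @param a,b numeric samples (each n >= 2 after NA removal).
#' @param paired use the Wilcoxon signed-rank test (requires equal lengths).
#' @return list: `statistic` (U, the Mann-Whitney count for sample `a`),
#'   `p_value`, `stars`, `n_a`, `n_b`, `method`.
#' @export
compare_distributions <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 finite values")
  if (paired) {
    if (length(a) != length(b))
      stop("paired comparison requires equal-length samples")
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                stars = p_stars(wt$p.value), n_a = length(a),
                n_b = length(b), method = "signed-rank"))
  }
  na <- length(a); nb <- length(b)
  ranks <- rank(c(a, b))
  u <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  if (max(na, nb) <= 8) {
    p <- exact_ranksum_p(ranks, na, u)
    method <- "rank-sum exact"
  } else {
    p <- normal_ranksum_p(ranks, na, nb, u)
    method <- "rank-sum normal"
  }
  p <- min(1, p)
  list(statistic = u, p_value = p, stars = p_stars(p), n_a = na, n_b = nb,
       method = method)
}

# exact two-sided p by enumerating all choose(na+nb, na) rank assignments
exact_ranksum_p <- function(ranks, na, u_obs) {
  n <- length(ranks)
  combs <- utils::combn(n, na)
  us <- colSums(matrix(ranks[combs], nrow = na)) - na * (na + 1) / 2
  if (stats::var(us) == 0) return(1)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# large-sample two-sided p for the Mann-Whitney U. Without ties the null
# distribution is symmetric with known excess kurtosis
# g2 = -(6/5)(m^2+n^2+mn+m+n)/(mn(N+1)), and a continuity-corrected
# Edgeworth expansion is accurate to a few 1e-4 even at m = n = 8; with
# ties it falls back to the tie-corrected normal approximation.
normal_ranksum_p <- function(ranks, na, nb, u_obs) {
  n <- na + nb
  mu <- na * nb / 2
  ties <- table(ranks)
  if (!any(ties > 1)) {
    s <- sqrt(na * nb * (n + 1) / 12)
    g2 <- -(6 / 5) * (na^2 + nb^2 + na * nb + na + nb) /
      (na * nb * (n + 1))
    z <- (min(u_obs, na * nb - u_obs) + 0.5 - mu) / s
    p_lo <- stats::pnorm(z) - stats::dnorm(z) * (z^3 - 3 * z) * g2 / 24
    return(min(1, max(0, 2 * p_lo)))
  }
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- na * nb / 12 * ((n + 1) - tiecor)
  if (sig2 <= 0) return(1)
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' Percent change of a statistic relative to a reference
#'
#' `100 * (x - ref) / ref`; e.g. the shrinkage of a sample's median
#' D-period against the unprocessed reference.
#'
#' @param x value (e.g. a sample median).
#' @param ref reference value; must be nonzero.
#' @return percent change.
#' @export
percent_change <- function(x, ref) {
  if (ref == 0) stop("reference must be nonzero")
  100 * (x - ref) / ref
}
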