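#' Two-sided Mann-Whitney comparison with star notation
#'
#' Exact U distribution when `min(n, m) <= 8` and the pooled data carry no
#' ties; otherwise the normal approximation with tie correction (and
#' continuity correction). Stars follow the printed thresholds:
#' `*` for 0.01 < p <= 0.05, `**` for 0.001 < p <= 0.01, `***` for
#' 1e-4 < p <= 0.001, `****` for p <= 1e-4, `ns` above 0.05.
#'
#' @param a,b numeric samples (each nonempty).
#' @return data.frame: `U`, `p`, `stars`, group sizes, medians, quartiles.
#' @export
mann_whitney <- function(a, b) {
  assert_that(length(a) >= 1 && length(b) >= 1, "both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied pooled sample: no evidence of difference
  data.frame(U = unname(wt$statistic), p = p, stars = p_stars(p),
             n_a = length(a), n_b = length(b),
             median_a = median(a), median_b = median(b),
             q25_a = quantile(a, 0.25, names = FALSE),
             q75_a = quantile(a, 0.75, names = FALSE),
             q25_b = quantile(b, 0.25, names = FALSE),
             q75_b = quantile(b, 0.75, names = FALSE),
             exact = exact)
}

#' @rdname mann_whitney
#' @param p p value.
#' @export
p_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
    ifelse(p <= 1e-3, "***",
      ifelse(p <= 1e-2, "**",
        ifelse(p <= 5e-2, "*", "ns"))))
}

#' Boxplot summary using the figure convention
#'
#' Median, 25th/75th percentiles, whiskers extending to the most extreme
#' values no further than 1.5 x IQR from the box, outliers beyond.
#'
#' @param x numeric sample.
#' @return list: `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
boxplot_summary <- function(x) {
  x <- x[!is.na(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inside <- x >= lo_lim & x <= hi_lim
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = x[!inside], n = length(x))
}

#' Gaussian kernel density estimate (Scott's rule)
#'
#' Density curve on a regular grid, normalized to integrate to 1. A
#' zero-variance sample gets a floored bandwidth with a warning.
#'
#' @param values numeric sample (n >= 2).
#' @param bw bandwidth; default Scott's rule (`bw.nrd`).
#' @param n grid points.
#' @return data.frame `x`, `density`.
#' @export
kde <- function(values, bw = NULL, n = 512) {
  assert_that(length(values) >= 2, "KDE needs at least 2 values")
  if (is.null(bw)) {
    if (stats::sd(values) == 0 || stats::IQR(values) == 0) {
      warning("zero-variance sample: applying bandwidth floor")
      bw <- max(abs(mean(values)) * 1e-3, 1e-3)
    } else {
      bw <- stats::bw.nrd(values)
    }
  }
  d <- stats::density(values, bw = bw, n = n)
  data.frame(x = d$x, density = d$y)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y equal-length numeric samples (n >= 3) with nonzero variance.
#' @return data.frame `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need equal-length samples of size >= 3")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Observed-vs-control distribution divergence (KS statistic)
#'
#' Reported alongside the KDE overlays of observed condensate distances vs
#' radius-matched random controls; an extension beyond the purely visual
#' comparison.
#'
#' @param observed,control numeric samples.
#' @return data.frame `ks_d`, `p`.
#' @export
ks_compare <- function(observed, control) {
  kt <- suppressWarnings(ks.test(observed, control))
  data.frame(ks_d = unname(kt$statistic), p = kt$p.value)
}
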