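#' BestKeeper descriptive statistics
#'
#' Per-gene descriptive statistics on raw Cq values: n, geometric and
#' arithmetic mean, min, max, standard deviation (n-1 denominator) and
#' CV% = 100 * SD / arithmetic mean. BestKeeper operates on raw Cq only —
#' amplification efficiencies never enter, which is why its output is
#' identical whichever efficiency table accompanies the data.
#'
#' @param cq a [cq_matrix()].
#' @param dispersion `"sd"` (sample standard deviation, default) or
#'   `"mad"` (mean absolute deviation from the arithmetic mean, the
#'   dispersion flavour of the original spreadsheet).
#' @return data.frame with columns gene, n, geo_mean, ar_mean, min, max,
#'   sd, cv_pct.
#' @export
bestkeeper_descriptives <- function(cq, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  v <- unclass(cq)
  disp <- switch(dispersion,
                 sd = apply(v, 1, stats::sd),
                 mad = rowMeans(abs(v - rowMeans(v))))
  data.frame(gene = rownames(v), n = ncol(v),
             geo_mean = exp(rowMeans(log(v))),
             ar_mean = rowMeans(v),
             min = apply(v, 1, min), max = apply(v, 1, max),
             sd = disp, cv_pct = 100 * disp / rowMeans(v),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' BestKeeper index and gene rankings
#'
#' Genes whose raw Cq dispersion exceeds `sd_threshold` (1.5 cycles by
#' convention) are flagged as too unstable and excluded from index
#' construction. The BestKeeper index is then the per-sample geometric mean
#' of the retained genes' Cq values, and every gene — including excluded
#' ones — is correlated (Pearson) with the index. Two rankings are
#' reported: `by_correlation` (r descending; the ranking of the original
#' software) and `by_sd` (Cq dispersion ascending; the ranking raw-Cq web
#' tools derive from the same numbers). The two can differ substantially: a
#' gene with a tight but panel-independent Cq profile ranks well by SD and
#' poorly by correlation.
#'
#' Correlation p-values (two-sided t approximation) are reported for
#' orientation only and never used for ranking.
#'
#' @inheritParams bestkeeper_descriptives
#' @param sd_threshold exclusion threshold on the dispersion, in cycles.
#' @return a `bestkeeper_result` list: `stats` (descriptives plus
#'   `excluded`, `r`, `p`, `rank_by_r`, `rank_by_sd`), `index` (per-sample),
#'   `by_correlation` and `by_sd` ([stability_ranking()]s),
#'   `retained` (gene names entering the index).
#' @export
bestkeeper_index <- function(cq, sd_threshold = 1.5,
                             dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  st <- bestkeeper_descriptives(cq, dispersion = dispersion)
  v <- unclass(cq)
  excluded <- st$sd > sd_threshold
  if (sum(!excluded) < 2)
    stop("fewer than 2 genes retained after SD exclusion")
  retained <- st$gene[!excluded]
  index <- exp(colMeans(log(v[retained, , drop = FALSE])))
  r <- apply(v, 1, function(g) stats::cor(g, index))
  n <- ncol(v)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  by_r <- stability_ranking(st$gene, r, method = "bestkeeper_r",
                            decreasing = TRUE)
  by_sd <- stability_ranking(st$gene, st$sd, method = "bestkeeper_sd")
  st$excluded <- excluded
  st$r <- r
  st$p <- p
  st$rank_by_r <- by_r$rank[match(st$gene, by_r$gene)]
  st$rank_by_sd <- by_sd$rank[match(st$gene, by_sd$gene)]
  structure(list(stats = st, index = index, by_correlation = by_r,
                 by_sd = by_sd, retained = retained,
                 sd_threshold = sd_threshold, dispersion = dispersion),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat(sprintf("BestKeeper (%d/%d genes retained, threshold %.2f)\n",
              length(x$retained), nrow(x$stats), x$sd_threshold))
  print(x$stats, digits = 4, ...)
  invisible(x)
}
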