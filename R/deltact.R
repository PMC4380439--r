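#' Comparative delta-Ct stability scores
#'
#' For every unordered gene pair (i, k) the per-sample Cq difference
#' d_j = Cq_ij - Cq_kj is formed; its SD across samples measures how much
#' the two genes drift apart. A gene's score is the mean of these pairwise
#' SDs over all partners, ranked ascending. Computed directly on raw Cq
#' (the method predates efficiency correction); it is algebraically
#' identical to the geNorm M value of the full panel computed on E = 2 log
#' quantities, since log2(RQ_i / RQ_k) at E = 2 differs from
#' -(Cq_i - Cq_k) only by a per-pair constant.
#'
#' @param cq a [cq_matrix()] (or plain genes x samples Cq matrix).
#' @return a `deltact_result` list: `score` (named vector), `ranking`.
#' @export
deltact_scores <- function(cq) {
  v <- unclass(cq)
  if (nrow(v) < 2 || ncol(v) < 2)
    stop("comparative delta-Ct needs at least 2 genes and 2 samples")
  genes <- rownames(v)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(v)))
  score <- stats::setNames(rowSums(.pairwise_sd(v)) / (nrow(v) - 1), genes)
  structure(list(score = score,
                 ranking = stability_ranking(genes, score,
                                             method = "deltact")),
            class = "deltact_result")
}

#' Comprehensive (RefFinder-style) ranking
#'
#' Emulates the aggregation performed by raw-Cq web tools: the four
#' methods are run from raw Cq (geNorm and NormFinder on E = 2 relative
#' quantities, BestKeeper ranked by Cq dispersion, comparative delta-Ct),
#' each produces a component rank (the geNorm terminal tie pair contributes
#' 1.5 to both genes; other ties contribute their mean rank), and genes are
#' ordered by the geometric mean of their four component ranks. Remaining
#' ties are broken by the delta-Ct score, then input order.
#'
#' Because the component methods see no efficiency information, this
#' ranking inherits whatever bias uncorrected amplification efficiencies
#' introduce; it is an advisory cross-method summary — a mere arithmetic
#' combination of ranks with no underlying statistical model — not a
#' validated statistic, and is reported as such.
#'
#' @param cq a [cq_matrix()].
#' @param sd_threshold BestKeeper exclusion threshold passed through.
#' @return a `comprehensive_ranking` list: `ranking` (final
#'   [stability_ranking()], ties broken so ranks are integers),
#'   `component_ranks` (genes x 4 matrix), `geom_mean`, plus the four
#'   component result objects.
#' @export
comprehensive_rank <- function(cq, sd_threshold = 1.5) {
  if (nrow(cq) < 3) stop("comprehensive ranking needs at least 3 genes")
  genes <- rownames(cq)
  rq <- compute_rq(cq, efficiency_mode = "E2")
  logq <- log_rq(rq)
  gn <- genorm_rank(logq, efficiency_mode = "E2")
  nf <- normfinder_ungrouped(logq, efficiency_mode = "E2")
  bk <- bestkeeper_index(cq, sd_threshold = sd_threshold)
  dc <- deltact_scores(cq)
  comp <- cbind(
    genorm = gn$ranking$rank[match(genes, gn$ranking$gene)],
    normfinder = nf$ranking$rank[match(genes, nf$ranking$gene)],
    bestkeeper_sd = bk$by_sd$rank[match(genes, bk$by_sd$gene)],
    deltact = dc$ranking$rank[match(genes, dc$ranking$gene)])
  rownames(comp) <- genes
  gm <- exp(rowMeans(log(comp)))
  ord <- order(gm, dc$score[genes], seq_along(genes))
  final <- stats::setNames(integer(length(genes)), genes[ord])
  final[genes[ord]] <- seq_along(genes)
  ranking <- stability_ranking(genes, final[genes],
                               method = "comprehensive",
                               efficiency_mode = "E2")
  ranking$value <- unname(gm[ranking$gene])
  structure(list(ranking = ranking, component_ranks = comp, geom_mean = gm,
                 genorm = gn, normfinder = nf, bestkeeper = bk,
                 deltact = dc,
                 caveat = paste("comprehensive ranking is an arithmetic",
                                "aggregation of method ranks from raw Cq;",
                                "advisory only, use as a complementary",
                                "tool, not a validated statistic")),
            class = "comprehensive_ranking")
}

#' @export
print.comprehensive_ranking <- function(x, ...) {
  print(x$ranking, ...)
  cat("note:", x$caveat, "\n")
  invisible(x)
}
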