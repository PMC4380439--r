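#' geNorm M values
#'
#' For every pair of genes (j, k) the pairwise variation V_jk is the
#' standard deviation over samples of the difference of their log2 relative
#' quantities (i.e. of the log expression ratio). The gene-stability
#' measure M_j is the mean of V_jk over all partners k. Two perfectly
#' co-regulated genes have a constant log ratio and hence contribute 0; a
#' gene fluctuating independently of the panel inflates every one of its
#' pairwise SDs.
#'
#' SDs use the n-1 denominator throughout, matching the spreadsheet STDEV
#' of the original implementation.
#'
#' @param logq genes x samples matrix of log2 relative quantities
#'   (see [log_rq()]).
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(logq) {
  if (nrow(logq) < 2 || ncol(logq) < 2)
    stop("geNorm needs at least 2 genes and 2 samples")
  V <- .pairwise_sd(logq)
  rowSums(V) / (nrow(logq) - 1)
}

# SD over samples of (row_j - row_k), all pairs at once via the covariance
# matrix: var(x_j - x_k) = var_j + var_k - 2 cov_jk.
.pairwise_sd <- function(x) {
  C <- stats::cov(t(x))
  v <- diag(C)
  V2 <- outer(v, v, "+") - 2 * C
  V2[V2 < 0] <- 0   # guard tiny negative round-off
  diag(V2) <- 0
  sqrt(V2)
}

#' geNorm stepwise ranking
#'
#' Iteratively removes the gene with the highest M value and recomputes M
#' on the remaining panel until only two genes are left. The removed genes
#' receive ranks G, G-1, ..., 3; the final two genes cannot be separated by
#' the pairwise criterion (each is the other's only partner) and share the
#' top tie set \{1, 2\}. Each gene's reported M is its value at the step it
#' was removed; for the final pair this is their common pairwise variation.
#' Exact ties in M are broken by removing the gene appearing later in the
#' input order (deterministic and documented).
#'
#' @param logq genes x samples matrix of log2 relative quantities.
#' @param efficiency_mode tag recorded in the resulting ranking.
#' @return a `genorm_result` list: `ranking` (a [stability_ranking()] with
#'   the \{1,2\} tie), `m` (per-gene M at removal), `exclusion_order`
#'   (genes from first removed to the final pair), and `m_trajectory`
#'   (full M table per elimination step, genes x steps).
#' @export
genorm_rank <- function(logq, efficiency_mode = NA_character_) {
  G <- nrow(logq)
  if (G < 3) stop("geNorm stepwise ranking needs at least 3 genes")
  genes <- rownames(logq)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  rownames(logq) <- genes
  keep <- genes
  m_final <- stats::setNames(numeric(G), genes)
  excluded <- character(0)
  traj <- matrix(NA_real_, G, G - 2, dimnames = list(genes, NULL))
  for (step in seq_len(G - 2)) {
    M <- genorm_m(logq[keep, , drop = FALSE])
    traj[keep, step] <- M
    if (length(keep) == 2) break
    worst <- which(M == max(M))
    # tie-break: later gene in input order removed first
    drop <- keep[worst[which.max(match(keep[worst], genes))]]
    m_final[drop] <- M[drop]
    excluded <- c(excluded, drop)
    keep <- setdiff(keep, drop)
  }
  pair <- keep  # in input order
  m_final[pair] <- genorm_m(logq[pair, , drop = FALSE])
  ranks <- stats::setNames(numeric(G), genes)
  ranks[excluded] <- seq(G, 3)
  ranks[pair] <- 1.5
  ranking <- stability_ranking(genes, ranks, method = "genorm",
                               efficiency_mode = efficiency_mode,
                               tie_sets = list(pair))
  ranking$value <- unname(m_final[ranking$gene])   # report M, not the rank key
  structure(list(ranking = ranking, m = m_final,
                 exclusion_order = excluded, top_pair = pair,
                 m_trajectory = traj),
            class = "genorm_result")
}

#' geNorm pairwise-variation curve and optimal gene number
#'
#' The normalization factor NF_n of a sample is the geometric mean of the
#' relative quantities of the n most stable genes (the top tie pair first,
#' then the reverse exclusion order). V(n, n+1) is the SD over samples of
#' log2(NF_n / NF_\{n+1\}): how much the normalization would shift if one
#' more gene were added. The smallest n with V below the cutoff is reported
#' as the optimal number of reference genes; 0.15 is the conventional
#' rule-of-thumb cutoff, not a hard statistical threshold, and when no V
#' falls below it the optimal number is undefined and visual inspection of
#' the trend is advised.
#'
#' @param logq genes x samples matrix of log2 relative quantities.
#' @param result a `genorm_result` from [genorm_rank()] on the same matrix.
#' @param cutoff pairwise-variation cutoff (default 0.15, rule of thumb).
#' @return a `pairwise_variation_curve` list: `n` (2..G-1), `v` (V(n,n+1)),
#'   `optimal_n` (integer or `NA`), `cutoff`, `advisory` (message when
#'   undefined), `nf` (samples x panel-size matrix of log2 NFs).
#' @export
pairwise_variation_curve <- function(logq, result, cutoff = 0.15) {
  G <- nrow(logq)
  if (G < 3) stop("pairwise-variation analysis needs at least 3 genes")
  stopifnot(inherits(result, "genorm_result"))
  stability_order <- c(result$top_pair, rev(result$exclusion_order))
  lognf <- sapply(2:G, function(n)
    colMeans(logq[stability_order[seq_len(n)], , drop = FALSE]))
  colnames(lognf) <- paste0("NF", 2:G)
  ns <- 2:(G - 1)
  v <- vapply(seq_along(ns), function(i)
    stats::sd(lognf[, i] - lognf[, i + 1]), numeric(1))
  below <- which(v < cutoff)
  optimal_n <- if (length(below)) ns[below[1]] else NA_integer_
  advisory <- if (is.na(optimal_n))
    paste("no pairwise variation fell below the cutoff; the cutoff is a",
          "rule of thumb and a visual interpretation of the trend of the",
          "pairwise variations can be informative") else NULL
  structure(list(n = ns, v = stats::setNames(v, paste0("V", ns, "/", ns + 1)),
                 optimal_n = optimal_n, cutoff = cutoff,
                 advisory = advisory, nf = lognf,
                 stability_order = stability_order),
            class = "pairwise_variation_curve")
}

#' @export
print.genorm_result <- function(x, ...) {
  print(x$ranking, ...)
  invisible(x)
}

#' @export
print.pairwise_variation_curve <- function(x, ...) {
  print(round(x$v, 4))
  if (is.na(x$optimal_n)) cat("optimal n: undefined.", x$advisory, "\n")
  else cat(sprintf("optimal n: %d (cutoff %.2f)\n", x$optimal_n, x$cutoff))
  invisible(x)
}
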