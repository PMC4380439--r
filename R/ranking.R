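#' Stability rankings
#'
#' A `stability_ranking` records, for one method run on one dataset, each
#' gene's stability value and its rank label. Rank labels are either a
#' single integer or a tie set such as "1/2" (the geNorm stepwise procedure
#' structurally ends with two genes that cannot be separated, conventionally
#' printed "1/2"). Integer ranks and tie sets together tile 1..G exactly
#' once. For numeric aggregation a tie set counts as its mean rank (so a
#' "1/2" pair contributes 1.5).
#'
#' @param genes character vector of gene identifiers.
#' @param values per-gene stability values (lower = more stable unless
#'   `decreasing`).
#' @param method method tag, e.g. `"genorm"`.
#' @param efficiency_mode `"corrected"`, `"E2"`, or `NA` when not
#'   applicable (e.g. methods running on raw Cq).
#' @param decreasing rank by decreasing value (used for correlation-based
#'   rankings where larger is better).
#' @param tie_sets optional list of character vectors of genes forced into a
#'   shared tie set (used by geNorm for the terminal pair); remaining ties
#'   are detected from equal values.
#' @return a `stability_ranking`: data.frame with columns `gene`, `value`,
#'   `rank` (numeric mean rank), `label` (printed rank), ordered by rank.
#' @export
stability_ranking <- function(genes, values, method = "unknown",
                              efficiency_mode = NA_character_,
                              decreasing = FALSE, tie_sets = NULL) {
  stopifnot(length(genes) == length(values), !anyDuplicated(genes))
  genes <- as.character(genes)
  v <- as.numeric(values)
  key <- if (decreasing) -v else v
  # forced tie sets share the mean of their members' keys
  if (!is.null(tie_sets)) {
    for (ts in tie_sets) {
      idx <- match(ts, genes)
      if (anyNA(idx)) stop("tie set names unknown gene")
      key[idx] <- mean(key[idx])
    }
  }
  ord <- order(key, seq_along(key))
  pos <- seq_along(key)
  grp <- match(key, key)          # identical keys -> same tie group
  ranks <- numeric(length(key))
  labels <- character(length(key))
  taken <- integer(0)
  for (g in unique(grp[ord])) {
    idx <- which(grp == g)
    slots <- setdiff(seq_along(key), taken)[seq_along(idx)]
    taken <- c(taken, slots)
    ranks[idx] <- mean(slots)
    labels[idx] <- paste(slots, collapse = "/")
  }
  df <- data.frame(gene = genes, value = unname(v), rank = ranks,
                   label = labels, stringsAsFactors = FALSE)
  df <- df[order(df$rank, match(df$gene, genes)), ]
  rownames(df) <- NULL
  structure(df, method = method, efficiency_mode = efficiency_mode,
            class = c("stability_ranking", "data.frame"))
}

#' Build a stability ranking directly from printed rank labels
#'
#' Used for replaying published ranking tables where only the rank labels
#' (e.g. "3", "1/2") are available, not the underlying stability values.
#'
#' @param genes character vector.
#' @param labels character vector of rank labels, tie sets as "a/b".
#' @inheritParams stability_ranking
#' @export
ranking_from_labels <- function(genes, labels, method = "unknown",
                                efficiency_mode = NA_character_) {
  sets <- lapply(strsplit(as.character(labels), "/", fixed = TRUE),
                 function(s) sort(as.integer(s)))
  ranks <- vapply(sets, mean, numeric(1))
  covered <- sort(unlist(lapply(unique(sets), identity)))
  if (!identical(covered, seq_along(genes)))
    stop("rank labels must tile 1..G exactly once")
  df <- data.frame(gene = as.character(genes), value = NA_real_,
                   rank = ranks,
                   label = vapply(sets, paste, "", collapse = "/"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  structure(df, method = method, efficiency_mode = efficiency_mode,
            class = c("stability_ranking", "data.frame"))
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("Stability ranking (%s%s)\n", attr(x, "method"),
              if (is.na(attr(x, "efficiency_mode"))) "" else
                paste0(", ", attr(x, "efficiency_mode"))))
  print.data.frame(x, ...)
  invisible(x)
}

.rank_sets <- function(r) {
  stats::setNames(lapply(strsplit(r$label, "/", fixed = TRUE), as.integer),
                  r$gene)
}

#' Compare two stability rankings gene by gene
#'
#' Computes, per gene, the rank-change magnitude between two rankings of
#' the same gene set and classifies it. A gene counts as changed whenever
#' its printed label differs (moving into or out of a tie set is a change
#' even when the numeric distance is small). The magnitude for a gene whose
#' rank is a tie set on one side is the distance to the nearest member of
#' the set; a gene lying in the tie set on both sides has magnitude 0.
#' Changes of at most one rank are "minor", larger ones "major" — the usual
#' screening language for whether an efficiency-uncorrected analysis would
#' have picked a different reference-gene set.
#'
#' @param a,b `stability_ranking` objects over identical gene sets.
#' @return a `rank_comparison`: data.frame with columns `gene`, `rank_a`,
#'   `rank_b`, `delta`, `class` plus a `summary` attribute (list with
#'   `n_total`, `n_changed`, `n_minor`, `n_major`, `pct_changed` (rounded to
#'   integer) and `frac_changed` (exact)).
#' @export
rank_compare <- function(a, b) {
  sa <- .rank_sets(a); sb <- .rank_sets(b)
  if (!setequal(names(sa), names(sb)))
    stop("rankings cover different gene sets")
  genes <- names(sa)
  delta <- numeric(length(genes))
  changed <- logical(length(genes))
  for (i in seq_along(genes)) {
    ta <- sa[[genes[i]]]; tb <- sb[[genes[i]]]
    delta[i] <- min(abs(outer(ta, tb, "-")))
    changed[i] <- !identical(ta, tb)
  }
  cls <- ifelse(!changed, "unchanged", ifelse(delta <= 1, "minor", "major"))
  df <- data.frame(gene = genes,
                   rank_a = vapply(sa, paste, "", collapse = "/"),
                   rank_b = vapply(sb, paste, "", collapse = "/"),
                   delta = delta, class = cls, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, summary = .comparison_summary(df),
            class = c("rank_comparison", "data.frame"))
}

.comparison_summary <- function(df) {
  n <- nrow(df)
  nc <- sum(df$class != "unchanged")
  list(n_total = n, n_changed = nc,
       n_minor = sum(df$class == "minor"),
       n_major = sum(df$class == "major"),
       frac_changed = nc / n,
       pct_changed = round(100 * nc / n))
}

#' Pool one or more rank comparisons into a summary row
#'
#' Aggregates per-gene change records across datasets (e.g. the same method
#' compared on two sample sets) into total / changed / minor / major counts
#' and the rounded percentage used for report display.
#'
#' @param ... `rank_comparison` objects.
#' @return list as in the `summary` attribute of [rank_compare()].
#' @export
summarize_pair <- function(...) {
  dfs <- list(...)
  stopifnot(length(dfs) > 0,
            all(vapply(dfs, inherits, TRUE, "rank_comparison")))
  .comparison_summary(do.call(rbind, lapply(dfs, as.data.frame)))
}

#' @export
print.rank_comparison <- function(x, ...) {
  print.data.frame(x, ...)
  s <- attr(x, "summary")
  cat(sprintf("changed %d/%d (%d%%): %d minor, %d major\n",
              s$n_changed, s$n_total, s$pct_changed, s$n_minor, s$n_major))
  invisible(x)
}
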