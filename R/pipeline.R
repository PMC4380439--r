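#' Run the full reference-gene validation study on one dataset
#'
#' One call reproduces the complete analysis: every requested stability
#' method in efficiency-corrected and/or E = 2 mode, the BestKeeper
#' correlation- and SD-based orderings, the comprehensive (raw-Cq
#' aggregation) ranking, the per-method comparison between the two
#' efficiency modes with minor/major classification, and the geNorm
#' pairwise-variation analysis for the optimal number of reference genes.
#'
#' @param cq a [cq_matrix()].
#' @param eff an [efficiency_table()]; required unless
#'   `efficiency_mode = "e2"`.
#' @param groups optional named sample-to-group vector; defaults to the
#'   groups carried by `cq`.
#' @param methods subset of `c("genorm", "normfinder", "bestkeeper",
#'   "deltact")`.
#' @param efficiency_mode `"both"` (default), `"corrected"` or `"e2"`.
#' @param genorm_cutoff pairwise-variation cutoff (rule of thumb 0.15).
#' @param bestkeeper_sd_threshold Cq-dispersion exclusion threshold.
#' @param normfinder_mode `"auto"` (grouped when a group design is
#'   present), `"grouped"` or `"ungrouped"`.
#' @return a `study_report` list: `rankings` (nested
#'   method -> mode -> [stability_ranking()]), `results` (full method
#'   objects), `comparisons` (per-method [rank_compare()] corrected vs E2
#'   plus summaries), `vcurve` (per mode), `comprehensive`, `table`
#'   (genes x method/mode rank-label matrix), and the parameters used.
#' @export
run_study <- function(cq, eff = NULL, groups = cq_groups(cq),
                      methods = c("genorm", "normfinder", "bestkeeper",
                                  "deltact"),
                      efficiency_mode = c("both", "corrected", "e2"),
                      genorm_cutoff = 0.15, bestkeeper_sd_threshold = 1.5,
                      normfinder_mode = c("auto", "grouped", "ungrouped")) {
  efficiency_mode <- match.arg(efficiency_mode)
  normfinder_mode <- match.arg(normfinder_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  modes <- switch(efficiency_mode, both = c("corrected", "E2"),
                  corrected = "corrected", e2 = "E2")
  if ("corrected" %in% modes && is.null(eff))
    stop("corrected mode requires an efficiency table")
  use_grouped <- switch(normfinder_mode,
                        auto = !is.null(groups), grouped = TRUE,
                        ungrouped = FALSE)
  if (use_grouped && is.null(groups))
    stop("normfinder_mode = 'grouped' requires a group design")

  rankings <- list(); results <- list(); vcurve <- list()
  for (mode in modes) {
    logq <- log_rq(compute_rq(cq, eff, efficiency_mode = mode))
    if ("genorm" %in% methods) {
      gn <- genorm_rank(logq, efficiency_mode = mode)
      results$genorm[[mode]] <- gn
      rankings$genorm[[mode]] <- gn$ranking
      vcurve[[mode]] <- pairwise_variation_curve(logq, gn,
                                                 cutoff = genorm_cutoff)
    }
    if ("normfinder" %in% methods) {
      nf <- if (use_grouped)
        normfinder_grouped(logq, groups, efficiency_mode = mode)
      else normfinder_ungrouped(logq, efficiency_mode = mode)
      results$normfinder[[mode]] <- nf
      rankings$normfinder[[mode]] <- nf$ranking
    }
  }
  if ("bestkeeper" %in% methods) {
    bk <- bestkeeper_index(cq, sd_threshold = bestkeeper_sd_threshold)
    results$bestkeeper <- bk
    rankings$bestkeeper <- list(by_correlation = bk$by_correlation,
                                by_sd = bk$by_sd)
  }
  if ("deltact" %in% methods) {
    dc <- deltact_scores(cq)
    results$deltact <- dc
    rankings$deltact <- list(raw = dc$ranking)
  }
  comprehensive <- comprehensive_rank(cq,
                                      sd_threshold = bestkeeper_sd_threshold)

  comparisons <- list()
  if (length(modes) == 2) {
    for (m in intersect(c("genorm", "normfinder"), methods)) {
      cmp <- rank_compare(rankings[[m]][["corrected"]],
                          rankings[[m]][["E2"]])
      comparisons[[m]] <- list(comparison = cmp,
                               summary = attr(cmp, "summary"))
    }
  }

  genes <- rownames(cq)
  tab <- do.call(cbind, lapply(unlist(rankings, recursive = FALSE),
                               function(r) r$label[match(genes, r$gene)]))
  tab <- cbind(tab,
               comprehensive = comprehensive$ranking$label[
                 match(genes, comprehensive$ranking$gene)])
  rownames(tab) <- genes

  structure(list(rankings = rankings, results = results,
                 comparisons = comparisons, vcurve = vcurve,
                 comprehensive = comprehensive, table = tab,
                 params = list(methods = methods, modes = modes,
                               genorm_cutoff = genorm_cutoff,
                               bestkeeper_sd_threshold =
                                 bestkeeper_sd_threshold,
                               normfinder_mode = normfinder_mode,
                               grouped = use_grouped)),
            class = "study_report")
}

#' Render a study report to files
#'
#' Deterministic: rendering the same report twice produces identical
#' bytes. `tsv` writes one file per component (`genorm_m.tsv`,
#' `genorm_v.tsv`, `normfinder.tsv`, `bestkeeper.tsv`, `deltact.tsv`,
#' `comprehensive.tsv`, `rank_changes.tsv`, `table.tsv`); `json` writes a
#' single versioned `report.json`; `md` writes a human-readable
#' `report.md` including the rule-of-thumb caveat on the pairwise-variation
#' cutoff and the advisory status of the comprehensive ranking.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @param format one or more of `"tsv"`, `"json"`, `"md"`.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, dir, format = c("tsv", "json", "md")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if ("tsv" %in% format) {
    if (!is.null(report$results$genorm)) {
      for (mode in names(report$results$genorm)) {
        gn <- report$results$genorm[[mode]]
        r <- gn$ranking
        wtsv(data.frame(gene = r$gene, M = r$value, rank = r$label,
                        exclusion_step = match(r$gene,
                                               gn$exclusion_order)),
             sprintf("genorm_m_%s.tsv", mode))
        vc <- report$vcurve[[mode]]
        wtsv(data.frame(n = vc$n, V = unname(vc$v)),
             sprintf("genorm_v_%s.tsv", mode))
      }
    }
    if (!is.null(report$results$normfinder)) {
      for (mode in names(report$results$normfinder)) {
        nf <- report$results$normfinder[[mode]]
        df <- data.frame(gene = nf$ranking$gene,
                         stability = nf$ranking$value,
                         rank = nf$ranking$label)
        if (nf$mode == "grouped") {
          df <- cbind(df,
                      stats::setNames(as.data.frame(
                        nf$sigma2[df$gene, , drop = FALSE]),
                        paste0("sigma2_", colnames(nf$sigma2))),
                      stats::setNames(as.data.frame(
                        nf$d_tilde[df$gene, , drop = FALSE]),
                        paste0("d_", colnames(nf$d_tilde))))
        }
        wtsv(df, sprintf("normfinder_%s.tsv", mode))
      }
    }
    if (!is.null(report$results$bestkeeper))
      wtsv(report$results$bestkeeper$stats, "bestkeeper.tsv")
    if (!is.null(report$results$deltact)) {
      dc <- report$results$deltact
      wtsv(data.frame(gene = dc$ranking$gene, score = dc$ranking$value,
                      rank = dc$ranking$label), "deltact.tsv")
    }
    comp <- report$comprehensive
    wtsv(data.frame(gene = rownames(comp$component_ranks),
                    comp$component_ranks,
                    geom_mean = comp$geom_mean,
                    final_rank = comp$ranking$rank[
                      match(rownames(comp$component_ranks),
                            comp$ranking$gene)]),
         "comprehensive.tsv")
    for (m in names(report$comparisons))
      wtsv(as.data.frame(report$comparisons[[m]]$comparison),
           sprintf("rank_changes_%s.tsv", m))
    wtsv(data.frame(gene = rownames(report$table), report$table,
                    check.names = FALSE), "table.tsv")
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    payload <- list(schema = "refstab-report/1",
                    params = report$params,
                    table = as.data.frame(report$table),
                    comparisons = lapply(report$comparisons, function(x)
                      c(list(genes = as.data.frame(x$comparison)),
                        x$summary)),
                    vcurve = lapply(report$vcurve, function(v)
                      list(n = v$n, v = unname(v$v),
                           optimal_n = v$optimal_n, cutoff = v$cutoff)))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, p)
  }
  if ("md" %in% format) {
    p <- file.path(dir, "report.md")
    lines <- c("# Reference-gene stability report", "",
               "## Rankings (rank labels per method/mode)", "",
               paste(c("gene", colnames(report$table)), collapse = " | "),
               paste(rep("---", ncol(report$table) + 1), collapse = " | "),
               apply(cbind(rownames(report$table), report$table), 1,
                     paste, collapse = " | "),
               "")
    for (m in names(report$comparisons)) {
      s <- report$comparisons[[m]]$summary
      lines <- c(lines, sprintf(
        "%s corrected vs E2: %d/%d ranks changed (%d%%), %d minor, %d major.",
        m, s$n_changed, s$n_total, s$pct_changed, s$n_minor, s$n_major))
    }
    for (mode in names(report$vcurve)) {
      vc <- report$vcurve[[mode]]
      lines <- c(lines, "", sprintf(
        "Optimal number of reference genes (%s mode): %s (V cutoff %.2f).",
        mode, ifelse(is.na(vc$optimal_n), "undefined", vc$optimal_n),
        vc$cutoff),
        paste("Note: the pairwise-variation cutoff is a rule of thumb;",
              "a visual interpretation of the trend of the pairwise",
              "variations can also be informative."))
    }
    lines <- c(lines, "", paste("Comprehensive ranking caveat:",
                                report$comprehensive$caveat))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report: methods", paste(x$params$methods, collapse = ", "),
      "| modes", paste(x$params$modes, collapse = ", "), "\n\n")
  print(x$table, quote = FALSE)
  for (m in names(x$comparisons)) {
    s <- x$comparisons[[m]]$summary
    cat(sprintf("\n%s corrected vs E2: %d/%d changed (%d%%), %d minor, %d major",
                m, s$n_changed, s$n_total, s$pct_changed, s$n_minor,
                s$n_major))
  }
  cat("\n")
  invisible(x)
}
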