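#' Published reference-gene ranking table
#'
#' A transcription of a published 14-gene ranking table from a human
#' testis reference-gene validation study, covering two sample sets (FS1:
#' Sertoli-cell cultures, n = 11; CIS: carcinoma-in-situ biopsies, n = 6)
#' and, per dataset, the geNorm and NormFinder rankings computed with and
#' without efficiency correction (the uncorrected columns coincide with
#' the raw-Cq web-tool output) plus the two BestKeeper orderings
#' (correlation-based and SD-based). Tie sets are printed "1/2". Ships as
#' `extdata/table2.tsv`; used to replay the study's discrepancy statistics
#' without access to the underlying raw Cq data.
#'
#' @param path fixture path; defaults to the installed copy.
#' @return data.frame, one row per (dataset, gene).
#' @export
published_rankings <- function(path = system.file("extdata", "table2.tsv",
                                                  package = "refstab")) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Replay the published efficiency-corrected vs uncorrected comparison
#'
#' Rebuilds [stability_ranking()]s from the printed rank labels of
#' [published_rankings()] and runs [rank_compare()] for each method on
#' each dataset, pooling the two datasets per method. This reproduces the
#' study-level discrepancy statistics: how many of the 2 x 14 per-gene
#' ranks move when amplification efficiency is ignored, and how many of
#' those moves exceed one rank position ("major").
#'
#' @param tbl data.frame as returned by [published_rankings()].
#' @return list with per-method entries (`genorm`, `normfinder`), each
#'   holding the per-dataset `rank_comparison`s and the pooled `summary`.
#' @export
replay_published_comparison <- function(tbl = published_rankings()) {
  out <- list()
  for (method in c("genorm", "normfinder")) {
    per_ds <- lapply(split(tbl, tbl$dataset), function(d) {
      a <- ranking_from_labels(d$gene, d[[paste0(method, "_eff")]],
                               method = method,
                               efficiency_mode = "corrected")
      b <- ranking_from_labels(d$gene, d[[paste0(method, "_noeff")]],
                               method = method, efficiency_mode = "E2")
      rank_compare(a, b)
    })
    out[[method]] <- list(comparisons = per_ds,
                          summary = do.call(summarize_pair, per_ds))
  }
  out
}
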