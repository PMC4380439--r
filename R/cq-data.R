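#' Construct a Cq matrix
#'
#' The central container of the package: a complete genes x samples matrix of
#' quantification-cycle (Cq) values, optionally carrying a sample-to-group
#' assignment. Cq values are the PCR cycle at which a reaction crosses the
#' detection threshold; lower Cq means more template.
#'
#' Matrices must be complete: stability algorithms downstream assume every
#' (gene, sample) cell is observed, and silent imputation would corrupt the
#' estimates, so missing cells are rejected rather than filled in.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene/sample identifiers unless `genes` /
#'   `samples` are given.
#' @param genes,samples optional character vectors of identifiers overriding
#'   the dimnames.
#' @param groups optional named character vector mapping every sample to a
#'   group label, or `NULL` for ungrouped designs.
#' @return an object of class `cq_matrix`: the numeric matrix with a
#'   `groups` attribute.
#' @examples
#' m <- matrix(c(24, 25, 26, 30, 31, 29), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("GAPDH", "TBP"), c("s1", "s2", "s3")))
#' cq <- cq_matrix(m)
#' @export
cq_matrix <- function(values, genes = rownames(values),
                      samples = colnames(values), groups = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes) || is.null(samples))
    stop("gene and sample identifiers are required (dimnames or arguments)")
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (length(genes) != nrow(values) || length(samples) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (anyNA(values) || any(!is.finite(values)))
    stop("incomplete matrix: all Cq values must be present and finite")
  if (any(values <= 0 | values >= 45))
    stop("Cq values must lie in (0, 45) cycles")
  dimnames(values) <- list(genes, samples)
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    if (is.null(names(groups)) || !setequal(names(groups), samples))
      stop("groups must be a named vector covering every sample exactly once")
    groups <- groups[samples]
  }
  structure(values, groups = groups, class = c("cq_matrix", "matrix", "array"))
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("Cq matrix: %d genes x %d samples%s\n", nrow(x), ncol(x),
              if (is.null(attr(x, "groups"))) "" else
                sprintf(" (%d groups)", length(unique(attr(x, "groups"))))))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Sample groups of a Cq matrix
#' @param cq a `cq_matrix`
#' @return named character vector (sample -> group) or `NULL`
#' @export
cq_groups <- function(cq) attr(cq, "groups")

.delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a Cq table from CSV/TSV
#'
#' Two layouts are supported. `wide`: first column `gene`, remaining columns
#' are sample identifiers, cells are Cq. `long`: columns `sample`, `gene`,
#' optionally `replicate`, and `cq`; technical replicates of the same
#' (gene, sample) are aggregated with `replicate_policy` (arithmetic mean of
#' Cq by default, matching the usual instrument-software treatment of
#' triplicates). The delimiter is inferred from the file extension
#' (`.csv` comma, `.tsv`/`.txt` tab).
#'
#' Gene and sample order follow first appearance in the file. Duplicate
#' (gene, sample, replicate) triples, non-numeric Cq and incomplete matrices
#' are errors, never silently repaired.
#'
#' @param path file path.
#' @param layout `"wide"` or `"long"`.
#' @param replicate_policy how to aggregate technical replicates in long
#'   layout: `"mean"` (default) or `"median"`.
#' @param groups optional named character vector or path to a `sample,group`
#'   CSV/TSV attaching a group design.
#' @param warn_spread optional numeric (cycles). When given, a warning is
#'   emitted for every (gene, sample) whose replicate range exceeds this
#'   threshold (0.5 cycles is a common screening value); no value is dropped.
#' @return a [cq_matrix()].
#' @export
read_cq <- function(path, layout = c("wide", "long"),
                    replicate_policy = c("mean", "median"),
                    groups = NULL, warn_spread = NULL) {
  layout <- match.arg(layout)
  replicate_policy <- match.arg(replicate_policy)
  sep <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (is.character(groups) && length(groups) == 1 && file.exists(groups))
    groups <- read_groups(groups)
  if (layout == "wide") {
    if (names(df)[1] != "gene")
      stop("wide layout requires first column 'gene'")
    genes <- df$gene
    samples <- names(df)[-1]
    vals <- vapply(df[-1], .as_cq_numeric, numeric(nrow(df)))
    vals <- matrix(vals, nrow = length(genes),
                   dimnames = list(genes, samples))
    return(cq_matrix(vals, groups = groups))
  }
  need <- c("sample", "gene", "cq")
  if (!all(need %in% names(df)))
    stop("long layout requires columns sample, gene, cq (optional replicate)")
  rep_id <- if ("replicate" %in% names(df)) df$replicate else
    stats::ave(seq_len(nrow(df)), df$gene, df$sample, FUN = seq_along)
  key <- paste(df$gene, df$sample, rep_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, sample, replicate) triple in input")
  cqv <- .as_cq_numeric(df$cq)
  genes <- unique(df$gene)
  samples <- unique(df$sample)
  agg <- switch(replicate_policy, mean = mean, median = stats::median)
  cell <- paste(df$gene, df$sample, sep = "\r")
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  spl <- split(cqv, cell)
  for (k in names(spl)) {
    gs <- strsplit(k, "\r", fixed = TRUE)[[1]]
    vals[gs[1], gs[2]] <- agg(spl[[k]])
    if (!is.null(warn_spread) && diff(range(spl[[k]])) > warn_spread)
      warning(sprintf("replicate spread %.2f cycles for (%s, %s) exceeds %.2f",
                      diff(range(spl[[k]])), gs[1], gs[2], warn_spread))
  }
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete matrix: missing Cq for (%s, %s)",
                 genes[miss[1]], samples[miss[2]]))
  }
  cq_matrix(vals, groups = groups)
}

.as_cq_numeric <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) stop("non-numeric Cq value: ", x[which(is.na(out))[1]])
  out
}

#' Write a Cq matrix to CSV/TSV (wide layout)
#' @param cq a `cq_matrix`
#' @param path output file; delimiter inferred from extension
#' @export
write_cq <- function(cq, path) {
  df <- data.frame(gene = rownames(cq), unclass(cq)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a sample-to-group table (`sample,group`)
#' @param path CSV/TSV with columns `sample` and `group`
#' @return named character vector sample -> group
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("groups table requires columns sample, group")
  stats::setNames(as.character(df$group), as.character(df$sample))
}

#' Construct a per-gene amplification-efficiency table
#'
#' The amplification base E is the per-cycle amplification factor of an
#' assay; E = 2 is perfect doubling ("100% efficiency") and efficiency in
#' percent is (E - 1) x 100. Both conventions circulate: values are accepted
#' either as the base (e.g. 1.93) or as percent (e.g. 93) and stored as
#' base.
#'
#' Bases outside [1.5, 2.2] are rejected as physically implausible; bases
#' outside [1.8, 2.1] draw a warning since such assays usually warrant
#' primer redesign rather than correction alone.
#'
#' @param e named numeric vector of efficiencies (names = genes).
#' @param format `"auto"` (values greater than 3 are treated as percent),
#'   `"base"`, or `"percent"`.
#' @return object of class `efficiency_table`: named numeric vector of bases.
#' @export
efficiency_table <- function(e, format = c("auto", "base", "percent")) {
  format <- match.arg(format)
  if (is.null(names(e)) || anyDuplicated(names(e)))
    stop("efficiencies must be named by gene, uniquely")
  e <- vapply(e, as.numeric, numeric(1))
  if (format == "percent" || (format == "auto" && any(e > 3)))
    e <- 1 + e / 100
  if (any(e < 1.5 | e > 2.2))
    stop("amplification base outside [1.5, 2.2]: check units (base vs percent)")
  if (any(e < 1.8 | e > 2.1))
    warning("amplification base outside [1.8, 2.1] for: ",
            paste(names(e)[e < 1.8 | e > 2.1], collapse = ", "))
  structure(e, class = "efficiency_table")
}

#' Read an efficiency table (`gene,efficiency` CSV/TSV)
#' @inheritParams efficiency_table
#' @param path file path
#' @export
read_efficiency <- function(path, format = c("auto", "base", "percent")) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "efficiency") %in% names(df)))
    stop("efficiency table requires columns gene, efficiency")
  efficiency_table(stats::setNames(df$efficiency, df$gene), format = format)
}

#' Efficiency-corrected relative quantities
#'
#' Converts Cq values to linear relative quantities per gene, using the
#' sample with the lowest Cq (most template) as the reference:
#' \deqn{RQ_{ij} = E_i^{\,minCq_i - Cq_{ij}}}
#' so the minimum-Cq sample of each gene gets RQ = 1 and all other samples
#' fall in (0, 1]. In `"E2"` mode every gene uses E = 2, i.e. 100% assumed
#' efficiency — the convention of raw-Cq web tools.
#'
#' @param cq a [cq_matrix()].
#' @param eff an [efficiency_table()] covering every gene; ignored (may be
#'   `NULL`) in `"E2"` mode.
#' @param efficiency_mode `"corrected"` or `"E2"`.
#' @return an `rq_matrix`: numeric matrix with attributes `efficiency_mode`
#'   and `groups`.
#' @examples
#' m <- matrix(c(22, 25, 23), nrow = 1, dimnames = list("g1", c("a","b","c")))
#' cq <- cq_matrix(m)
#' compute_rq(cq, efficiency_mode = "E2")  # 1, 2^-3, 2^-1
#' @export
compute_rq <- function(cq, eff = NULL,
                       efficiency_mode = c("corrected", "E2")) {
  efficiency_mode <- match.arg(efficiency_mode)
  stopifnot(inherits(cq, "cq_matrix"))
  if (efficiency_mode == "corrected") {
    if (is.null(eff)) stop("corrected mode requires an efficiency table")
    missing <- setdiff(rownames(cq), names(eff))
    if (length(missing))
      stop("gene absent from efficiency table: ",
           paste(missing, collapse = ", "))
    e <- unclass(eff)[rownames(cq)]
  } else {
    e <- rep(2, nrow(cq))
  }
  v <- unclass(cq)
  rq <- e ^ (apply(v, 1, min) - v)
  structure(rq, efficiency_mode = efficiency_mode, groups = cq_groups(cq),
            class = c("rq_matrix", "matrix", "array"))
}

#' Log2 relative quantities
#'
#' Shared log transform feeding geNorm, NormFinder and normalization-factor
#' computations. In E2 mode this equals `minCq - Cq` exactly (base-2
#' identity), which is why raw-Cq tools and E = 2 relative quantities give
#' identical rankings.
#'
#' @param rq an `rq_matrix` from [compute_rq()], or any positive matrix.
#' @return plain numeric matrix of log2 values, `groups` attribute carried
#'   over when present.
#' @export
log_rq <- function(rq) {
  if (any(rq <= 0)) stop("relative quantities must be strictly positive")
  out <- log2(unclass(rq))
  attr(out, "efficiency_mode") <- attr(rq, "efficiency_mode")
  attr(out, "groups") <- attr(rq, "groups")
  out
}
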