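#' Simulation configuration for synthetic Cq data
#'
#' The generator works on a latent log2-abundance scale: sample j of group
#' g carries a shared loading factor L_j ~ N(0, tau^2) (pipetting / input
#' amount variation affecting every gene alike), gene i adds a
#' group-dependent expression shift delta_ig (zero for genes designed
#' stable) and independent noise eps_ij ~ N(0, sigma_i^2). Abundance is
#' converted to quantification cycles through each assay's amplification
#' base:
#' \deqn{Cq_{ij} = b_i - q_{ij} \cdot \ln 2 / \ln E_i}
#' so one log2 unit of abundance is worth one cycle only for a perfectly
#' doubling assay (E = 2). Technical replicates add N(0, rep_sd^2) cycles
#' around the true Cq.
#'
#' "Stability" has a well-defined ground truth under this model: a gene is
#' stable when its sigma_i is small and its delta_ig are zero; the shared
#' loading L_j cancels from all pairwise comparisons.
#'
#' @param genes character vector of gene names.
#' @param baseline per-gene baseline Cq b_i (cycles).
#' @param sigma per-gene noise SD (log2 units).
#' @param efficiency per-gene amplification base E_i in [1.5, 2.2].
#' @param tau shared per-sample loading SD (log2 units).
#' @param group_sizes integer vector of group sizes (a single size = one
#'   ungrouped set).
#' @param group_names optional group labels.
#' @param delta genes x groups matrix of expression shifts (log2 units);
#'   defaults to all zero.
#' @param replicates technical replicates per reaction.
#' @param rep_sd replicate noise SD (cycles).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(genes, baseline, sigma, efficiency, tau = 0.5,
                       group_sizes = 6, group_names = NULL, delta = NULL,
                       replicates = 3, rep_sd = 0.1) {
  G <- length(genes)
  stopifnot(length(baseline) == G, length(sigma) == G,
            length(efficiency) == G,
            all(sigma >= 0), tau >= 0, rep_sd >= 0, replicates >= 1,
            all(group_sizes >= 1),
            all(efficiency >= 1.5 & efficiency <= 2.2))
  K <- length(group_sizes)
  if (is.null(group_names)) group_names <- paste0("grp", seq_len(K))
  stopifnot(length(group_names) == K)
  if (is.null(delta)) delta <- matrix(0, G, K)
  delta <- matrix(delta, G, K, dimnames = list(genes, group_names))
  structure(list(genes = as.character(genes), baseline = baseline,
                 sigma = sigma,
                 efficiency = stats::setNames(efficiency, genes),
                 tau = tau, group_sizes = as.integer(group_sizes),
                 group_names = group_names, delta = delta,
                 replicates = as.integer(replicates), rep_sd = rep_sd),
            class = "sim_config")
}

#' Simulate a synthetic Cq dataset
#'
#' Draws one dataset under a [sim_config()]. The seed is mandatory: every
#' dataset is fully reproducible and the latent draws are returned in a
#' truth record so tests never need to re-derive them.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (required).
#' @return list with `cq` (replicate-averaged [cq_matrix()] with groups
#'   attached when the design has more than one group), `cq_replicates`
#'   (long data.frame sample/gene/replicate/cq), `efficiency`
#'   ([efficiency_table()]), `groups` (named vector or `NULL`), and
#'   `truth` (list of the latent `L`, `q`, `true_cq`, per-gene `sigma`,
#'   `delta`, and the config).
#' @export
simulate_cq <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  G <- length(config$genes)
  n <- sum(config$group_sizes)
  grp <- rep(config$group_names, config$group_sizes)
  samples <- paste0(rep(config$group_names, config$group_sizes), "_",
                    unlist(lapply(config$group_sizes, seq_len)))
  L <- stats::rnorm(n, 0, config$tau)
  eps <- matrix(stats::rnorm(G * n, 0, config$sigma), G, n)  # sigma recycles by row
  q <- rep(L, each = G) + config$delta[, grp, drop = FALSE] + eps
  dimnames(q) <- list(config$genes, samples)
  true_cq <- config$baseline - q * (log(2) / log(config$efficiency))
  reps <- config$replicates
  rep_noise <- array(stats::rnorm(G * n * reps, 0, config$rep_sd),
                     dim = c(G, n, reps))
  cq_rep <- sweep(rep_noise, c(1, 2), true_cq, "+")
  long <- data.frame(
    sample = rep(rep(samples, each = G), reps),
    gene = rep(config$genes, n * reps),
    replicate = rep(seq_len(reps), each = G * n),
    cq = as.vector(cq_rep), stringsAsFactors = FALSE)
  agg <- apply(cq_rep, c(1, 2), mean)
  dimnames(agg) <- list(config$genes, samples)
  groups <- if (length(config$group_sizes) > 1)
    stats::setNames(grp, samples) else NULL
  list(cq = cq_matrix(agg, groups = groups),
       cq_replicates = long,
       # off-range efficiencies are by design here, not a data-QC issue
       efficiency = suppressWarnings(efficiency_table(config$efficiency)),
       groups = groups,
       truth = list(L = stats::setNames(L, samples), q = q,
                    true_cq = true_cq, sigma = config$sigma,
                    delta = config$delta, config = config))
}

# shared gene panel: 14 common human reference-gene assays. sigma encodes
# the designed stability ordering (HMBS/SDHA/TOP2B most stable, RLP13 a
# designed outlier); four assays (RPS18, TBP, UBC, YWHAZ) have
# amplification bases more than 10% away from perfect doubling, i.e.
# outside [1.9, 2.1].
.panel <- function() {
  data.frame(
    gene = c("ACTB", "B2M", "GAPDH", "HMBS", "HPRT1", "IGF1R", "RLP13",
             "RPS18", "SDHA", "SOX9", "TBP", "TOP2B", "UBC", "YWHAZ"),
    baseline = c(18.5, 20.0, 19.5, 26.0, 25.0, 28.0, 21.0,
                 19.0, 24.0, 27.5, 26.5, 27.0, 22.0, 23.0),
    sigma = c(0.35, 0.45, 0.30, 0.10, 0.22, 0.40, 0.90,
              0.33, 0.12, 0.50, 0.28, 0.15, 0.25, 0.30),
    efficiency = c(2.02, 2.05, 1.98, 1.96, 2.03, 2.04, 1.95,
                   1.75, 2.00, 1.97, 1.87, 1.99, 2.15, 1.85),
    stringsAsFactors = FALSE)
}

#' Built-in simulation presets
#'
#' Two presets mirror the sample sets of a typical reference-gene
#' validation study in human testicular material: `"fs1"` — a Sertoli-cell
#' culture experiment with three conditions (monoculture, co-culture with
#' a seminoma-like line, co-culture with mesenchymal stem cells) of sizes
#' 4/4/3, where two growth-factor/transcription-factor genes (IGF1R, SOX9)
#' respond to the co-culture condition and are therefore designed
#' unstable; `"cis"` — six ungrouped tissue biopsies with a larger shared
#' loading spread, as expected for snap-frozen clinical material. Both use
#' a 14-gene panel in which four assays (RPS18, TBP, UBC, YWHAZ) deviate
#' by more than 10% from 100% amplification efficiency.
#'
#' @param name `"fs1"` or `"cis"`.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("fs1", "cis")) {
  name <- match.arg(name)
  p <- .panel()
  if (name == "fs1") {
    delta <- matrix(0, nrow(p), 3,
                    dimnames = list(p$gene, c("mono", "tcam2", "msc")))
    delta["IGF1R", ] <- c(0, 0.8, 0.3)
    delta["SOX9", ] <- c(0, 1.2, -0.5)
    delta["B2M", ] <- c(0, 0.4, 0.4)
    sim_config(p$gene, p$baseline, p$sigma, p$efficiency, tau = 0.5,
               group_sizes = c(4, 4, 3),
               group_names = c("mono", "tcam2", "msc"), delta = delta,
               replicates = 3, rep_sd = 0.1)
  } else {
    sim_config(p$gene, p$baseline, p$sigma, p$efficiency, tau = 0.8,
               group_sizes = 6, group_names = "cis",
               replicates = 3, rep_sd = 0.1)
  }
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `cq.csv` (long layout with replicates), `efficiency.csv`,
#' `groups.csv` (when grouped), `truth.json` and `config.json` into a
#' directory.
#'
#' @param sim result of [simulate_cq()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$cq_replicates, file.path(dir, "cq.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gene = names(sim$efficiency),
                              efficiency = as.numeric(sim$efficiency)),
                   file.path(dir, "efficiency.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(sim$groups))
    utils::write.csv(data.frame(sample = names(sim$groups),
                                group = unname(sim$groups)),
                     file.path(dir, "groups.csv"),
                     row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  jsonlite::write_json(unclass(sim$truth$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}
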