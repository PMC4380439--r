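#' NormFinder stability, ungrouped samples
#'
#' Model-based stability estimation. Log2 relative quantities are assumed
#' to follow an additive two-way model x_ij = alpha_i + beta_j + e_ij
#' (gene effect + sample loading + gene-specific noise with variance
#' sigma_i^2). Two-way residuals
#' r_ij = x_ij - mean_i - mean_j + grand mean estimate the noise, and the
#' raw per-gene variance s2_i = sum_j r_ij^2 / (n-1) is de-biased for the
#' contamination every gene's residuals receive from the panel:
#' \deqn{\hat\sigma^2_i = \max\{ (s^2_i - \sum_{i'} s^2_{i'} / (G(G-1)))
#'   \cdot G/(G-2),\; 0 \}}
#' This method-of-moments corrected estimator is unbiased under the model
#' (verified by simulation in the test suite). The stability value is
#' rho_i = sigma-hat_i, ranked ascending: genes whose expression tracks the
#' common sample loading with the least extra noise rank best.
#'
#' Stability values are implementation-specific across the various
#' NormFinder ports; rankings, not absolute values, are the contract.
#'
#' @param logq genes x samples matrix of log2 relative quantities
#'   (G >= 3 genes, n >= 4 samples).
#' @param efficiency_mode tag recorded in the resulting ranking.
#' @return a `normfinder_result` list: `ranking` ([stability_ranking()]),
#'   `rho`, `sigma2`, `mode = "ungrouped"`.
#' @export
normfinder_ungrouped <- function(logq, efficiency_mode = NA_character_) {
  G <- nrow(logq); n <- ncol(logq)
  if (G < 3) stop("NormFinder needs at least 3 genes")
  if (n < 4) stop("NormFinder needs at least 4 samples")
  genes <- rownames(logq)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  s2 <- .nf_s2(logq)
  sigma2_raw <- (s2 - sum(s2) / (G * (G - 1))) * G / (G - 2)
  sigma2 <- pmax(sigma2_raw, 0)
  rho <- stats::setNames(sqrt(sigma2), genes)
  structure(list(ranking = stability_ranking(genes, rho,
                                             method = "normfinder",
                                             efficiency_mode = efficiency_mode),
                 rho = rho, sigma2 = stats::setNames(sigma2, genes),
                 # un-truncated moment estimator: unbiased under the model,
                 # may go (slightly) negative; truncation is for reporting rho
                 sigma2_raw = stats::setNames(sigma2_raw, genes),
                 mode = "ungrouped"),
            class = "normfinder_result")
}

# per-gene residual variance from the two-way additive fit, n-1 denominator
.nf_s2 <- function(x) {
  r <- x - rowMeans(x) - rep(colMeans(x), each = nrow(x)) + mean(x)
  rowSums(r^2) / (ncol(x) - 1)
}

.nf_sigma2 <- function(x) {
  G <- nrow(x)
  s2 <- .nf_s2(x)
  pmax((s2 - sum(s2) / (G * (G - 1))) * G / (G - 2), 0)
}

#' NormFinder stability with sample groups
#'
#' Separates intragroup from intergroup variation, the defining feature of
#' the model-based approach: a gene may be quiet within every condition yet
#' shift systematically between conditions, and such a gene is a poor
#' normalizer even though its pooled variance looks acceptable.
#'
#' Within each group the ungrouped machinery yields per-gene intragroup
#' variances sigma2_ig. Intergroup deviations d_ig are the group means of
#' sample-centered expression, centered per gene across groups with
#' group-size weights (so the size-weighted sum of d_ig is 0 per gene).
#' The common intergroup variance gamma^2 = max(mean d_ig^2 -
#' mean sigma2_ig/n_g, 0) shrinks the raw deviations,
#' d~_ig = d_ig * gamma^2 / (gamma^2 + sigma2_ig/n_g), pulling
#' noise-dominated deviations toward zero. The stability value combines
#' both components:
#' \deqn{\rho_i = \frac{1}{K}\sum_g (|\tilde d_{ig}| +
#'   \hat\sigma_{ig}/\sqrt{n_g})}
#' ranked ascending.
#'
#' Every group needs at least 3 samples. A single-group design is accepted
#' (the intergroup terms vanish and the ordering reduces to the ungrouped
#' one); it exists for cross-checking, not as a recommended analysis.
#'
#' @param logq genes x samples matrix of log2 relative quantities.
#' @param groups named character vector mapping every sample (column) to a
#'   group label; defaults to the `groups` attribute of `logq`.
#' @param efficiency_mode tag recorded in the resulting ranking.
#' @return a `normfinder_result` list: `ranking`, `rho`, `sigma2`
#'   (genes x groups), `d_hat`, `d_tilde` (genes x groups), `gamma2`,
#'   `mode = "grouped"`.
#' @export
normfinder_grouped <- function(logq, groups = attr(logq, "groups"),
                               efficiency_mode = NA_character_) {
  G <- nrow(logq)
  if (G < 3) stop("NormFinder needs at least 3 genes")
  if (is.null(groups)) stop("grouped NormFinder requires a group assignment")
  samples <- colnames(logq)
  if (is.null(samples) || !all(samples %in% names(groups)))
    stop("every sample needs a group label")
  grp <- factor(groups[samples], levels = unique(groups[samples]))
  K <- nlevels(grp)
  ng <- as.vector(table(grp))
  if (any(ng < 3)) stop("every group needs at least 3 samples")
  genes <- rownames(logq)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))

  sigma2 <- sapply(levels(grp), function(g)
    .nf_sigma2(logq[, grp == g, drop = FALSE]))
  sigma2 <- matrix(sigma2, nrow = G, dimnames = list(genes, levels(grp)))

  y <- logq - rep(colMeans(logq), each = G)      # sample-centered
  d_hat <- sapply(levels(grp), function(g)
    rowMeans(y[, grp == g, drop = FALSE]))
  d_hat <- matrix(d_hat, nrow = G, dimnames = list(genes, levels(grp)))
  d_hat <- d_hat - as.vector(d_hat %*% ng) / sum(ng)  # size-weighted centering

  se2 <- sweep(sigma2, 2, ng, "/")               # sigma2_ig / n_g
  gamma2 <- if (K > 1) max(mean(d_hat^2) - mean(se2), 0) else 0
  d_tilde <- if (gamma2 > 0) d_hat * gamma2 / (gamma2 + se2) else d_hat * 0
  rho <- rowMeans(abs(d_tilde) + sqrt(se2))
  rho <- stats::setNames(rho, genes)

  structure(list(ranking = stability_ranking(genes, rho,
                                             method = "normfinder",
                                             efficiency_mode = efficiency_mode),
                 rho = rho, sigma2 = sigma2, d_hat = d_hat,
                 d_tilde = d_tilde, gamma2 = gamma2, mode = "grouped"),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder (%s mode)\n", x$mode))
  print(x$ranking, ...)
  invisible(x)
}
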