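# Brute-force reference implementations, kept deliberately naive (explicit
# loops straight from the formula definitions) and independent of the
# package's vectorized code paths.

rand_cq <- function(G, n, seed, spread = 2) {
  set.seed(seed)
  m <- matrix(stats::rnorm(G * n, mean = 25, sd = spread), G, n,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(n))))
  cq_matrix(m)
}

rand_logq <- function(G, n, seed, spread = 1) {
  set.seed(seed)
  matrix(stats::rnorm(G * n, 0, spread), G, n,
         dimnames = list(paste0("g", seq_len(G)), paste0("s", seq_len(n))))
}

oracle_genorm_m <- function(x) {
  G <- nrow(x)
  M <- numeric(G)
  for (j in seq_len(G)) {
    vs <- c()
    for (k in seq_len(G)) if (k != j)
      vs <- c(vs, stats::sd(x[j, ] - x[k, ]))
    M[j] <- mean(vs)
  }
  stats::setNames(M, rownames(x))
}

# stepwise exclusion with the same documented tie-break (later input order
# removed first), but driven entirely by the loop oracle above
oracle_genorm_exclusion <- function(x) {
  genes <- rownames(x)
  keep <- genes
  excluded <- character(0)
  while (length(keep) > 2) {
    M <- oracle_genorm_m(x[keep, , drop = FALSE])
    worst <- names(M)[M == max(M)]
    drop <- worst[which.max(match(worst, genes))]
    excluded <- c(excluded, drop)
    keep <- setdiff(keep, drop)
  }
  list(excluded = excluded, pair = keep)
}

oracle_deltact <- function(cq) {
  v <- unclass(cq)
  G <- nrow(v)
  score <- numeric(G)
  for (i in seq_len(G)) {
    sds <- c()
    for (k in seq_len(G)) if (k != i)
      sds <- c(sds, stats::sd(v[i, ] - v[k, ]))
    score[i] <- mean(sds)
  }
  stats::setNames(score, rownames(v))
}

oracle_bestkeeper <- function(cq, sd_threshold = 1.5) {
  v <- unclass(cq)
  sds <- apply(v, 1, stats::sd)
  retained <- rownames(v)[sds <= sd_threshold]
  idx <- numeric(ncol(v))
  for (j in seq_len(ncol(v)))
    idx[j] <- prod(v[retained, j])^(1 / length(retained))
  r <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) r[i] <- stats::cor(v[i, ], idx)
  list(index = idx, r = stats::setNames(r, rownames(v)),
       sd = sds, retained = retained)
}

oracle_vcurve <- function(rq, stability_order) {
  # direct recomputation on the linear RQ scale
  G <- nrow(rq)
  nf <- function(n) apply(rq[stability_order[seq_len(n)], , drop = FALSE],
                          2, function(col) prod(col)^(1 / n))
  vapply(2:(G - 1), function(n) stats::sd(log2(nf(n) / nf(n + 1))),
         numeric(1))
}
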