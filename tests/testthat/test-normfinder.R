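test_that("a gene equal to the per-sample panel mean is maximally stable", {
  x <- rand_logq(5, 8, seed = 4)
  # a row equal to the column means of the others also equals the column
  # means of the full matrix, so its two-way residuals vanish identically
  x <- rbind(ref = colMeans(x), x)
  nf <- normfinder_ungrouped(x)
  expect_equal(unname(nf$rho["ref"]), 0)
  expect_identical(nf$ranking$gene[1], "ref")
})

test_that("rho is invariant to sample permutation and per-gene shifts", {
  x <- rand_logq(6, 10, seed = 21)
  perm <- sample(ncol(x))
  expect_equal(normfinder_ungrouped(x)$rho,
               normfinder_ungrouped(x[, perm])$rho)
  x2 <- x; x2[3, ] <- x2[3, ] + 4
  expect_equal(normfinder_ungrouped(x)$rho, normfinder_ungrouped(x2)$rho)

  g <- rep(c("a", "b"), each = 5)
  names(g) <- colnames(x)
  expect_equal(normfinder_grouped(x, g)$rho,
               normfinder_grouped(x2, g)$rho)
})

test_that("the moment estimator recovers known variances (scaled-down run)", {
  # scaled-down version of the 1000-rep recovery in test-acceptance.R
  G <- 14; n <- 50; reps <- 200
  sigma <- 0.05 * (0.8 / 0.05)^((0:(G - 1)) / (G - 1))
  set.seed(11)
  acc <- matrix(0, G, reps)
  for (r in seq_len(reps)) {
    x <- matrix(stats::rnorm(G * n, 0, sigma), G, n) +
      rep(stats::rnorm(n, 0, 1), each = G)
    rownames(x) <- paste0("g", 1:G)
    acc[, r] <- normfinder_ungrouped(x)$sigma2_raw
  }
  # 5% estimator-bias band plus a Monte-Carlo allowance: at 200 reps the
  # SE of the smallest-sigma gene's mean is ~9% of its true value (the
  # full-scale 5% check at 1000 reps runs in test-acceptance.R)
  expect_lt(max(abs(rowMeans(acc) / sigma^2 - 1)), 0.15)
})

test_that("grouped mode: intergroup invariants and degenerate branches", {
  x <- rand_logq(6, 12, seed = 31)
  g <- stats::setNames(rep(c("a", "b", "c"), each = 4), colnames(x))
  nf <- normfinder_grouped(x, g)
  # size-weighted centering: weighted d_hat sums to 0 per gene
  ng <- table(g[colnames(x)])[colnames(nf$d_hat)]
  expect_lt(max(abs(nf$d_hat %*% as.numeric(ng))), 1e-9)
  expect_true(all(nf$sigma2 >= 0))

  # zero-residual, zero-shift gene is rank 1 with rho = 0
  x2 <- rbind(ref = colMeans(x), x)
  nf2 <- normfinder_grouped(x2, g)
  expect_equal(unname(nf2$rho["ref"]), 0)
  expect_identical(nf2$ranking$gene[1], "ref")

  # identical groups: gamma2 = 0, d_tilde = 0, ranking by mean sigma/sqrt(n)
  blk <- rand_logq(5, 4, seed = 32)
  x3 <- cbind(blk, blk, blk)
  colnames(x3) <- paste0("s", 1:12)
  g3 <- stats::setNames(rep(c("a", "b", "c"), each = 4), colnames(x3))
  nf3 <- normfinder_grouped(x3, g3)
  expect_identical(nf3$gamma2, 0)
  expect_true(all(nf3$d_tilde == 0))
  expect_identical(order(rowMeans(sqrt(sweep(nf3$sigma2, 2,
                                             as.numeric(table(g3)), "/")))),
                   order(nf3$rho))

  expect_error(normfinder_grouped(x, stats::setNames(
    rep(c("a", "b"), c(10, 2)), colnames(x))), "at least 3 samples")
})

test_that("a group-shifted gene is flagged least stable", {
  worst <- vapply(1:100, function(seed) {
    set.seed(seed)
    G <- 10; ng <- 20
    x <- matrix(stats::rnorm(G * 3 * ng, 0, 0.2), G, 3 * ng) +
      rep(stats::rnorm(3 * ng, 0, 0.5), each = G)
    x[1, ] <- x[1, ] + rep(c(0, 1, 0), each = ng)  # delta = 1 in group b
    dimnames(x) <- list(paste0("g", 1:G), paste0("s", 1:(3 * ng)))
    g <- stats::setNames(rep(c("a", "b", "c"), each = ng), colnames(x))
    nf <- normfinder_grouped(x, g)
    nf$ranking$gene[G] == "g1"
  }, logical(1))
  expect_gte(mean(worst), 0.95)
})

test_that("single-group grouped mode reduces to the ungrouped ordering", {
  x <- rand_logq(7, 9, seed = 41)
  g <- stats::setNames(rep("all", ncol(x)), colnames(x))
  grouped <- normfinder_grouped(x, g)
  ungrouped <- normfinder_ungrouped(x)
  expect_identical(grouped$ranking$gene, ungrouped$ranking$gene)
  expect_true(all(grouped$d_tilde == 0))
})

test_that("preconditions are enforced", {
  x <- rand_logq(2, 6, seed = 1)
  expect_error(normfinder_ungrouped(x), "at least 3 genes")
  expect_error(normfinder_ungrouped(rand_logq(4, 3, seed = 1)),
               "at least 4 samples")
})
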