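test_that("simulation is deterministic given the seed", {
  cfg <- sim_preset("cis")
  a <- simulate_cq(cfg, seed = 42)
  b <- simulate_cq(cfg, seed = 42)
  expect_identical(a, b)
  c <- simulate_cq(cfg, seed = 43)
  expect_false(identical(as.vector(a$cq), as.vector(c$cq)))
  expect_error(simulate_cq(cfg), "seed is required")
})

test_that("degenerate configs collapse to the expected exact structure", {
  genes <- paste0("g", 1:4)
  cfg0 <- sim_config(genes, baseline = c(20, 22, 24, 26),
                     sigma = rep(0, 4), efficiency = rep(2, 4), tau = 0,
                     group_sizes = 5, replicates = 1, rep_sd = 0)
  sim0 <- simulate_cq(cfg0, seed = 1)
  # every gene constant across samples -> all M exactly 0
  expect_true(all(apply(sim0$cq, 1, stats::sd) == 0))
  lq <- log_rq(compute_rq(sim0$cq, efficiency_mode = "E2"))
  expect_equal(unname(genorm_m(lq)), rep(0, 4))

  # with E = 2 everywhere, Cq = baseline - q exactly
  cfg2 <- sim_config(genes, baseline = c(20, 22, 24, 26),
                     sigma = rep(0.3, 4), efficiency = rep(2, 4),
                     tau = 0.4, group_sizes = 5, replicates = 1, rep_sd = 0)
  sim2 <- simulate_cq(cfg2, seed = 2)
  expect_equal(unclass(sim2$cq),
               c(20, 22, 24, 26) - sim2$truth$q, ignore_attr = TRUE)
})

test_that("presets encode the two study designs", {
  fs1 <- sim_preset("fs1")
  expect_length(fs1$genes, 14)
  expect_identical(fs1$group_sizes, c(4L, 4L, 3L))
  cis <- sim_preset("cis")
  expect_identical(cis$group_sizes, 6L)
  expect_length(unique(cis$group_names), 1)
  # at least four assays deviate by more than 10% from perfect doubling
  expect_gte(sum(fs1$efficiency < 1.9 | fs1$efficiency > 2.1), 4)
  expect_error(sim_preset("nope"))

  sim <- simulate_cq(fs1, seed = 5)
  expect_identical(dim(sim$cq), c(14L, 11L))
  expect_identical(as.integer(table(sim$groups)[c("mono", "tcam2", "msc")]),
                   c(4L, 4L, 3L))
  expect_identical(sort(unique(sim$cq_replicates$replicate)), 1:3)
})

test_that("written datasets round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_cq(sim_preset("fs1"), seed = 9)
  write_simulation(sim, dir)
  cq <- read_cq(file.path(dir, "cq.csv"), layout = "long",
                groups = file.path(dir, "groups.csv"))
  expect_equal(unclass(cq), unclass(sim$cq), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(cq_groups(cq), sim$groups)
  # the preset deliberately contains off-range assays, hence the QC warning
  eff <- suppressWarnings(read_efficiency(file.path(dir, "efficiency.csv")))
  expect_equal(unclass(eff), unclass(sim$efficiency), tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("designed stability structure is recovered at large n", {
  # scaled-up FS1 design (50 samples per group), scaled-down seed count;
  # the designed most-stable trio has the smallest sigma and no group shift
  cfg <- sim_preset("fs1")
  cfg$group_sizes <- c(50L, 50L, 50L)
  cfg$replicates <- 1L
  stable3 <- c("HMBS", "SDHA", "TOP2B")
  # NormFinder is evaluated on the pooled (ungrouped) path: with designed
  # group-shifted genes in the panel, the grouped rho is dominated by the
  # per-gene luck of the intergroup-deviation noise (panel-shift leakage
  # from sample-centering), which is not monotone in sigma even at large n
  hits <- vapply(1:40, function(seed) {
    sim <- simulate_cq(cfg, seed = seed)
    lq <- log_rq(compute_rq(sim$cq, sim$efficiency))
    gn <- genorm_rank(lq)$ranking
    nf <- normfinder_ungrouped(lq)$ranking
    c(genorm_top = all(gn$gene[1:3] %in% stable3),
      nf_top = all(nf$gene[1:3] %in% stable3))
  }, logical(2))
  expect_gte(mean(hits["genorm_top", ]), 0.9)
  expect_gte(mean(hits["nf_top", ]), 0.9)

  # "largest sigma ranks last" is only well-posed without group shifts
  # (a strongly shifted gene legitimately competes for last place), so it
  # is checked on the ungrouped cis design scaled to 50 samples
  cis <- sim_preset("cis")
  cis$group_sizes <- 50L
  cis$replicates <- 1L
  worst_last <- vapply(1:40, function(seed) {
    sim <- simulate_cq(cis, seed = seed)
    lq <- log_rq(compute_rq(sim$cq, sim$efficiency))
    genorm_rank(lq)$ranking$gene[14] == "RLP13" &&
      normfinder_ungrouped(lq)$ranking$gene[14] == "RLP13"
  }, logical(1))
  expect_gte(mean(worst_last), 0.95)
})
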