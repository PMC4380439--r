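test_that("long layout aggregates replicates and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,gene,replicate,cq",
               "s1,g1,1,24.1", "s1,g1,2,24.3", "s1,g1,3,24.2",
               "s2,g1,1,25.0",
               "s1,g2,1,30.0", "s2,g2,1,31.0"), f)
  cq <- read_cq(f, layout = "long")
  expect_equal(unname(cq["g1", "s1"]), 24.2)
  expect_equal(rownames(cq), c("g1", "g2"))
  expect_equal(colnames(cq), c("s1", "s2"))

  # duplicate (gene, sample, replicate) triple
  writeLines(c("sample,gene,replicate,cq",
               "s1,g1,1,24.1", "s1,g1,1,24.3"), f)
  expect_error(read_cq(f, layout = "long"), "duplicate")

  # missing cell
  writeLines(c("sample,gene,replicate,cq",
               "s1,g1,1,24.1", "s2,g1,1,25.0", "s1,g2,1,30.0"), f)
  expect_error(read_cq(f, layout = "long"), "incomplete")

  # non-numeric Cq
  writeLines(c("sample,gene,replicate,cq",
               "s1,g1,1,abc", "s1,g2,1,30.0"), f)
  expect_error(read_cq(f, layout = "long"), "non-numeric")
})

test_that("replicate spread warning is flag-enabled", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,gene,replicate,cq",
               "s1,g1,1,24.0", "s1,g1,2,24.8",
               "s2,g1,1,25.0", "s2,g1,2,25.1"), f)
  expect_silent(read_cq(f, layout = "long"))
  expect_warning(read_cq(f, layout = "long", warn_spread = 0.5),
                 "replicate spread")
})

test_that("wide layout round-trips through write_cq", {
  cq <- rand_cq(3, 4, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cq(cq, f)
  back <- read_cq(f, layout = "wide")
  expect_equal(rownames(back), rownames(cq))
  expect_equal(colnames(back), colnames(cq))
  expect_equal(unclass(back), unclass(cq), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("cq_matrix enforces its invariants", {
  m <- matrix(c(24, 25, 26, 27), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(cq_matrix(m), "cq_matrix")
  m2 <- m; m2[1, 1] <- NA
  expect_error(cq_matrix(m2), "incomplete")
  m3 <- m; m3[1, 1] <- 50
  expect_error(cq_matrix(m3), "\\(0, 45\\)")
  expect_error(cq_matrix(m, groups = c(s1 = "a")), "every sample")
  expect_error(cq_matrix(matrix(m, 2, dimnames = list(c("a", "a"),
                                                      c("s1", "s2")))),
               "duplicate gene")
})

test_that("compute_rq implements the efficiency-corrected transform", {
  m <- matrix(c(22, 25, 23,
                24, 24, 26), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  cq <- cq_matrix(m)
  eff <- efficiency_table(c(g1 = 1.9, g2 = 2.0))

  rq <- compute_rq(cq, eff)
  # the min-Cq sample of each gene is the reference: RQ = 1
  expect_equal(unname(rq["g1", "a"]), 1)
  expect_equal(unname(rq["g2", "a"]), 1)
  # one cycle at E = 2 is one doubling
  expect_equal(unname(rq["g2", "c"]), 0.25)
  # E = 1.9, 3 cycles above min: frozen from direct power evaluation
  expect_equal(unname(rq["g1", "b"]), 0.1457938475, tolerance = 1e-9)
  # per-gene max is 1, all values in (0, 1]
  expect_true(all(rq > 0 & rq <= 1))
  expect_equal(unname(apply(rq, 1, max)), c(1, 1))

  expect_error(compute_rq(cq, efficiency_table(c(g1 = 1.9))),
               "absent from efficiency table")
  expect_error(compute_rq(cq, NULL, efficiency_mode = "corrected"),
               "requires an efficiency table")
})

test_that("log_rq is exact in E2 mode and matches the closed form", {
  m <- matrix(c(22, 25, 23), nrow = 1,
              dimnames = list("g1", c("a", "b", "c")))
  cq <- cq_matrix(m)
  lq <- log_rq(compute_rq(cq, efficiency_mode = "E2"))
  expect_identical(unname(lq[1, ]), c(0, -3, -1))  # minCq - Cq exactly
  lq19 <- log_rq(compute_rq(cq, efficiency_table(c(g1 = 1.9))))
  expect_equal(unname(lq19[1, "b"]), -2.77799825567, tolerance = 1e-9)
  expect_equal(unname(lq19[1, "a"]), 0)
})

test_that("E2 mode is bitwise identical to an all-2.0 efficiency table", {
  cq <- rand_cq(5, 6, seed = 3)
  eff2 <- efficiency_table(stats::setNames(rep(2, 5), rownames(cq)))
  a <- compute_rq(cq, eff2, efficiency_mode = "corrected")
  b <- compute_rq(cq, efficiency_mode = "E2")
  expect_identical(as.vector(a), as.vector(b))
  expect_identical(dimnames(a), dimnames(b))
})

test_that("negating the Eq.-1 exponent changes no stability value", {
  # the printed formula is sign-ambiguous; SD-based statistics cannot see it
  for (seed in 1:5) {
    lq <- rand_logq(5, 8, seed)
    expect_equal(genorm_m(lq), genorm_m(-lq))
    expect_equal(genorm_rank(lq)$ranking$label,
                 genorm_rank(-lq)$ranking$label)
    expect_equal(normfinder_ungrouped(lq)$rho,
                 normfinder_ungrouped(-lq)$rho)
  }
})

test_that("efficiency tables accept base and percent conventions", {
  expect_equal(unclass(efficiency_table(c(g1 = 93), format = "percent")),
               c(g1 = 1.93))
  expect_equal(unclass(efficiency_table(c(g1 = 93))), c(g1 = 1.93))  # auto
  expect_equal(unclass(efficiency_table(c(g1 = 1.93))), c(g1 = 1.93))
  expect_warning(efficiency_table(c(g1 = 1.75)), "outside \\[1.8, 2.1\\]")
  expect_error(suppressWarnings(efficiency_table(c(g1 = 1.3))),
               "outside \\[1.5, 2.2\\]")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,efficiency", "g1,1.95", "g2,2.0"), f)
  eff <- read_efficiency(f)
  expect_equal(unclass(eff), c(g1 = 1.95, g2 = 2.0))
})

test_that("groups tables attach to matrices read from disk", {
  fg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group", "s1,a", "s2,a", "s3,b"), fg)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2,s3", "g1,24,25,26", "g2,30,31,29"), f)
  cq <- read_cq(f, layout = "wide", groups = fg)
  expect_equal(cq_groups(cq), c(s1 = "a", s2 = "a", s3 = "b"))
})
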