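test_that("site-pattern counting follows the ABBA/BABA definitions", {
  aln <- rbind(p1 = c("A", "G", "A", "A", "A"),
               p2 = c("G", "A", "C", "A", "-"),
               p3 = c("G", "G", "G", "A", "A"),
               o  = c("A", "A", "A", "A", "A"))
  # col1 ABBA, col2 BABA, col3 three states (skip), col4 invariant, col5 gap
  expect_equal(count_site_patterns(aln, "p1", "p2", "p3", "o"),
               c(nABBA = 1L, nBABA = 1L))
  expect_error(count_site_patterns(aln, "p1", "p2", "p3", "zz"),
               "not in alignment")
  # which nucleotide is ancestral vs derived is irrelevant
  aln2 <- rbind(p1 = c("T"), p2 = c("C"), p3 = c("C"), o = c("T"))
  expect_equal(count_site_patterns(aln2, "p1", "p2", "p3", "o"),
               c(nABBA = 1L, nBABA = 0L))
})

test_that("the D statistic and its boundary cases", {
  expect_equal(d_statistic(30, 10), 0.5)
  expect_equal(d_statistic(7, 7), 0)
  expect_equal(d_statistic(0, 12), -1)
  expect_warning(expect_true(is.na(d_statistic(0, 0))), "undefined")
})

test_that("swapping P1 and P2 negates D exactly", {
  sp <- read_newick(text = "(((p1:1,p2:1):1,p3:2):1,o:3);")
  aln <- simulate_dstat_alignment(sp, 40, 200, seed = 61)
  a <- bootstrap_z(aln, "p1", "p2", "p3", "o", seed = 1)
  b <- bootstrap_z(aln, "p2", "p1", "p3", "o", seed = 1)
  expect_equal(a$nABBA, b$nBABA)
  expect_equal(a$D, -b$D)
})

test_that("bootstrap Z is seeded, honors blocks, and handles degeneracy", {
  sp <- read_newick(text = "(((p1:1,p2:1):1,p3:2):1,o:3);")
  aln <- simulate_dstat_alignment(sp, 40, 200, seed = 62)
  r1 <- bootstrap_z(aln, "p1", "p2", "p3", "o", seed = 3)
  r2 <- bootstrap_z(aln, "p1", "p2", "p3", "o", seed = 3)
  expect_identical(r1, r2)
  rb <- bootstrap_z(aln, "p1", "p2", "p3", "o", seed = 3, block = 50)
  expect_true(rb$defined)
  # all-ABBA alignment: D = 1, SD = 0 -> Z = Inf, p = 0
  pure <- rbind(p1 = rep("A", 30), p2 = rep("G", 30), p3 = rep("G", 30),
                o = rep("A", 30))
  rp <- bootstrap_z(pure, "p1", "p2", "p3", "o", seed = 4)
  expect_equal(rp$D, 1)
  expect_equal(rp$Z, Inf)
  expect_equal(rp$p, 0)
  # nothing informative -> undefined flag
  blank <- rbind(p1 = rep("A", 10), p2 = rep("A", 10), p3 = rep("A", 10),
                 o = rep("A", 10))
  expect_false(bootstrap_z(blank, "p1", "p2", "p3", "o", seed = 5)$defined)
})

test_that("holm_bonferroni equals the literal step-down rule", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(0.7), 0.7)
  set.seed(63)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(holm_bonferroni(p), oracle_holm(p))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_design enumerates combinations and categorizes the summary", {
  sp <- read_newick(text = "(((p1:1,p2:1):1,p3:2):1,o:3);")
  aln <- simulate_dstat_alignment(sp, 40, 200, seed = 64)
  rownames(aln) <- c("p1", "p2", "p3", "o")
  # duplicate taxa rows under new names to build groups of 2
  aln8 <- rbind(aln, a2 = aln["p1", ], b2 = aln["p2", ], c2 = aln["p3", ])
  design <- list(P1 = c("p1", "a2"), P2 = c("p2", "b2"),
                 P3 = c("p3", "c2"), O = "o")
  res <- run_design(aln8, design, n_boot = 50, seed = 2)
  expect_equal(nrow(res$results), 8)
  expect_true(res$category %in%
                c("significant gene flow", "insignificant", "ambiguous"))
  expect_true(all(!is.na(res$results$p_holm)))
  expect_error(run_design(aln8, list(P1 = "p1", P2 = "p2", P3 = "p3",
                                     O = character(0))), "non-empty")
  expect_error(run_design(aln8, list(P1 = "p1", P2 = "p1", P3 = "p3",
                                     O = "o")), "disjoint")
})
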