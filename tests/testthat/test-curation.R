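test_that("orthogroup selection applies the three criteria", {
  cm <- rbind(og1 = c(1, 1, 2, 9),   # mean 3.25, median 1.5, all present
              og2 = c(6, 6, 6, 6),   # mean 6 > 5
              og3 = c(1, 1, 0, 1),   # absence
              og4 = c(3, 3, 3, 3))   # median 3 > 2
  expect_identical(select_orthogroups(cm), "og1")
  expect_identical(select_orthogroups(cm, min_presence = 3),
                   c("og1", "og3"))
  expect_identical(select_orthogroups(cm[0, , drop = FALSE]), character(0))
  # absent species excluded from mean/median by default, includable
  cm2 <- rbind(og = c(4, 4, 0))
  expect_identical(select_orthogroups(cm2, min_presence = 2,
                                      max_median = 4), "og")
  expect_identical(select_orthogroups(cm2, min_presence = 2, max_median = 4,
                                      include_absent = TRUE), "og")
  expect_identical(select_orthogroups(cm2, min_presence = 2, max_median = 3,
                                      include_absent = FALSE),
                   character(0))
})

test_that("long-branch pruning follows the tip-ratio and absolute rules", {
  # 0.25 tip with 0.01 sister: > 0.2 and > 10x -> pruned
  t1 <- read_newick(text = "((x:0.25,y:0.01):0.1,(z:0.05,w:0.04):0.1);")
  r1 <- prune_long_branches(t1, min_tips = 3)
  expect_identical(r1$removed$tip, "x")
  expect_identical(r1$removed$rule, "tip_ratio")
  # 0.25 tip with 0.05 sister: ratio test fails -> kept
  t2 <- read_newick(text = "((x:0.25,y:0.05):0.1,(z:0.05,w:0.04):0.1);")
  r2 <- prune_long_branches(t2, min_tips = 3)
  expect_equal(nrow(r2$removed), 0)
  expect_identical(sort(r2$tree$tip.label), c("w", "x", "y", "z"))
  # internal branch 0.6 splitting 10 vs 3 tips: 3-tip side removed
  big <- read_newick(text = paste0(
    "(((t1:.1,t2:.1):.1,((t3:.1,t4:.1):.1,(t5:.1,(t6:.1,(t7:.1,(t8:.1,",
    "(t9:.1,t10:.1):.1):.1):.1):.1):.1):.1):.6,(u1:.1,(u2:.1,u3:.1):.1):.1);"))
  r3 <- prune_long_branches(big)
  expect_identical(sort(r3$removed$tip), c("u1", "u2", "u3"))
  expect_equal(length(r3$tree$tip.label), 10)
  expect_identical(unique(r3$removed$rule), "abs_cutoff")
})

test_that("pruning is idempotent and flags over-pruned trees", {
  set.seed(31)
  for (i in 1:10) {
    tr <- ape::rtree(10)
    tr$edge.length <- rexp(nrow(tr$edge), 8)
    r1 <- prune_long_branches(tr)
    if (r1$discarded) next
    r2 <- prune_long_branches(r1$tree)
    expect_equal(nrow(r2$removed), 0)
    expect_identical(write_newick(r2$tree), write_newick(r1$tree))
  }
  tiny <- read_newick(text = "((a:0.9,b:0.9):0.1,(c:0.9,d:0.9):0.1);")
  rt <- prune_long_branches(tiny)
  expect_true(rt$discarded)
  expect_null(rt$tree)
})

test_that("RT extraction returns single-copy orthologs", {
  # single-copy homolog tree comes back unchanged
  t0 <- read_newick(text = "(((a@1,b@1),(c@1,d@1)),o@1);")
  orth <- extract_rt_orthologs(t0, outgroups = "o", min_taxa = 4)
  expect_length(orth, 1)
  expect_setequal(orth[[1]]$tip.label, t0$tip.label)
  # duplication at the ingroup root: one (a,b) side kept
  t1 <- read_newick(text = "(((a@1,b@1),(a@2,b@2)),o@1);")
  orth1 <- extract_rt_orthologs(t1, outgroups = "o", min_taxa = 2)
  expect_length(orth1, 1)
  expect_setequal(sub("@\\d+", "", orth1[[1]]$tip.label), c("a", "b"))
  # all-one-species tree yields nothing at min_taxa >= 2
  t2 <- read_newick(text = "(((a@1,a@2),(a@3,a@4)),o@1);")
  expect_length(extract_rt_orthologs(t2, outgroups = "o", min_taxa = 2), 0)
  # no outgroup -> skipped
  t3 <- read_newick(text = "((a@1,b@1),(c@1,d@1));")
  r3 <- extract_rt_orthologs(t3, outgroups = "o")
  expect_length(r3, 0)
  expect_identical(attr(r3, "skipped"), "no outgroup")
})

test_that("RT extraction is single-copy on simulated duplicate-rich trees", {
  sp <- simulate_species_tree(8, seed = 33)
  og <- sp$tip.label[1]
  dl <- simulate_dl_gene_trees(sp, 30, dup_rate = 0.15, loss_rate = 0.05,
                               seed = 34)
  n_checked <- 0
  for (tr in dl$trees) {
    orth <- extract_rt_orthologs(tr, outgroups = og, map = dl$map,
                                 min_taxa = 3)
    for (o in orth) {
      sp_o <- sub("@\\d+$", "", o$tip.label)
      expect_false(any(duplicated(sp_o)))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("zero-duplication homolog trees give back exactly one ortholog", {
  sp <- simulate_species_tree(7, seed = 35)
  dl <- simulate_dl_gene_trees(sp, 10, seed = 36)
  for (tr in dl$trees) {
    orth <- extract_rt_orthologs(tr, outgroups = sp$tip.label[1],
                                 map = dl$map, min_taxa = 4)
    expect_length(orth, 1)
    expect_setequal(orth[[1]]$tip.label, tr$tip.label)
  }
})
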