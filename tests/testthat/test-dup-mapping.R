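test_that("LCA reconciliation reproduces hand-worked examples", {
  sp <- read_newick(text = "(a:1,b:1);")
  r1 <- lca_reconcile(read_newick(text = "((a@1,b@1),(a@2,b@2));"), sp)
  expect_equal(r1$n_dups, 1)
  expect_equal(r1$losses, 0)
  expect_equal(r1$dup_nodes, 3)  # species root
  r2 <- lca_reconcile(read_newick(text = "((a@1,a@2),b@1);"), sp)
  expect_equal(r2$n_dups, 1)
  expect_equal(r2$dup_nodes, match("a", sp$tip.label))
  expect_equal(r2$losses, 0)
  sp4 <- read_newick(text = "((a,b),(c,d));")
  r3 <- lca_reconcile(read_newick(text = "((a@1,b@1),(c@1,d@1));"), sp4)
  expect_equal(r3$n_dups, 0)
  expect_equal(r3$losses, 0)
  # one loss: gene tree missing d, root still maps to species root
  r4 <- lca_reconcile(read_newick(text = "((a@1,b@1),c@1);"), sp4)
  expect_equal(r4$n_dups, 0)
  expect_equal(r4$losses, 1)
  expect_error(lca_reconcile(read_newick(text = "(a@1,zz@1);"), sp4),
               "absent")
})

test_that("LCA reconciliation matches the exhaustive oracle", {
  set.seed(71)
  for (i in 1:60) {
    nsp <- sample(3:5, 1)
    sp <- simulate_species_tree(nsp, seed = i)
    ntip <- sample(3:6, 1)
    labs <- paste0(sample(sp$tip.label, ntip, replace = TRUE), "@",
                   seq_len(ntip))
    g <- ape::rtree(ntip)
    g$tip.label <- labs
    map <- taxon_map(labs, sub("@\\d+$", "", labs))
    r <- lca_reconcile(g, sp, map)
    expect_equal(r$n_dups + r$losses, oracle_reconcile(g, sp, map),
                 info = paste("instance", i))
  }
})

test_that("duplication counts ignore gene-copy label permutations", {
  sp <- simulate_species_tree(5, seed = 72)
  dl <- simulate_dl_gene_trees(sp, 5, dup_rate = 0.2, seed = 73)
  for (tr in dl$trees) {
    r1 <- lca_reconcile(tr, sp, dl$map)
    tr2 <- tr
    # swap copy indices within each species
    tr2$tip.label <- vapply(strsplit(tr$tip.label, "@"), function(x)
      paste0(x[1], "@", 1000L - as.integer(x[2])), character(1))
    map2 <- taxon_map(tr2$tip.label, sub("@.*", "", tr2$tip.label))
    r2 <- lca_reconcile(tr2, sp, map2)
    expect_equal(r1$n_dups, r2$n_dups)
    expect_equal(r1$losses, r2$losses)
    expect_equal(r1$dups_per_node, r2$dups_per_node)
  }
})

test_that("the ladder walks from the seed tip to the root", {
  cat6 <- make_caterpillar(LETTERS[1:6])
  lad <- build_ladder(cat6, "A")
  expect_length(lad, 5)
  expect_equal(lad[[1]]$ingroup, "A")
  expect_equal(lad[[1]]$sister, "B")
  expect_equal(lad[[5]]$sister, "F")
  expect_setequal(unlist(lad[[5]]$groups), LETTERS[1:6])
  expect_error(build_ladder(cat6, "zz"), "unknown seed tip")
})

test_that("a clean WGD yields 100% shared duplications at its node only", {
  cat5 <- make_caterpillar(LETTERS[1:5])
  lad <- build_ladder(cat5, "A")
  wnode <- lad[[2]]$node  # above the (A,B,C) clade... node joining ABC
  dl <- simulate_dl_gene_trees(cat5, 40, wgd_node = wnode, retention = 1,
                               seed = 74)
  prof <- maps_analysis(dl, cat5, lad)
  expect_equal(prof$percent[prof$node == wnode], 100)
  others <- prof[prof$node != wnode & prof$examined > 0, ]
  expect_true(all(others$percent == 0))
  # hand-built example: one duplicated subtree among four at a node
  g_dup <- read_newick(text = "(((A@1,B@1),(A@2,B@2)),C@1);")
  g_pl <- read_newick(text = "((A@1,B@1),C@1);")
  prof2 <- maps_analysis(list(g_dup, g_pl, g_pl, g_pl),
                         make_caterpillar(LETTERS[1:3]),
                         build_ladder(make_caterpillar(LETTERS[1:3]), "A"))
  # the ((A,B),(A,B)) duplication maps to the node joining A and B
  node2 <- prof2[prof2$label == "B", ]
  expect_equal(node2$examined, 4)
  expect_equal(node2$shared, 1)
  expect_equal(node2$percent, 25)
  expect_equal(prof2$percent[prof2$label == "C"], 0)
})

test_that("null simulations give flat low percentages and Fisher flags work", {
  cat5 <- make_caterpillar(LETTERS[1:5])
  lad <- build_ladder(cat5, "A")
  null_prof <- lapply(1:4, function(i)
    maps_analysis(simulate_dl_gene_trees(cat5, 250, dup_rate = 0.05,
                                         loss_rate = 0.05, seed = 80 + i),
                  cat5, lad))
  pooled <- Reduce(`+`, lapply(null_prof, `[[`, "shared")) /
    pmax(Reduce(`+`, lapply(null_prof, `[[`, "examined")), 1)
  expect_true(all(pooled < 0.25))
  pos_prof <- lapply(1:4, function(i)
    maps_analysis(simulate_dl_gene_trees(cat5, 250, dup_rate = 0.05,
                                         loss_rate = 0.05,
                                         wgd_node = lad[[2]]$node,
                                         retention = 0.5, seed = 90 + i),
                  cat5, lad))
  obs <- maps_analysis(simulate_dl_gene_trees(cat5, 400, dup_rate = 0.05,
                                              loss_rate = 0.05,
                                              wgd_node = lad[[2]]$node,
                                              retention = 0.5, seed = 99),
                       cat5, lad)
  sig <- maps_significance(obs, null_prof, pos_prof)
  expect_true(sig$wgd_like[sig$node == lad[[2]]$node])
  expect_false(any(sig$wgd_like[sig$node != lad[[2]]$node]))
  # observed exactly at the pooled null rate is not flagged
  ex0 <- Reduce(`+`, lapply(null_prof, `[[`, "examined"))
  sh0 <- Reduce(`+`, lapply(null_prof, `[[`, "shared"))
  flat <- null_prof[[1]]
  flat$examined <- ex0
  flat$shared <- sh0
  sig0 <- maps_significance(flat, null_prof, pos_prof)
  expect_false(any(sig0$p_null < 0.4, na.rm = TRUE))
})
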