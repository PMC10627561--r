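test_that("Yule species trees have the required shape and are reproducible", {
  tr <- simulate_species_tree(3, seed = 1)
  expect_equal(tr$Nnode, 2)          # root + one internal node
  expect_error(simulate_species_tree(2), ">= 3")
  t20a <- simulate_species_tree(20, seed = 5)
  t20b <- simulate_species_tree(20, seed = 5)
  expect_identical(write_newick(t20a), write_newick(t20b))
  expect_equal(t20a$Nnode, 19)
  expect_true(all(t20a$edge.length > 0))
  expect_true(ape::is.ultrametric(t20a))
})

test_that("MSC quartet frequencies follow 1 - (2/3) exp(-t)", {
  # one informative internal branch; the other has length 0
  n <- 4000
  for (t in c(0, 1, 2)) {
    st <- read_newick(text = sprintf("((a:1,b:1):%g,(c:1,d:1):0);", t))
    g <- simulate_msc_gene_trees(st, n, seed = 100 + t)
    cq <- count_quartets(g, quadruples = matrix(c("a", "b", "c", "d"), 1))
    p_exp <- msc_concordance(t)
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(cq$n1 / n - p_exp), 3 * se + 1e-12)
  }
})

test_that("MSC scale multiplies branch lengths exactly", {
  st <- read_newick(text = "((a:1,b:1):0.5,(c:1,d:1):0);")
  st4 <- st
  st4$edge.length <- st$edge.length * 4
  g1 <- simulate_msc_gene_trees(st, 50, scale = 4, seed = 9)
  g2 <- simulate_msc_gene_trees(st4, 50, scale = 1, seed = 9)
  expect_identical(write_newick(g1$trees), write_newick(g2$trees))
})

test_that("missing terminal branch lengths follow the stated policy", {
  st <- read_newick(text = "((a,b):1,(c,d):1);")  # no terminal lengths
  expect_error(simulate_msc_gene_trees(st, 2, default_tip_len = NULL),
               "terminal-branch policy")
  g <- simulate_msc_gene_trees(st, 5, seed = 2, default_tip_len = 2)
  expect_length(g$trees, 5)
})

test_that("network simulator is the MSC at gamma = 0 and rewires at 1", {
  sp <- read_newick(text = "(((p1:1,p2:1):1,p3:2):1,o:3);")
  quad <- matrix(c("p1", "p2", "p3", "o"), 1)
  g0 <- simulate_network_gene_trees(
    sp, introgression_edge("p3", "p2", 0.5, 0), 1500, seed = 3)
  gm <- simulate_msc_gene_trees(sp, 1500, seed = 4)
  c0 <- as.numeric(count_quartets(g0, quad)[, c("n1", "n2", "n3")])
  cm <- as.numeric(count_quartets(gm, quad)[, c("n1", "n2", "n3")])
  expect_gt(chisq.test(rbind(c0, cm))$p.value, 0.001)
  expect_true(all(vapply(g0$truth, function(x) x[[1]]$n_moved, 1) == 0))
  # gamma = 1: every p2 lineage moves
  g1 <- simulate_network_gene_trees(
    sp, introgression_edge("p3", "p2", 0.5, 1), 300, seed = 5)
  expect_true(all(vapply(g1$truth, function(x) x[[1]]$n_moved, 1) == 1))
  # monotone in gamma: frequency of the p2-p3 pairing increases
  f <- vapply(c(0, 0.5, 1), function(gam) {
    g <- simulate_network_gene_trees(
      sp, introgression_edge("p3", "p2", 0.5, gam), 1500, seed = 6)
    cq <- count_quartets(g, quad)
    cq$n1 / cq$n  # sorted order (o,p1,p2,p3): n1 = o,p1 | p2,p3
  }, numeric(1))
  expect_true(all(diff(f) > 0))
  # event time outside a branch errors
  expect_error(simulate_network_gene_trees(
    sp, introgression_edge("p3", "p2", 1.5, 0.5), 2, seed = 1),
    "outside")
})

test_that("DL simulator reduces to the species tree at zero rates", {
  sp <- simulate_species_tree(6, seed = 11)
  dl <- simulate_dl_gene_trees(sp, 10, seed = 12)
  for (tr in dl$trees) {
    expect_equal(sort(tr$tip.label), sort(paste0(sp$tip.label, "@1")))
    t2 <- tr
    t2$tip.label <- sub("@1", "", t2$tip.label)
    expect_identical(robinson_foulds(t2, sp), 0L)
  }
  expect_true(all(vapply(dl$truth, function(x)
    length(x$dup_nodes) == 0, logical(1))))
})

test_that("WGD with full retention duplicates every lineage at the node", {
  sp <- read_newick(text = "(((A:1,B:1):1,C:2):1,D:3);")
  wnode <- lca(sp, c("A", "B"))
  dl <- simulate_dl_gene_trees(sp, 20, wgd_node = wnode, retention = 1,
                               seed = 13)
  for (i in seq_along(dl$trees)) {
    tr <- dl$trees[[i]]
    expect_setequal(tr$tip.label,
                    c("A@1", "A@2", "B@1", "B@2", "C@1", "D@1"))
    expect_equal(dl$truth[[i]]$dup_nodes, wnode)
    r <- lca_reconcile(tr, sp, dl$map)
    expect_equal(r$dup_nodes, wnode)
  }
  # partial retention: empirical both-copy rate matches the retention rate
  dl2 <- simulate_dl_gene_trees(sp, 600, wgd_node = wnode, retention = 0.3,
                                seed = 14)
  both <- mean(vapply(dl2$truth, `[[`, logical(1), "wgd_both"))
  expect_lt(abs(both - 0.3), 3 * sqrt(0.3 * 0.7 / 600))
})

test_that("alignment simulation matches the JC69 expected divergence", {
  two <- read_newick(text = "(x:0.05,y:0.05);")
  aln <- simulate_alignment(two, 100000, seed = 15)
  pdiff <- mean(aln["x", ] != aln["y", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(pdiff - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))
  # zero branch lengths give identical rows
  z <- two; z$edge.length[] <- 0
  a0 <- simulate_alignment(z, 500, seed = 16)
  expect_identical(a0["x", ], a0["y", ])
  expect_identical(simulate_alignment(two, 50, seed = 17),
                   simulate_alignment(two, 50, seed = 17))
  expect_error(simulate_alignment(two, -1), "non-negative")
})

test_that("codon-pair simulator is seeded, stop-free, and truth-consistent", {
  p1 <- simulate_codon_pairs(0.2, 0.05, n_codons = 200, seed = 18)
  p2 <- simulate_codon_pairs(0.2, 0.05, n_codons = 200, seed = 18)
  expect_identical(p1, p2)
  expect_identical(simulate_codon_pairs(0, 0, 100, seed = 19)[[1]],
                   simulate_codon_pairs(0, 0, 100, seed = 19)[[2]])
  codons <- substring(p1[["derived"]], seq(1, 600, 3), seq(3, 600, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
})

test_that("Ks mixture draws respect weights, window and determinism", {
  x <- simulate_ks_mixture(c(0.2, 0.8), c(0.1, 0.1), c(1, 0), 500, seed = 20)
  expect_true(all(x >= 0.05 & x <= 3))
  expect_lt(abs(median(x) - 0.2), 0.03)
  expect_identical(x, simulate_ks_mixture(c(0.2, 0.8), c(0.1, 0.1), c(1, 0),
                                          500, seed = 20))
  expect_error(simulate_ks_mixture(c(0.2), c(0.1, 0.2), c(1), 10), "equal")
})
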