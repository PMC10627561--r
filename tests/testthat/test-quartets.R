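test_that("quartet counts agree with per-tree induced-quartet enumeration", {
  g1 <- read_newick(text = "((a,b),(c,d));")
  cq <- count_quartets(list(g1, g1, g1),
                       quadruples = matrix(c("a", "b", "c", "d"), 1))
  expect_equal(as.numeric(cq[, c("n1", "n2", "n3")]), c(3, 0, 0))
  # missing taxon contributes nothing
  g2 <- read_newick(text = "((a,b),c);")
  cq2 <- count_quartets(list(g1, g2),
                        quadruples = matrix(c("a", "b", "c", "d"), 1))
  expect_equal(cq2$n, 1)
  # oracle comparison on random 6-taxon trees
  set.seed(51)
  trees <- replicate(10, ape::rtree(6, tip.label = letters[1:6]),
                     simplify = FALSE)
  cq3 <- count_quartets(trees)
  for (r in sample(nrow(cq3), 5)) {
    quad <- as.character(cq3[r, 1:4])
    expected <- c(0L, 0L, 0L)
    for (tr in trees) {
      res <- oracle_quartet(tr, quad)
      if (res > 0) expected[res] <- expected[res] + 1L
    }
    expect_equal(as.integer(cq3[r, c("n1", "n2", "n3")]), expected)
  }
  expect_error(count_quartets(trees, matrix(c("a", "a", "b", "c"), 1)),
               "distinct")
})

test_that("T3 fits the boundary cases exactly", {
  star <- t3_test(c(100, 100, 100), seed = 1)
  expect_equal(star$mu_hat, 1 / 3)
  expect_equal(star$lrt, 0)
  expect_equal(star$p, 1)
  tree <- t3_test(c(300, 0, 0), seed = 1)
  expect_equal(tree$mu_hat, 0)
  expect_equal(tree$lrt, 0)
  expect_equal(tree$p, 1)
  mid <- t3_test(c(150, 140, 10), alpha = 0.01, seed = 1)
  expect_equal(mid$mu_hat, 0.25)
  expect_equal(mid$lrt, 2 * (140 * log(140 / 75) + 10 * log(10 / 75)),
               tolerance = 1e-10)
  expect_true(mid$rejected)
})

test_that("T3 p-values are invariant to permuting the two minor counts", {
  a <- t3_test(c(200, 40, 15), B = 500, seed = 5)
  b <- t3_test(c(200, 15, 40), B = 500, seed = 5)
  expect_equal(a$lrt, b$lrt)
  expect_equal(a$p, b$p)
})

test_that("T1 rejects when the modal resolution contradicts the species tree", {
  fits <- t1_test(c(90, 5, 5), species_resolution = 1, seed = 7)
  expect_false(fits$rejected)
  wrong <- t1_test(c(5, 90, 5), species_resolution = 1, alpha = 0.01,
                   seed = 7)
  expect_true(wrong$rejected)
  perfect <- t1_test(c(250, 0, 0), species_resolution = 1, seed = 7)
  expect_equal(perfect$p, 1)
})

test_that("simplex coordinates normalize counts", {
  expect_equal(simplex_coordinates(c(50, 30, 20)), c(0.5, 0.3, 0.2))
  expect_equal(simplex_coordinates(c(1, 1, 1)), rep(1 / 3, 3))
  set.seed(8)
  cm <- data.frame(n1 = rpois(10, 20) + 1, n2 = rpois(10, 5),
                   n3 = rpois(10, 5))
  sc <- simplex_coordinates(cm)
  expect_equal(rowSums(sc[, c("p1", "p2", "p3")]), rep(1, 10))
  expect_error(simplex_coordinates(c(0, 0, 0)), "zero")
})

test_that("rejected quadruples map onto the induced internal path", {
  cat6 <- make_caterpillar(LETTERS[1:6])
  # quartet (A,B,C,D): junctions at mrca(A,B) and mrca(ABC); one edge
  m1 <- map_rejected_quartets(cat6, matrix(c("A", "B", "C", "D"), 1))
  expect_equal(sum(m1$count), 1)
  expect_equal(m1$clade[m1$count == 1], "A.B")
  # quartet (A,B,E,F): path spans the ABC and ABCD edges too
  m2 <- map_rejected_quartets(cat6, matrix(c("A", "B", "E", "F"), 1))
  expect_setequal(m2$clade[m2$count == 1], c("A.B", "A.B.C", "A.B.C.D"))
  # empty set -> all zero
  m0 <- map_rejected_quartets(cat6, matrix(character(0), 0, 4))
  expect_true(all(m0$count == 0))
  expect_error(map_rejected_quartets(cat6, matrix(c("A", "B", "zz", "D"), 1)),
               "unknown taxon")
})

test_that("eqp_ic scores concordance and flips sign on dominant conflict", {
  sp <- read_newick(text = "(((a,b),(c,d)),(e,f));")
  conc <- eqp_ic(sp, rep(list(sp), 20), seed = 1)
  expect_true(all(conc$score == 1))
  # gene trees all showing a conflicting resolution around one edge
  alt <- read_newick(text = "(((a,c),(b,d)),(e,f));")
  mix <- eqp_ic(sp, rep(list(alt), 20), seed = 1)
  ab_edge <- mix[mix$clade == "a.b", ]
  expect_lt(ab_edge$score, 0)
  # maximum entropy -> score ~ 0 given equal counts
  trees <- c(rep(list(sp), 5),
             rep(list(read_newick(text = "(((a,c),(b,d)),(e,f));")), 5),
             rep(list(read_newick(text = "(((a,d),(b,c)),(e,f));")), 5))
  z <- eqp_ic(sp, trees, seed = 1)
  expect_lt(abs(z$score[z$clade == "a.b"]), 1e-10)
})

test_that("eqp_ic increases with the reference-resolution frequency", {
  sp <- read_newick(text = "(((a,b),(c,d)),(e,f));")
  alt <- read_newick(text = "(((a,c),(b,d)),(e,f));")
  scores <- vapply(c(2, 5, 8), function(k) {
    trees <- c(rep(list(sp), k), rep(list(alt), 10 - k))
    z <- eqp_ic(sp, trees, seed = 1)
    z$score[z$clade == "a.b"]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
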