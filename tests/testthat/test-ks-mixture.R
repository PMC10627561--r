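test_that("NG86 reproduces the hand-enumerated AAA/AAG example", {
  e <- ng86_ks(strrep("AAA", 10), paste0("AAG", strrep("AAA", 9)))
  expect_equal(e$S, 10 / 3, tolerance = 1e-12)
  expect_equal(e$Sd, 1)
  expect_equal(e$pS, 0.3)
  expect_equal(e$Ks, -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(e$Ka, 0)
  # identical sequences
  z <- ng86_ks("ATGGCT", "ATGGCT")
  expect_equal(z$Ks, 0)
  expect_equal(z$Ka, 0)
  expect_error(ng86_ks("ATGG", "ATGG"), "divisible by 3")
})

test_that("NG86 is symmetric and matches an independent pathway oracle", {
  set.seed(91)
  for (i in 1:12) {
    p <- simulate_codon_pairs(runif(1, 0.05, 0.6), runif(1, 0, 0.2),
                              n_codons = 50, seed = 910 + i)
    a <- ng86_ks(p[["ancestor"]], p[["derived"]])
    b <- ng86_ks(p[["derived"]], p[["ancestor"]])
    expect_equal(a$Ks, b$Ks)
    expect_equal(a$Ka, b$Ka)
    o <- oracle_ng86(p[["ancestor"]], p[["derived"]])
    expect_equal(a$S, o$S, tolerance = 1e-9)
    expect_equal(a$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(a$Nd, o$Nd, tolerance = 1e-9)
    expect_equal(a$Ks, o$Ks, tolerance = 1e-9)
  }
})

test_that("saturated pairs are flagged undefined", {
  # force pS >= 3/4 artificially: many synonymous third-position changes in
  # a short sequence are unlikely, so just check the flag logic on the JC
  # boundary via a crafted high-divergence pair
  p <- suppressWarnings(simulate_codon_pairs(8, 0.1, n_codons = 60,
                                             seed = 92))
  e <- ng86_ks(p[["ancestor"]], p[["derived"]])
  expect_identical(e$ks_defined, e$pS < 0.75)
})

test_that("Ks tables enumerate paralog and ortholog pairs", {
  base <- "ATGGCTAAAGGGTTTCCCGAAGATCTTCAC"   # 10 codons
  flip <- function(pos, nt) { s <- base; substr(s, pos, pos) <- nt; s }
  seqs <- list(
    og1 = c("spA@1" = base, "spA@2" = flip(12, "A"),   # GGG -> GGA (syn)
            "spA@3" = flip(15, "C"),                   # TTT -> TTC (syn)
            "spB@1" = flip(9, "G")),                   # AAA -> AAG (syn)
    og2 = c("spA@1" = base, "spB@1" = flip(9, "G")))
  par <- build_ks_table(seqs, "paralog", window = NULL)
  expect_equal(nrow(par), 3)  # 3 pairs among the 3 spA copies of og1
  expect_true(all(par$orthogroup == "og1"))
  ort <- build_ks_table(seqs, "ortholog", species_pair = c("spA", "spB"),
                        window = NULL)
  expect_equal(nrow(ort), 4)  # 3 cross pairs in og1 + 1 in og2
  # window filtering
  win <- build_ks_table(seqs, "paralog", window = c(0.05, 3))
  expect_true(all(win$Ks >= 0.05 & win$Ks <= 3))
  expect_equal(nrow(win) + attr(win, "n_outside") +
                 attr(win, "n_undefined"), 3)
})

test_that("BIC-selected mixtures recover simulated components", {
  # single tight component -> k = 1
  x1 <- simulate_ks_mixture(0.3, 0.15, 1, 800, seed = 93)
  f1 <- fit_gmm(x1, k_range = 1:3, seed = 93)
  expect_equal(f1$k, 1)
  expect_lt(abs(f1$modes - 0.3), 0.03)
  # two components at the observed study peaks
  x2 <- simulate_ks_mixture(c(0.18, 0.75), c(0.25, 0.25), c(0.6, 0.4),
                            3000, seed = 94)
  f2 <- fit_gmm(x2, k_range = 1:4, seed = 94)
  expect_equal(f2$k, 2)
  expect_lt(abs(f2$modes[1] - 0.18), 0.03)
  expect_lt(abs(f2$modes[2] - 0.75), 0.10)
  # determinism
  f2b <- fit_gmm(x2, k_range = 1:4, seed = 94)
  expect_identical(f2$modes, f2b$modes)
  expect_error(fit_gmm(x2[1:20], k_range = 1:5), "at least")
})

test_that("posterior isolation and the Welch comparison order the classes", {
  set.seed(95)
  ogs <- sprintf("og%03d", 1:60)
  par_tab <- data.frame(
    orthogroup = rep(ogs, each = 3),
    Ks = simulate_ks_mixture(0.18, 0.2, 1, 180, seed = 96),
    stringsAsFactors = FALSE)
  ort_tab <- data.frame(
    orthogroup = rep(ogs, each = 3),
    Ks = simulate_ks_mixture(0.10, 0.2, 1, 180, seed = 97),
    stringsAsFactors = FALSE)
  cmp <- within_orthogroup_compare(par_tab, ort_tab, k_range = 1:2,
                                   seed = 95)
  expect_true(cmp$defined)
  expect_gt(cmp$mean_paralog, cmp$mean_ortholog)
  expect_identical(cmp$direction, "paralogs older")
  expect_lt(cmp$p, 0.001)
  # degenerate posterior threshold empties the classes
  cmp2 <- within_orthogroup_compare(par_tab[0, ], ort_tab, k_range = 1:2)
  expect_false(cmp2$defined)
})
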