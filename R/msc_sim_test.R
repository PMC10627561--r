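# Coalescent plastome-simulation test: can incomplete lineage sorting alone
# explain the conflict between a nuclear species tree and a plastid tree?

#' Plastome ILS simulation test
#'
#' Simulates `n_sim` plastome genealogies under the multispecies coalescent
#' on the nuclear species tree, with every branch length multiplied by
#' `scale` (default 4.0, the expected factor for a haploid, uniparentally
#' inherited genome), and summarizes the frequency of every non-trivial clade
#' of the empirical plastid tree among the simulated trees.  Clades of the
#' plastid tree that are absent from the nuclear topology ("unique" clades)
#' and rare among the simulations (frequency `<= threshold`) are classified
#' as implausible under ILS alone, pointing at hybridization instead.
#'
#' @param nuclear rooted nuclear species tree (`phylo`), internal branch
#'   lengths in coalescent units.
#' @param plastid rooted empirical plastid tree on the same tip set.
#' @param n_sim number of simulated genealogies.
#' @param scale branch-length multiplier for organellar inheritance.
#' @param threshold frequency at or below which a unique clade is called
#'   ILS-implausible.
#' @param seed optional integer seed.
#' @param default_tip_len terminal-branch policy passed to
#'   [simulate_msc_gene_trees()].
#' @return a data frame of class `ils_test_report`, one row per non-trivial
#'   plastid clade: `clade`, `size`, `shared` (present in the nuclear
#'   topology), `frequency` among simulations, and `classification`
#'   (`"shared"`, `"ILS-plausible"` or `"ILS-implausible"`).
#' @export
plastome_ils_test <- function(nuclear, plastid, n_sim = 10000, scale = 4.0,
                              threshold = 0.15, seed = NULL,
                              default_tip_len = 2) {
  if (!setequal(nuclear$tip.label, plastid$tip.label))
    stop("nuclear and plastid trees must share the same tip set",
         call. = FALSE)
  sims <- simulate_msc_gene_trees(nuclear, n_sim, scale = scale, seed = seed,
                                  default_tip_len = default_tip_len)
  rep <- clade_frequencies(plastid, sims$trees, rooted = TRUE)
  universe <- plastid$tip.label
  nuc_keys <- .clade_keys(nuclear, universe, rooted = TRUE,
                          shared = seq_along(universe))
  plastid_sets <- .clade_sets(plastid, universe, rooted = TRUE,
                              shared = seq_along(universe))
  keys <- vapply(plastid_sets, .setkey, character(1))
  # align with clade_frequencies row order (same enumeration)
  rep$shared <- keys %in% nuc_keys
  rep$classification <- ifelse(
    rep$shared, "shared",
    ifelse(rep$frequency <= threshold, "ILS-implausible", "ILS-plausible"))
  attr(rep, "n_sim") <- n_sim
  attr(rep, "scale") <- scale
  attr(rep, "threshold") <- threshold
  class(rep) <- c("ils_test_report", class(rep))
  rep
}

#' @export
print.ils_test_report <- function(x, ...) {
  cat(sprintf(
    "Plastome ILS test: %d simulated genealogies, scale %.1f, threshold %.2f\n",
    attr(x, "n_sim"), attr(x, "scale"), attr(x, "threshold")))
  uniq <- x[!x$shared, , drop = FALSE]
  cat(sprintf(" %d plastid clades, %d unique; %d classified ILS-implausible\n",
              nrow(x), nrow(uniq),
              sum(uniq$classification == "ILS-implausible")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
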