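#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study inputs with known ground truth.
#
# Produces, under results/data/:
#   nuclear20.nwk        20-taxon nuclear species tree (coalescent units)
#   plastid20.nwk        plastid tree with one hybridization-style conflict
#   genetrees_msc.nwk    365 single-copy gene trees under the MSC
#   genetrees_net.nwk    365 gene trees with one introgression edge (gamma=0.4)
#   homologs.nwk         200 multi-copy homolog trees (dup/loss + WGD r=0.5)
#   homologs_map.tsv     gene-copy -> species map for the homolog trees
#   truth.json           ground-truth record for every simulated set

suppressPackageStartupMessages(library(polyconflict))
seed <- 42
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

nuclear <- simulate_species_tree(20, birth_rate = 1, seed = seed)
write_newick(nuclear, "results/data/nuclear20.nwk")

# a plastid tree that conflicts with the nuclear tree: regraft one cherry
# next to a distant tip (the signature of chloroplast capture)
lt_tips <- nuclear$tip.label
edge_tab <- nuclear$edge
is_cherry <- function(v) {
  ch <- edge_tab[edge_tab[, 1] == v, 2]
  length(ch) == 2 && all(ch <= length(lt_tips))
}
cherry_node <- Find(is_cherry, sort(unique(edge_tab[, 1])))
cherry_tips <- lt_tips[edge_tab[edge_tab[, 1] == cherry_node, 2]]
far_tip <- setdiff(lt_tips, cherry_tips)[10]
cherry <- ape::keep.tip(nuclear, cherry_tips)
cherry$root.edge <- 0.1
pl <- ape::drop.tip(nuclear, cherry_tips)
plastid <- ape::bind.tree(pl, cherry,
                          where = which(pl$tip.label == far_tip),
                          position = pl$edge.length[
                            which(pl$edge[, 2] ==
                                    which(pl$tip.label == far_tip))] / 2)
write_newick(plastid, "results/data/plastid20.nwk")
cat("species trees written; plastid regrafts", paste(cherry_tips,
    collapse = "+"), "next to", far_tip, "\n")

msc <- simulate_msc_gene_trees(nuclear, 365, seed = seed + 1)
write_newick(msc$trees, "results/data/genetrees_msc.nwk")

# introgression between the regrafted cherry's first tip and the far tip,
# placed shallow enough to sit inside both terminal branches
bt <- ape::branching.times(nuclear)
parent_age <- function(tip) {
  p <- nuclear$edge[nuclear$edge[, 2] == which(lt_tips == tip), 1]
  bt[as.character(p)]
}
ev_time <- 0.5 * min(parent_age(cherry_tips[1]), parent_age(far_tip))
edge <- introgression_edge(donor = far_tip, recipient = cherry_tips[1],
                           time = ev_time, gamma = 0.4)
net <- simulate_network_gene_trees(nuclear, list(edge), 365, seed = seed + 2)
write_newick(net$trees, "results/data/genetrees_net.nwk")
cat("gene trees written: 365 MSC +", length(net$trees), "network\n")

wgd_node <- lca(nuclear, lt_tips[1:4])
hom <- simulate_dl_gene_trees(nuclear, 200, dup_rate = 0.05,
                              loss_rate = 0.05, wgd_node = wgd_node,
                              retention = 0.5, seed = seed + 3)
write_newick(hom$trees, "results/data/homologs.nwk")
write.table(hom$map, "results/data/homologs_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat("homolog trees written: WGD (r = 0.5) at node", wgd_node, "\n")

truth <- list(
  plastid_moved_clade = cherry_tips,
  introgression = list(donor = far_tip,
                       recipient = cherry_tips[1], gamma = 0.4),
  wgd = list(node = wgd_node, clade = lt_tips[1:4], retention = 0.5),
  n_dup_trees = sum(vapply(hom$truth, function(x)
    length(x$dup_nodes) > 0, logical(1))))
jsonlite::write_json(truth, "results/data/truth.json", auto_unbox = TRUE,
                     pretty = TRUE)
cat("ground truth recorded in results/data/truth.json\n")
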