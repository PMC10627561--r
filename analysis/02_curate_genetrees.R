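#!/usr/bin/env Rscript
# Stage 2: orthogroup selection, long-branch pruning and RT ortholog
# extraction on the simulated multi-copy homolog trees.
#
# Reads results/data/homologs.nwk (+ map); writes
#   results/curation_log.tsv   per-tree outcome (rule fired, tips removed)
#   results/orthogroups_kept.txt
#   results/orthologs.nwk      extracted single-copy ortholog trees

suppressPackageStartupMessages(library(polyconflict))
hom <- read_newick("results/data/homologs.nwk")
map <- read_taxon_map("results/data/homologs_map.tsv")
species <- read_newick("results/data/nuclear20.nwk", single = TRUE)
dir.create("results", showWarnings = FALSE)

counts <- orthogroup_stats(hom, map, species = species$tip.label)
kept <- select_orthogroups(counts)       # all present, mean <= 5, median <= 2
writeLines(kept, "results/orthogroups_kept.txt")
cat(sprintf("orthogroup selection: %d of %d retained\n",
            length(kept), nrow(counts)))

# simulated gene trees carry coalescent-unit branch lengths; convert to
# expected substitutions per site (0.05 subst/site per CU) so the pruning
# thresholds, which are in substitutions/site, apply on the right scale
subst_per_cu <- 0.05
hom <- lapply(hom, function(tr) {
  tr$edge.length <- tr$edge.length * subst_per_cu
  tr
})

outgroup <- species$tip.label[20]
log <- list(); orthologs <- list()
for (i in seq_along(hom)) {
  id <- rownames(counts)[i]
  if (!id %in% kept) {
    log[[i]] <- data.frame(tree = id, action = "rejected_copy_number",
                           tips_removed = NA, orthologs = 0)
    next
  }
  cur <- prune_long_branches(hom[[i]])
  if (cur$discarded) {
    log[[i]] <- data.frame(tree = id, action = "discarded_pruning",
                           tips_removed = nrow(cur$removed), orthologs = 0)
    next
  }
  ort <- extract_rt_orthologs(cur$tree, outgroups = outgroup, map = map,
                              min_taxa = 4)
  orthologs <- c(orthologs, ort)
  log[[i]] <- data.frame(tree = id, action = "curated",
                         tips_removed = nrow(cur$removed),
                         orthologs = length(ort))
}
log <- do.call(rbind, log)
write.table(log, "results/curation_log.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (length(orthologs))
  write_newick(orthologs, "results/orthologs.nwk")
cat(sprintf("curation: %d trees curated, %d ortholog trees extracted\n",
            sum(log$action == "curated"), length(orthologs)))
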