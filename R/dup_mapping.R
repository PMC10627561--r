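# LCA duplication-loss reconciliation and ladder-based shared-duplication
# (MAPS-style) profiling with simulated null/positive significance.

# arrays for the C++ reconciliation core
.recon_arrays <- function(phy) {
  lt <- .lt(phy)
  list(gpar = lt$parent, gpost = lt$postorder, lt = lt)
}

#' LCA duplication-loss reconciliation
#'
#' Maps every gene-tree node to the most recent species-tree node containing
#' its descendant species (the LCA map); a gene node is a duplication iff it
#' maps to the same species node as one of its children, and losses follow
#' the standard path-length rule.
#'
#' @param gene rooted gene tree (`phylo`), tips are gene copies.
#' @param species rooted species tree (`phylo`).
#' @param map optional taxon map; defaults to `species@k` labels.
#' @return list: `n_dups`, `losses`, `dup_nodes` (species node of every gene
#'   duplication), `dups_per_node` (named counts over species nodes), and
#'   `node_map` (species node per gene node).
#' @export
lca_reconcile <- function(gene, species, map = NULL) {
  slt <- .lt(species)
  ga <- .recon_arrays(gene)
  sp <- .tip_species(gene$tip.label, map)
  tipix <- match(sp, species$tip.label)
  if (anyNA(tipix))
    stop("gene copies map to species absent from the species tree: ",
         paste(unique(sp[is.na(tipix)]), collapse = ", "), call. = FALSE)
  gtipmap <- integer(ga$lt$n_node)
  gtipmap[seq_len(ga$lt$n_tip)] <- tipix
  r <- cpp_lca_reconcile(ga$gpar, ga$gpost, gtipmap, slt$parent, slt$depth)
  dup_nodes <- r$map[r$isdup == 1L]
  per <- tabulate(dup_nodes, nbins = slt$n_node)
  names(per) <- seq_len(slt$n_node)
  list(n_dups = r$dups, losses = r$losses, dup_nodes = dup_nodes,
       dups_per_node = per, node_map = r$map)
}

#' Build the ladder of nested clades from a seed tip to the root
#'
#' MAPS-style profiling walks a path of internal nodes from one taxon to the
#' root; at each node the "ingroup" is everything below the previous node on
#' the path and the "sister" group is the newly added clade.
#'
#' @param species rooted `phylo`.
#' @param seed_tip tip label at the bottom of the ladder.
#' @return list of class `maps_ladder`; element `i` has `node` (species node
#'   id), `ingroup` and `sister` (species label vectors), and `groups` (the
#'   ladder groups accumulated so far, innermost first).
#' @export
build_ladder <- function(species, seed_tip) {
  lt <- .lt(species)
  tip <- match(seed_tip, species$tip.label)
  if (is.na(tip)) stop("unknown seed tip: ", seed_tip, call. = FALSE)
  sets <- .lt_tipsets(lt, species$tip.label)
  path <- integer(0)
  v <- tip
  while (v != lt$root) {
    v <- lt$parent[v]
    path <- c(path, v)
  }
  groups <- list(species$tip.label[tip])
  out <- vector("list", length(path))
  below <- tip
  for (i in seq_along(path)) {
    v <- path[i]
    ingroup <- species$tip.label[sets[[below]]]
    sister <- setdiff(species$tip.label[sets[[v]]], ingroup)
    groups[[length(groups) + 1L]] <- sister
    out[[i]] <- list(node = v, ingroup = ingroup, sister = sister,
                     groups = groups)
    below <- v
  }
  structure(out, class = "maps_ladder", seed_tip = seed_tip)
}

#' Shared-duplication profile along a ladder of species-tree nodes
#'
#' For every ladder node, gene subtrees are examined whose root LCA-maps to
#' that node, that contain at least one gene copy from the ingroup and one
#' from the sister group, and whose group representatives branch concordantly
#' with the ladder (strictly nested MRCAs).  A subtree supports a shared
#' duplication at the node iff it contains an internal node LCA-mapping there
#' whose two children each hold at least one ingroup taxon.
#'
#' @param genes multi-copy gene trees (`gene_tree_set` or list).
#' @param species rooted species tree.
#' @param ladder a [build_ladder()] result.
#' @param map optional taxon map (defaults to `species@k` labels, or the
#'   `gene_tree_set`'s own map).
#' @return data frame of class `maps_profile`, one row per ladder node:
#'   `node`, `label` (sister clade), `examined`, `shared`, `percent`.
#' @export
maps_analysis <- function(genes, species, ladder, map = NULL) {
  trees <- .as_gene_trees(genes)
  if (is.null(map) && inherits(genes, "gene_tree_set")) map <- genes$map
  slt <- .lt(species)
  nlad <- length(ladder)
  lad_nodes <- vapply(ladder, `[[`, integer(1), "node")
  # group id per species label (0 = not in any ladder group)
  all_groups <- ladder[[nlad]]$groups
  gid <- integer(length(species$tip.label))
  names(gid) <- species$tip.label
  for (g in seq_along(all_groups)) gid[all_groups[[g]]] <- g
  examined <- shared <- integer(nlad)
  for (tr in trees) {
    lt <- .lt(tr)
    sp <- .tip_species(tr$tip.label, map)
    tipix <- match(sp, species$tip.label)
    if (anyNA(tipix)) stop("gene copies map to unknown species",
                           call. = FALSE)
    gtipmap <- integer(lt$n_node)
    gtipmap[seq_len(lt$n_tip)] <- tipix
    r <- cpp_lca_reconcile(lt$parent, lt$postorder, gtipmap, slt$parent,
                           slt$depth)
    m <- r$map
    # per gene node: bitmask of ladder groups present below (31-bit limit)
    gmask <- integer(lt$n_node)
    grp <- gid[species$tip.label[tipix]]
    for (v in lt$postorder) {
      ch <- lt$children[[v]]
      if (!length(ch)) {
        gmask[v] <- if (grp[v] > 0L) bitwShiftL(1L, grp[v] - 1L) else 0L
      } else {
        x <- 0L
        for (u in ch) x <- bitwOr(x, gmask[u])
        gmask[v] <- x
      }
    }
    for (i in seq_len(nlad)) {
      node <- lad_nodes[i]
      in_bits <- bitwShiftL(1L, i) - 1L           # groups 1..i
      sis_bit <- bitwShiftL(1L, i)                # group i+1
      cand <- which(m == node & lt$parent == 0L |
                    (m == node & lt$parent > 0L &
                     m[pmax(lt$parent, 1L)] != node))
      cand <- cand[cand > lt$n_tip]
      cand <- cand[bitwAnd(gmask[cand], in_bits) > 0L &
                   bitwAnd(gmask[cand], sis_bit) > 0L]
      for (h in cand) {
        if (!.ladder_concordant(h, lt, grp, i + 1L)) next
        examined[i] <- examined[i] + 1L
        # shared duplication: node in subtree mapping here, both children
        # holding ingroup taxa
        if (.has_shared_dup(h, lt, m, gmask, node, in_bits))
          shared[i] <- shared[i] + 1L
      }
    }
  }
  out <- data.frame(
    node = lad_nodes,
    label = vapply(ladder, function(l)
      paste(l$sister, collapse = "."), character(1)),
    examined = examined, shared = shared,
    percent = ifelse(examined > 0, 100 * shared / examined, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("maps_profile", class(out))
  out
}

# concordance of the subtree at h with the ladder: pick the first tip per
# group (groups 1..ngrp present below h) and require strictly nested MRCAs in
# ladder order
.ladder_concordant <- function(h, lt, grp, ngrp) {
  tips <- .subtree_tips(h, lt)
  reps <- integer(0)
  for (g in seq_len(ngrp)) {
    tg <- tips[grp[tips] == g]
    if (length(tg)) reps <- c(reps, tg[1L])
  }
  if (length(reps) < 3L) return(TRUE)
  cur <- reps[1L]
  for (j in 2L:length(reps)) {
    nxt <- .lca2r(cur, reps[j], lt$parent, lt$depth)
    if (j > 2L && nxt == cur) return(FALSE)
    cur <- nxt
  }
  TRUE
}

.subtree_tips <- function(h, lt) {
  if (h <= lt$n_tip) return(h)
  out <- integer(0)
  stack <- h
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- lt$children[[v]]
    if (!length(ch)) out <- c(out, v)
    else stack <- c(stack, ch)
  }
  out
}

.has_shared_dup <- function(h, lt, m, gmask, node, in_bits) {
  stack <- h
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- lt$children[[v]]
    if (length(ch) < 2L) next
    if (m[v] == node) {
      hits <- vapply(ch, function(u)
        bitwAnd(gmask[u], in_bits) > 0L, logical(1))
      if (sum(hits) >= 2L) return(TRUE)
    }
    stack <- c(stack, ch)
  }
  FALSE
}

#' Significance of a shared-duplication profile against simulations
#'
#' Pools simulated null (no WGD) and positive (WGD) profiles across
#' replicates and compares the observed per-node shared/examined counts by
#' one-sided Fisher exact tests.  A node is flagged WGD-like iff it is
#' significantly above the null rate and not significantly below the positive
#' rate.
#'
#' @param observed a [maps_analysis()] profile.
#' @param null_profiles,positive_profiles lists of profiles from simulated
#'   replicates (matching ladder).
#' @param alpha test level.
#' @param adjust `"holm"` (default) applies a Holm correction to the
#'   null-comparison p-values across the ladder nodes, controlling the
#'   family-wise false-flag rate per data set; `"none"` uses raw p-values.
#' @return the observed profile with `p_null`, `p_positive` and `wgd_like`
#'   columns appended.
#' @export
maps_significance <- function(observed, null_profiles, positive_profiles,
                              alpha = 0.05, adjust = c("holm", "none")) {
  adjust <- match.arg(adjust)
  pool <- function(profiles) {
    ex <- Reduce(`+`, lapply(profiles, `[[`, "examined"))
    sh <- Reduce(`+`, lapply(profiles, `[[`, "shared"))
    list(examined = ex, shared = sh)
  }
  np <- pool(null_profiles)
  pp <- pool(positive_profiles)
  n <- nrow(observed)
  p_null <- p_pos <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (observed$examined[i] == 0) next
    if (np$examined[i] > 0)
      p_null[i] <- fisher.test(matrix(c(
        observed$shared[i], observed$examined[i] - observed$shared[i],
        np$shared[i], np$examined[i] - np$shared[i]), 2, byrow = TRUE),
        alternative = "greater")$p.value
    if (pp$examined[i] > 0)
      p_pos[i] <- fisher.test(matrix(c(
        observed$shared[i], observed$examined[i] - observed$shared[i],
        pp$shared[i], pp$examined[i] - pp$shared[i]), 2, byrow = TRUE),
        alternative = "less")$p.value
  }
  if (adjust == "holm") {
    ok <- !is.na(p_null)
    p_null[ok] <- p.adjust(p_null[ok], method = "holm")
  }
  observed$p_null <- p_null
  observed$p_positive <- p_pos
  observed$wgd_like <- !is.na(p_null) & p_null < alpha &
    (is.na(p_pos) | p_pos >= alpha)
  observed
}
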