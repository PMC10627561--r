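# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately avoid the package's internal helpers.

# --- bipartitions / Robinson-Foulds ----------------------------------------

# non-trivial bipartitions of an unrooted tree as canonical keys, derived
# directly from the edge matrix
oracle_bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    if (child <= n) next
    # tips below this edge by graph reachability, avoiding the parent
    below <- c()
    stack <- child
    repeat {
      if (!length(stack)) break
      v <- stack[1]; stack <- stack[-1]
      kids <- phy$edge[phy$edge[, 1] == v, 2]
      below <- c(below, kids[kids <= n])
      stack <- c(stack, kids[kids > n])
    }
    side <- sort(phy$tip.label[below])
    other <- sort(setdiff(phy$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    anchor <- min(phy$tip.label)
    keys <- c(keys, paste(if (anchor %in% side) side else other,
                          collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- quartet resolution -----------------------------------------------------

# induced quartet of a tree restricted to four taxa, via keep.tip + RF
# against the three reference topologies; 0 when a taxon is missing
oracle_quartet <- function(tree, quad) {
  quad <- sort(quad)
  if (!all(quad %in% tree$tip.label)) return(0L)
  sub <- ape::unroot(ape::keep.tip(tree, quad))
  refs <- c(
    sprintf("((%s,%s),(%s,%s));", quad[1], quad[2], quad[3], quad[4]),
    sprintf("((%s,%s),(%s,%s));", quad[1], quad[3], quad[2], quad[4]),
    sprintf("((%s,%s),(%s,%s));", quad[1], quad[4], quad[2], quad[3]))
  for (i in 1:3) {
    ref <- ape::unroot(ape::read.tree(text = refs[i]))
    if (ape::dist.topo(sub, ref) == 0) return(i)
  }
  0L
}

# --- Holm-Bonferroni (literal step-down definition) ------------------------

oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# --- exhaustive duplication-loss reconciliation ----------------------------

# minimal dup+loss score over ALL valid gene-node -> species-node mappings
# (tips fixed, parent maps must be ancestors-or-equal of child maps), with
# the standard per-edge loss rule.  Only feasible for tiny trees.
oracle_reconcile <- function(gene, species, map = NULL) {
  stip <- species$tip.label
  ns <- length(stip) + species$Nnode
  spar <- integer(ns)
  spar[species$edge[, 2]] <- species$edge[, 1]
  sdep <- integer(ns)
  ord <- rev(ape::reorder.phylo(species, "postorder")$edge[, 2])
  for (v in ord) sdep[v] <- sdep[spar[v]] + 1L
  anc <- function(v) { out <- v; while (spar[v] != 0) { v <- spar[v]; out <- c(out, v) }; out }
  ntg <- length(gene$tip.label)
  ngn <- ntg + gene$Nnode
  gpar <- integer(ngn)
  gpar[gene$edge[, 2]] <- gene$edge[, 1]
  kids <- split(gene$edge[, 2], gene$edge[, 1])
  gpost <- ape::reorder.phylo(gene, "postorder")$edge[, 2]
  gpost <- c(gpost[!duplicated(gpost)], ntg + 1L)
  sp_lab <- if (is.null(map)) sub("@\\d+$", "", gene$tip.label)
    else map$species[match(gene$tip.label, map$gene_copy)]
  tipmap <- match(sp_lab, stip)
  # candidate species nodes per internal gene node: ancestors of the LCA of
  # its descendant species tips
  lca_pair <- function(a, b) {
    while (a != b) if (sdep[a] >= sdep[b]) a <- spar[a] else b <- spar[b]
    a
  }
  clade_lca <- integer(ngn)
  for (v in gpost) {
    if (v <= ntg) { clade_lca[v] <- tipmap[v]; next }
    ks <- kids[[as.character(v)]]
    m <- clade_lca[ks[1]]
    for (u in ks[-1]) m <- lca_pair(m, clade_lca[u])
    clade_lca[v] <- m
  }
  internals <- gpost[gpost > ntg]
  cand <- lapply(internals, function(v) anc(clade_lca[v]))
  best <- Inf
  assign_map <- integer(ngn)
  assign_map[seq_len(ntg)] <- tipmap
  score <- function() {
    isdup <- logical(ngn)
    for (v in internals) {
      ks <- kids[[as.character(v)]]
      # speciation only when the node sits exactly at the LCA of its
      # children's maps and the children map strictly below it (into
      # different child subtrees); anything else is a duplication
      l <- assign_map[ks[1]]
      for (u in ks[-1]) l <- lca_pair(l, assign_map[u])
      isdup[v] <- !(assign_map[v] == l &&
                      all(assign_map[ks] != assign_map[v]))
    }
    loss <- 0
    for (v in seq_len(ngn)) {
      p <- gpar[v]
      if (p == 0) next
      d <- sdep[assign_map[v]] - sdep[assign_map[p]]
      loss <- loss + d - 1 + as.integer(isdup[p])
    }
    sum(isdup) + loss
  }
  rec <- function(i) {
    if (i > length(internals)) {
      s <- score()
      if (s < best) best <<- s
      return(invisible())
    }
    v <- internals[i]
    for (m in cand[[i]]) {
      # child constraint: children already assigned (postorder) must map at
      # or below m
      ks <- kids[[as.character(v)]]
      ok <- all(vapply(ks, function(u) m %in% anc(assign_map[u]),
                       logical(1)))
      if (!ok) next
      assign_map[v] <<- m
      rec(i + 1)
    }
    assign_map[v] <<- 0L
  }
  rec(1)
  best
}

# --- NG86 via an independent code source -----------------------------------

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_ng86 <- function(seq1, seq2) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(toupper(seq1)); c2 <- split3(toupper(seq2))
  nts <- c("A", "C", "G", "T")
  syn_sites <- function(cd) {
    aa <- oracle_translate(cd)
    b <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) for (nt in setdiff(nts, b[pos])) {
      b2 <- b; b2[pos] <- nt
      if (oracle_translate(paste(b2, collapse = "")) == aa) s <- s + 1 / 3
    }
    s
  }
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  pair_sd_nd <- function(a, b) {
    if (a == b) return(c(0, 0))
    ba <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
    dif <- which(ba != bb)
    acc <- NULL; viable <- NULL
    for (path in perms(dif)) {
      cur <- ba; sd <- nd <- 0; v <- TRUE
      for (pos in path) {
        aa1 <- oracle_translate(paste(cur, collapse = ""))
        cur[pos] <- bb[pos]
        to <- paste(cur, collapse = "")
        aa2 <- oracle_translate(to)
        if (aa2 == "*" && to != b) v <- FALSE
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      }
      acc <- rbind(acc, c(sd, nd)); viable <- c(viable, v)
    }
    use <- if (any(viable)) viable else rep(TRUE, length(viable))
    colMeans(acc[use, , drop = FALSE])
  }
  S <- (sum(sapply(c1, syn_sites)) + sum(sapply(c2, syn_sites))) / 2
  N <- 3 * length(c1) - S
  dd <- rowSums(sapply(seq_along(c1), function(i) pair_sd_nd(c1[i], c2[i])))
  pS <- dd[1] / S; pN <- dd[2] / N
  list(S = S, N = N, Sd = dd[1], Nd = dd[2], pS = pS, pN = pN,
       Ks = if (pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA,
       Ka = if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA)
}

# --- misc helpers -----------------------------------------------------------

# caterpillar species tree (((A,B),C),D)... with unit internal branches
make_caterpillar <- function(labels, blen = 1) {
  n <- length(labels)
  txt <- paste0(labels[1], ":", blen)
  for (i in 2:n)
    txt <- paste0("(", txt, ",", labels[i], ":", blen * (i - 1), "):", blen)
  ape::read.tree(text = paste0(txt, ";"))
}

msc_concordance <- function(t) 1 - (2 / 3) * exp(-t)

# random binary rooted gene tree over gene-copy labels
random_gene_tree <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = TRUE)
  tr$tip.label <- sample(labels)
  tr
}
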