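# Orthogroup selection, long-branch pruning, and rooted-tree (RT) ortholog
# extraction from multi-copy homolog trees.

#' Per-species copy-number table for a set of homolog trees
#'
#' @param genes a `gene_tree_set` or list of trees whose tips are gene copies.
#' @param map optional gene-copy to species map; defaults to the `species@k`
#'   naming convention.
#' @param species optional character vector fixing the column set.
#' @return an integer matrix, orthogroups (trees) in rows, species in columns.
#' @export
orthogroup_stats <- function(genes, map = NULL, species = NULL) {
  trees <- .as_gene_trees(genes)
  if (is.null(map) && inherits(genes, "gene_tree_set")) map <- genes$map
  sp_per_tree <- lapply(trees, function(tr) .tip_species(tr$tip.label, map))
  if (is.null(species))
    species <- sort(unique(unlist(sp_per_tree)))
  out <- t(vapply(sp_per_tree, function(sv)
    tabulate(factor(sv, levels = species), nbins = length(species)),
    integer(length(species))))
  colnames(out) <- species
  rownames(out) <- if (!is.null(names(trees))) names(trees)
    else sprintf("og%04d", seq_along(trees))
  out
}

#' Select orthogroups by presence and copy-number criteria
#'
#' An orthogroup is retained iff (1) it has at least one copy in at least
#' `min_presence` species, (2) its mean copy number is `<= max_mean`, and
#' (3) its median copy number is `<= max_median`.  By default the mean and
#' median are taken over the species that have at least one copy.
#'
#' @param counts copy-number matrix as from [orthogroup_stats()] (orthogroups
#'   in rows, species in columns, rownames are ids).
#' @param min_presence minimum number of species with >= 1 copy; default all
#'   species (every column).
#' @param max_mean,max_median copy-number ceilings.
#' @param include_absent include zero-count species in the mean/median.
#' @return character vector of retained orthogroup ids (row names).
#' @export
select_orthogroups <- function(counts, min_presence = NULL, max_mean = 5,
                               max_median = 2, include_absent = FALSE) {
  counts <- as.matrix(counts)
  if (!nrow(counts)) return(character(0))
  if (is.null(min_presence)) min_presence <- ncol(counts)
  keep <- apply(counts, 1, function(x) {
    pres <- sum(x >= 1)
    v <- if (include_absent) x else x[x >= 1]
    pres >= min_presence && mean(v) <= max_mean && median(v) <= max_median
  })
  rn <- rownames(counts)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(counts)))
  rn[keep]
}

#' Prune spuriously long branches from a gene tree
#'
#' Iterates two rules to a fixed point: (a) any branch (internal or terminal)
#' longer than `abs_cutoff` is cut and the component with more tips kept
#' (ties keep the rootward component); (b) any terminal branch longer than
#' `tip_cutoff` *and* more than `ratio` times the longest (or mean, see
#' `sister_stat`) terminal branch of its sister clade is pruned.  Branch
#' lengths are substitutions per site.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tip_cutoff minimum terminal branch length for rule (b).
#' @param ratio sister-relative factor for rule (b).
#' @param abs_cutoff absolute cutoff for rule (a).
#' @param sister_stat compare against the `"max"` (default, conservative) or
#'   `"mean"` terminal branch length of the sister clade.
#' @param min_tips trees reduced below this many tips are flagged as
#'   discarded rather than returned.
#' @return a list of class `curated_tree`: `tree` (`NULL` when discarded),
#'   `removed` (data frame of tip labels and the rule that fired),
#'   `n_internal_cuts`, and `discarded`.
#' @export
prune_long_branches <- function(tree, tip_cutoff = 0.2, ratio = 10,
                                abs_cutoff = 0.5,
                                sister_stat = c("max", "mean"),
                                min_tips = 4) {
  sister_stat <- match.arg(sister_stat)
  if (is.null(tree$edge.length))
    stop("`tree` has no branch lengths", call. = FALSE)
  removed <- data.frame(tip = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  n_cuts <- 0L
  phy <- tree
  drop_rec <- function(tips, rule) {
    removed <<- rbind(removed, data.frame(tip = tips, rule = rule,
                                          stringsAsFactors = FALSE))
  }
  repeat {
    if (length(phy$tip.label) < min_tips)
      return(structure(list(tree = NULL, removed = removed,
                            n_internal_cuts = n_cuts, discarded = TRUE),
                       class = "curated_tree"))
    changed <- FALSE
    # rule (a): absolute cutoff, longest branch first
    repeat {
      lt <- .lt(phy)
      over <- which(!is.na(lt$elen) & lt$elen > abs_cutoff)
      if (!length(over)) break
      v <- over[which.max(lt$elen[over])]
      below <- if (v <= lt$n_tip) phy$tip.label[v] else
        phy$tip.label[.lt_tipsets(lt, phy$tip.label)[[v]]]
      keep_clade <- length(below) > lt$n_tip - length(below)
      n_cuts <- n_cuts + 1L
      changed <- TRUE
      if (keep_clade) {
        drop_rec(setdiff(phy$tip.label, below), "abs_cutoff")
        phy <- ape::extract.clade(phy, v)
      } else {
        drop_rec(below, "abs_cutoff")
        phy <- ape::drop.tip(phy, below)
      }
      if (is.null(phy) || length(phy$tip.label) < 2L)
        return(structure(list(tree = NULL, removed = removed,
                              n_internal_cuts = n_cuts, discarded = TRUE),
                         class = "curated_tree"))
    }
    # rule (b): relative terminal-branch rule
    lt <- .lt(phy)
    sets <- .lt_tipsets(lt, phy$tip.label)
    bad <- character(0)
    for (u in seq_len(lt$n_tip)) {
      bl <- lt$elen[u]
      if (is.na(bl) || bl <= tip_cutoff) next
      par <- lt$parent[u]
      if (par == 0L) next
      sibs <- setdiff(lt$children[[par]], u)
      sis_tips <- unlist(sets[sibs], use.names = FALSE)
      sis_len <- lt$elen[sis_tips]
      sis_len <- sis_len[!is.na(sis_len)]
      if (!length(sis_len)) next
      stat <- if (sister_stat == "max") max(sis_len) else mean(sis_len)
      if (bl > ratio * stat) bad <- c(bad, phy$tip.label[u])
    }
    if (length(bad)) {
      changed <- TRUE
      drop_rec(bad, "tip_ratio")
      phy <- ape::drop.tip(phy, bad)
      if (is.null(phy))
        return(structure(list(tree = NULL, removed = removed,
                              n_internal_cuts = n_cuts, discarded = TRUE),
                         class = "curated_tree"))
    }
    if (!changed) break
  }
  if (length(phy$tip.label) < min_tips)
    return(structure(list(tree = NULL, removed = removed,
                          n_internal_cuts = n_cuts, discarded = TRUE),
                     class = "curated_tree"))
  structure(list(tree = phy, removed = removed, n_internal_cuts = n_cuts,
                 discarded = FALSE), class = "curated_tree")
}

#' @export
print.curated_tree <- function(x, ...) {
  if (x$discarded) cat("curated_tree: discarded (", nrow(x$removed),
                       "tips removed )\n")
  else cat("curated_tree:", length(x$tree$tip.label), "tips kept,",
           nrow(x$removed), "removed,", x$n_internal_cuts,
           "internal cuts\n")
  invisible(x)
}

#' Extract single-copy orthologs by the rooted-tree (RT) method
#'
#' Roots the homolog tree on the outgroup copies, then walks rootward to
#' tipward: at every node whose child subtrees share at least one species (a
#' putative duplication) only the child with more distinct species is kept
#' (ties: more tips, then the lexicographically smallest species set); nodes
#' whose children share no species but are not yet single-copy are descended
#' on all sides.  Maximal strictly single-copy-per-species subtrees with at
#' least `min_taxa` species are emitted.
#'
#' @param homolog_tree a `phylo` whose tips are gene copies.
#' @param outgroups character vector of outgroup species.
#' @param map optional taxon map (defaults to `species@k` labels).
#' @param min_taxa minimum number of distinct species per emitted ortholog.
#' @return a list of single-copy `phylo` trees; when no outgroup copy is
#'   present an empty list with attribute `skipped = "no outgroup"`.
#' @export
extract_rt_orthologs <- function(homolog_tree, outgroups, map = NULL,
                                 min_taxa = 4) {
  sp <- .tip_species(homolog_tree$tip.label, map)
  og_tips <- homolog_tree$tip.label[sp %in% outgroups]
  if (!length(og_tips))
    return(structure(list(), skipped = "no outgroup"))
  phy <- tryCatch(
    ape::root(homolog_tree, outgroup = og_tips, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(phy))
    phy <- ape::root(homolog_tree, outgroup = og_tips[1L],
                     resolve.root = TRUE)
  lt <- .lt(phy)
  sp <- .tip_species(phy$tip.label, map)
  sets <- .lt_tipsets(lt, phy$tip.label)
  spset <- lapply(sets, function(ix) sp[ix])
  out <- list()
  queue <- lt$root
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    sv <- spset[[v]]
    if (!anyDuplicated(sv)) {
      if (length(unique(sv)) >= min_taxa) {
        sub <- if (v == lt$root) phy
          else if (v <= lt$n_tip) NULL
          else ape::extract.clade(phy, v)
        if (!is.null(sub)) out[[length(out) + 1L]] <- sub
      }
      next
    }
    ch <- lt$children[[v]]
    shares <- FALSE
    if (length(ch) >= 2L)
      for (i in seq_along(ch)) for (j in seq_along(ch))
        if (i < j && length(intersect(unique(spset[[ch[i]]]),
                                      unique(spset[[ch[j]]]))))
          shares <- TRUE
    if (shares) {
      pick <- .rt_pick(ch, spset, sets)
      queue <- c(queue, pick)
    } else {
      queue <- c(queue, ch)
    }
  }
  out
}

# duplication-node tie-breaking: more distinct species, then more tips, then
# lexicographically smallest sorted species set
.rt_pick <- function(ch, spset, sets) {
  nsp <- vapply(ch, function(v) length(unique(spset[[v]])), integer(1))
  cand <- ch[nsp == max(nsp)]
  if (length(cand) > 1L) {
    ntip <- vapply(cand, function(v) length(sets[[v]]), integer(1))
    cand <- cand[ntip == max(ntip)]
  }
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(v)
      paste(sort(unique(spset[[v]])), collapse = "|"), character(1))
    cand <- cand[order(keys)][1L]
  }
  cand[1L]
}
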