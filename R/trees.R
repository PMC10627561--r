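#' Read trees from Newick text or file
#'
#' Thin validating wrapper around [ape::read.tree()].  Accepts one or more
#' trees (one per line when reading a file).  Internal node labels are kept
#' verbatim (they usually carry support values); branch lengths are optional.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text a Newick string (may contain several trees separated by `;`).
#' @param single require exactly one tree and return it bare.
#' @return a `phylo` object (when a single tree is read or `single = TRUE`)
#'   or a list of `phylo` objects.
#' @export
read_newick <- function(file = NULL, text = NULL, single = FALSE) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(file)
      else ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree could be read",
                        call. = FALSE)
  trees <- if (inherits(tr, "phylo")) list(tr) else unclass(tr)
  for (t in trees) {
    dup <- unique(t$tip.label[duplicated(t$tip.label)])
    if (length(dup))
      stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
  }
  if (single || length(trees) == 1L) {
    if (length(trees) != 1L) stop("expected a single tree, got ",
                                  length(trees), call. = FALSE)
    return(trees[[1L]])
  }
  trees
}

#' Write trees as Newick
#'
#' @param tree a `phylo` or list of `phylo`.
#' @param file output path or `NULL` to return the string(s).
#' @param digits significant digits for branch lengths.
#' @return the Newick string(s), invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  trees <- .as_gene_trees(tree)
  out <- vapply(trees, function(t)
    ape::write.tree(t, digits = digits), character(1))
  if (is.null(file)) return(if (length(out) == 1L) out[[1L]] else out)
  writeLines(out, file)
  invisible(out)
}

#' Last common ancestor of a set of tips
#'
#' @param tree a rooted `phylo`.
#' @param tips character vector of tip labels (or integer tip indices).
#' @return the node number (ape numbering) of the most recent common
#'   ancestor; a single tip returns that tip's number.
#' @export
lca <- function(tree, tips) {
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted", call. = FALSE)
  if (is.character(tips)) {
    ix <- match(tips, tree$tip.label)
    if (anyNA(ix)) stop("unknown tip(s): ",
                        paste(tips[is.na(ix)], collapse = ", "),
                        call. = FALSE)
  } else ix <- as.integer(tips)
  if (!length(ix)) stop("`tips` is empty", call. = FALSE)
  ix <- unique(ix)
  if (length(ix) == 1L) return(ix)
  ape::getMRCA(tree, ix)
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference distance between the unrooted bipartition sets of two
#' trees on the same tip set (computed via [phangorn::RF.dist()]).
#'
#' @param t1,t2 `phylo` trees with identical tip sets.
#' @return a non-negative integer; 0 iff the unrooted topologies agree.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("tip sets differ between the two trees", call. = FALSE)
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Clade frequencies of a reference tree in a tree collection
#'
#' For every non-trivial clade of `reference`, the fraction of trees in
#' `collection` that contain it.  When both the reference and all collection
#' trees are rooted, clades are matched as rooted tip sets; otherwise as
#' unrooted bipartitions.  Trees missing some reference tips are restricted
#' to the shared tip set first; a clade reduced to fewer than two tips (or to
#' the whole shared set) is skipped for that tree and does not enter its
#' denominator.
#'
#' @param reference a `phylo` tree whose clades are scored.
#' @param collection a list of `phylo` trees (or a `gene_tree_set`).
#' @param rooted force rooted (`TRUE`) or bipartition (`FALSE`) matching;
#'   default `NULL` decides from the trees.
#' @return a data frame with one row per non-trivial reference clade:
#'   `clade` (dot-joined sorted tip labels), `size`, `n_present`, `n_used`,
#'   and `frequency` = `n_present / n_used`.
#' @export
clade_frequencies <- function(reference, collection, rooted = NULL) {
  trees <- .as_gene_trees(collection)
  if (!length(trees)) stop("`collection` is empty", call. = FALSE)
  if (is.null(rooted))
    rooted <- ape::is.rooted(reference) &&
      all(vapply(trees, ape::is.rooted, logical(1)))
  universe <- reference$tip.label
  n <- length(universe)
  ref_sets <- .clade_sets(reference, universe, rooted,
                          shared = seq_len(n))
  if (!length(ref_sets))
    stop("reference tree has no non-trivial clade", call. = FALSE)
  n_present <- n_used <- integer(length(ref_sets))
  for (tr in trees) {
    shared <- sort(match(intersect(tr$tip.label, universe), universe))
    if (length(shared) < 4L && !rooted) next
    if (length(shared) < 3L) next
    keys <- .clade_keys(tr, universe, rooted, shared)
    for (i in seq_along(ref_sets)) {
      s <- ref_sets[[i]][ref_sets[[i]] %in% shared]
      if (length(s) < 2L || length(s) >= length(shared)) next
      n_used[i] <- n_used[i] + 1L
      k <- if (rooted) .setkey(s) else .bipkey(s, shared)
      if (k %in% keys) n_present[i] <- n_present[i] + 1L
    }
  }
  data.frame(
    clade = vapply(ref_sets, function(s)
      paste(sort(universe[s]), collapse = "."), character(1)),
    size = lengths(ref_sets),
    n_present = n_present,
    n_used = n_used,
    frequency = ifelse(n_used > 0, n_present / n_used, NA_real_),
    stringsAsFactors = FALSE)
}

# non-trivial clades of `phy` as sorted universe-index sets
.clade_sets <- function(phy, universe, rooted, shared) {
  lt <- .lt(phy)
  sets <- .lt_tipsets(lt, universe)
  internal <- setdiff(lt$postorder, seq_len(lt$n_tip))
  out <- list()
  for (v in internal) {
    s <- sets[[v]]
    if (length(s) < 2L || length(s) >= length(shared)) next
    out[[length(out) + 1L]] <- s
  }
  unique(out)
}

# canonical bipartition key: the side containing the smallest shared index
.bipkey <- function(s, shared) {
  if (shared[1L] %in% s) .setkey(s)
  else .setkey(setdiff(shared, s))
}

# keys of all non-trivial clades/bipartitions of `phy`, expressed in
# universe indices restricted to `shared`
.clade_keys <- function(phy, universe, rooted, shared) {
  lt <- .lt(phy)
  sets <- .lt_tipsets(lt, universe)
  internal <- setdiff(lt$postorder, seq_len(lt$n_tip))
  keys <- character(0)
  for (v in internal) {
    s <- sets[[v]]
    s <- s[s %in% shared]
    if (length(s) < 2L || length(s) >= length(shared)) next
    keys <- c(keys, if (rooted) .setkey(s) else .bipkey(s, shared))
  }
  unique(keys)
}

#' Read a gene-copy to species map
#'
#' Reads a two-column TSV (`gene_copy<TAB>species`, no header required) into
#' the data frame used by the reconciliation and curation functions.
#'
#' @param file path to the TSV.
#' @return data frame with columns `gene_copy` and `species`.
#' @export
read_taxon_map <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene_copy", "species"))
  validate_taxon_map(df)
}

#' Construct / validate a gene-copy to species map
#'
#' @param gene_copy character vector of gene-copy labels (unique).
#' @param species character vector of species labels, recycled against
#'   `gene_copy`.
#' @return data frame with columns `gene_copy` and `species`.
#' @export
taxon_map <- function(gene_copy, species) {
  validate_taxon_map(data.frame(gene_copy = as.character(gene_copy),
                                species = as.character(species),
                                stringsAsFactors = FALSE))
}

validate_taxon_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("gene_copy", "species") %in% names(map)))
  if (anyDuplicated(map$gene_copy))
    stop("taxon map assigns some gene copy more than one species",
         call. = FALSE)
  map
}

# species labels for gene-copy tip labels; falls back on the `species@k`
# naming convention when no map is supplied.
.tip_species <- function(labels, map = NULL) {
  if (is.null(map)) return(sub("@\\d+$", "", labels))
  sp <- map$species[match(labels, map$gene_copy)]
  if (anyNA(sp))
    stop("gene copies missing from the taxon map: ",
         paste(head(labels[is.na(sp)], 5), collapse = ", "), call. = FALSE)
  sp
}
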