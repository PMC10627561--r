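# Internal light-weight tree representation used by the simulators and the
# counting code.  Nodes keep ape's numbering: tips 1..n, internals n+1..n+m
# with the root at n+1.

.lt <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree", call. = FALSE)
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  parent <- integer(nn)
  elen <- rep(NA_real_, nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (!is.null(phy$edge.length)) elen[phy$edge[, 2]] <- phy$edge.length
  children <- vector("list", nn)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  children[as.integer(names(kids))] <- kids
  root <- nt + 1L
  po_edge <- ape::reorder.phylo(phy, "postorder")$edge
  postorder <- c(po_edge[, 2][!duplicated(po_edge[, 2])], root)
  depth <- integer(nn)
  for (v in rev(postorder)) if (v != root) depth[v] <- depth[parent[v]] + 1L
  list(phy = phy, n_tip = nt, n_node = nn, root = root, parent = parent,
       children = children, elen = elen, postorder = postorder,
       depth = depth, tip_label = phy$tip.label)
}

# node ages (distance above the tips), taking branch lengths as given; for a
# non-ultrametric tree the age of an internal node is the maximum path length
# to any descendant tip.
.lt_ages <- function(lt) {
  age <- numeric(lt$n_node)
  for (v in lt$postorder) {
    ch <- lt$children[[v]]
    if (length(ch))
      age[v] <- max(age[ch] + lt$elen[ch])
  }
  age
}

# per-node descendant tip index sets (indices into `universe`); tips absent
# from `universe` are dropped.
.lt_tipsets <- function(lt, universe) {
  m <- match(lt$tip_label, universe)
  sets <- vector("list", lt$n_node)
  for (v in lt$postorder) {
    ch <- lt$children[[v]]
    if (!length(ch)) {
      sets[[v]] <- if (is.na(m[v])) integer(0) else m[v]
    } else {
      sets[[v]] <- sort(unlist(sets[ch], use.names = FALSE))
    }
  }
  sets
}

.setkey <- function(ix) paste(ix, collapse = ".")

# Build an ape phylo from parent pointers and node heights.  `parent` is 0
# for the root; tips are entries 1..n_tip and carry `tip_label`.  Unifurcating
# chains are not expected (callers emit binary trees).
.parents_to_phylo <- function(parent, height, tip_label) {
  n <- length(tip_label)
  nn <- length(parent)
  stopifnot(nn == 2L * n - 1L || n == 1L)
  if (n == 1L) stop("cannot build a one-tip tree", call. = FALSE)
  children <- vector("list", nn)
  for (v in seq_len(nn)) {
    p <- parent[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }
  root <- which(parent == 0L)
  newid <- integer(nn)
  newid[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    newid[v] <- nxt
    nxt <- nxt + 1L
    ch <- children[[v]]
    stack <- c(stack, rev(ch[ch > n]))
  }
  has_par <- which(parent > 0L)
  edge <- cbind(newid[parent[has_par]], newid[has_par])
  elen <- height[parent[has_par]] - height[has_par]
  elen[elen < 0] <- 0
  phy <- list(edge = edge, edge.length = elen, Nnode = n - 1L,
              tip.label = tip_label)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

# Normalize a gene-tree collection argument: either a bare list of phylo
# trees, a multiPhylo, or a gene_tree_set.
.as_gene_trees <- function(genes) {
  if (inherits(genes, "gene_tree_set")) return(genes$trees)
  if (inherits(genes, "phylo")) return(list(genes))
  if (inherits(genes, "multiPhylo")) return(unclass(genes))
  if (is.list(genes)) return(genes)
  stop("`genes` must be a list of trees or a gene_tree_set", call. = FALSE)
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("gene_tree_set:", length(x$trees), "trees")
  if (!is.null(x$map)) cat(";", nrow(x$map), "gene copies mapped to",
                           length(unique(x$map$species)), "species")
  cat("\n")
  invisible(x)
}
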