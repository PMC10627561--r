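# GRAMPA-style multilabeled (MUL) tree construction, duplication-loss
# reconciliation with ambiguous tip assignment, and search over
# allopolyploidy hypotheses (H1 = polyploid clade, H2 = second placement).

#' Build a MUL tree: graft a second copy of a clade onto another edge
#'
#' @param species rooted `phylo`.
#' @param h1 the hypothesized polyploid clade: a branch spec (tip label,
#'   dot/comma-joined labels, or node id; see [introgression_edge()]).
#' @param h2 the edge (identified by the node below it) onto which the second
#'   copy of `h1` is attached, halfway along.  `h2 = h1` grafts onto the
#'   clade's own stem (the autopolyploidy hypothesis).
#' @return a `phylo` with repeated tip labels, class `c("mul_tree","phylo")`,
#'   attributes `h1_tips`, `h1`, `h2`.
#' @export
build_mul_tree <- function(species, h1, h2) {
  lt <- .lt(species)
  v1 <- .resolve_branch(species, h1)
  v2 <- .resolve_branch(species, h2)
  if (v1 == lt$root) stop("`h1` must be a proper clade, not the whole tree",
                          call. = FALSE)
  sets <- .lt_tipsets(lt, species$tip.label)
  if (v2 != v1 && v2 %in% .descendants(v1, lt))
    stop("`h2` lies inside the `h1` clade", call. = FALSE)
  h1_tips <- species$tip.label[sets[[v1]]]
  sub <- if (v1 <= lt$n_tip)
    ape::read.tree(text = paste0("(", species$tip.label[v1], ":",
                                 lt$elen[v1], ");"))
  else {
    s <- ape::extract.clade(species, v1)
    s$root.edge <- lt$elen[v1]
    s
  }
  pos <- lt$elen[v2] / 2
  if (is.na(pos)) pos <- 0
  mul <- ape::bind.tree(species, sub, where = v2, position = pos)
  class(mul) <- c("mul_tree", "phylo")
  attr(mul, "h1_tips") <- h1_tips
  attr(mul, "h1") <- h1
  attr(mul, "h2") <- h2
  mul
}

.descendants <- function(v, lt) {
  out <- v
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- lt$children[[u]]
    out <- c(out, ch)
    stack <- c(stack, ch)
  }
  out
}

#' Reconcile a gene tree against a MUL tree
#'
#' Gene copies of species appearing twice in the MUL tree may map to either
#' copy; the duplication+loss score is minimized over assignments —
#' exhaustively when at most `cap` tips are ambiguous, otherwise by greedy
#' single-flip descent from deterministic starts (with a warning).
#'
#' @param gene rooted gene tree.
#' @param mul a [build_mul_tree()] result (or any `phylo` with repeated tip
#'   labels).
#' @param map optional taxon map (defaults to `species@k` labels).
#' @param cap maximum number of ambiguous tips for exhaustive search.
#' @return list: `dups`, `losses`, `total`, `exhaustive`, `n_ambiguous`.
#' @export
mul_reconcile <- function(gene, mul, map = NULL, cap = 12) {
  slt <- .lt(mul)
  ga <- .recon_arrays(gene)
  sp <- .tip_species(gene$tip.label, map)
  optA <- optB <- integer(ga$lt$n_node)
  for (i in seq_len(ga$lt$n_tip)) {
    w <- which(mul$tip.label == sp[i])
    if (!length(w))
      stop("gene copy maps to species absent from the MUL tree: ", sp[i],
           call. = FALSE)
    optA[i] <- w[1L]
    optB[i] <- w[length(w)]
  }
  n_amb <- sum(optA != optB & optA > 0L)
  if (n_amb > cap)
    warning(n_amb, " ambiguous tips exceed cap=", cap,
            "; falling back to greedy search")
  r <- cpp_mul_reconcile(ga$gpar, ga$gpost, optA, optB, slt$parent,
                         slt$depth, as.integer(cap))
  r
}

#' Search allopolyploidy hypotheses by total MUL-tree reconciliation score
#'
#' Scores every (H1, H2) MUL tree and the singly-labeled species tree by the
#' summed duplication+loss reconciliation cost over the gene trees, ranked
#' ascending (ties: fewer duplications, then hypothesis id).  A WGD clade
#' whose best placement beats the singly-labeled tree indicates
#' allopolyploidy (H2 elsewhere) or autopolyploidy (H2 on H1's own stem).
#'
#' @param genes multi-copy gene trees.
#' @param species rooted species tree.
#' @param h1_candidates list of branch specs for candidate polyploid clades.
#' @param h2_candidates list of branch specs for placements, or `"all"` for
#'   every branch not inside the current H1.
#' @param map optional taxon map.
#' @param cap exhaustive-search cap per gene tree, see [mul_reconcile()].
#' @return data frame of class `grampa_result`, ranked: `h1`, `h2` (label
#'   strings; the singly-labeled baseline has `h1 = "none"`), `dups`,
#'   `losses`, `total`, `n_trees_best` (gene trees scoring strictly better
#'   than on the singly-labeled tree), `rank`.
#' @export
grampa_search <- function(genes, species, h1_candidates,
                          h2_candidates = "all", map = NULL, cap = 12) {
  trees <- .as_gene_trees(genes)
  if (!length(trees)) stop("empty gene set", call. = FALSE)
  if (is.null(map) && inherits(genes, "gene_tree_set")) map <- genes$map
  lt <- .lt(species)
  sets <- .lt_tipsets(lt, species$tip.label)
  lab_of <- function(v) paste(species$tip.label[sets[[v]]], collapse = ".")
  base_tot <- base_dup <- 0
  base_per <- numeric(length(trees))
  for (i in seq_along(trees)) {
    r <- lca_reconcile(trees[[i]], species, map)
    base_per[i] <- r$n_dups + r$losses
    base_tot <- base_tot + base_per[i]
    base_dup <- base_dup + r$n_dups
  }
  h1_nodes <- vapply(h1_candidates, function(h)
    .resolve_branch(species, h), integer(1))
  rows <- list(data.frame(h1 = "none", h2 = "none", dups = base_dup,
                          losses = base_tot - base_dup, total = base_tot,
                          n_trees_best = NA_integer_,
                          stringsAsFactors = FALSE))
  for (j in seq_along(h1_nodes)) {
    v1 <- h1_nodes[j]
    h2n <- if (identical(h2_candidates, "all"))
      setdiff(seq_len(lt$n_node), c(lt$root, setdiff(.descendants(v1, lt),
                                                     v1)))
    else vapply(h2_candidates, function(h)
      .resolve_branch(species, h), integer(1))
    for (v2 in h2n) {
      if (v2 != v1 && v2 %in% .descendants(v1, lt)) next
      mul <- build_mul_tree(species, v1, v2)
      tot <- dup <- 0
      nbest <- 0L
      for (i in seq_along(trees)) {
        r <- mul_reconcile(trees[[i]], mul, map, cap)
        tot <- tot + r$total
        dup <- dup + r$dups
        if (r$total < base_per[i]) nbest <- nbest + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        h1 = lab_of(v1), h2 = lab_of(v2), dups = dup, losses = tot - dup,
        total = tot, n_trees_best = nbest, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # a MUL hypothesis must strictly beat the singly-labeled tree: some
  # placements (second copy grafted outside every gene root's map) tie the
  # baseline exactly and must not displace it
  ord <- order(out$total, out$h1 != "none", out$dups, out$h1, out$h2)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("grampa_result", class(out))
  out
}

#' @export
print.grampa_result <- function(x, ...) {
  cat("MUL-tree reconciliation search (ascending duplication+loss):\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more hypotheses\n")
  invisible(x)
}
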