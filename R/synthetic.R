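# Simulators with known ground truth: Yule species trees, multispecies
# coalescent (MSC) gene trees with optional introgression edges, gene-family
# birth-death trees with optional whole-genome duplication, JC69 alignments
# and log-normal Ks mixtures.

#' Simulate a Yule species tree
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate speciation rate of the pure-birth process.
#' @param seed optional integer seed.
#' @return an ultrametric rooted `phylo`; branch lengths are in the units of
#'   `1/birth_rate` and are treated as coalescent units downstream.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 3) stop("`n_taxa` must be >= 3", call. = FALSE)
  stopifnot(birth_rate > 0)
  .with_seed(seed, {
    phy <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
    phy$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
    phy
  })
}

# scaled branch lengths + node ages for a species tree used in simulation;
# terminal branches without a length get `default_tip_len` (in CU) before
# scaling, missing internal lengths are an error.
.sim_prep <- function(species, scale = 1, default_tip_len = 2) {
  lt <- .lt(species)
  bl <- lt$elen
  tips <- seq_len(lt$n_tip)
  miss_tip <- tips[is.na(bl[tips])]
  if (length(miss_tip)) {
    if (is.null(default_tip_len))
      stop("terminal branches lack lengths; set `default_tip_len` ",
           "(coalescent units) to state a terminal-branch policy",
           call. = FALSE)
    bl[miss_tip] <- default_tip_len
  }
  internal <- setdiff(seq_len(lt$n_node), c(tips, lt$root))
  if (anyNA(bl[internal]))
    stop("internal branches lack coalescent-unit lengths", call. = FALSE)
  lt$elen <- bl * scale
  lt$ages <- .lt_ages(lt)
  lt
}

# coalesce lineage ids within one interval; env carries gp/gh/cnt
.coalesce <- function(ids, t0, t1, env) {
  k <- length(ids)
  t <- t0
  while (k >= 2L) {
    t <- t + rexp(1, k * (k - 1) / 2)
    if (t > t1) break
    pr <- sample.int(k, 2L)
    env$cnt <- env$cnt + 1L
    env$gp[ids[pr]] <- env$cnt
    env$gh[env$cnt] <- t
    ids <- c(ids[-pr], env$cnt)
    k <- k - 1L
  }
  ids
}

.msc_one <- function(slt) {
  n <- slt$n_tip
  env <- new.env(parent = emptyenv())
  env$gp <- integer(2L * n - 1L)
  env$gh <- numeric(2L * n - 1L)
  env$cnt <- n
  lin <- vector("list", slt$n_node)
  for (v in slt$postorder) {
    ch <- slt$children[[v]]
    ids <- if (length(ch)) unlist(lin[ch], use.names = FALSE) else v
    top <- if (v == slt$root) Inf else slt$ages[v] + slt$elen[v]
    lin[[v]] <- .coalesce(ids, slt$ages[v], top, env)
  }
  .parents_to_phylo(env$gp, env$gh, slt$tip_label)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One lineage is sampled per species; within every species-tree branch the
#' standard coalescent runs over the branch length (in coalescent units)
#' multiplied by `scale`, and remaining lineages coalesce freely above the
#' root.  Gene-tree tips carry the species labels.
#'
#' @param species rooted `phylo` with coalescent-unit branch lengths.
#' @param n_trees number of gene trees.
#' @param scale multiplier applied to every branch length (e.g. 4.0 for a
#'   haploid, uniparentally inherited plastome).
#' @param seed optional integer seed.
#' @param default_tip_len length (CU) assigned to terminal branches that lack
#'   one, before scaling; `NULL` makes missing terminal lengths an error.
#' @return a `gene_tree_set` whose `trees` element is a list of `phylo`.
#' @export
simulate_msc_gene_trees <- function(species, n_trees, scale = 1, seed = NULL,
                                    default_tip_len = 2) {
  stopifnot(n_trees >= 1, scale > 0)
  slt <- .sim_prep(species, scale, default_tip_len)
  .with_seed(seed, {
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) trees[[i]] <- .msc_one(slt)
    structure(list(trees = trees, map = NULL, truth = NULL),
              class = "gene_tree_set")
  })
}

# resolve a branch specification (tip label, dot/comma-joined clade labels,
# or a node number) to the node below the branch
.resolve_branch <- function(species, spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  tips <- strsplit(as.character(spec), "[,.]")[[1]]
  ix <- match(tips, species$tip.label)
  if (anyNA(ix)) stop("unknown taxa in branch spec: ",
                      paste(tips[is.na(ix)], collapse = ", "), call. = FALSE)
  if (length(ix) == 1L) return(ix)
  ape::getMRCA(species, ix)
}

#' Construct an introgression edge
#'
#' @param donor,recipient branch specifications: a tip label, a dot- or
#'   comma-joined set of tip labels (the branch above their MRCA), or a node
#'   number.
#' @param time age of the event in coalescent units above the tips; must fall
#'   strictly inside both branches.
#' @param gamma inheritance probability in `[0, 1]`: each lineage on the
#'   recipient branch at `time` follows the donor with probability `gamma`.
#' @return a list of class `introgression_edge`.
#' @export
introgression_edge <- function(donor, recipient, time, gamma) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]",
                                   call. = FALSE)
  structure(list(donor = donor, recipient = recipient, time = time,
                 gamma = gamma), class = "introgression_edge")
}

#' Simulate gene trees under an MSC model with introgression edges
#'
#' As [simulate_msc_gene_trees()], but at each introgression event every
#' lineage sitting on the recipient branch independently moves to the donor
#' branch with probability `gamma`.  The species tree must be time-consistent
#' (ultrametric) so that event ages are well defined.
#'
#' @inheritParams simulate_msc_gene_trees
#' @param edges a list of [introgression_edge()] objects (or a single one).
#' @return a `gene_tree_set`; its `truth` element records, per gene tree and
#'   edge, how many lineages were present and moved, and the species whose
#'   lineages moved.
#' @export
simulate_network_gene_trees <- function(species, edges, n_trees, seed = NULL,
                                        scale = 1, default_tip_len = 2) {
  if (inherits(edges, "introgression_edge")) edges <- list(edges)
  stopifnot(length(edges) >= 1, n_trees >= 1)
  slt <- .sim_prep(species, scale, default_tip_len)
  ev_intro <- lapply(edges, function(e) {
    dn <- .resolve_branch(species, e$donor)
    rc <- .resolve_branch(species, e$recipient)
    tm <- e$time * scale
    for (b in c(dn, rc)) {
      lo <- slt$ages[b]
      hi <- if (b == slt$root) Inf else slt$ages[b] + slt$elen[b]
      if (tm <= lo || tm >= hi)
        stop("introgression time ", e$time,
             " lies outside branch above node ", b, call. = FALSE)
    }
    list(donor = dn, recipient = rc, time = tm, gamma = e$gamma)
  })
  n <- slt$n_tip
  node_ev <- setdiff(slt$postorder, seq_len(n))
  sched <- rbind(
    data.frame(age = slt$ages[node_ev], type = "node", id = node_ev),
    data.frame(age = vapply(ev_intro, `[[`, numeric(1), "time"),
               type = "intro", id = seq_along(ev_intro)))
  sched <- sched[order(sched$age, sched$type != "intro"), ]
  .with_seed(seed, {
    trees <- vector("list", n_trees)
    truth <- vector("list", n_trees)
    for (g in seq_len(n_trees)) {
      env <- new.env(parent = emptyenv())
      env$gp <- integer(2L * n - 1L)
      env$gh <- numeric(2L * n - 1L)
      env$cnt <- n
      lin <- vector("list", slt$n_node)
      for (i in seq_len(n)) lin[[i]] <- i
      cur <- 0
      rec <- vector("list", length(ev_intro))
      for (r in seq_len(nrow(sched))) {
        a <- sched$age[r]
        for (b in seq_len(slt$n_node))
          if (length(lin[[b]]) >= 2L)
            lin[[b]] <- .coalesce(lin[[b]], cur, a, env)
        if (sched$type[r] == "node") {
          v <- sched$id[r]
          lin[[v]] <- unlist(lin[slt$children[[v]]], use.names = FALSE)
          for (c2 in slt$children[[v]]) lin[[c2]] <- integer(0)
        } else {
          e <- ev_intro[[sched$id[r]]]
          ids <- lin[[e$recipient]]
          mv <- ids[runif(length(ids)) < e$gamma]
          if (length(mv)) {
            lin[[e$recipient]] <- setdiff(ids, mv)
            lin[[e$donor]] <- c(lin[[e$donor]], mv)
          }
          rec[[sched$id[r]]] <- list(n_present = length(ids),
                                     n_moved = length(mv), moved_ids = mv)
        }
        cur <- a
      }
      lin[[slt$root]] <- .coalesce(lin[[slt$root]], cur, Inf, env)
      trees[[g]] <- .parents_to_phylo(env$gp, env$gh, slt$tip_label)
      # resolve moved lineage ids to the species they subtend
      kids <- vector("list", 2L * n - 1L)
      for (v in seq_len(2L * n - 1L)) {
        p <- env$gp[v]
        if (p > 0L) kids[[p]] <- c(kids[[p]], v)
      }
      desc_tips <- function(v) {
        if (v <= n) return(slt$tip_label[v])
        unlist(lapply(kids[[v]], desc_tips))
      }
      truth[[g]] <- lapply(rec, function(x)
        list(n_present = x$n_present, n_moved = x$n_moved,
             moved_species = sort(unique(unlist(lapply(x$moved_ids,
                                                       desc_tips))))))
    }
    structure(list(trees = trees, map = NULL, truth = truth),
              class = "gene_tree_set")
  })
}

#' Simulate multi-copy gene family trees by birth-death along a species tree
#'
#' A single gene lineage starts at the species-tree root and evolves tipward;
#' along every branch each lineage duplicates at rate `dup_rate` and is lost
#' at rate `loss_rate` (events per coalescent unit per lineage).  If a
#' whole-genome duplication is placed at `wgd_node`, every lineage reaching
#' that node (just rootward of it) duplicates and the extra copy is retained
#' with probability `retention`.  Gene copies are named `species@k`.  Trees
#' left with fewer than two surviving copies are redrawn (the count of such
#' redraws is reported in the truth record).
#'
#' @param species rooted `phylo` with branch lengths in coalescent units.
#'   Repeated tip labels are allowed (a MUL tree can serve as the model, in
#'   which case copies from the two subgenomes are numbered consecutively).
#' @param n_trees number of gene trees.
#' @param dup_rate,loss_rate birth and death rates (>= 0).
#' @param wgd_node optional branch spec (see [introgression_edge()]) of an
#'   internal node carrying the WGD.
#' @param retention survival probability of the extra WGD copy, in `[0, 1]`.
#' @param seed optional integer seed.
#' @param default_tip_len terminal-branch policy, as in
#'   [simulate_msc_gene_trees()].
#' @return a `gene_tree_set` with `trees`, a `map` (gene copy to species) and
#'   `truth`: per tree, the species node of every surviving duplication
#'   (`dup_nodes`), whether at least one WGD duplication retained both copies
#'   (`wgd_both`), and the number of redraws.
#' @export
simulate_dl_gene_trees <- function(species, n_trees, dup_rate = 0,
                                   loss_rate = 0, wgd_node = NULL,
                                   retention = 0, seed = NULL,
                                   default_tip_len = 2) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, retention >= 0, retention <= 1,
            n_trees >= 1)
  slt <- .sim_prep(species, 1, default_tip_len)
  wgd <- if (is.null(wgd_node)) 0L else .resolve_branch(species, wgd_node)
  if (wgd > 0L && wgd <= slt$n_tip)
    stop("`wgd_node` must be an internal node", call. = FALSE)
  .with_seed(seed, {
    trees <- vector("list", n_trees)
    maps <- vector("list", n_trees)
    truth <- vector("list", n_trees)
    for (g in seq_len(n_trees)) {
      redraws <- -1L
      repeat {
        redraws <- redraws + 1L
        res <- .dl_one(slt, dup_rate, loss_rate, wgd, retention)
        if (length(res$tip_ids) >= 2L) break
        if (redraws > 10000L)
          stop("gene families go extinct too often; lower `loss_rate`",
               call. = FALSE)
      }
      sp <- slt$tip_label[res$tip_species]
      k <- stats::ave(seq_along(sp), sp, FUN = seq_along)
      labels <- paste0(sp, "@", k)
      trees[[g]] <- .dl_to_phylo(res, labels)
      maps[[g]] <- data.frame(gene_copy = labels, species = sp,
                              stringsAsFactors = FALSE)
      truth[[g]] <- list(dup_nodes = res$dup_nodes, wgd_both = res$wgd_both,
                         redraws = redraws)
    }
    map <- unique(do.call(rbind, maps))
    rownames(map) <- NULL
    structure(list(trees = trees, map = map, truth = truth),
              class = "gene_tree_set")
  })
}

# one birth-death gene family on the prepared species tree; returns parent
# pointers/heights over surviving nodes only (unifurcations never created)
.dl_one <- function(slt, dup_rate, loss_rate, wgd, retention) {
  env <- new.env(parent = emptyenv())
  env$gp <- integer(64L); env$gh <- numeric(64L); env$cnt <- 0L
  env$tip_ids <- integer(0); env$tip_species <- integer(0)
  env$dup_nodes <- integer(0); env$wgd_both <- FALSE
  rate <- dup_rate + loss_rate
  new_node <- function(h) {
    env$cnt <- env$cnt + 1L
    if (env$cnt > length(env$gp)) {
      env$gp <- c(env$gp, integer(length(env$gp)))
      env$gh <- c(env$gh, numeric(length(env$gh)))
    }
    env$gh[env$cnt] <- h
    env$cnt
  }
  join <- function(l, r, h, snode, is_dup) {
    if (l == 0L) return(r)
    if (r == 0L) return(l)
    d <- new_node(h)
    env$gp[l] <- d; env$gp[r] <- d
    if (is_dup) env$dup_nodes <- c(env$dup_nodes, snode)
    d
  }
  at_node <- function(snode) {
    if (snode == wgd) {
      l <- descend(snode)
      r <- if (runif(1) < retention) descend(snode) else 0L
      if (l > 0L && r > 0L) env$wgd_both <- TRUE
      return(join(l, r, slt$ages[snode], snode, TRUE))
    }
    descend(snode)
  }
  descend <- function(snode) {
    ch <- slt$children[[snode]]
    if (!length(ch)) {
      t <- new_node(slt$ages[snode])
      env$tip_ids <- c(env$tip_ids, t)
      env$tip_species <- c(env$tip_species, snode)
      return(t)
    }
    res <- 0L
    for (c2 in ch)
      res <- join(res, evolve(c2, slt$ages[snode]), slt$ages[snode],
                  snode, FALSE)
    res
  }
  # one lineage entering the branch above `snode` at height `h`
  evolve <- function(snode, h) {
    repeat {
      dt <- if (rate > 0) rexp(1, rate) else Inf
      if (h - dt <= slt$ages[snode]) return(at_node(snode))
      h <- h - dt
      if (runif(1) < loss_rate / rate) return(0L)
      l <- evolve(snode, h)
      r <- evolve(snode, h)
      res <- join(l, r, h, snode, TRUE)
      return(res)
    }
  }
  root_res <- at_node(slt$root)
  list(gp = env$gp[seq_len(env$cnt)], gh = env$gh[seq_len(env$cnt)],
       root = root_res, tip_ids = env$tip_ids,
       tip_species = env$tip_species, dup_nodes = env$dup_nodes,
       wgd_both = env$wgd_both)
}

.dl_to_phylo <- function(res, labels) {
  n <- length(res$tip_ids)
  children <- vector("list", length(res$gp))
  for (v in seq_along(res$gp)) {
    p <- res$gp[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }
  newid <- integer(length(res$gp))
  newid[res$tip_ids] <- seq_len(n)
  nxt <- n + 1L
  stack <- res$root
  n_int <- 0L
  order_int <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (length(children[[v]])) {
      newid[v] <- nxt; nxt <- nxt + 1L; n_int <- n_int + 1L
      stack <- c(stack, rev(children[[v]]))
    }
  }
  edge <- NULL; elen <- NULL
  for (v in seq_along(res$gp)) {
    p <- res$gp[v]
    if (p > 0L && newid[v] > 0L) {
      edge <- rbind(edge, c(newid[p], newid[v]))
      elen <- c(elen, max(res$gh[p] - res$gh[v], 0))
    }
  }
  phy <- list(edge = edge, edge.length = elen, Nnode = n_int,
              tip.label = labels)
  class(phy) <- "phylo"
  phy
}

#' Simulate a nucleotide alignment along a gene tree (JC69)
#'
#' Wrapper around [phangorn::simSeq()]; branch lengths are expected in
#' substitutions per site.
#'
#' @param gene_tree a `phylo`.
#' @param length number of sites (>= 0).
#' @param model substitution model; only `"JC69"` is offered.
#' @param seed optional integer seed.
#' @return a character matrix (`A`/`C`/`G`/`T`), one row per tip.
#' @export
simulate_alignment <- function(gene_tree, length, model = "JC69",
                               seed = NULL) {
  model <- match.arg(model)
  if (length < 0) stop("`length` must be non-negative", call. = FALSE)
  if (length == 0)
    return(matrix(character(0), nrow = length(gene_tree$tip.label), ncol = 0,
                  dimnames = list(gene_tree$tip.label, NULL)))
  .with_seed(seed, {
    dat <- phangorn::simSeq(gene_tree, l = length)
    m <- toupper(as.character(dat))
    rownames(m) <- names(dat)
    m
  })
}

#' Simulate a concatenated alignment over coalescent gene trees
#'
#' Convenience composer for the D-statistic analyses: draws `n_genes` gene
#' trees under the MSC (or network MSC when `edges` is given), rescales their
#' coalescent-unit branch lengths to substitutions per site with
#' `subst_scale`, simulates a JC69 block per gene and concatenates.
#'
#' @inheritParams simulate_network_gene_trees
#' @param n_genes number of gene blocks.
#' @param sites_per_gene sites per block.
#' @param subst_scale substitutions per site per coalescent unit.
#' @return a character matrix, taxa in rows; attribute `n_genes` records the
#'   block structure.
#' @export
simulate_dstat_alignment <- function(species, n_genes, sites_per_gene,
                                     subst_scale = 0.05, edges = NULL,
                                     seed = NULL, default_tip_len = 2) {
  .with_seed(seed, {
    gts <- if (is.null(edges))
      simulate_msc_gene_trees(species, n_genes,
                              default_tip_len = default_tip_len)
    else simulate_network_gene_trees(species, edges, n_genes,
                                     default_tip_len = default_tip_len)
    taxa <- species$tip.label
    blocks <- lapply(gts$trees, function(tr) {
      tr$edge.length <- tr$edge.length * subst_scale
      aln <- simulate_alignment(tr, sites_per_gene)
      aln[taxa, , drop = FALSE]
    })
    out <- do.call(cbind, blocks)
    rownames(out) <- taxa
    attr(out, "n_genes") <- n_genes
    out
  })
}

#' Draw Ks values from a log-normal mixture, truncated to a window
#'
#' Components are parameterized by their back-transformed medians: draws are
#' `exp(rnorm(log(means[i]), sds[i]))` for a component picked by `weights`,
#' redrawn until they fall inside `window` (the conventional Ks plotting
#' window excludes near-zero allelic noise and saturated pairs).
#'
#' @param means component medians on the Ks scale (> 0).
#' @param sds component standard deviations on the log scale (> 0).
#' @param weights mixture weights, summing to 1.
#' @param n sample size.
#' @param seed optional integer seed.
#' @param window truncation window on the Ks scale.
#' @return numeric vector of `n` Ks values.
#' @export
simulate_ks_mixture <- function(means, sds, weights, n, seed = NULL,
                                window = c(0.05, 3)) {
  k <- length(means)
  if (length(sds) != k || length(weights) != k)
    stop("`means`, `sds`, `weights` must have equal length", call. = FALSE)
  stopifnot(all(means > 0), all(sds > 0), abs(sum(weights) - 1) < 1e-8,
            n >= 1)
  .with_seed(seed, {
    out <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      comp <- sample.int(k, length(todo), replace = TRUE, prob = weights)
      x <- exp(rnorm(length(todo), log(means[comp]), sds[comp]))
      ok <- x >= window[1] & x <= window[2]
      out[todo[ok]] <- x[ok]
      todo <- todo[!ok]
    }
    out
  })
}
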