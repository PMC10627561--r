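# Quartet count concordance factors (qcCFs), MSC hypothesis tests with (T1)
# and without (T3) a specified species tree, simplex coordinates,
# rejected-quartet mapping, and a per-edge quadripartition concordance score.

# resolution of a 4-taxon set within one tree: 1 = q1q2|q3q4, 2 = q1q3|q2q4,
# 3 = q1q4|q2q3 for the SORTED quadruple (q1<q2<q3<q4); 0 = unresolved or
# taxa missing.  `sets` are universe-index tip sets per node; any edge with
# exactly two of the four on its tipward side fixes the resolution.
.quartet_res2 <- function(sets, internal, tipset, quad) {
  if (!all(quad %in% tipset)) return(0L)
  for (v in internal) {
    x <- sets[[v]]
    x <- x[x %in% quad]
    if (length(x) != 2L) next
    has <- quad %in% x
    if (has[1]) {
      if (has[2]) return(1L)
      if (has[3]) return(2L)
      return(3L)
    }
    if (has[2]) return(if (has[3]) 3L else 2L)
    return(1L)                             # {q3,q4}
  }
  0L
}

#' Quartet count concordance factors over a gene-tree collection
#'
#' For each taxon quadruple, counts how many gene trees display each of the
#' three possible resolutions.  Resolutions are reported in the canonical
#' order of the sorted labels `(t1,t2,t3,t4)`: `n1` = t1t2|t3t4, `n2` =
#' t1t3|t2t4, `n3` = t1t4|t2t3.  A gene tree contributes to a quadruple only
#' if it contains all four taxa.
#'
#' @param genes a list of trees or `gene_tree_set`.
#' @param quadruples `"all"` (every 4-subset of the observed taxa), a matrix
#'   or data frame with four label columns, or a list of 4-vectors.
#' @param m_sample with `quadruples = "all"`, optionally sample this many
#'   quadruples instead of enumerating.
#' @param seed seed for the optional sampling.
#' @return a data frame with columns `t1..t4`, `n1`, `n2`, `n3`, `n`.
#' @export
count_quartets <- function(genes, quadruples = "all", m_sample = NULL,
                           seed = NULL) {
  trees <- .as_gene_trees(genes)
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  if (is.character(quadruples) && identical(quadruples, "all")) {
    qm <- t(combn(taxa, 4))
    if (!is.null(m_sample) && m_sample < nrow(qm))
      qm <- .with_seed(seed, qm[sample.int(nrow(qm), m_sample), ,
                                drop = FALSE])
  } else {
    if (is.list(quadruples) && !is.data.frame(quadruples))
      quadruples <- do.call(rbind, quadruples)
    qm <- as.matrix(quadruples)
  }
  if (ncol(qm) != 4L) stop("quadruples must have four columns", call. = FALSE)
  qm <- t(apply(qm, 1, sort))
  bad <- apply(qm, 1, anyDuplicated) > 0
  if (any(bad)) stop("quadruple with fewer than 4 distinct labels",
                     call. = FALSE)
  qidx <- matrix(match(qm, taxa), ncol = 4)
  if (anyNA(qidx)) stop("quadruple taxa absent from the gene trees",
                        call. = FALSE)
  counts <- matrix(0L, nrow(qm), 3)
  for (tr in trees) {
    lt <- .lt(tr)
    sets <- .lt_tipsets(lt, taxa)
    internal <- setdiff(lt$postorder, seq_len(lt$n_tip))
    tipset <- sets[[lt$root]]
    for (r in seq_len(nrow(qm))) {
      res <- .quartet_res2(sets, internal, tipset, qidx[r, ])
      if (res > 0L) counts[r, res] <- counts[r, res] + 1L
    }
  }
  out <- data.frame(qm, counts, rowSums(counts), stringsAsFactors = FALSE)
  names(out) <- c("t1", "t2", "t3", "t4", "n1", "n2", "n3", "n")
  out
}

# log-likelihood-ratio statistic of the MSC quartet null (1-2mu, mu, mu)
# against the saturated multinomial; `counts` is an m x 3 matrix and `conc`
# the concordant class per row.
.quartet_lrt <- function(counts, conc) {
  n <- rowSums(counts)
  nc <- counts[cbind(seq_len(nrow(counts)), conc)]
  mu <- pmin((n - nc) / (2 * n), 1 / 3)
  xlx <- function(x, p) ifelse(x > 0, x * log(p), 0)
  ll_sat <- rowSums(ifelse(counts > 0, counts * log(counts / n), 0))
  ll_null <- xlx(nc, pmax(1 - 2 * mu, 1e-300)) + xlx(n - nc, mu)
  lrt <- pmax(2 * (ll_sat - ll_null), 0)
  list(lrt = lrt, mu = mu)
}

.quartet_test_one <- function(n123, conc_fixed, alpha, pvalue_method, B,
                              model) {
  n <- sum(n123)
  if (n == 0)
    return(list(mu_hat = NA_real_, lrt = NA_real_, p = NA_real_,
                model = model, rejected = NA, defined = FALSE))
  cm <- matrix(n123, 1)
  conc <- if (is.null(conc_fixed)) which.max(n123) else conc_fixed
  obs <- .quartet_lrt(cm, conc)
  if (pvalue_method == "chisq1") {
    p <- pchisq(obs$lrt, df = 1, lower.tail = FALSE)
  } else {
    probs <- rep(obs$mu, 3)
    probs[conc] <- 1 - 2 * obs$mu
    sim <- t(rmultinom(B, n, probs))
    conc_sim <- if (is.null(conc_fixed)) max.col(sim, ties.method = "first")
      else rep(conc_fixed, B)
    lrt_sim <- .quartet_lrt(sim, conc_sim)$lrt
    p <- (1 + sum(lrt_sim >= obs$lrt - 1e-9)) / (B + 1)
  }
  list(mu_hat = obs$mu, lrt = obs$lrt, p = p, model = model,
       rejected = p < alpha, defined = TRUE)
}

#' T3 quartet test: do the counts fit the MSC with no species tree given?
#'
#' Under the multispecies coalescent the three resolutions of a quadruple
#' occur with probabilities `(1-2mu, mu, mu)` for some `mu <= 1/3`, with the
#' concordant class unspecified (taken as the modal count).  The
#' likelihood-ratio statistic against the saturated multinomial is calibrated
#' by parametric bootstrap (default) or by a chi-square(1) approximation.
#'
#' @param counts a length-3 count vector `(n1,n2,n3)`, or a matrix/data frame
#'   with columns `n1`,`n2`,`n3` (e.g. from [count_quartets()]).
#' @param alpha rejection level.
#' @param pvalue_method `"bootstrap"` (parametric, `B` replicates) or
#'   `"chisq1"`.
#' @param B bootstrap replicates.
#' @param seed optional integer seed for the bootstrap.
#' @return for a single quadruple, a list with `mu_hat`, `lrt`, `p`,
#'   `rejected`; for a table, the table with those columns appended.
#' @export
t3_test <- function(counts, alpha = 0.01,
                    pvalue_method = c("bootstrap", "chisq1"), B = 2000,
                    seed = NULL) {
  pvalue_method <- match.arg(pvalue_method)
  .quartet_test_batch(counts, NULL, alpha, pvalue_method, B, seed, "T3")
}

#' T1 quartet test: do the counts fit the MSC on a known species tree?
#'
#' As [t3_test()], but the concordant class is fixed by the species tree
#' rather than taken as the modal count, so quadruples whose modal resolution
#' contradicts the species tree are rejected even when they would fit a star
#' or alternative tree.
#'
#' @inheritParams t3_test
#' @param species_resolution the concordant class (1, 2 or 3, in the
#'   canonical sorted-label order); recycled against the rows of `counts`.
#' @export
t1_test <- function(counts, species_resolution, alpha = 0.01,
                    pvalue_method = c("bootstrap", "chisq1"), B = 2000,
                    seed = NULL) {
  pvalue_method <- match.arg(pvalue_method)
  if (!all(species_resolution %in% 1:3))
    stop("`species_resolution` must be 1, 2 or 3", call. = FALSE)
  .quartet_test_batch(counts, species_resolution, alpha, pvalue_method, B,
                      seed, "T1")
}

.quartet_test_batch <- function(counts, conc, alpha, pvalue_method, B, seed,
                                model) {
  single <- is.numeric(counts) && is.null(dim(counts))
  if (single) {
    stopifnot(length(counts) == 3)
    cm <- matrix(counts, 1)
  } else {
    df <- as.data.frame(counts)
    cm <- as.matrix(df[, c("n1", "n2", "n3")])
  }
  if (!is.null(conc)) conc <- rep_len(conc, nrow(cm))
  .with_seed(seed, {
    res <- lapply(seq_len(nrow(cm)), function(i)
      .quartet_test_one(cm[i, ], if (is.null(conc)) NULL else conc[i],
                        alpha, pvalue_method, B, model))
    if (single) return(res[[1L]])
    df$mu_hat <- vapply(res, `[[`, numeric(1), "mu_hat")
    df$lrt <- vapply(res, `[[`, numeric(1), "lrt")
    df$p <- vapply(res, `[[`, numeric(1), "p")
    df$model <- model
    df$rejected <- vapply(res, `[[`, logical(1), "rejected")
    df
  })
}

#' Barycentric simplex coordinates of quartet counts
#'
#' @param counts length-3 vector or matrix/data frame with `n1`,`n2`,`n3`.
#' @return proportions `(p1,p2,p3)` summing to 1 (vector or data frame).
#' @export
simplex_coordinates <- function(counts) {
  if (is.numeric(counts) && is.null(dim(counts))) {
    n <- sum(counts)
    if (n == 0) stop("counts sum to zero", call. = FALSE)
    return(counts / n)
  }
  df <- as.data.frame(counts)
  cm <- as.matrix(df[, c("n1", "n2", "n3")])
  n <- rowSums(cm)
  if (any(n == 0)) stop("counts sum to zero", call. = FALSE)
  out <- cm / n
  colnames(out) <- c("p1", "p2", "p3")
  cbind(df, out)
}

# pairwise LCA by parent walking
.lca2r <- function(a, b, parent, depth) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
  }
  a
}

#' Map rejected quadruples onto the internal edges of the species tree
#'
#' Each rejected quadruple increments every internal species-tree edge on the
#' path that forms the internal edge of its induced quartet, so gene flow
#' (which clusters rejections around specific branches) can be told apart
#' from gene-tree estimation error (which spreads them uniformly).
#'
#' @param species rooted `phylo`.
#' @param rejected matrix/data frame with four label columns (or a list of
#'   4-vectors); typically the rejected rows of a [t1_test()]/[t3_test()]
#'   table.
#' @return data frame over internal edges (identified by the node below
#'   them): `node`, `clade` (dot-joined tips below), `count`.
#' @export
map_rejected_quartets <- function(species, rejected) {
  if (is.list(rejected) && !is.data.frame(rejected))
    rejected <- do.call(rbind, rejected)
  qm <- as.matrix(as.data.frame(rejected)[, 1:4, drop = FALSE])
  lt <- .lt(species)
  universe <- species$tip.label
  sets <- .lt_tipsets(lt, universe)
  internal <- setdiff(lt$postorder, seq_len(lt$n_tip))
  cnt <- integer(lt$n_node)
  if (nrow(qm)) {
    for (r in seq_len(nrow(qm))) {
      qi <- match(qm[r, ], universe)
      if (anyNA(qi)) stop("unknown taxon in quadruple: ",
                          paste(qm[r, ], collapse = ","), call. = FALSE)
      quad <- sort(qi)
      res <- .quartet_res2(sets, internal, sets[[lt$root]], quad)
      if (res == 0L) next
      pair1 <- switch(res, quad[c(1, 2)], quad[c(1, 3)], quad[c(1, 4)])
      pair2 <- setdiff(quad, pair1)
      j1 <- .median_node(pair1[1], pair1[2], pair2[1], lt)
      j2 <- .median_node(pair2[1], pair2[2], pair1[1], lt)
      for (v in .path_nodes(j1, j2, lt))
        cnt[v] <- cnt[v] + 1L
    }
  }
  keep <- setdiff(internal, lt$root)
  data.frame(node = keep,
             clade = vapply(sets[keep], function(s)
               paste(universe[s], collapse = "."), character(1)),
             count = cnt[keep], stringsAsFactors = FALSE)
}

# node where the paths from x and y towards z meet
.median_node <- function(x, y, z, lt) {
  l_xy <- .lca2r(x, y, lt$parent, lt$depth)
  l_xz <- .lca2r(x, z, lt$parent, lt$depth)
  l_yz <- .lca2r(y, z, lt$parent, lt$depth)
  cand <- c(l_xy, l_xz, l_yz)
  cand[which.max(lt$depth[cand])]
}

# nodes subtending the edges on the path between two nodes
.path_nodes <- function(a, b, lt) {
  l <- .lca2r(a, b, lt$parent, lt$depth)
  out <- integer(0)
  while (a != l) { out <- c(out, a); a <- lt$parent[a] }
  while (b != l) { out <- c(out, b); b <- lt$parent[b] }
  out
}

#' Per-edge quadripartition concordance score
#'
#' Every internal edge of the species tree splits the taxa into four parts
#' (A,B | C,D).  Quartets with one taxon per part are counted across the
#' gene trees and aggregated into `(q1,q2,q3)` with `q1` the resolution that
#' matches the species tree; the score is `1 + sum p_i log3 p_i` (an
#' internode-certainty-style information measure in `[-1, 1]`), negated when
#' the modal resolution differs from the reference.
#'
#' @param species rooted binary `phylo`.
#' @param genes gene-tree collection.
#' @param max_exhaustive enumerate all one-per-part quartets when their
#'   number is at most this; otherwise sample.
#' @param m_sample number of sampled quartets above `max_exhaustive`.
#' @param seed seed for the sampling.
#' @return data frame over internal edges: `node`, `clade`, `q1`, `q2`, `q3`,
#'   `score`.
#' @export
eqp_ic <- function(species, genes, max_exhaustive = 5000, m_sample = 1000,
                   seed = NULL) {
  trees <- .as_gene_trees(genes)
  lt <- .lt(species)
  universe <- species$tip.label
  sets <- .lt_tipsets(lt, universe)
  gsets <- lapply(trees, function(tr) {
    g <- .lt(tr)
    s <- .lt_tipsets(g, universe)
    list(sets = s, internal = setdiff(g$postorder, seq_len(g$n_tip)),
         tipset = s[[g$root]])
  })
  all_ix <- seq_along(universe)
  rows <- list()
  .with_seed(seed, {
    for (v in setdiff(lt$postorder, c(seq_len(lt$n_tip), lt$root))) {
      ch <- lt$children[[v]]
      if (length(ch) < 2L) next
      A <- sets[[ch[1]]]; B <- sets[[ch[2]]]
      p <- lt$parent[v]
      sibs <- setdiff(lt$children[[p]], v)
      C <- sort(unlist(sets[sibs], use.names = FALSE))
      D <- setdiff(all_ix, c(A, B, C))
      if (p == lt$root && length(D) == 0L && length(sibs) == 1L &&
          sibs > lt$n_tip) {
        # root edge: the sibling's children provide C and D, but only score
        # the unrooted edge once (from the lower-numbered child)
        if (v > sibs) next
        sch <- lt$children[[sibs]]
        C <- sets[[sch[1]]]
        D <- sort(unlist(sets[sch[-1]], use.names = FALSE))
      }
      if (!length(C) || !length(D)) next
      nn <- prod(length(A), length(B), length(C), length(D))
      combos <- if (nn <= max_exhaustive)
        as.matrix(expand.grid(A = A, B = B, C = C, D = D))
      else cbind(A = sample(A, m_sample, TRUE), B = sample(B, m_sample, TRUE),
                 C = sample(C, m_sample, TRUE), D = sample(D, m_sample, TRUE))
      q <- c(0L, 0L, 0L)
      for (r in seq_len(nrow(combos))) {
        quad <- combos[r, ]
        o <- order(quad)
        sq <- quad[o]
        # reference resolution pairs the A taxon with the B taxon
        ab <- which(o %in% 1:2)
        ref <- if (all(ab == c(1, 2)) || all(ab == c(3, 4))) 1L
          else if (all(ab == c(1, 3)) || all(ab == c(2, 4))) 2L
          else 3L
        alt <- setdiff(1:3, ref)
        for (gt in gsets) {
          res <- .quartet_res2(gt$sets, gt$internal, gt$tipset, sq)
          if (res == 0L) next
          slot <- if (res == ref) 1L else if (res == alt[1]) 2L else 3L
          q[slot] <- q[slot] + 1L
        }
      }
      tot <- sum(q)
      score <- if (tot == 0) NA_real_ else {
        pr <- q / tot
        s <- 1 + sum(ifelse(pr > 0, pr * log(pr, base = 3), 0))
        if (which.max(q) != 1L) -s else s
      }
      rows[[length(rows) + 1L]] <- data.frame(
        node = v, clade = paste(universe[sort(c(A, B))], collapse = "."),
        q1 = q[1], q2 = q[2], q3 = q[3], score = score,
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
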