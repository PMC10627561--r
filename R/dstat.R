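# ABBA-BABA D statistics over four-taxon designs, with site-bootstrap
# significance and Holm-Bonferroni correction across combinations.

#' Count ABBA and BABA site patterns
#'
#' With the outgroup state as ancestral (A) and the single alternative state
#' as derived (B): ABBA sites have (P1,P2,P3) = (A,B,B) and BABA sites
#' (B,A,B).  Sites with gaps, ambiguity codes, or more than two states among
#' the four rows are skipped; which nucleotide plays A or B is irrelevant.
#'
#' @param alignment character matrix, taxa in rows (A/C/G/T, anything else
#'   treated as missing).
#' @param p1,p2,p3,o row names of the four taxa.
#' @return integer vector `c(nABBA, nBABA)`.
#' @export
count_site_patterns <- function(alignment, p1, p2, p3, o) {
  for (tx in c(p1, p2, p3, o))
    if (!tx %in% rownames(alignment))
      stop("taxon not in alignment: ", tx, call. = FALSE)
  x1 <- alignment[p1, ]; x2 <- alignment[p2, ]
  x3 <- alignment[p3, ]; xo <- alignment[o, ]
  ok <- x1 %in% .NT & x2 %in% .NT & x3 %in% .NT & xo %in% .NT
  abba <- ok & x1 == xo & x2 != xo & x3 == x2
  baba <- ok & x2 == xo & x1 != xo & x3 == x1
  c(nABBA = sum(abba), nBABA = sum(baba))
}

#' The D statistic
#'
#' @param nABBA,nBABA pattern counts.
#' @return `(nABBA - nBABA) / (nABBA + nBABA)`, or `NA` with a warning when
#'   the denominator is zero.
#' @export
d_statistic <- function(nABBA, nBABA) {
  if (nABBA + nBABA == 0) {
    warning("no ABBA or BABA sites; D undefined")
    return(NA_real_)
  }
  (nABBA - nBABA) / (nABBA + nBABA)
}

#' Bootstrap D statistic for one four-taxon combination
#'
#' Resamples alignment columns (in contiguous blocks of `block` sites) with
#' replacement, takes the standard deviation of the bootstrap D distribution,
#' and reports `Z = D/SD` with a two-tailed normal p-value.
#'
#' @inheritParams count_site_patterns
#' @param n_boot bootstrap replicates (>= 2).
#' @param block resampling block width in sites (1 = single sites).
#' @param seed optional integer seed.
#' @return a list of class `dstat_result`: taxa, `nABBA`, `nBABA`, `D`,
#'   `sd`, `Z`, `p`, `defined`.  A degenerate bootstrap (SD 0 with D != 0)
#'   yields `Z = Inf`, `p = 0`.
#' @export
bootstrap_z <- function(alignment, p1, p2, p3, o, n_boot = 200, block = 1,
                        seed = NULL) {
  stopifnot(n_boot >= 2, block >= 1)
  cnt <- count_site_patterns(alignment, p1, p2, p3, o)
  res <- list(p1 = p1, p2 = p2, p3 = p3, o = o,
              nABBA = cnt[["nABBA"]], nBABA = cnt[["nBABA"]],
              D = NA_real_, sd = NA_real_, Z = NA_real_, p = NA_real_,
              defined = FALSE)
  class(res) <- "dstat_result"
  if (sum(cnt) == 0) return(res)
  D <- (cnt[["nABBA"]] - cnt[["nBABA"]]) / sum(cnt)
  L <- ncol(alignment)
  x1 <- alignment[p1, ]; x2 <- alignment[p2, ]
  x3 <- alignment[p3, ]; xo <- alignment[o, ]
  ok <- x1 %in% .NT & x2 %in% .NT & x3 %in% .NT & xo %in% .NT
  abba <- ok & x1 == xo & x2 != xo & x3 == x2
  baba <- ok & x2 == xo & x1 != xo & x3 == x1
  boot <- .with_seed(seed, {
    if (block == 1) {
      nA <- sum(abba); nB <- sum(baba)
      m <- rmultinom(n_boot, L, c(nA, nB, L - nA - nB) / L)
      (m[1, ] - m[2, ]) / (m[1, ] + m[2, ])
    } else {
      nb <- ceiling(L / block)
      grp <- rep(seq_len(nb), each = block, length.out = L)
      a_blk <- tapply(abba, grp, sum)
      b_blk <- tapply(baba, grp, sum)
      idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
      A <- colSums(matrix(a_blk[idx], nrow = nb))
      B <- colSums(matrix(b_blk[idx], nrow = nb))
      (A - B) / (A + B)
    }
  })
  s <- sd(boot, na.rm = TRUE)
  if (is.na(s)) return(res)
  res$D <- D
  res$sd <- s
  res$defined <- TRUE
  if (s == 0) {
    res$Z <- if (D == 0) 0 else sign(D) * Inf
    res$p <- if (D == 0) 1 else 0
  } else {
    res$Z <- D / s
    res$p <- 2 * pnorm(abs(res$Z), lower.tail = FALSE)
  }
  res
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf(
    "D[(((%s,%s),%s),%s)]: ABBA=%d BABA=%d D=%.4f sd=%.4f Z=%.2f p=%.3g\n",
    x$p1, x$p2, x$p3, x$o, x$nABBA, x$nBABA, x$D, x$sd, x$Z, x$p))
  invisible(x)
}

#' Holm-Bonferroni adjusted p-values
#'
#' Step-down adjustment: with the p-values sorted ascending,
#' `adj(i) = min(1, max_{j <= i} (m - j + 1) p_(j))`, returned in the
#' original order (via [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
holm_bonferroni <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "holm")
}

#' Run a full four-taxon D-statistic design
#'
#' Enumerates the Cartesian product of the taxa in the P1, P2, P3 and O
#' groups, bootstraps each combination, applies Holm-Bonferroni across all
#' combinations of the design, and summarizes the fraction of combinations
#' with `Z > z_thresh` and adjusted `p < alpha`: more than 50% of
#' combinations significant is reported as `"significant gene flow"`, fewer
#' than 10% as `"insignificant"`, the band between as `"ambiguous"`.
#'
#' @param alignment character matrix, taxa in rows.
#' @param design data frame with columns `group` (`P1`,`P2`,`P3`,`O`) and
#'   `taxon`, or a named list of taxon vectors.
#' @param z_thresh Z cutoff.
#' @param alpha level applied to the Holm-adjusted p-values.
#' @param n_boot,block,seed bootstrap controls, see [bootstrap_z()].
#' @return list of class `dstat_design`: `results` (one row per combination:
#'   taxa, counts, `D`, `sd`, `Z`, `p`, `p_holm`, `significant`),
#'   `fraction_significant`, and `category`.
#' @export
run_design <- function(alignment, design, z_thresh = 3, alpha = 0.05,
                       n_boot = 200, block = 1, seed = NULL) {
  if (is.data.frame(design)) {
    groups <- split(design$taxon, design$group)
  } else groups <- design
  need <- c("P1", "P2", "P3", "O")
  if (!all(need %in% names(groups)) ||
      any(!lengths(groups[need])))
    stop("design must provide non-empty groups P1, P2, P3, O", call. = FALSE)
  if (anyDuplicated(unlist(groups[need])))
    stop("design groups must be pairwise disjoint", call. = FALSE)
  combos <- expand.grid(p1 = groups$P1, p2 = groups$P2, p3 = groups$P3,
                        o = groups$O, stringsAsFactors = FALSE)
  rows <- .with_seed(seed, lapply(seq_len(nrow(combos)), function(i) {
    r <- bootstrap_z(alignment, combos$p1[i], combos$p2[i], combos$p3[i],
                     combos$o[i], n_boot = n_boot, block = block)
    data.frame(p1 = r$p1, p2 = r$p2, p3 = r$p3, o = r$o, nABBA = r$nABBA,
               nBABA = r$nBABA, D = r$D, sd = r$sd, Z = r$Z, p = r$p,
               stringsAsFactors = FALSE)
  }))
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p)
  res$p_holm <- NA_real_
  res$p_holm[ok] <- holm_bonferroni(res$p[ok])
  res$significant <- !is.na(res$Z) & res$Z > z_thresh &
    !is.na(res$p_holm) & res$p_holm < alpha
  frac <- mean(res$significant)
  category <- if (frac > 0.5) "significant gene flow"
    else if (frac < 0.1) "insignificant" else "ambiguous"
  structure(list(results = res, fraction_significant = frac,
                 category = category, z_thresh = z_thresh, alpha = alpha),
            class = "dstat_design")
}

#' @export
print.dstat_design <- function(x, ...) {
  cat(sprintf(
    "D-statistic design: %d combinations, %.0f%% significant (Z > %g and Holm p < %g) -> %s\n",
    nrow(x$results), 100 * x$fraction_significant, x$z_thresh, x$alpha,
    x$category))
  invisible(x)
}
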