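# Nei-Gojobori (1986) synonymous/nonsynonymous counting with Jukes-Cantor
# correction, plus the codon-pair simulator used to validate it.

.NT <- c("T", "C", "A", "G")

# standard genetic code, codons ordered base1/base2/base3 each in TCAG
.GC_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]
.GC_CODON <- as.vector(t(outer(
  as.vector(t(outer(.NT, .NT, paste0))), .NT, paste0)))
.GENETIC_CODE <- setNames(.GC_AA, .GC_CODON)
.SENSE_CODONS <- .GC_CODON[.GC_AA != "*"]

.ng86_cache <- new.env(parent = emptyenv())

# all nine single-nucleotide neighbours of a codon, with change class:
# "syn", "nonsyn", or "stop" (mutation creating a stop codon)
.codon_changes <- function(codon) {
  key <- paste0("chg:", codon)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  aa <- .GENETIC_CODE[[codon]]
  base <- strsplit(codon, "")[[1]]
  tgt <- character(9); cls <- character(9); k <- 0L
  for (pos in 1:3) for (nt in .NT) {
    if (nt == base[pos]) next
    k <- k + 1L
    b2 <- base; b2[pos] <- nt
    t2 <- paste(b2, collapse = "")
    tgt[k] <- t2
    aa2 <- .GENETIC_CODE[[t2]]
    cls[k] <- if (aa2 == "*") "stop" else if (aa2 == aa) "syn" else "nonsyn"
  }
  res <- list(target = tgt, class = cls, pos = rep(1:3, each = 3))
  .ng86_cache[[key]] <- res
  res
}

# NG86 synonymous site count of one codon: per position, a third of a site
# for every synonymous single-nucleotide change; stop-creating changes count
# as nonsynonymous.
.syn_sites <- function(codon) {
  key <- paste0("S:", codon)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  ch <- .codon_changes(codon)
  s <- sum(ch$class == "syn") / 3
  .ng86_cache[[key]] <- s
  s
}

# synonymous/nonsynonymous difference counts between two codons, averaging
# over all minimal substitution pathways; pathways passing through a stop
# codon get weight zero (unless every pathway does, in which case all
# pathways are averaged).
.ng86_pair <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste(c1, c2, sep = "|")
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  dif <- which(b1 != b2)
  paths <- if (length(dif) == 1L) list(dif) else
    lapply(seq_len(ncol(p <- .permutations(dif))), function(j) p[, j])
  acc <- matrix(0, nrow = length(paths), ncol = 2)
  ok <- logical(length(paths))
  for (i in seq_along(paths)) {
    cur <- b1
    sd <- nd <- 0
    viable <- TRUE
    for (pos in paths[[i]]) {
      from <- paste(cur, collapse = "")
      cur[pos] <- b2[pos]
      to <- paste(cur, collapse = "")
      if (.GENETIC_CODE[[to]] == "*" && to != c2) viable <- FALSE
      if (.GENETIC_CODE[[from]] == .GENETIC_CODE[[to]]) sd <- sd + 1
      else nd <- nd + 1
    }
    acc[i, ] <- c(sd, nd)
    ok[i] <- viable
  }
  use <- if (any(ok)) ok else rep(TRUE, length(paths))
  res <- c(sd = mean(acc[use, 1]), nd = mean(acc[use, 2]))
  .ng86_cache[[key]] <- res
  res
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    sub <- .permutations(x[-i])
    out <- cbind(out, rbind(rep(x[i], ncol(sub)), sub))
  }
  out
}

.split_codons <- function(s) {
  s <- toupper(gsub("[ \t\n]", "", s))
  if (nchar(s) %% 3 != 0)
    stop("sequence length not divisible by 3", call. = FALSE)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

#' NG86 pairwise Ks/Ka estimate
#'
#' Nei-Gojobori (1986) counting of synonymous (S) and nonsynonymous (N) sites
#' and differences between two codon-aligned, gap-free coding sequences, with
#' the Jukes-Cantor correction `K = -(3/4) log(1 - (4/3) p)`.  Multi-hit
#' codons are resolved by averaging over all minimal substitution pathways;
#' pathways through a stop codon get zero weight and mutations that would
#' create stops count as nonsynonymous in the site counts.
#'
#' @param seq1,seq2 coding sequences (strings), equal length, divisible by 3.
#'   Codon pairs containing characters outside ACGT are skipped.
#' @return a list of class `ks_estimate`: `codons_used`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, and logical `ks_defined` / `ka_defined`
#'   (the Jukes-Cantor correction is undefined at `p >= 3/4`).
#' @export
ng86_ks <- function(seq1, seq2) {
  cd1 <- .split_codons(seq1)
  cd2 <- .split_codons(seq2)
  if (length(cd1) != length(cd2))
    stop("sequences differ in length", call. = FALSE)
  keep <- grepl("^[ACGT]{3}$", cd1) & grepl("^[ACGT]{3}$", cd2) &
    .GENETIC_CODE[cd1] != "*" & .GENETIC_CODE[cd2] != "*"
  cd1 <- cd1[keep]; cd2 <- cd2[keep]
  if (!length(cd1)) stop("no usable codons", call. = FALSE)
  S <- (sum(vapply(cd1, .syn_sites, numeric(1))) +
        sum(vapply(cd2, .syn_sites, numeric(1)))) / 2
  N <- 3 * length(cd1) - S
  sdnd <- vapply(seq_along(cd1),
                 function(i) .ng86_pair(cd1[i], cd2[i]), numeric(2))
  Sd <- sum(sdnd[1, ]); Nd <- sum(sdnd[2, ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  out <- list(codons_used = length(cd1), S = S, N = N, Sd = Sd, Nd = Nd,
              pS = pS, pN = pN,
              Ks = if (pS < 0.75) jc(pS) else NA_real_,
              Ka = if (pN < 0.75) jc(pN) else NA_real_,
              ks_defined = pS < 0.75, ka_defined = pN < 0.75)
  class(out) <- "ks_estimate"
  out
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("NG86: %d codons; S=%.2f N=%.2f Sd=%.2f Nd=%.2f; Ks=%s Ka=%s\n",
              x$codons_used, x$S, x$N, x$Sd, x$Nd,
              if (x$ks_defined) sprintf("%.4f", x$Ks) else "undefined",
              if (x$ka_defined) sprintf("%.4f", x$Ka) else "undefined"))
  invisible(x)
}

#' Simulate a diverged codon-sequence pair with known substitution truth
#'
#' Draws a random stop-free ancestral sequence and evolves a copy by a
#' Gillespie process in which each synonymous single-nucleotide change fires
#' at rate `ks_true/3` and each nonsynonymous change at `ka_true/3` per unit
#' time (NG86 site definitions), over one time unit, so the expected number
#' of synonymous events per synonymous site is `ks_true` (before the
#' Jukes-Cantor correction collapses multiple hits).  Changes that would
#' create a stop codon have rate zero, so no stop codons are ever emitted.
#'
#' @param ks_true expected synonymous events per synonymous site (>= 0).
#' @param ka_true expected nonsynonymous events per nonsynonymous site.
#' @param n_codons number of codons (>= 50).
#' @param seed optional integer seed.
#' @param ancestor optional ancestral coding sequence (stop-free, length
#'   `3 * n_codons`) to evolve from instead of a random draw — useful for
#'   building orthogroups where several pairs share one ancestor.
#' @return character vector of the two sequences (`ancestor`, `derived`),
#'   with attribute `truth` = named vector of realized `syn_events` and
#'   `nonsyn_events`.
#' @export
simulate_codon_pairs <- function(ks_true, ka_true = 0, n_codons = 500,
                                 seed = NULL, ancestor = NULL) {
  stopifnot(ks_true >= 0, ka_true >= 0)
  if (!is.null(ancestor)) {
    anc0 <- .split_codons(ancestor)
    n_codons <- length(anc0)
  }
  if (n_codons < 50) stop("`n_codons` must be >= 50", call. = FALSE)
  if (0.75 * (1 - exp(-4 * ks_true / 3)) > 0.70)
    warning("ks_true deep in saturation: the NG86 estimate will be ",
            "undefined for some replicates")
  .with_seed(seed, {
    anc <- if (is.null(ancestor))
      sample(.SENSE_CODONS, n_codons, replace = TRUE) else anc0
    der <- anc
    syn_ev <- nonsyn_ev <- 0L
    for (i in seq_len(n_codons)) {
      t <- 0
      repeat {
        ch <- .codon_changes(der[i])
        rate <- ifelse(ch$class == "syn", ks_true / 3,
                       ifelse(ch$class == "nonsyn", ka_true / 3, 0))
        R <- sum(rate)
        if (R <= 0) break
        t <- t + rexp(1, R)
        if (t > 1) break
        j <- sample.int(9L, 1L, prob = rate)
        if (ch$class[j] == "syn") syn_ev <- syn_ev + 1L
        else nonsyn_ev <- nonsyn_ev + 1L
        der[i] <- ch$target[j]
      }
    }
    out <- c(ancestor = paste(anc, collapse = ""),
             derived = paste(der, collapse = ""))
    attr(out, "truth") <- c(syn_events = syn_ev, nonsyn_events = nonsyn_ev)
    out
  })
}
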