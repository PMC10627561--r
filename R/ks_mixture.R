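# Ks pair tables, Gaussian mixture fitting on log-Ks with BIC model choice,
# and the within-orthogroup paralog-vs-ortholog comparison.

#' Ks estimates for all paralog or ortholog pairs of a set of orthogroups
#'
#' @param orthogroups named list; each element is a named character vector of
#'   codon-aligned coding sequences (names are gene-copy labels).
#' @param pair_type `"paralog"` (pairs within one species) or `"ortholog"`
#'   (pairs between the two species of `species_pair`).
#' @param map optional taxon map; defaults to `species@k` labels.
#' @param species_pair length-2 character vector, required for orthologs.
#' @param window keep pairs with Ks inside this window (the conventional
#'   plotting window that drops allelic noise and saturated pairs); `NULL`
#'   keeps everything.
#' @return data frame: `orthogroup`, `copy1`, `copy2`, `species1`,
#'   `species2`, `type`, `Ks`, `Ka`.  Attributes `n_undefined` and
#'   `n_outside` count excluded pairs.
#' @export
build_ks_table <- function(orthogroups, pair_type = c("paralog", "ortholog"),
                           map = NULL, species_pair = NULL,
                           window = c(0.05, 3)) {
  pair_type <- match.arg(pair_type)
  if (pair_type == "ortholog" &&
      (is.null(species_pair) || length(species_pair) != 2))
    stop("`species_pair` (two species) is required for ortholog pairs",
         call. = FALSE)
  if (is.null(names(orthogroups)))
    names(orthogroups) <- sprintf("og%04d", seq_along(orthogroups))
  rows <- list()
  n_undef <- n_out <- 0L
  for (og in names(orthogroups)) {
    seqs <- orthogroups[[og]]
    sp <- .tip_species(names(seqs), map)
    pairs <- NULL
    if (pair_type == "paralog") {
      for (s in unique(sp)) {
        ix <- which(sp == s)
        if (length(ix) >= 2) pairs <- cbind(pairs, combn(ix, 2))
      }
    } else {
      i1 <- which(sp == species_pair[1])
      i2 <- which(sp == species_pair[2])
      if (length(i1) && length(i2))
        pairs <- t(as.matrix(expand.grid(i1, i2)))
    }
    if (is.null(pairs)) next
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      est <- ng86_ks(seqs[[i]], seqs[[j]])
      if (!est$ks_defined) { n_undef <- n_undef + 1L; next }
      if (!is.null(window) &&
          (est$Ks < window[1] || est$Ks > window[2])) {
        n_out <- n_out + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = og, copy1 = names(seqs)[i], copy2 = names(seqs)[j],
        species1 = sp[i], species2 = sp[j], type = pair_type,
        Ks = est$Ks, Ka = est$Ka, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup = character(0), copy1 = character(0),
               copy2 = character(0), species1 = character(0),
               species2 = character(0), type = character(0),
               Ks = numeric(0), Ka = numeric(0), stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- n_undef
  attr(out, "n_outside") <- n_out
  out
}

#' Fit a Gaussian mixture to log-Ks and pick the component count by BIC
#'
#' Unequal-variance univariate Gaussian mixtures are fitted to `log(ks)` for
#' every `k` in `k_range` (EM via [mclust::Mclust()]); `BIC(k) = -2 LL +
#' (3k - 1) log n` and the selected `k` minimizes it.  Component "peaks" are
#' reported as the back-transformed medians `exp(mean)`.
#'
#' @param ks positive Ks values; `n >= 10 * max(k_range)` required.
#' @param k_range candidate component counts.
#' @param seed,n_restarts kept for interface stability; the EM initialization
#'   used here is deterministic.
#' @return list of class `ks_mixture_fit`: `k` (selected), `means`/`sds`/
#'   `weights` on the log scale, `modes` (back-transformed medians), `bic`
#'   (named vector over `k_range`), `loglik`, `n`, `model` (the fitted
#'   mclust object for posterior queries).
#' @export
fit_gmm <- function(ks, k_range = 1:5, seed = NULL, n_restarts = 10) {
  ks <- ks[is.finite(ks) & ks > 0]
  n <- length(ks)
  if (n < 10 * max(k_range))
    stop("need at least 10 * max(k_range) = ", 10 * max(k_range),
         " Ks values, got ", n, call. = FALSE)
  x <- log(ks)
  fits <- vector("list", length(k_range))
  bic <- setNames(rep(NA_real_, length(k_range)), k_range)
  ll <- bic
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    # Mclust resolves its helpers in the caller's frame, so evaluate the
    # call inside the mclust namespace
    cl <- as.call(list(quote(Mclust), data = x, G = as.integer(k),
                       modelNames = "V", verbose = FALSE))
    f <- .with_seed(seed, tryCatch(eval(cl, asNamespace("mclust")),
                                   error = function(e) NULL))
    if (is.null(f) || is.na(f$loglik)) next
    fits[[i]] <- f
    ll[i] <- f$loglik
    bic[i] <- -2 * f$loglik + (3 * k - 1) * log(n)
  }
  if (all(is.na(bic))) stop("no mixture could be fitted", call. = FALSE)
  sel <- which.min(bic)
  f <- fits[[sel]]
  mu <- as.numeric(f$parameters$mean)
  sig <- sqrt(as.numeric(f$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, length(mu))
  w <- as.numeric(f$parameters$pro)
  ord <- order(mu)
  structure(list(k = k_range[sel], means = mu[ord], sds = sig[ord],
                 weights = w[ord], modes = exp(mu[ord]), bic = bic,
                 loglik = ll, n = n, component_order = ord, model = f),
            class = "ks_mixture_fit")
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat(sprintf("log-Ks Gaussian mixture: k = %d selected by BIC (n = %d)\n",
              x$k, x$n))
  for (i in seq_len(x$k))
    cat(sprintf("  peak %d: Ks ~ %.3f (log-sd %.3f, weight %.2f)\n",
                i, x$modes[i], x$sds[i], x$weights[i]))
  invisible(x)
}

#' Posterior component memberships under a fitted Ks mixture
#'
#' @param fit a [fit_gmm()] result.
#' @param ks Ks values to classify.
#' @return matrix of posterior probabilities, columns ordered like
#'   `fit$modes` (ascending peak).
#' @export
ks_posteriors <- function(fit, ks) {
  z <- predict(fit$model, newdata = log(ks))$z
  z[, fit$component_order, drop = FALSE]
}

#' Compare paralog and ortholog Ks within shared orthogroups
#'
#' Restricts both tables to the orthogroups present in each, isolates the
#' focal mixture component of each class (pairs with posterior membership of
#' at least `posterior_min`), and compares the two Ks samples by a Welch
#' unpaired t-test.
#'
#' @param paralog_table,ortholog_table [build_ks_table()] results.
#' @param posterior_min posterior membership threshold for component
#'   isolation.
#' @param paralog_component,ortholog_component component index (ascending
#'   peak order) to isolate; default the heaviest-weight component.
#' @param k_range mixture sizes tried per class.
#' @param seed passed to [fit_gmm()].
#' @return list of class `ks_compare`: per-class `n`, `mean`, `var`, the
#'   isolated `peak`, Welch `t`, `df`, `p`, `direction`
#'   (`"paralogs older"`/`"paralogs younger"`), `defined`.
#' @export
within_orthogroup_compare <- function(paralog_table, ortholog_table,
                                      posterior_min = 0.95,
                                      paralog_component = NULL,
                                      ortholog_component = NULL,
                                      k_range = 1:3, seed = NULL) {
  shared <- intersect(paralog_table$orthogroup, ortholog_table$orthogroup)
  par <- paralog_table[paralog_table$orthogroup %in% shared, ]
  ort <- ortholog_table[ortholog_table$orthogroup %in% shared, ]
  iso <- function(tab, comp) {
    if (nrow(tab) < 10 * max(k_range)) return(list(ks = tab$Ks, peak = NA))
    fit <- fit_gmm(tab$Ks, k_range = k_range, seed = seed)
    if (is.null(comp)) comp <- which.max(fit$weights)
    z <- ks_posteriors(fit, tab$Ks)
    list(ks = tab$Ks[z[, comp] >= posterior_min], peak = fit$modes[comp])
  }
  pk <- iso(par, paralog_component)
  ok <- iso(ort, ortholog_component)
  if (length(pk$ks) < 2 || length(ok$ks) < 2)
    return(structure(list(defined = FALSE, n_paralog = length(pk$ks),
                          n_ortholog = length(ok$ks)),
                     class = "ks_compare"))
  tt <- t.test(pk$ks, ok$ks, var.equal = FALSE)
  structure(list(
    defined = TRUE, n_paralog = length(pk$ks), n_ortholog = length(ok$ks),
    mean_paralog = mean(pk$ks), var_paralog = stats::var(pk$ks),
    mean_ortholog = mean(ok$ks), var_ortholog = stats::var(ok$ks),
    peak_paralog = pk$peak, peak_ortholog = ok$peak,
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    direction = if (mean(pk$ks) > mean(ok$ks)) "paralogs older"
      else "paralogs younger"),
    class = "ks_compare")
}

#' @export
print.ks_compare <- function(x, ...) {
  if (!x$defined) {
    cat("Ks comparison undefined: a class is empty after isolation\n")
    return(invisible(x))
  }
  cat(sprintf(
    "paralog Ks %.3f (n=%d) vs ortholog Ks %.3f (n=%d): Welch t=%.2f, p=%.3g (%s)\n",
    x$mean_paralog, x$n_paralog, x$mean_ortholog, x$n_ortholog, x$t, x$p,
    x$direction))
  invisible(x)
}
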