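# Within-population diversity, Hardy-Weinberg and temporal-change statistics.

#' Observed and expected heterozygosity per group and locus
#'
#' For each group and locus (complete-case per locus): reference-allele
#' frequency p, expected heterozygosity \eqn{H_E = 1 - p^2 - (1-p)^2},
#' the unbiased estimate \eqn{uH_E = 2n/(2n-1) H_E} (n typed individuals),
#' observed heterozygosity \eqn{H_O} (fraction heterozygous among typed)
#' and the number of alleles observed \eqn{A_n}.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Grouping variable or vector (see
#'   \code{\link{allele_frequencies}}).
#' @return A data.frame of class \code{diversity_table} with columns
#'   \code{pop, locus, n_typed, p, H_E, uH_E, H_O, A_n}. Multi-locus means
#'   are available via \code{summary()}.
#' @export
heterozygosity <- function(gm, group = "pop") {
  g <- resolve_group(gm, group)
  groups <- unique(g)
  d <- gm$dosage
  out <- lapply(groups, function(gr) {
    sub <- d[g == gr, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    he <- 1 - p^2 - (1 - p)^2
    uhe <- ifelse(n > 0, 2 * n / (2 * n - 1) * he, NA_real_)
    ho <- ifelse(n > 0, colSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
    an <- ifelse(n > 0, (colSums(sub > 0L, na.rm = TRUE) > 0) +
                        (colSums(sub < 2L, na.rm = TRUE) > 0), NA_real_)
    data.frame(pop = gr, locus = colnames(d), n_typed = n, p = p,
               H_E = he, uH_E = uhe, H_O = ho, A_n = an,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("diversity_table", class(res))
  res
}

#' @export
summary.diversity_table <- function(object, ...) {
  sp <- split(as.data.frame(object), object$pop)
  res <- do.call(rbind, lapply(sp, function(x) {
    ok <- x$n_typed > 0
    data.frame(pop = x$pop[1],
               n_loci = sum(ok),
               H_E = mean(x$H_E[ok]), uH_E = mean(x$uH_E[ok]),
               H_O = mean(x$H_O[ok]), A_n = mean(x$A_n[ok]),
               stringsAsFactors = FALSE)
  }))
  res[match(unique(object$pop), res$pop), , drop = FALSE]
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction to a standard number of gene copies g:
#' \deqn{A_R = \sum_i [1 - C(2N - N_i, g) / C(2N, g)]}
#' where \eqn{N_i} is the copy count of allele i and 2N the typed copies.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Grouping variable or vector.
#' @param g Rarefaction size in gene copies. Default: the smallest typed
#'   copy count over all groups and loci (the convention of rarefaction to
#'   the least-sampled comparison unit).
#' @return Data.frame with columns \code{pop, locus, g, A_R}; \code{A_R} is
#'   NA where fewer than \code{g} copies were typed.
#' @export
allelic_richness <- function(gm, group = "pop", g = NULL) {
  aft <- allele_frequencies(gm, group)
  copies <- aft$copies
  if (is.null(g)) {
    pos <- copies[copies > 0]
    if (length(pos) == 0L) stop("no typed gene copies")
    g <- min(pos)
  }
  if (g < 1) stop("g must be >= 1")
  ref <- round(aft$freq * copies)
  out <- expand.grid(pop = rownames(copies), locus = colnames(copies),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$g <- g
  ar <- matrix(NA_real_, nrow(copies), ncol(copies))
  for (i in seq_len(nrow(copies))) for (l in seq_len(ncol(copies))) {
    N2 <- copies[i, l]
    if (N2 < g) next
    counts <- c(ref[i, l], N2 - ref[i, l])
    ar[i, l] <- sum(1 - exp(lchoose(N2 - counts, g) - lchoose(N2, g)))
  }
  out$A_R <- as.vector(ar)  # expand.grid varies pop fastest, matching as.vector
  out
}

## -------------------------------------------------------------------- FIS

# Weir-Cockerham variance components b (among individuals within sample) and
# c (within individuals) for a single sample, per locus, from dosage matrix.
wc_bc_single <- function(sub) {
  n <- colSums(!is.na(sub))
  p <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
  ok <- n >= 2
  b <- ifelse(ok, n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h),
              NA_real_)
  c_ <- h / 2
  list(b = b, c = c_, n = n, p = p, h = h, ok = ok)
}

#' Weir-Cockerham inbreeding coefficient f (F_IS) within samples
#'
#' Per-locus and multi-locus small f from variance components; the
#' multi-locus estimate is the ratio of summed components. Significance is
#' assessed by permuting gene copies among individuals within the sample
#' (separately at each locus), which enforces Hardy-Weinberg proportions
#' while preserving allele frequencies; the two-sided p-value compares
#' |f| of permuted data sets with the observed |f|.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Grouping variable or vector.
#' @param n_perm Number of permutations for the significance test
#'   (0 = no test). Use >= 10000 for production calls.
#' @param seed Optional RNG seed for the permutation test.
#' @return A list of class \code{fis_result} with \code{per_locus}
#'   (data.frame pop, locus, f), \code{multilocus} (data.frame pop, f,
#'   p_value).
#' @export
fis <- function(gm, group = "pop", n_perm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- resolve_group(gm, group)
  groups <- unique(g)
  per <- list(); multi <- list()
  for (gr in groups) {
    sub <- gm$dosage[g == gr, , drop = FALSE]
    cmp <- wc_bc_single(sub)
    use <- cmp$ok & !is.na(cmp$b) & (cmp$b + cmp$c) != 0
    f_loc <- ifelse(use, 1 - cmp$c / (cmp$b + cmp$c), NA_real_)
    denom <- sum(cmp$b[use] + cmp$c[use])
    if (!any(use) || denom == 0) {
      f_ml <- NA_real_
    } else {
      f_ml <- 1 - sum(cmp$c[use]) / denom
    }
    p_val <- NA_real_
    if (n_perm > 0 && !is.na(f_ml)) {
      f_perm <- replicate(n_perm, {
        perm <- permute_gene_copies(sub)
        pc <- wc_bc_single(perm)
        u <- pc$ok & !is.na(pc$b) & (pc$b + pc$c) != 0
        dn <- sum(pc$b[u] + pc$c[u])
        if (!any(u) || dn == 0) NA_real_ else 1 - sum(pc$c[u]) / dn
      })
      f_perm <- f_perm[!is.na(f_perm)]
      p_val <- (1 + sum(abs(f_perm) >= abs(f_ml))) / (length(f_perm) + 1)
    }
    per[[gr]] <- data.frame(pop = gr, locus = colnames(sub), f = f_loc,
                            row.names = NULL, stringsAsFactors = FALSE)
    multi[[gr]] <- data.frame(pop = gr, f = f_ml, p_value = p_val,
                              stringsAsFactors = FALSE)
  }
  structure(list(per_locus = do.call(rbind, per),
                 multilocus = do.call(rbind, multi)),
            class = "fis_result")
}

# Shuffle the 2n gene copies at each locus independently and re-pair them
# into diploid genotypes (HWE null preserving allele frequencies).
permute_gene_copies <- function(sub) {
  out <- sub
  for (l in seq_len(ncol(sub))) {
    x <- sub[, l]
    typed <- which(!is.na(x))
    if (length(typed) < 2L) next
    copies <- c(rep(1L, sum(x[typed])), rep(0L, 2L * length(typed) - sum(x[typed])))
    copies <- sample(copies)
    out[typed, l] <- copies[seq_along(typed)] +
      copies[seq_along(typed) + length(typed)]
  }
  out
}

## -------------------------------------------------------------- HWE exact

#' Exact test of Hardy-Weinberg proportions (biallelic)
#'
#' Conditional on the observed allele counts, enumerates all heterozygote
#' counts of matching parity and sums the probabilities of configurations no
#' more probable than the observed one (two-sided exact test). Per-group
#' overall p-values combine loci with Fisher's method.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Grouping variable or vector.
#' @return A list of class \code{hwe_result} with \code{per_locus}
#'   (pop, locus, p_value; monomorphic loci have p = 1) and \code{overall}
#'   (pop, chisq, df, p_value by Fisher's combination).
#' @export
hwe_exact <- function(gm, group = "pop") {
  g <- resolve_group(gm, group)
  groups <- unique(g)
  per <- list(); overall <- list()
  for (gr in groups) {
    sub <- gm$dosage[g == gr, , drop = FALSE]
    p <- vapply(seq_len(ncol(sub)), function(l) {
      x <- sub[, l]; x <- x[!is.na(x)]
      if (length(x) == 0L) return(NA_real_)
      hwe_exact_p(sum(x == 2L), sum(x == 1L), sum(x == 0L))
    }, numeric(1))
    ok <- !is.na(p)
    chisq <- -2 * sum(log(p[ok]))
    df <- 2 * sum(ok)
    per[[gr]] <- data.frame(pop = gr, locus = colnames(sub), p_value = p,
                            row.names = NULL, stringsAsFactors = FALSE)
    overall[[gr]] <- data.frame(pop = gr, chisq = chisq, df = df,
                                p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                                stringsAsFactors = FALSE)
  }
  structure(list(per_locus = do.call(rbind, per),
                 overall = do.call(rbind, overall)),
            class = "hwe_result")
}

#' Exact Hardy-Weinberg p-value from genotype counts
#'
#' @param n_aa Count of reference-homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of alternate-homozygotes.
#' @return Two-sided exact p-value (1 for monomorphic samples).
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2L * n_aa + n_ab
  nB <- 2L * n - nA
  if (nA == 0L || nB == 0L) return(1)
  hets <- seq(nA %% 2L, min(nA, nB), by = 2L)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

## ------------------------------------------------------ paired change test

#' Locus-paired test of temporal change in a diversity measure
#'
#' Compares per-locus values of a diversity measure at two time points with
#' the Wilcoxon matched-pairs signed-rank test (primary; zero differences
#' dropped, exact for <= 25 informative pairs, else normal approximation
#' with continuity correction) and the paired Student t test (reported
#' alongside).
#'
#' @param before,after Numeric vectors of per-locus values in the same locus
#'   order (length >= 5).
#' @param measure Label for the measure being compared.
#' @param alpha Significance level for the significance flag.
#' @return A list of class \code{paired_change} with elements
#'   \code{measure, n, mean_before, mean_after, p_wilcoxon, p_t, direction}
#'   (\code{increase}/\code{decrease}/\code{none}) and \code{significant}
#'   (Wilcoxon p < alpha).
#' @export
paired_change_test <- function(before, after, measure = "H_E", alpha = 0.05) {
  if (length(before) != length(after)) stop("before/after length mismatch")
  ok <- !is.na(before) & !is.na(after)
  before <- before[ok]; after <- after[ok]
  if (length(before) < 5L) stop("need at least 5 paired loci")
  d <- after - before
  nz <- sum(d != 0)
  if (nz == 0L) {
    p_w <- 1; p_t <- 1
  } else {
    w <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                             exact = nz <= 25, correct = TRUE))
    p_w <- w$p.value
    # an identical shift at every locus degenerates the t statistic; that is
    # maximal evidence of change, not absence of it
    p_t <- tryCatch(stats::t.test(after, before, paired = TRUE)$p.value,
                    error = function(e) 0)
  }
  md <- mean(d)
  direction <- if (md > 0) "increase" else if (md < 0) "decrease" else "none"
  structure(list(measure = measure, n = length(before),
                 mean_before = mean(before), mean_after = mean(after),
                 p_wilcoxon = p_w, p_t = p_t, direction = direction,
                 significant = p_w < alpha),
            class = "paired_change")
}
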