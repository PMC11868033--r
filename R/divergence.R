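# Between-population structure: Weir-Cockerham F-statistics, Nei's Da
# distance and bootstrapped neighbor-joining trees.

# Per-locus Weir-Cockerham (1984) variance components a, b, c for the
# reference allele, from a dosage matrix and a group factor. For biallelic
# loci the alternate allele contributes identical components, so ratios of
# sums are unaffected by using one allele. Vectorized across loci.
wc_components <- function(dosage, g) {
  groups <- unique(g)
  L <- ncol(dosage)
  G <- length(groups)
  n <- matrix(0, G, L); p <- matrix(0, G, L); h <- matrix(0, G, L)
  for (i in seq_len(G)) {
    sub <- dosage[g == groups[i], , drop = FALSE]
    ni <- colSums(!is.na(sub))
    n[i, ] <- ni
    p[i, ] <- ifelse(ni > 0, colSums(sub, na.rm = TRUE) / (2 * ni), 0)
    h[i, ] <- ifelse(ni > 0, colSums(sub == 1L, na.rm = TRUE) / ni, 0)
  }
  r <- colSums(n > 0)
  nsum <- colSums(n)
  nbar <- nsum / r
  nc <- ifelse(r > 1, (nsum - colSums(n^2) / nsum) / (r - 1), NA_real_)
  pbar <- colSums(n * p) / nsum
  s2 <- ifelse(r > 1, colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar),
               NA_real_)
  hbar <- colSums(n * h) / nsum
  pq <- pbar * (1 - pbar)
  a <- nbar / nc * (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  usable <- r >= 2 & nbar > 1 & is.finite(a) & is.finite(b) & is.finite(c_)
  list(a = a, b = b, c = c_, usable = usable, loci = colnames(dosage))
}

wc_theta_multilocus <- function(cmp) {
  u <- cmp$usable
  denom <- sum(cmp$a[u] + cmp$b[u] + cmp$c[u])
  if (!any(u) || denom == 0) return(NA_real_)
  sum(cmp$a[u]) / denom
}

#' Weir-Cockerham F-statistics
#'
#' Estimates the hierarchical fixation indices theta (F_ST), f (F_IS) and
#' F (F_IT) from the 1984 variance components a (among populations),
#' b (among individuals within populations) and c (within individuals),
#' per locus and multi-locus (ratios of summed components, never means of
#' per-locus ratios). Pairwise theta is computed by restricting the
#' components to each population pair; its significance by permuting
#' individuals between the two samples.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Grouping variable or vector.
#' @param pairwise Compute the pairwise theta matrix?
#' @param n_perm Permutations for the pairwise test (0 = none; the
#'   conventional production setting is 9999).
#' @param seed Optional RNG seed for permutations.
#' @return A list of class \code{fstats_result}: \code{per_locus}
#'   (locus, theta, f, F), \code{overall} (theta, f, F),
#'   \code{pairwise} (symmetric theta matrix) and \code{pairwise_p}.
#' @export
wc_fstats <- function(gm, group = "pop", pairwise = TRUE, n_perm = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- resolve_group(gm, group)
  groups <- unique(g)
  if (length(groups) < 2L) stop("need at least two groups")
  typed_per_group <- vapply(groups, function(gr)
    sum(rowSums(!is.na(gm$dosage[g == gr, , drop = FALSE])) > 0), numeric(1))
  if (any(typed_per_group == 0))
    stop(sprintf("group '%s' has no typed genotypes",
                 groups[which(typed_per_group == 0)[1]]))
  cmp <- wc_components(gm$dosage, g)
  u <- cmp$usable
  theta_l <- ifelse(u & (cmp$a + cmp$b + cmp$c) != 0,
                    cmp$a / (cmp$a + cmp$b + cmp$c), NA_real_)
  f_l <- ifelse(u & (cmp$b + cmp$c) != 0, 1 - cmp$c / (cmp$b + cmp$c), NA_real_)
  F_l <- ifelse(u & (cmp$a + cmp$b + cmp$c) != 0,
                1 - cmp$c / (cmp$a + cmp$b + cmp$c), NA_real_)
  sa <- sum(cmp$a[u]); sb <- sum(cmp$b[u]); sc <- sum(cmp$c[u])
  overall <- list(theta = sa / (sa + sb + sc),
                  f = 1 - sc / (sb + sc),
                  F = 1 - sc / (sa + sb + sc))
  pw <- NULL; pw_p <- NULL
  if (pairwise) {
    G <- length(groups)
    pw <- matrix(0, G, G, dimnames = list(groups, groups))
    pw_p <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
    for (i in seq_len(G - 1L)) for (j in seq(i + 1L, G)) {
      idx <- g %in% groups[c(i, j)]
      d2 <- gm$dosage[idx, , drop = FALSE]
      g2 <- g[idx]
      th <- wc_theta_multilocus(wc_components(d2, g2))
      pw[i, j] <- pw[j, i] <- th
      if (n_perm > 0) {
        cnt <- 0L
        for (b in seq_len(n_perm)) {
          thp <- wc_theta_multilocus(wc_components(d2, sample(g2)))
          if (!is.na(thp) && thp >= th) cnt <- cnt + 1L
        }
        pw_p[i, j] <- pw_p[j, i] <- (1 + cnt) / (n_perm + 1)
      }
    }
  }
  structure(list(per_locus = data.frame(locus = cmp$loci, theta = theta_l,
                                        f = f_l, F = F_l,
                                        stringsAsFactors = FALSE),
                 overall = overall, pairwise = pw, pairwise_p = pw_p),
            class = "fstats_result")
}

#' @export
print.fstats_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics: theta = %.4f, f = %.4f, F = %.4f\n",
              x$overall$theta, x$overall$f, x$overall$F))
  invisible(x)
}

#' Nei's Da genetic distance
#'
#' \deqn{D_a = 1 - (1/L) \sum_l \sum_u \sqrt{x_{lu} y_{lu}}}
#' over the L loci with defined frequencies in both populations.
#'
#' @param aft An \code{\link{allele_freq_table}} (populations x loci).
#' @return A symmetric matrix of pairwise Da distances.
#' @export
nei_da <- function(aft) {
  f <- aft$freq
  G <- nrow(f)
  d <- matrix(0, G, G, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(G - 1L)) for (j in seq(i + 1L, G)) {
    ok <- !is.na(f[i, ]) & !is.na(f[j, ])
    if (!any(ok)) stop(sprintf("no shared defined loci between %s and %s",
                               rownames(f)[i], rownames(f)[j]))
    s <- sqrt(f[i, ok] * f[j, ok]) + sqrt((1 - f[i, ok]) * (1 - f[j, ok]))
    d[i, j] <- d[j, i] <- 1 - mean(s)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{\link[ape]{nj}}) with
#' negative branch lengths clamped to zero, moving each deficit onto the
#' sister branch so path lengths are preserved where possible.
#'
#' @param d Square symmetric distance matrix with >= 3 taxa.
#' @return A list of class \code{distance_tree} with elements \code{tree}
#'   (an \code{ape::phylo}), \code{dist} and \code{support} (NULL until
#'   \code{\link{bootstrap_tree}} fills it).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  tr <- clamp_negative_edges(tr)
  structure(list(tree = tr, dist = d, support = NULL),
            class = "distance_tree")
}

clamp_negative_edges <- function(tr) {
  for (pass in 1:10) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    for (e in neg) {
      deficit <- -tr$edge.length[e]
      tr$edge.length[e] <- 0
      parent <- tr$edge[e, 1L]
      sib <- setdiff(which(tr$edge[, 1L] == parent), e)
      if (length(sib) > 0L)
        tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrapped neighbor-joining tree over loci
#'
#' Resamples loci with replacement, recomputes allele frequencies, Nei's Da
#' and the NJ tree, and reports for each internal edge of the point tree the
#' percentage of replicates containing the same bipartition.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Grouping variable or vector.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Optional RNG seed.
#' @return A \code{distance_tree} whose \code{support} element holds the
#'   percentage support per internal node (also stored as node labels).
#' @export
bootstrap_tree <- function(gm, group = "pop", B = 1000, seed = NULL) {
  if (B < 100) stop("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  aft <- allele_frequencies(gm, group)
  point <- nj_tree(nei_da(aft))
  L <- ncol(aft$freq)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- allele_freq_table(aft$freq[, idx, drop = FALSE],
                             aft$copies[, idx, drop = FALSE])
    reps[[b]] <- nj_tree(nei_da(sub))$tree
  }
  counts <- ape::prop.clades(point$tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / B
  point$tree$node.label <- round(support, 1)
  point$support <- support
  point
}

#' Write a distance tree as Newick
#'
#' @param dt A \code{distance_tree}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tree_newick <- function(dt, path) {
  ape::write.tree(dt$tree, file = path)
  invisible(path)
}
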