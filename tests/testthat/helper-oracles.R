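# Independent brute-force oracles, deliberately coded from different
# formulations than the package implementation.

# Weir-Cockerham variance components from raw ANOVA sums of squares
# (mean-squares formulation), one locus at a time.
wc_oracle <- function(dosage, g) {
  groups <- unique(g)
  L <- ncol(dosage)
  a <- b <- c_ <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    x <- dosage[, l]
    keep <- !is.na(x)
    xi <- x[keep]; gi <- g[keep]
    grs <- unique(gi)
    r <- length(grs)
    if (r < 2) next
    n_i <- sapply(grs, function(gr) sum(gi == gr))
    p_i <- sapply(grs, function(gr) sum(xi[gi == gr]) / (2 * sum(gi == gr)))
    n1_i <- sapply(grs, function(gr) sum(xi[gi == gr] == 1))
    n2_i <- sapply(grs, function(gr) sum(xi[gi == gr] == 2))
    nsum <- sum(n_i)
    if (nsum == r) next
    pbar <- sum(n_i * p_i) / nsum
    SSP <- sum(2 * n_i * (p_i - pbar)^2)
    SSI <- sum(2 * (n2_i + n1_i / 4 - n_i * p_i^2))
    SSG <- sum(n1_i / 2)
    MSP <- SSP / (r - 1)
    MSI <- SSI / (nsum - r)
    MSG <- SSG / nsum
    nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
    c_[l] <- MSG
    b[l] <- (MSI - MSG) / 2
    a[l] <- (MSP - MSI) / (2 * nc)
  }
  u <- !is.na(a)
  list(a = a, b = b, c = c_,
       theta = sum(a[u]) / sum(a[u] + b[u] + c_[u]),
       theta_locus = ifelse(u, a / (a + b + c_), NA_real_))
}

# Exact HWE p by enumerating every perfect matching of the 2n gene copies
# into n diploid individuals (double-factorial recursion; distinguishable
# copies). Feasible for n <= 7 individuals.
hwe_oracle_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  alleles <- c(rep(1L, 2L * n_aa + n_ab), rep(0L, 2L * n_bb + n_ab))
  het_counts <- integer(0)
  pair_up <- function(items, hets) {
    if (length(items) == 0L) {
      het_counts[length(het_counts) + 1L] <<- hets
      return(invisible())
    }
    first <- items[1L]
    rest <- items[-1L]
    for (k in seq_along(rest)) {
      pair_up(rest[-k], hets + as.integer(first != rest[k]))
    }
  }
  pair_up(alleles, 0L)
  tab <- table(het_counts) / length(het_counts)
  obs <- tab[as.character(n_ab)]
  sum(tab[tab <= obs * (1 + 1e-9)])
}

# Allelic richness by exhaustive enumeration of all g-subsets of gene copies.
richness_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(seq_along(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Pearson correlation from explicit sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# Pearson chi-square from explicit observed/expected sums.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Nei Da by direct transcription of the definition over both alleles.
da_oracle <- function(x, y) {
  1 - mean(sqrt(x * y) + sqrt((1 - x) * (1 - y)))
}
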