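# Effective population size: the linkage-disequilibrium method (Burrows
# composite disequilibrium with the random-mating bias correction) and the
# temporal standardized-variance method under sampling plan II.

#' Expected squared correlation from sampling alone (random mating)
#'
#' The finite-sample expectation of the Burrows r-squared for unlinked loci
#' in a sample of S diploids under random mating: 1/S + 3.19/S^2 for
#' S >= 30, else 0.0018 + 0.907/S + 4.44/S^2.
#'
#' @param s Sample size (diploid individuals).
#' @return Expected r-squared due to sampling.
#' @export
expected_r2_sample <- function(s) {
  if (s >= 30) 1 / s + 3.19 / s^2 else 0.0018 + 0.907 / s + 4.44 / s^2
}

#' Effective size from drift r-squared (random-mating LD model)
#'
#' Inverts the relation between the sampling-corrected mean r-squared and Ne
#' under random mating: for S >= 30,
#' \deqn{N_e = (1/3 + \sqrt{1/9 - 2.76 r'^2}) / (2 r'^2)}
#' and with constants 0.308 and 2.08 for S < 30. Nonpositive r-squared or a
#' negative discriminant give Inf (no drift signal).
#'
#' @param r2_prime Sampling-corrected mean r-squared.
#' @param s Sample size used (selects the constant set).
#' @return Point estimate of Ne (possibly Inf).
#' @export
ld_ne_from_r2 <- function(r2_prime, s) {
  if (is.na(r2_prime) || r2_prime <= 0) return(Inf)
  if (s >= 30) { a <- 1 / 3; disc <- 1 / 9 - 2.76 * r2_prime }
  else { a <- 0.308; disc <- 0.308^2 - 2.08 * r2_prime }
  if (disc < 0) return(Inf)
  (a + sqrt(disc)) / (2 * r2_prime)
}

#' Linkage-disequilibrium estimate of effective population size
#'
#' For every pair of polymorphic loci passing the minor-allele-frequency
#' screen, computes the Burrows composite disequilibrium from unphased
#' genotypes,
#' \deqn{\hat\Delta = \frac{n}{n-1}\left[\frac{\sum_i X_i Y_i}{2n} -
#'       2\hat p\hat q\right],\quad
#'       \hat r^2 = \frac{\hat\Delta^2}{\hat p(1-\hat p)\hat q(1-\hat q)}}
#' averages r-squared over pairs (weighted by the pairwise sample size),
#' subtracts the random-mating sampling expectation
#' (\code{\link{expected_r2_sample}}) and inverts to Ne
#' (\code{\link{ld_ne_from_r2}}). The parametric confidence interval treats
#' the number of locus pairs as the chi-square degrees of freedom.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Optional single group label to subset to (default: use all
#'   individuals).
#' @param maf Minor-allele-frequency screen (default 0.02).
#' @param alpha 1 - confidence level for the CI.
#' @return A list of class \code{ne_estimate} with \code{method = "LD"},
#'   \code{estimate}, \code{ci}, \code{r2}, \code{r2_prime}, \code{s}
#'   (harmonic-mean pairwise sample size), \code{n_loci}, \code{n_pairs},
#'   \code{maf}.
#' @export
ne_ld <- function(gm, group = NULL, maf = 0.02, alpha = 0.05) {
  if (!is.null(group)) gm <- subset_genotypes(gm, gm$pop == group)
  X <- gm$dosage
  S <- nrow(X)
  if (S < 10L) stop("need at least 10 typed individuals")
  typed <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(typed, 1))
  keep <- typed >= 2 & pmin(p, 1 - p) >= maf
  X <- X[, keep, drop = FALSE]
  L <- ncol(X)
  if (L < 2L) stop("fewer than 2 usable loci after the MAF screen")
  M <- (!is.na(X)) * 1
  X0 <- X; X0[is.na(X)] <- 0
  n_pair <- crossprod(M)                      # individuals typed at both
  Sxy <- crossprod(X0)                        # sum of dosage products
  Pij <- crossprod(X0, M) / (2 * pmax(n_pair, 1))  # freq of locus i among co-typed
  corr <- n_pair / pmax(n_pair - 1, 1)
  Delta <- corr * (Sxy / (2 * pmax(n_pair, 1)) - 2 * Pij * t(Pij))
  denom <- Pij * (1 - Pij) * t(Pij) * (1 - t(Pij))
  r2 <- Delta^2 / denom
  ut <- upper.tri(r2)
  ok <- ut & is.finite(r2) & n_pair >= 10
  r2v <- r2[ok]; w <- n_pair[ok]
  if (length(r2v) == 0L) stop("no usable locus pairs")
  r2_mean <- sum(w * r2v) / sum(w)
  s_harm <- length(w) / sum(1 / w)
  e_samp <- expected_r2_sample(s_harm)
  r2p <- r2_mean - e_samp
  est <- ld_ne_from_r2(r2p, s_harm)
  npair <- length(r2v)
  r2_lo <- npair * r2_mean / stats::qchisq(1 - alpha / 2, npair)
  r2_hi <- npair * r2_mean / stats::qchisq(alpha / 2, npair)
  ci <- c(ld_ne_from_r2(r2_hi - e_samp, s_harm),
          ld_ne_from_r2(r2_lo - e_samp, s_harm))
  ci <- sort(ci)
  structure(list(method = "LD", estimate = est, ci = ci, r2 = r2_mean,
                 r2_prime = r2p, s = s_harm, n_loci = L, n_pairs = npair,
                 maf = maf),
            class = "ne_estimate")
}

#' Temporal (standardized allele-frequency variance) estimate of Ne
#'
#' Pooled standardized variance over loci,
#' \deqn{F_s = \frac{\sum_l (x_l - y_l)^2}{\sum_l z_l (1 - z_l)},\quad
#'       z = (x + y)/2,}
#' corrected for finite samples under sampling plan II (individuals removed
#' before reproduction):
#' \deqn{F_s' = \frac{F_s (1 - 1/(4\tilde n)) - 1/\tilde n}{1 + F_s/4}}
#' with \eqn{\tilde n} the harmonic mean sample size, and
#' \eqn{\hat N_e = t / (2 F_s')} for t elapsed generations. Nonpositive
#' corrected variance gives Inf. The confidence interval is a jackknife over
#' loci.
#'
#' @param gm_t0,gm_t1 \code{\link{genotype_matrix}} samples at the two time
#'   points (same loci).
#' @param t_generations Elapsed generations (>= 1).
#' @param alpha 1 - confidence level.
#' @return A list of class \code{ne_estimate} with \code{method =
#'   "temporal"}, \code{estimate}, \code{ci}, \code{fs}, \code{fs_prime},
#'   \code{t}, \code{n_loci}, \code{s} (harmonic mean sample size).
#' @export
ne_temporal <- function(gm_t0, gm_t1, t_generations, alpha = 0.05) {
  if (t_generations < 1) stop("t_generations must be >= 1")
  loci <- intersect(colnames(gm_t0$dosage), colnames(gm_t1$dosage))
  if (length(loci) == 0L) stop("no shared loci")
  d0 <- gm_t0$dosage[, loci, drop = FALSE]
  d1 <- gm_t1$dosage[, loci, drop = FALSE]
  n0 <- colSums(!is.na(d0)); n1 <- colSums(!is.na(d1))
  x <- ifelse(n0 > 0, colSums(d0, na.rm = TRUE) / (2 * n0), NA_real_)
  y <- ifelse(n1 > 0, colSums(d1, na.rm = TRUE) / (2 * n1), NA_real_)
  z <- (x + y) / 2
  use <- !is.na(x) & !is.na(y) & z > 0 & z < 1
  if (!any(use)) stop("no shared polymorphic loci")
  num <- (x - y)^2
  den <- z * (1 - z)
  fs_of <- function(keep) sum(num[keep]) / sum(den[keep])
  nh0 <- sum(use) / sum(1 / n0[use])
  nh1 <- sum(use) / sum(1 / n1[use])
  n_tilde <- 2 / (1 / nh0 + 1 / nh1)
  correct <- function(fs) (fs * (1 - 1 / (4 * n_tilde)) - 1 / n_tilde) / (1 + fs / 4)
  ne_of <- function(fsp) if (is.na(fsp) || fsp <= 0) Inf else t_generations / (2 * fsp)
  fs <- fs_of(use)
  fsp <- correct(fs)
  est <- ne_of(fsp)
  # jackknife over loci on the corrected Fs'
  li <- which(use)
  fsp_j <- vapply(li, function(l) correct(fs_of(setdiff(li, l))), numeric(1))
  m <- length(li)
  se <- sqrt((m - 1) / m * sum((fsp_j - mean(fsp_j))^2))
  zq <- stats::qnorm(1 - alpha / 2)
  ci_fsp <- c(fsp - zq * se, fsp + zq * se)
  ci <- sort(c(ne_of(ci_fsp[2]), ne_of(ci_fsp[1])))
  structure(list(method = "temporal", estimate = est, ci = ci, fs = fs,
                 fs_prime = fsp, t = t_generations, n_loci = m, s = n_tilde),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne (%s): %.1f  [%.1f, %.1f]\n", x$method, x$estimate,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Harmonic mean of effective-size estimates
#'
#' \deqn{\tilde N_e = k / \sum 1/x_i}; infinite estimates contribute zero to
#' the sum of reciprocals (and are flagged).
#'
#' @param values Positive Ne values (Inf allowed).
#' @return A list of class \code{harmonic_summary}: \code{values},
#'   \code{harmonic_mean}, \code{n_infinite}.
#' @export
harmonic_mean_ne <- function(values) {
  if (length(values) == 0L) stop("no values")
  if (any(is.na(values)) || any(values <= 0)) stop("values must be > 0")
  hm <- length(values) / sum(1 / values)
  structure(list(values = values, harmonic_mean = hm,
                 n_infinite = sum(is.infinite(values))),
            class = "harmonic_summary")
}
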