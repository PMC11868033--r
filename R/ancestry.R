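# Baseline construction, supervised maximum-likelihood ancestry estimation,
# threshold classification into genetic groups, immigrant detection,
# introgression rates and the ancestry-distance cline statistic.

#' Select baseline individuals by homozygosity at a diagnostic locus
#'
#' Mirrors the field procedure of picking reference ("pure") fish for a
#' source population as the individuals homozygous for that population's
#' allele at a diagnostic locus (cohort/site filters are applied by the
#' caller beforehand).
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param locus Locus id.
#' @param allele \code{"ref"} (dosage 2) or \code{"alt"} (dosage 0).
#' @return The \code{genotype_matrix} subset of homozygous individuals.
#' @export
select_baseline_by_diagnostic <- function(gm, locus, allele = c("ref", "alt")) {
  allele <- match.arg(allele)
  if (!locus %in% colnames(gm$dosage))
    stop(sprintf("locus '%s' not present", locus))
  x <- gm$dosage[, locus]
  keep <- !is.na(x) & x == if (allele == "ref") 2L else 0L
  subset_genotypes(gm, keep)
}

#' Build a baseline (reference allele-frequency profile) from genotypes
#'
#' @param gm A \code{\link{genotype_matrix}} holding only the baseline
#'   individuals of one source population.
#' @param id Source id (e.g. "A", "B", "CreekI_pre").
#' @param rule Free-text provenance of the selection rule.
#' @return A list of class \code{baseline}: \code{id}, \code{freq} (per-locus
#'   reference-allele frequency), \code{n} (individuals), \code{rule}.
#'   Frequencies are stored unclamped; likelihood code clamps them to
#'   [eps, 1-eps] with eps = 1/(2n+2).
#' @export
baseline_from_genotypes <- function(gm, id, rule = "caller-supplied") {
  aft <- allele_frequencies(gm, rep(id, n_individuals(gm)))
  structure(list(id = id, freq = aft$freq[1, ], copies = aft$copies[1, ],
                 n = n_individuals(gm), rule = rule),
            class = "baseline")
}

#' Assemble a baseline directly from an allele-frequency vector
#'
#' @param id Source id.
#' @param freq Named per-locus reference-allele frequencies.
#' @param n Number of individuals behind the frequencies (drives the
#'   clamping constant eps = 1/(2n+2)).
#' @param rule Provenance note.
#' @return A \code{baseline}.
#' @export
baseline_from_freqs <- function(id, freq, n, rule = "frequencies supplied") {
  structure(list(id = id, freq = freq, copies = rep(2 * n, length(freq)),
                 n = n, rule = rule), class = "baseline")
}

# K x L matrix of clamped baseline frequencies, aligned to gm loci.
baseline_p_matrix <- function(baselines, loci) {
  K <- length(baselines)
  P <- matrix(NA_real_, K, length(loci),
              dimnames = list(vapply(baselines, `[[`, "", "id"), loci))
  for (k in seq_len(K)) {
    b <- baselines[[k]]
    f <- b$freq[loci]
    eps <- 1 / (2 * b$n + 2)
    f[is.na(f)] <- 0.5  # uninformative where a baseline lacks data
    P[k, ] <- pmin(pmax(f, eps), 1 - eps)
  }
  P
}

#' Supervised maximum-likelihood ancestry estimation
#'
#' Estimates, for every individual, the ancestry vector Q on the simplex that
#' maximizes the admixture log-likelihood with the baseline allele
#' frequencies held fixed:
#' \deqn{\ell(Q) = \sum_l [g_l \ln \sum_k Q_k p_{kl} +
#'       (2-g_l) \ln \sum_k Q_k (1-p_{kl})]}
#' by EM from a uniform start (the Q update averages, over the individual's
#' gene copies, the posterior probability of each source). Missing loci are
#' skipped. The EM log-likelihood is non-decreasing; iteration stops when the
#' total improvement falls below \code{tol} or after \code{max_iter} steps.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param baselines List of \code{baseline} objects (K >= 2).
#' @param tol Convergence tolerance on the summed log-likelihood.
#' @param max_iter Iteration cap.
#' @return A data.frame of class \code{ancestry_result}: \code{id}, one
#'   \code{Q_<source>} column per baseline, \code{loglik},
#'   \code{n_loci_used}. Attribute \code{loglik_trace} holds the summed
#'   log-likelihood per EM iteration.
#' @export
estimate_q_supervised <- function(gm, baselines, tol = 1e-8, max_iter = 2000) {
  K <- length(baselines)
  if (K < 2L) stop("need at least two baselines")
  loci <- colnames(gm$dosage)
  P <- baseline_p_matrix(baselines, loci)
  G <- gm$dosage
  M <- !is.na(G)
  if (any(rowSums(M) == 0L)) stop("individual with all loci missing")
  G0 <- G; G0[!M] <- 0L
  Gc <- 2L - G0; Gc[!M] <- 0L     # alt-allele copies, zeroed where missing
  n <- nrow(G); Lused <- rowSums(M)
  Q <- matrix(1 / K, n, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    R <- Q %*% P            # expected ref-allele freq per ind x locus
    A <- Q %*% (1 - P)
    ll <- sum(G0 * log(R) + Gc * log(A))
    trace <- c(trace, ll)
    Qnew <- Q * ((G0 / R) %*% t(P) + (Gc / A) %*% t(1 - P)) / (2 * Lused)
    Qnew <- Qnew / rowSums(Qnew)
    delta <- if (it > 1L) ll - trace[it - 1L] else Inf
    Q <- Qnew
    if (is.finite(delta) && delta < tol) break
  }
  R <- Q %*% P; A <- Q %*% (1 - P)
  ll_i <- rowSums(G0 * log(R) + Gc * log(A))
  res <- data.frame(id = rownames(G), Q, loglik = ll_i, n_loci_used = Lused,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(res)[2:(K + 1)] <- paste0("Q_", rownames(P))
  attr(res, "loglik_trace") <- trace
  class(res) <- c("ancestry_result", class(res))
  res
}

#' Unsupervised admixture model fit by block EM
#'
#' Joint maximum likelihood over ancestry vectors Q and cluster allele
#' frequencies P for a chosen number of clusters K, by alternating the
#' supervised Q update with the P update, from multiple random restarts
#' (best final log-likelihood kept). When baselines are supplied, cluster
#' labels are aligned to them by allele-frequency correlation.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param K Number of clusters (>= 1; K = 1 has the closed-form solution
#'   Q = 1, P = sample frequencies).
#' @param n_restarts Random restarts.
#' @param seed Optional RNG seed.
#' @param baselines Optional list of \code{baseline}s used only to label
#'   clusters.
#' @param tol,max_iter EM stopping rule per restart.
#' @return A list of class \code{admixture_fit}: \code{q}
#'   (an \code{ancestry_result}), \code{P} (K x loci), \code{loglik},
#'   \code{loglik_trace} of the winning restart.
#' @export
fit_admixture_unsupervised <- function(gm, K, n_restarts = 5, seed = NULL,
                                       baselines = NULL, tol = 1e-6,
                                       max_iter = 500) {
  if (!is.null(seed)) set.seed(seed)
  if (K > n_individuals(gm)) stop("K exceeds the number of individuals")
  if (K < 1L) stop("K must be >= 1")
  G <- gm$dosage; M <- !is.na(G)
  G0 <- G; G0[!M] <- 0L
  Gc <- 2L - G0; Gc[!M] <- 0L
  n <- nrow(G); L <- ncol(G); Lused <- rowSums(M)
  if (K == 1L) {
    p <- colSums(G0) / pmax(2 * colSums(M), 1)
    P <- matrix(p, 1, L, dimnames = list("K1", colnames(G)))
    eps <- 1 / (2 * n + 2)
    Pc <- pmin(pmax(P, eps), 1 - eps)
    ll_i <- rowSums(G0 * log(Pc[rep(1, n), , drop = FALSE]) +
                    Gc * log(1 - Pc[rep(1, n), , drop = FALSE]))
    q <- data.frame(id = rownames(G), Q_K1 = rep(1, n), loglik = ll_i,
                    n_loci_used = Lused, stringsAsFactors = FALSE)
    class(q) <- c("ancestry_result", class(q))
    return(structure(list(q = q, P = P, loglik = sum(ll_i),
                          loglik_trace = sum(ll_i)),
                     class = "admixture_fit"))
  }
  eps <- 1e-6
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      R <- Q %*% P; A <- Q %*% (1 - P)
      ll <- sum(G0 * log(R) + Gc * log(A))
      trace <- c(trace, ll)
      W_ref <- (G0 / R)    # n x L weights
      W_alt <- (Gc / A)
      Qnew <- Q * (W_ref %*% t(P) + W_alt %*% t(1 - P)) / (2 * Lused)
      Qnew <- Qnew / rowSums(Qnew)
      # P update: expected ref copies from k / expected total copies from k
      ref_k <- t(W_ref) %*% Q * t(P)          # L x K
      alt_k <- t(W_alt) %*% Q * t(1 - P)
      Pnew <- t(ref_k / (ref_k + alt_k))
      Pnew <- pmin(pmax(Pnew, eps), 1 - eps)
      if (it > 1L && ll - trace[it - 1L] < tol) { Q <- Qnew; P <- Pnew; break }
      Q <- Qnew; P <- Pnew
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(Q = Q, P = P, loglik = trace[length(trace)], trace = trace)
    }
  }
  Q <- best$Q; P <- best$P
  labels <- paste0("K", seq_len(K))
  if (!is.null(baselines)) {
    Pb <- baseline_p_matrix(baselines, colnames(G))
    taken <- integer(0)
    for (k in seq_len(K)) {
      cors <- apply(Pb, 1, function(f) suppressWarnings(stats::cor(f, P[k, ])))
      cors[taken] <- -Inf
      j <- which.max(cors)
      if (is.finite(cors[j])) { labels[k] <- rownames(Pb)[j]; taken <- c(taken, j) }
    }
  }
  rownames(P) <- labels
  colnames(P) <- colnames(G)
  R <- Q %*% P; A <- Q %*% (1 - P)
  ll_i <- rowSums(G0 * log(R) + Gc * log(A))
  q <- data.frame(id = rownames(G), Q, loglik = ll_i, n_loci_used = Lused,
                  row.names = NULL, stringsAsFactors = FALSE)
  names(q)[2:(K + 1)] <- paste0("Q_", labels)
  attr(q, "loglik_trace") <- best$trace
  class(q) <- c("ancestry_result", class(q))
  structure(list(q = q, P = P, loglik = best$loglik,
                 loglik_trace = best$trace),
            class = "admixture_fit")
}

#' Classify lake fish into genetic groups A / AB / B
#'
#' Threshold rule on the assignment probability to source A:
#' A if \eqn{Q_A \ge 0.75}, B if \eqn{Q_A \le 0.25}, else AB (the boundary
#' values belong to the pure groups).
#'
#' @param q_a Numeric vector of Q_A values in [0,1].
#' @return Character vector in \{"A", "AB", "B"\}.
#' @export
classify_lake_group <- function(q_a) {
  stopifnot(all(q_a >= 0 & q_a <= 1, na.rm = TRUE))
  ifelse(q_a >= 0.75, "A", ifelse(q_a <= 0.25, "B", "AB"))
}

#' Flag individuals as pure at a purity cutoff
#'
#' Two conventional cutoffs: the strict one calls an individual pure when its
#' largest ancestry component is >= 0.99; the relaxed one when it is > 0.75
#' (strict inequality).
#'
#' @param q_max Numeric vector of per-individual maximum Q values.
#' @param cutoff 0.99 (default) or 0.75.
#' @return Logical vector.
#' @export
flag_pure <- function(q_max, cutoff = 0.99) {
  stopifnot(all(q_max >= 0 & q_max <= 1, na.rm = TRUE))
  if (isTRUE(all.equal(cutoff, 0.75))) q_max > cutoff else q_max >= cutoff
}

#' Detect immigrants in creek samples from 4-baseline ancestry
#'
#' An individual is an immigrant from above the waterfall when its
#' assignment to the creek locality where it was caught is Q_local < 0.25.
#' In the downstream creek, fish assigned to the upstream creek with
#' Q >= 0.75 are downstream immigrants (they take precedence over the
#' generic immigrant call).
#'
#' @param q An \code{ancestry_result} with Q columns over the four baselines.
#' @param local_id Baseline id of the locality where the fish were caught.
#' @param upstream_id Baseline id of the creek locality directly upstream,
#'   or NULL when there is none.
#' @param immigrant_cutoff Threshold on Q_local (default 0.25).
#' @param downstream_cutoff Threshold on Q_upstream (default 0.75).
#' @return Data.frame of class \code{group_calls}: \code{id}, \code{group}
#'   in \{local, immigrant, downstream-immigrant\}, \code{Q_local}.
#' @export
detect_immigrants <- function(q, local_id, upstream_id = NULL,
                              immigrant_cutoff = 0.25,
                              downstream_cutoff = 0.75) {
  col_local <- paste0("Q_", local_id)
  if (!col_local %in% names(q))
    stop(sprintf("missing local baseline column '%s'", col_local))
  q_local <- q[[col_local]]
  group <- rep("local", nrow(q))
  if (!is.null(upstream_id)) {
    col_up <- paste0("Q_", upstream_id)
    if (!col_up %in% names(q))
      stop(sprintf("missing upstream baseline column '%s'", col_up))
    group[q[[col_up]] >= downstream_cutoff] <- "downstream-immigrant"
  }
  group[group == "local" & q_local < immigrant_cutoff] <- "immigrant"
  structure(data.frame(id = q$id, group = group, Q_local = q_local,
                       stringsAsFactors = FALSE),
            class = c("group_calls", "data.frame"))
}

#' Introgression rate from released populations
#'
#' Mean proportion of genes originating from the released source populations
#' among the fish that are not immigrants (\code{introgression}), plus the
#' total alien contribution over all fish including immigrants
#' (\code{total_alien}).
#'
#' @param q An \code{ancestry_result}.
#' @param calls \code{group_calls} from \code{\link{detect_immigrants}}
#'   (matched by position).
#' @param alien_ids Baseline ids counted as alien (default \code{c("A","B")}).
#' @return List with \code{introgression}, \code{total_alien},
#'   \code{n_local}, \code{n_immigrant}.
#' @export
introgression_rate <- function(q, calls, alien_ids = c("A", "B")) {
  cols <- paste0("Q_", alien_ids)
  if (!all(cols %in% names(q))) stop("missing alien baseline columns")
  alien <- rowSums(as.matrix(q[, cols, drop = FALSE]))
  non_imm <- calls$group == "local"
  if (!any(non_imm)) stop("no non-immigrant individuals left in sample")
  list(introgression = mean(alien[non_imm]),
       total_alien = mean(alien),
       n_local = sum(non_imm),
       n_immigrant = sum(!non_imm))
}

#' Ancestry-distance cline correlation
#'
#' Pearson correlation between per-lake mean assignment to a source and the
#' geographic distance from the release site, with the two-sided t-test.
#'
#' @param q_mean Per-lake mean Q values (>= 3 lakes).
#' @param distance Distances from the release site (same length).
#' @return List with \code{r}, \code{p_value}, \code{n}.
#' @export
cline_correlation <- function(q_mean, distance) {
  if (length(q_mean) != length(distance)) stop("length mismatch")
  if (length(q_mean) < 3L) stop("need at least 3 lakes")
  if (stats::sd(q_mean) == 0 || stats::sd(distance) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(q_mean, distance, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(q_mean))
}

#' Chi-square contingency test of spawning status by genetic group
#'
#' Pearson chi-square without continuity correction on the genetic-group by
#' spawner-status contingency table.
#'
#' @param group Character vector of genetic group calls (e.g. A/AB/B).
#' @param spawner Logical or factor vector of spawning status.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{table}.
#' @export
spawning_contingency <- function(group, spawner) {
  tab <- table(group, spawner)
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty row or column")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
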