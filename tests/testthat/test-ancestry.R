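test_that("diagnostic-locus baseline selection picks exactly the homozygotes", {
  d <- matrix(c(2L, 1L, 0L, 2L), 4, 1, dimnames = list(paste0("i", 1:4), "diag"))
  gm <- genotype_matrix(d, rep("P", 4))
  selA <- select_baseline_by_diagnostic(gm, "diag", "ref")
  expect_equal(rownames(selA$dosage), c("i1", "i4"))
  selB <- select_baseline_by_diagnostic(gm, "diag", "alt")
  expect_equal(rownames(selB$dosage), "i3")   # heterozygotes never selected
  expect_error(select_baseline_by_diagnostic(gm, "nope", "ref"), "not present")
})

test_that("diagnostic selection recovers the pure individuals in a P+F1 mixture", {
  set.seed(4)
  L <- 50
  pA <- c(1, runif(L - 1, 0.5, 0.95)); pB <- c(0, runif(L - 1, 0.05, 0.5))
  names(pA) <- names(pB) <- paste0("L", 1:L)
  Q <- rbind(matrix(rep(c(1, 0), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(0.5, 0.5), 20), ncol = 2, byrow = TRUE))
  # F1s are heterozygous at the fixed diagnostic locus by construction
  gm <- admixed_gm(Q, rbind(pA, pB))
  gm$dosage[, 1] <- ifelse(Q[, 1] == 1, 2L, ifelse(Q[, 2] == 1, 0L, 1L))
  selA <- select_baseline_by_diagnostic(gm, "L1", "ref")
  selB <- select_baseline_by_diagnostic(gm, "L1", "alt")
  pure <- Q[, 1] %in% c(0, 1)
  expect_equal(n_individuals(selA) + n_individuals(selB), sum(pure))
})

test_that("supervised Q: degenerate and symmetric cases", {
  L <- 96
  loci <- paste0("L", 1:L)
  bA <- baseline_from_freqs("A", setNames(rep(1, L), loci), n = 1000)
  bB <- baseline_from_freqs("B", setNames(rep(0, L), loci), n = 1000)
  gm_ref <- gm_from_dosage(matrix(2L, 1, L, dimnames = list("i1", loci)))
  q <- estimate_q_supervised(gm_ref, list(bA, bB))
  expect_gte(q$Q_A, 0.999)
  gm_het <- gm_from_dosage(matrix(1L, 1, L, dimnames = list("i1", loci)))
  q2 <- estimate_q_supervised(gm_het, list(bA, bB))
  expect_equal(q2$Q_A, 0.5, tolerance = 1e-6)
  # simplex invariant
  expect_equal(q2$Q_A + q2$Q_B, 1, tolerance = 1e-8)
})

test_that("supervised Q recovers F1 ancestry at founder-level divergence", {
  set.seed(14)
  f <- simulate_founder_freqs(sim_config(), seed = 14)
  pA <- f$freq["A", ]; pB <- f$freq["B", ]
  bA <- sampled_baseline(pA, 110, "A")
  bB <- sampled_baseline(pB, 108, "B")
  gm <- f1_gm(pA, pB, 200)
  q <- estimate_q_supervised(gm, list(bA, bB))
  expect_lt(mean(abs(q$Q_A - 0.5)), 0.05)
  expect_lt(sqrt(mean((q$Q_A - 0.5)^2)), 0.08)
  # EM log-likelihood is non-decreasing
  tr <- attr(q, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-8))
})

test_that("supervised Q is equivariant under swapping baseline labels", {
  set.seed(15)
  f <- simulate_founder_freqs(sim_config(n_loci = 40), seed = 15)
  pA <- f$freq["A", ]; pB <- f$freq["B", ]
  qa <- runif(10)
  gm <- admixed_gm(cbind(qa, 1 - qa), rbind(pA, pB))
  bA <- baseline_from_freqs("A", pA, 100)
  bB <- baseline_from_freqs("B", pB, 100)
  q1 <- estimate_q_supervised(gm, list(bA, bB))
  q2 <- estimate_q_supervised(gm, list(bB, bA))
  expect_equal(q1$Q_A, q2$Q_A, tolerance = 1e-6)
  expect_equal(q1$Q_B, q2$Q_B, tolerance = 1e-6)
})

test_that("pure-A simulated fish get mean Q_A at least 0.95", {
  set.seed(16)
  f <- simulate_founder_freqs(sim_config(), seed = 16)
  pA <- f$freq["A", ]; pB <- f$freq["B", ]
  gm <- admixed_gm(cbind(rep(1, 60), 0), rbind(pA, pB))
  q <- estimate_q_supervised(gm, list(sampled_baseline(pA, 110, "A"),
                                      sampled_baseline(pB, 108, "B")))
  expect_gte(mean(q$Q_A), 0.95)
})

test_that("unsupervised admixture: K = 1 closed form and K = 2 recovery", {
  set.seed(17)
  gm <- random_gm(n = 20, L = 12, miss = 0.1, seed = 17)
  fit1 <- fit_admixture_unsupervised(gm, K = 1)
  expect_true(all(fit1$q[[2]] == 1))
  aft <- allele_frequencies(gm, rep("all", 20))
  expect_equal(unname(fit1$P[1, ]), unname(aft$freq[1, ]), tolerance = 1e-12)
  # two diverged sources, pure individuals
  f <- simulate_founder_freqs(sim_config(n_loci = 60), seed = 18)
  pA <- f$freq["A", ]; pB <- f$freq["B", ]
  Q <- rbind(cbind(rep(1, 30), 0), cbind(rep(0, 30), 1))
  gm2 <- admixed_gm(Q, rbind(pA, pB))
  fit2 <- fit_admixture_unsupervised(gm2, K = 2, n_restarts = 3, seed = 19,
                                     baselines = list(
                                       baseline_from_freqs("A", pA, 100),
                                       baseline_from_freqs("B", pB, 100)))
  agree <- mean((fit2$q$Q_A >= 0.5) == (Q[, 1] == 1))
  expect_gt(agree, 0.95)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-6))
  expect_error(fit_admixture_unsupervised(gm, K = 50), "exceeds")
})

test_that("lake group classification follows the printed thresholds", {
  expect_equal(classify_lake_group(c(0.80, 0.50, 0.75, 0.25, 0.10)),
               c("A", "AB", "A", "B", "B"))
})

test_that("purity flags implement both cutoffs", {
  expect_true(flag_pure(0.995, 0.99))
  expect_true(flag_pure(0.995, 0.75))
  expect_false(flag_pure(0.80, 0.99))
  expect_true(flag_pure(0.80, 0.75))
  expect_false(flag_pure(0.5, 0.75))
  expect_false(flag_pure(0.75, 0.75))   # relaxed cutoff is strict
  expect_true(flag_pure(0.99, 0.99))    # strict cutoff is inclusive
})

test_that("immigrant detection applies the Q thresholds", {
  q <- data.frame(id = c("a", "b", "c", "d"),
                  Q_A = c(0.5, 0.05, 0.05, 0.1),
                  Q_B = c(0.3, 0.05, 0.05, 0.05),
                  Q_CreekI_pre = c(0.0, 0.80, 0.10, 0.05),
                  Q_CreekII_pre = c(0.2, 0.10, 0.80, 0.80))
  calls <- detect_immigrants(q, "CreekII_pre", upstream_id = "CreekI_pre")
  expect_equal(calls$group,
               c("immigrant", "downstream-immigrant", "local", "local"))
  calls1 <- detect_immigrants(q, "CreekI_pre")
  expect_equal(calls1$group, c("immigrant", "local", "immigrant", "immigrant"))
  expect_error(detect_immigrants(q, "nope"), "missing local")
})

test_that("introgression rate is the mean alien ancestry of non-immigrants", {
  q <- data.frame(id = paste0("i", 1:4),
                  Q_A = c(0, 0.02, 0.04, 0.6),
                  Q_B = c(0, 0.01, 0.02, 0.3),
                  Q_CreekI_pre = c(1, 0.97, 0.94, 0.1),
                  Q_CreekII_pre = 0)
  calls <- detect_immigrants(q, "CreekI_pre")
  ir <- introgression_rate(q, calls)
  expect_equal(ir$introgression, mean(c(0, 0.03, 0.06)))
  expect_equal(ir$n_immigrant, 1)
  # closed population
  q0 <- data.frame(id = "x", Q_A = 0, Q_B = 0, Q_CreekI_pre = 1,
                   Q_CreekII_pre = 0)
  expect_equal(introgression_rate(q0, detect_immigrants(q0, "CreekI_pre"))$introgression, 0)
})

test_that("introgression estimate recovers a known alien pedigree fraction", {
  set.seed(20)
  f <- simulate_founder_freqs(sim_config(), seed = 20)
  P <- f$freq
  ests <- replicate(30, {
    Q <- rbind(matrix(rep(c(0, 0, 1, 0), 48), ncol = 4, byrow = TRUE),
               matrix(rep(c(0.125, 0.125, 0.75, 0), 12), ncol = 4, byrow = TRUE))
    gm <- admixed_gm(Q, P)
    bl <- list(sampled_baseline(P["A", ], 110, "A"),
               sampled_baseline(P["B", ], 108, "B"),
               sampled_baseline(P["CreekI_pre", ], 135, "CreekI_pre"),
               sampled_baseline(P["CreekII_pre", ], 127, "CreekII_pre"))
    q <- estimate_q_supervised(gm, bl)
    calls <- detect_immigrants(q, "CreekI_pre")
    introgression_rate(q, calls)$introgression
  })
  expect_lt(abs(mean(ests) - 0.05), 0.03)
})

test_that("cline correlation matches the covariance oracle", {
  q <- c(0.30, 0.44, 0.56, 0.72, 0.81, 0.89, 0.94)
  dist <- 1:7
  cl <- cline_correlation(q, dist)
  expect_equal(cl$r, pearson_oracle(q, dist), tolerance = 1e-12)
  # exact linearity
  expect_equal(cline_correlation(seq(0.1, 0.7, 0.1), 1:7)$r, 1)
  expect_error(cline_correlation(rep(0.5, 5), 1:5), "zero variance")
  # null calibration: permuted distances give uniform p
  set.seed(22)
  pv <- replicate(200, cline_correlation(runif(7), sample(7))$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.05)
  expect_gt(mean(pv > 0.5), 0.3)
})

test_that("spawning contingency test matches the hand-computed chi-square", {
  tab <- matrix(c(10, 10, 10, 10, 10, 40), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "AB", "B"), c("no", "yes")))
  group <- rep(rownames(tab), times = rowSums(tab))
  spawner <- unlist(lapply(seq_len(nrow(tab)), function(i)
    rep(colnames(tab), times = tab[i, ])))
  res <- spawning_contingency(group, spawner)
  expect_equal(res$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(res$df, 2)   # 2x3 table
  # exact independence -> chi-square 0
  tab0 <- outer(c(20, 30, 50), c(0.4, 0.6))
  g0 <- rep(c("A", "AB", "B"), times = rowSums(tab0))
  s0 <- unlist(lapply(1:3, function(i) rep(c("no", "yes"), times = tab0[i, ])))
  expect_equal(spawning_contingency(g0, s0)$statistic, 0, tolerance = 1e-12)
  expect_error(spawning_contingency(c("A", "A"), c("yes", "yes")), "empty")
})
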