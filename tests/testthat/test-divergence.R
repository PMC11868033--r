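test_that("theta equals 1 for populations fixed for alternate alleles", {
  d <- rbind(matrix(2L, 5, 4), matrix(0L, 5, 4))
  colnames(d) <- paste0("L", 1:4)
  gm <- genotype_matrix(d, rep(c("A", "B"), each = 5))
  res <- wc_fstats(gm, pairwise = FALSE)
  expect_equal(res$overall$theta, 1)
})

test_that("theta matches the brute-force variance-components oracle", {
  # 4-individual toy
  d <- matrix(c(2L, 1L, 0L, 1L,
                2L, 2L, 1L, 0L,
                0L, 1L, 1L, 1L), 4, 3,
              dimnames = list(paste0("i", 1:4), paste0("L", 1:3)))
  g <- c("A", "A", "B", "B")
  gm <- genotype_matrix(d, g)
  res <- wc_fstats(gm, pairwise = FALSE)
  orc <- wc_oracle(d, g)
  expect_equal(res$overall$theta, orc$theta, tolerance = 1e-12)
  expect_equal(res$per_locus$theta, orc$theta_locus, tolerance = 1e-12)
  # larger random cases with missing data and three groups
  for (seed in 1:5) {
    gm2 <- random_gm(n = 18, L = 7, n_pops = 3, miss = 0.1, seed = seed)
    res2 <- wc_fstats(gm2, pairwise = FALSE)
    orc2 <- wc_oracle(gm2$dosage, gm2$pop)
    expect_equal(res2$overall$theta, orc2$theta, tolerance = 1e-10)
  }
})

test_that("theta is unbiased under the null of identical frequencies", {
  set.seed(21)
  thetas <- replicate(200, {
    p <- runif(40, 0.2, 0.8)
    d <- matrix(rbinom(100 * 40, 2, rep(p, each = 100)), 100, 40,
                dimnames = list(NULL, paste0("L", 1:40)))
    gm <- genotype_matrix(d, rep(c("A", "B"), each = 50))
    wc_fstats(gm, pairwise = FALSE)$overall$theta
  })
  expect_lt(abs(mean(thetas)), 0.01)
})

test_that("pairwise permutation p is uniform under the null and small under divergence", {
  set.seed(31)
  # null: same source frequencies
  pvals <- replicate(60, {
    p <- runif(20, 0.3, 0.7)
    d <- matrix(rbinom(30 * 20, 2, rep(p, each = 30)), 30, 20,
                dimnames = list(NULL, paste0("L", 1:20)))
    gm <- genotype_matrix(d, rep(c("A", "B"), each = 15))
    wc_fstats(gm, n_perm = 99)$pairwise_p["A", "B"]
  })
  expect_gt(mean(pvals > 0.05), 0.80)   # roughly uniform: most p above alpha
  # strong divergence: p small
  d <- rbind(matrix(2L, 10, 10), matrix(0L, 10, 10))
  colnames(d) <- paste0("L", 1:10)
  gm <- genotype_matrix(d, rep(c("A", "B"), each = 10))
  expect_lt(wc_fstats(gm, n_perm = 199)$pairwise_p["A", "B"], 0.02)
})

test_that("Nei Da matches hand evaluation and has its stated range", {
  f <- rbind(x = c(1, 1), y = c(0.5, 0.5), z = c(1, 1))
  colnames(f) <- c("L1", "L2")
  aft <- allele_freq_table(f, matrix(10, 3, 2, dimnames = dimnames(f)))
  d <- nei_da(aft)
  expect_equal(d["x", "z"], 0)                      # identical frequencies
  expect_equal(d["x", "y"], 1 - sqrt(0.5), tolerance = 1e-12)
  expect_equal(d["x", "y"], da_oracle(c(1, 1), c(0.5, 0.5)), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # fully disjoint fixation -> Da = 1
  f2 <- rbind(a = c(1, 1), b = c(0, 0))
  aft2 <- allele_freq_table(f2, matrix(10, 2, 2))
  expect_equal(nei_da(aft2)[1, 2], 1)
})

test_that("NJ recovers additive trees and solves the 3-taxon closed form", {
  # additive distances on a 4-taxon tree: ((a,b),(c,d))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  # branch lengths: a=1, b=2, internal=3, c=4, d=5
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 8
  d["a", "d"] <- d["d", "a"] <- 9
  d["b", "c"] <- d["c", "b"] <- 9
  d["b", "d"] <- d["d", "b"] <- 10
  d["c", "d"] <- d["d", "c"] <- 9
  dt <- nj_tree(d)
  # the a|b vs c|d bipartition must be present
  splits <- ape::prop.part(dt$tree)
  expect_true(any(vapply(splits, function(s)
    setequal(dt$tree$tip.label[s], c("a", "b")) ||
    setequal(dt$tree$tip.label[s], c("c", "d")), logical(1))))
  # path lengths reproduce the additive distances
  pd <- ape::cophenetic.phylo(dt$tree)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-10)
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  el <- setNames(t3$tree$edge.length,
                 t3$tree$tip.label[t3$tree$edge[, 2]])
  expect_equal(el[["x"]], (3 + 5 - 6) / 2)
  expect_equal(el[["y"]], (3 + 6 - 5) / 2)
  expect_equal(el[["z"]], (5 + 6 - 3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("NJ agrees with exhaustive least-squares over the 3 quartet topologies", {
  set.seed(77)
  for (rep in 1:5) {
    # near-additive random distances: additive tree plus small noise
    bl <- runif(5, 0.5, 2)   # a, b, c, d, internal
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d["a", "b"] <- bl[1] + bl[2]
    d["a", "c"] <- bl[1] + bl[5] + bl[3]
    d["a", "d"] <- bl[1] + bl[5] + bl[4]
    d["b", "c"] <- bl[2] + bl[5] + bl[3]
    d["b", "d"] <- bl[2] + bl[5] + bl[4]
    d["c", "d"] <- bl[3] + bl[4]
    d <- d + t(d)
    noise <- matrix(runif(16, 0, 0.05), 4, 4); noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    d <- d + noise
    # least-squares fit of each quartet topology; path matrix columns =
    # 4 pendant edges + 1 internal edge
    pairs <- t(utils::combn(1:4, 2))
    fit_ss <- function(split) {
      X <- matrix(0, 6, 5)
      y <- numeric(6)
      for (r in seq_len(6)) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        X[r, i] <- 1; X[r, j] <- 1
        same <- (i %in% split) == (j %in% split)
        if (!same) X[r, 5] <- 1
        y[r] <- d[i, j]
      }
      sum(stats::lm.fit(X, y)$residuals^2)
    }
    ss <- c(ab = fit_ss(c(1, 2)), ac = fit_ss(c(1, 3)), ad = fit_ss(c(1, 4)))
    best <- names(which.min(ss))
    dt <- nj_tree(d)
    splits <- ape::prop.part(dt$tree)
    nj_split <- NULL
    for (s in splits) if (length(s) == 2)
      nj_split <- sort(match(dt$tree$tip.label[s], letters[1:4]))
    if (is.null(nj_split)) {  # splits list stores one side; derive pair split
      nj_split <- sort(match(dt$tree$tip.label[splits[[2]]], letters[1:4]))
    }
    got <- paste(letters[nj_split], collapse = "")
    alias <- c(ab = "cd", ac = "bd", ad = "bc")
    expect_true(got == best || got == alias[[best]])
  }
})

test_that("bootstrap supports: forced bipartitions get 100, order invariance", {
  set.seed(8)
  p <- runif(30, 0.2, 0.8)
  make <- function(pp, n, pop) {
    d <- matrix(rbinom(n * 30, 2, rep(pp, each = n)), n, 30,
                dimnames = list(NULL, paste0("L", 1:30)))
    gm_from_dosage(d, pop)
  }
  gmA <- make(p, 15, "A")
  gmB <- make(pmin(p + 0.4, 0.98), 15, "B")
  # duplicate taxa: X1 and X2 share the exact same genotypes -> Da = 0
  d <- gmA$dosage
  big <- genotype_matrix(rbind(d, d, gmB$dosage, make(runif(30), 15, "C")$dosage),
                         rep(c("X1", "X2", "B", "C"), each = 15))
  bt <- bootstrap_tree(big, B = 100, seed = 1)
  # the X1|X2 bipartition is forced in every replicate
  pd <- ape::cophenetic.phylo(bt$tree)
  expect_equal(unname(pd["X1", "X2"]), 0, tolerance = 1e-12)
  expect_true(any(bt$support >= 99.5))
  # same seed, permuted taxa order: same supports for the same bipartitions
  perm <- sample(n_individuals(big))
  bt2 <- bootstrap_tree(subset_genotypes(big, perm), B = 100, seed = 1)
  expect_setequal(round(sort(bt$support), 6), round(sort(bt2$support), 6))
})
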