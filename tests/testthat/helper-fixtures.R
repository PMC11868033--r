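# Programmatic fixtures shared across test files.

# Random genotype matrix with optional missing data.
random_gm <- function(n = 12, L = 8, n_pops = 2, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(L, 0.2, 0.8)
  d <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L,
              dimnames = list(paste0("i", seq_len(n)), paste0("L", seq_len(L))))
  if (miss > 0) d[runif(n * L) < miss] <- NA
  # contiguous population blocks (the layout GENEPOP can represent)
  pops <- rep(paste0("P", seq_len(n_pops)), each = ceiling(n / n_pops))[1:n]
  genotype_matrix(d, pops)
}

# Genotypes under the admixture model: dosage ~ Binomial(2, (Q P)_il).
admixed_gm <- function(Q, P, pop = "mix") {
  n <- nrow(Q); L <- ncol(P)
  pr <- Q %*% P
  d <- matrix(rbinom(n * L, 2, pr), n, L,
              dimnames = list(paste0("i", seq_len(n)), colnames(P)))
  genotype_matrix(d, rep(pop, n))
}

# True F1 hybrids: one gamete from each source population's gene pool.
f1_gm <- function(pA, pB, n, pop = "F1") {
  L <- length(pA)
  d <- matrix(rbinom(n * L, 1, rep(pA, each = n)) +
              rbinom(n * L, 1, rep(pB, each = n)), n, L,
              dimnames = list(paste0("i", seq_len(n)), names(pA)))
  genotype_matrix(d, rep(pop, n))
}

# Diploid Wright-Fisher population (random union of gametes); returns the
# dosage matrix after `gens` generations of size N.
wf_generation <- function(dos, n_off) {
  N <- nrow(dos); L <- ncol(dos)
  mi <- sample.int(N, n_off, replace = TRUE)
  fi <- sample.int(N, n_off, replace = TRUE)
  m <- matrix(rbinom(n_off * L, 1, dos[mi, , drop = FALSE] / 2) +
              rbinom(n_off * L, 1, dos[fi, , drop = FALSE] / 2), n_off, L)
  colnames(m) <- colnames(dos)
  m
}

wf_sim <- function(N, L, gens, p0 = runif(L, 0.2, 0.8)) {
  dos <- matrix(rbinom(N * L, 2, rep(p0, each = N)), N, L,
                dimnames = list(NULL, paste0("L", seq_len(L))))
  for (g in seq_len(gens)) dos <- wf_generation(dos, N)
  dos
}

gm_from_dosage <- function(d, pop = "x") {
  if (is.null(colnames(d))) colnames(d) <- paste0("L", seq_len(ncol(d)))
  genotype_matrix(d, rep(pop, nrow(d)))
}

# Baselines estimated from finite samples of the founder frequencies.
sampled_baseline <- function(freq, n, id) {
  d <- matrix(rbinom(n * length(freq), 2, rep(freq, each = n)), n,
              dimnames = list(NULL, names(freq)))
  colnames(d) <- names(freq)
  baseline_from_genotypes(gm_from_dosage(d, id), id)
}
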