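# Forward simulator of a two-population release spreading through a lake
# chain, with ancestry-linked downstream dispersal and one-way leakage over
# a waterfall into two native creek demes. Produces genotypes plus
# per-individual pedigree-ancestry truth for recovery tests.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: two founder
#' populations at multi-locus FST ~ 0.40 (about 100 and 17 spawners,
#' 1000 released fry each), a seven-lake chain colonized over 6 generations
#' with downstream dispersal increasing with ancestry to the migratory
#' founder, a one-way waterfall into a native creek deme and a further
#' downstream creek deme diverged from it at FST ~ 0.21, and a five-year
#' generation length.
#'
#' @param n_loci Number of biallelic loci (default 96).
#' @param fst_founders Target multi-locus FST between founders A and B.
#' @param n_spawners_A,n_spawners_B Spawners producing the released fry.
#' @param n_fry_released Released fry per founder population.
#' @param n_lakes Lakes in the chain.
#' @param generations Discrete generations simulated after release.
#' @param deme_size Carrying capacity (offspring per generation) per lake.
#' @param creek_deme_size Carrying capacity per creek deme.
#' @param m0 Baseline per-generation probability of moving one lake
#'   downstream.
#' @param beta Extra downstream-move probability per unit true ancestry to
#'   the migratory founder A.
#' @param waterfall_rate Probability that a fish in the lowest lake passes
#'   the (one-way) waterfall into Creek I.
#' @param creek_downstream_rate Probability of moving Creek I -> Creek II.
#' @param creek_fst Target pre-release FST between the two native creeks.
#' @param diag_share Fraction of founder-diagnostic loci whose alleles are
#'   also naturally present in Creek II at low frequency.
#' @param generation_length_years Years per generation.
#' @param seed Default RNG seed carried by the config.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_loci = 96, fst_founders = 0.40,
                       n_spawners_A = 100, n_spawners_B = 17,
                       n_fry_released = 1000, n_lakes = 7, generations = 6,
                       deme_size = 300, creek_deme_size = 200,
                       m0 = 0.1, beta = 0.3, waterfall_rate = 0.005,
                       creek_downstream_rate = 0.02, creek_fst = 0.21,
                       diag_share = 0.3, generation_length_years = 5,
                       seed = 1L) {
  cfg <- list(n_loci = n_loci, fst_founders = fst_founders,
              n_spawners_A = n_spawners_A, n_spawners_B = n_spawners_B,
              n_fry_released = n_fry_released, n_lakes = n_lakes,
              generations = generations, deme_size = deme_size,
              creek_deme_size = creek_deme_size, m0 = m0, beta = beta,
              waterfall_rate = waterfall_rate,
              creek_downstream_rate = creek_downstream_rate,
              creek_fst = creek_fst, diag_share = diag_share,
              generation_length_years = generation_length_years,
              seed = seed)
  rates <- c(cfg$m0, cfg$beta, cfg$waterfall_rate, cfg$creek_downstream_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]")
  if (any(c(cfg$n_loci, cfg$n_spawners_A, cfg$n_spawners_B, cfg$n_fry_released,
            cfg$n_lakes, cfg$generations, cfg$deme_size,
            cfg$creek_deme_size) < 1)) stop("sizes must be >= 1")
  if (cfg$fst_founders <= 0 || cfg$fst_founders >= 1 ||
      cfg$creek_fst <= 0 || cfg$creek_fst >= 1)
    stop("fst targets must be in (0,1)")
  class(cfg) <- "sim_config"
  cfg
}

# Parametric (infinite-sample) multi-locus Weir-Cockerham theta between two
# populations given their per-locus allele frequencies.
theta_from_freqs <- function(f1, f2) {
  pbar <- (f1 + f2) / 2
  s2 <- (f1 - f2)^2 / 2
  num <- s2
  den <- s2 / 2 + pbar * (1 - pbar)
  sum(num) / sum(den)
}

# Draw Balding-Nichols population frequencies from ancestral p with
# divergence F, using pre-drawn uniforms so the draw is a deterministic,
# monotone-ish function of F (common random numbers for bisection).
bn_freqs <- function(p_anc, F, u) {
  if (F <= 0) return(p_anc)
  shape1 <- p_anc * (1 - F) / F
  shape2 <- (1 - p_anc) * (1 - F) / F
  # tiny shapes (strong divergence) trip qbeta precision warnings; the
  # resulting near-fixed frequencies are fine for our purposes and the
  # realized theta is verified downstream
  suppressWarnings(stats::qbeta(u, shape1, shape2))
}

# Bisection on the Balding-Nichols divergence parameter so that the realized
# parametric theta between the two drawn populations hits `target`.
calibrate_bn <- function(p_anc, u1, u2, target, tol = 1e-4, max_iter = 80) {
  fn <- function(F) {
    theta_from_freqs(bn_freqs(p_anc, F, u1), bn_freqs(p_anc, F, u2)) - target
  }
  lo <- 1e-6; hi <- 0.98
  if (fn(lo) > 0 || fn(hi) < 0) stop("FST calibration failed: target not bracketed")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- fn(mid)
    if (abs(v) < tol) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(fn(mid)) > 0.02) stop("FST calibration failed to converge")
  mid
}

#' Simulate founder and native-creek allele frequencies
#'
#' Per-locus ancestral frequencies are uniform on (0.05, 0.95); each
#' population pair (founders A/B, native creeks I/II) is drawn from a
#' Balding-Nichols beta model whose divergence parameter is calibrated by
#' bisection so the realized parametric multi-locus Weir-Cockerham theta
#' matches the configured target. The first locus is made diagnostic (fixed
#' reference in A and Creek I, fixed alternate in B, polymorphic in
#' Creek II), and a \code{diag_share} fraction of strongly divergent
#' founder loci also segregate at low frequency in Creek II, emulating a
#' natively polymorphic diagnostic marker.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed RNG seed (default: \code{cfg$seed}).
#' @return An \code{\link{allele_freq_table}} with rows A, B, CreekI_pre,
#'   CreekII_pre (population frequencies: copy counts are Inf).
#' @export
simulate_founder_freqs <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  L <- cfg$n_loci
  p_anc <- stats::runif(L, 0.05, 0.95)
  uA <- stats::runif(L); uB <- stats::runif(L)
  p_anc_c <- stats::runif(L, 0.05, 0.95)
  u1 <- stats::runif(L); u2 <- stats::runif(L)
  Fab <- calibrate_bn(p_anc, uA, uB, cfg$fst_founders)
  fA <- bn_freqs(p_anc, Fab, uA)
  fB <- bn_freqs(p_anc, Fab, uB)
  Fc <- calibrate_bn(p_anc_c, u1, u2, cfg$creek_fst)
  fC1 <- bn_freqs(p_anc_c, Fc, u1)
  fC2 <- bn_freqs(p_anc_c, Fc, u2)
  # diagnostic locus: fixed contrast between A and B, fixed in Creek I,
  # naturally polymorphic in Creek II
  fA[1] <- 1; fB[1] <- 0; fC1[1] <- 1; fC2[1] <- 0.9
  # a share of founder-diagnostic alleles segregate at low frequency in
  # Creek II even before the release
  diag <- which(abs(fA - fB) > 0.8)
  diag <- setdiff(diag, 1L)
  if (length(diag) > 0 && cfg$diag_share > 0) {
    take <- diag[seq_len(ceiling(length(diag) * cfg$diag_share))]
    fC2[take] <- pmin(pmax(fC2[take], 0.05), 0.95)
  }
  freq <- rbind(A = fA, B = fB, CreekI_pre = fC1, CreekII_pre = fC2)
  colnames(freq) <- paste0("L", seq_len(L))
  copies <- matrix(Inf, 4, L, dimnames = dimnames(freq))
  allele_freq_table(freq, copies)
}

# n diploid genotypes drawn from per-locus frequencies (rows = individuals).
draw_diploids <- function(freq, n) {
  L <- length(freq)
  m <- matrix(stats::rbinom(n * L, 2L, rep(freq, each = n)), n, L)
  storage.mode(m) <- "integer"
  m
}

# Mendelian offspring: one gamete from each of two parent dosage rows.
mate <- function(dos, mothers, fathers) {
  P1 <- dos[mothers, , drop = FALSE] / 2
  P2 <- dos[fathers, , drop = FALSE] / 2
  g1 <- matrix(stats::rbinom(length(P1), 1L, P1), nrow(P1), ncol(P1))
  g2 <- matrix(stats::rbinom(length(P2), 1L, P2), nrow(P2), ncol(P2))
  m <- g1 + g2
  storage.mode(m) <- "integer"
  m
}

# Random-mating parent pairs (no selfing when >= 2 parents are available).
draw_parents <- function(n_parents, n_off) {
  mothers <- sample.int(n_parents, n_off, replace = TRUE)
  fathers <- sample.int(n_parents, n_off, replace = TRUE)
  if (n_parents >= 2L) {
    while (any(clash <- fathers == mothers)) {
      fathers[clash] <- sample.int(n_parents, sum(clash), replace = TRUE)
    }
  }
  cbind(mothers, fathers)
}

#' Simulate the release and downstream spread
#'
#' Discrete non-overlapping generations. Founders are sampled as diploids
#' from the A/B frequencies through the spawner bottlenecks; the released
#' fry (generation 0) start in the uppermost lake while the two native creek
#' demes are initialized from their own frequencies and run in parallel.
#' Each generation, adults first migrate -- a fish in lake i moves to lake
#' i+1 with probability min(1, m0 + beta * true_Q_A) and may keep moving from
#' its new position (downstream-biased cascade); from the lowest lake it
#' passes the one-way waterfall into Creek I with probability
#' \code{waterfall_rate}, and Creek I fish drop to Creek II with
#' \code{creek_downstream_rate} -- then each deme's adults mate at random
#' (two distinct parents) to produce \code{deme_size} offspring, with
#' Mendelian transmission and \code{true_Q} equal to the parental mean. The
#' final cohort also migrates so that every cohort has an adult location.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param founders Optional \code{allele_freq_table} from
#'   \code{\link{simulate_founder_freqs}} (rebuilt from \code{cfg} if NULL).
#' @param seed RNG seed (default \code{cfg$seed}).
#' @return A list of class \code{sim_result}: \code{genotypes}
#'   (a \code{\link{genotype_matrix}} of all individuals, pop label = adult
#'   deme, year = release year + 5 * generation), \code{truth} (data.frame
#'   id, Q_A, Q_B, Q_CreekI_pre, Q_CreekII_pre, deme, natal_deme,
#'   generation), \code{founders}, \code{config}.
#' @export
simulate_release_and_spread <- function(cfg = sim_config(), founders = NULL,
                                        seed = cfg$seed) {
  if (is.null(founders)) founders <- simulate_founder_freqs(cfg, seed = seed)
  set.seed(stage_seed(seed, "spread"))
  L <- cfg$n_loci
  lakes <- paste0("Lake", seq_len(cfg$n_lakes))
  demes <- c(lakes, "CreekI", "CreekII")
  n_demes <- length(demes)
  sources <- c("A", "B", "CreekI_pre", "CreekII_pre")

  # founder bottlenecks and released fry
  spA <- draw_diploids(founders$freq["A", ], cfg$n_spawners_A)
  spB <- draw_diploids(founders$freq["B", ], cfg$n_spawners_B)
  prA <- draw_parents(cfg$n_spawners_A, cfg$n_fry_released)
  prB <- draw_parents(cfg$n_spawners_B, cfg$n_fry_released)
  fryA <- mate(spA, prA[, 1], prA[, 2])
  fryB <- mate(spB, prB[, 1], prB[, 2])

  qmat <- function(k, n) {
    m <- matrix(0, n, 4, dimnames = list(NULL, sources)); m[, k] <- 1; m
  }
  cI <- draw_diploids(founders$freq["CreekI_pre", ], cfg$creek_deme_size)
  cII <- draw_diploids(founders$freq["CreekII_pre", ], cfg$creek_deme_size)

  # current cohort state
  dos <- rbind(fryA, fryB, cI, cII)
  Q <- rbind(qmat(1, nrow(fryA)), qmat(2, nrow(fryB)),
             qmat(3, nrow(cI)), qmat(4, nrow(cII)))
  pos <- c(rep(1L, nrow(fryA) + nrow(fryB)),
           rep(n_demes - 1L, nrow(cI)), rep(n_demes, nrow(cII)))
  natal <- pos
  gen <- 0L

  rec_dos <- list(); rec_truth <- list()
  counter <- 0L
  record <- function(dos, Q, pos, natal, gen) {
    ids <- sprintf("g%d_%s_%d", gen, demes[natal],
                   seq_len(nrow(dos)) + counter)
    counter <<- counter + nrow(dos)
    rownames(dos) <- ids
    rec_dos[[length(rec_dos) + 1L]] <<- dos
    rec_truth[[length(rec_truth) + 1L]] <<- data.frame(
      id = ids, Q, deme = demes[pos], natal_deme = demes[natal],
      generation = gen, stringsAsFactors = FALSE)
  }

  # downstream cascade: a fish that moves may attempt a further hop from its
  # new position within the same generation; everyone gets one attempt per
  # position reached, so the loop is bounded by the number of demes
  migrate <- function(pos, Q) {
    k_lake <- cfg$n_lakes
    active <- rep(TRUE, length(pos))
    repeat {
      pmove <- rep(0, length(pos))
      cand <- active & pos < k_lake
      pmove[cand] <- pmin(1, cfg$m0 + cfg$beta * Q[cand, "A"])
      cand <- active & pos == k_lake
      pmove[cand] <- cfg$waterfall_rate
      cand <- active & pos == n_demes - 1L
      pmove[cand] <- cfg$creek_downstream_rate
      mv <- stats::runif(length(pos)) < pmove
      if (!any(mv)) break
      pos[mv] <- pos[mv] + 1L
      active <- mv
    }
    pos
  }

  for (g in seq_len(cfg$generations)) {
    occupied_before <- sort(unique(pos))
    pos <- migrate(pos, Q)
    gone <- setdiff(occupied_before, unique(pos))
    if (length(gone) > 0)
      stop(sprintf("deme %s went extinct at generation %d",
                   demes[gone[1]], g))
    # record the parental cohort at its adult (post-migration) location
    record(dos, Q, pos, natal, gen)
    # reproduction
    new_dos <- list(); new_Q <- list(); new_pos <- integer(0)
    for (d in sort(unique(pos))) {
      idx <- which(pos == d)
      cap <- if (d <= cfg$n_lakes) cfg$deme_size else cfg$creek_deme_size
      pr <- draw_parents(length(idx), cap)
      new_dos[[length(new_dos) + 1L]] <-
        mate(dos[idx, , drop = FALSE], pr[, 1], pr[, 2])
      new_Q[[length(new_Q) + 1L]] <-
        (Q[idx, , drop = FALSE][pr[, 1], , drop = FALSE] +
         Q[idx, , drop = FALSE][pr[, 2], , drop = FALSE]) / 2
      new_pos <- c(new_pos, rep(d, cap))
    }
    dos <- do.call(rbind, new_dos)
    Q <- do.call(rbind, new_Q)
    pos <- new_pos
    natal <- pos
    gen <- g
  }
  # the final cohort migrates too, so creek samples can contain immigrants
  pos <- migrate(pos, Q)
  record(dos, Q, pos, natal, gen)

  all_dos <- do.call(rbind, rec_dos)
  colnames(all_dos) <- colnames(founders$freq)
  truth <- do.call(rbind, rec_truth)
  names(truth)[2:5] <- paste0("Q_", sources)
  gm <- genotype_matrix(all_dos, truth$deme,
                        year = 1979 + cfg$generation_length_years * truth$generation,
                        meta = truth[, c("generation", "natal_deme")])
  structure(list(genotypes = gm, truth = truth, founders = founders,
                 config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d individuals over %d generations, %d loci\n",
              nrow(x$truth), max(x$truth$generation), ncol(x$genotypes$dosage)))
  invisible(x)
}

#' Sample individuals from a simulated deme at a generation
#'
#' Samples without replacement from the fish of one cohort whose adult
#' (post-migration) location is the requested deme, carrying the truth
#' records along for recovery tests.
#'
#' @param sim A \code{sim_result}.
#' @param deme Deme name (e.g. "Lake3", "CreekI").
#' @param generation Cohort generation.
#' @param n Sample size (error if it exceeds the deme census).
#' @param seed Optional RNG seed.
#' @param by Sample fish by their adult (post-migration) location
#'   (\code{"deme"}, the default; immigrants present) or by their natal deme
#'   (\code{"natal"}; the locally produced cohort).
#' @return A \code{\link{genotype_matrix}} with attribute \code{truth}.
#' @export
sample_population <- function(sim, deme, generation, n, seed = NULL,
                              by = c("deme", "natal")) {
  by <- match.arg(by)
  if (!is.null(seed)) set.seed(seed)
  where <- if (by == "deme") sim$truth$deme else sim$truth$natal_deme
  idx <- which(where == deme & sim$truth$generation == generation)
  if (length(idx) == 0L)
    stop(sprintf("deme %s is not populated at generation %d", deme, generation))
  if (n > length(idx))
    stop(sprintf("n = %d exceeds deme census %d", n, length(idx)))
  take <- sort(sample(idx, n))
  gm <- subset_genotypes(sim$genotypes, take)
  attr(gm, "truth") <- sim$truth[take, , drop = FALSE]
  gm
}
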