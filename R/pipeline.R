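# End-to-end monitoring pipeline: simulate -> baselines -> ancestry ->
# diversity / divergence -> Ne -> indicators, with a run manifest.

#' Pipeline run configuration
#'
#' Bundles the simulation settings, sampling design, thresholds and runtime
#' knobs for \code{\link{run_monitoring}}. Defaults mirror the monitoring
#' design the simulator emulates: creek demes sampled before the release and
#' at two later time points, lakes sampled at the final generation.
#'
#' @param sim A \code{\link{sim_config}}.
#' @param sample_generations Generations at which the creeks are sampled
#'   (first entry = pre-release baseline).
#' @param creek_sample_n Creek sample size at the post-release time points.
#' @param baseline_n_creek Pre-release baseline sample sizes (Creek I, II).
#' @param lake_sample_n Per-lake sample size at the final generation.
#' @param baseline_n_ab Cap on the A/B baseline sizes selected by
#'   diagnostic-locus homozygosity.
#' @param n_perm Permutations for F-statistics and F_IS tests.
#' @param tree_boot Bootstrap replicates for the NJ tree.
#' @param anthropogenic Anthropogenic-cause flag passed to the dH indicator
#'   (TRUE here: the release is a known anthropogenic event).
#' @param seed Global seed; fanned out to stages via
#'   \code{\link{stage_seed}}.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(), sample_generations = c(0, 4, 6),
                       creek_sample_n = 60, baseline_n_creek = c(135, 127),
                       lake_sample_n = 60, baseline_n_ab = c(110, 108),
                       n_perm = 199, tree_boot = 200, anthropogenic = TRUE,
                       seed = 1L) {
  sample_generations <- sort(unique(sample_generations))
  if (max(sample_generations) > sim$generations)
    stop("sample_generations exceed the simulated horizon")
  structure(list(sim = sim, sample_generations = sample_generations,
                 creek_sample_n = creek_sample_n,
                 baseline_n_creek = baseline_n_creek,
                 lake_sample_n = lake_sample_n,
                 baseline_n_ab = baseline_n_ab, n_perm = n_perm,
                 tree_boot = tree_boot, anthropogenic = anthropogenic,
                 seed = seed),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[troutmon] %s: %s", stage, sprintf(...)))
}

combine_genotypes <- function(gms, labels) {
  d <- do.call(rbind, lapply(gms, function(g) g$dosage))
  pop <- unlist(mapply(function(g, l) rep(l, n_individuals(g)), gms, labels,
                       SIMPLIFY = FALSE))
  rownames(d) <- make.unique(rownames(d))
  genotype_matrix(d, pop)
}

#' Run the full genetic-monitoring workflow on simulated data
#'
#' Simulates the release, builds the four baselines (A and B by
#' diagnostic-locus homozygosity in the first post-release cohort, the two
#' creeks from their pre-release samples), estimates supervised ancestry for
#' lake and creek samples, computes diversity and F-statistics, effective
#' sizes (LD per time point, temporal between time points), classifies the
#' three indicators and writes all artifacts plus a manifest with file
#' digests.
#'
#' @param cfg A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_monitoring <- function(cfg = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  seed <- cfg$seed
  gl <- cfg$sim$generation_length_years

  ## --- simulate -----------------------------------------------------------
  founders <- simulate_founder_freqs(cfg$sim, seed = stage_seed(seed, "founders"))
  sim <- simulate_release_and_spread(cfg$sim, founders,
                                     seed = stage_seed(seed, "spread"))
  stage_log("simulate", "%d individuals, %d loci", nrow(sim$truth),
            cfg$sim$n_loci)

  ## --- samples ------------------------------------------------------------
  set.seed(stage_seed(seed, "samples"))
  diag_locus <- colnames(sim$genotypes$dosage)[1]
  lake1_g1 <- sample_population(sim, "Lake1", 1,
                                n = min(cfg$sim$deme_size,
                                        sum(sim$truth$deme == "Lake1" &
                                            sim$truth$generation == 1)))
  gmA <- select_baseline_by_diagnostic(lake1_g1, diag_locus, "ref")
  gmB <- select_baseline_by_diagnostic(lake1_g1, diag_locus, "alt")
  gmA <- subset_genotypes(gmA, seq_len(min(cfg$baseline_n_ab[1], n_individuals(gmA))))
  gmB <- subset_genotypes(gmB, seq_len(min(cfg$baseline_n_ab[2], n_individuals(gmB))))
  g_pre <- cfg$sample_generations[1]
  creekI_pre <- sample_population(sim, "CreekI", g_pre,
                                  min(cfg$baseline_n_creek[1], cfg$sim$creek_deme_size))
  creekII_pre <- sample_population(sim, "CreekII", g_pre,
                                   min(cfg$baseline_n_creek[2], cfg$sim$creek_deme_size))
  baselines <- list(
    baseline_from_genotypes(gmA, "A", "diagnostic-locus homozygotes"),
    baseline_from_genotypes(gmB, "B", "diagnostic-locus homozygotes"),
    baseline_from_genotypes(creekI_pre, "CreekI_pre", "pre-release sample"),
    baseline_from_genotypes(creekII_pre, "CreekII_pre", "pre-release sample"))
  stage_log("baselines", "A n=%d, B n=%d, CreekI n=%d, CreekII n=%d",
            n_individuals(gmA), n_individuals(gmB),
            n_individuals(creekI_pre), n_individuals(creekII_pre))

  g_final <- cfg$sim$generations
  lakes <- paste0("Lake", seq_len(cfg$sim$n_lakes))
  lake_samples <- list()
  for (lk in lakes) {
    avail <- sum(sim$truth$deme == lk & sim$truth$generation == g_final)
    if (avail == 0) next
    lake_samples[[lk]] <- sample_population(sim, lk, g_final,
                                            min(cfg$lake_sample_n, avail))
  }
  post_gens <- cfg$sample_generations[-1]
  creek_samples <- list()
  for (ck in c("CreekI", "CreekII")) {
    for (g in post_gens) {
      avail <- sum(sim$truth$deme == ck & sim$truth$generation == g)
      key <- sprintf("%s_g%d", ck, g)
      creek_samples[[key]] <- sample_population(sim, ck, g,
                                                min(cfg$creek_sample_n, avail))
    }
  }
  creek_pre <- list(CreekI = creekI_pre, CreekII = creekII_pre)

  ## --- ancestry -----------------------------------------------------------
  q_rows <- list(); call_rows <- list(); intro_rows <- list()
  for (lk in names(lake_samples)) {
    q <- estimate_q_supervised(lake_samples[[lk]], baselines[1:2])
    q$population <- lk
    q$group <- classify_lake_group(q$Q_A)
    q_rows[[lk]] <- q
  }
  for (key in names(creek_samples)) {
    ck <- sub("_g\\d+$", "", key)
    q <- estimate_q_supervised(creek_samples[[key]], baselines)
    q$population <- key
    calls <- detect_immigrants(q, paste0(ck, "_pre"),
                               upstream_id = if (ck == "CreekII") "CreekI_pre" else NULL)
    q$group <- calls$group
    q_rows[[key]] <- q
    call_rows[[key]] <- cbind(population = key, calls)
    ir <- introgression_rate(q, calls)
    intro_rows[[key]] <- data.frame(population = key,
                                    introgression = ir$introgression,
                                    total_alien = ir$total_alien,
                                    n_local = ir$n_local,
                                    n_immigrant = ir$n_immigrant,
                                    stringsAsFactors = FALSE)
  }
  q_all <- do.call(rbind, lapply(q_rows, function(x) {
    x[setdiff(names(x), "group")] -> y
    cols <- c("population", "id", grep("^Q_", names(y), value = TRUE),
              "loglik", "n_loci_used")
    for (s in c("Q_A", "Q_B", "Q_CreekI_pre", "Q_CreekII_pre"))
      if (!s %in% names(y)) y[[s]] <- NA_real_
    y[, c("population", "id", "Q_A", "Q_B", "Q_CreekI_pre", "Q_CreekII_pre",
          "loglik", "n_loci_used")]
  }))
  calls_all <- do.call(rbind, c(
    lapply(names(lake_samples), function(lk) data.frame(
      population = lk, id = q_rows[[lk]]$id, group = q_rows[[lk]]$group,
      Q_local = NA_real_, stringsAsFactors = FALSE)),
    unname(call_rows)))
  intro <- do.call(rbind, intro_rows)
  lake_means <- vapply(names(lake_samples), function(lk) mean(q_rows[[lk]]$Q_A),
                       numeric(1))
  cline <- if (length(lake_means) >= 3)
    cline_correlation(lake_means, seq_along(lake_means)) else NULL
  stage_log("ancestry", "%d lake + %d creek samples assigned",
            length(lake_samples), length(creek_samples))

  ## --- diversity / divergence ---------------------------------------------
  all_samples <- c(list(A = gmA, B = gmB,
                        CreekI_g0 = creekI_pre, CreekII_g0 = creekII_pre),
                   lake_samples, creek_samples)
  big <- combine_genotypes(all_samples, names(all_samples))
  div <- heterozygosity(big)
  ar <- allelic_richness(big)
  div$A_R <- ar$A_R[match(paste(div$pop, div$locus), paste(ar$pop, ar$locus))]
  fst <- wc_fstats(big, n_perm = cfg$n_perm,
                   seed = stage_seed(seed, "fst_perm"))
  tree <- bootstrap_tree(big, B = max(100, cfg$tree_boot),
                         seed = stage_seed(seed, "tree"))
  stage_log("divergence", "overall theta = %.3f", fst$overall$theta)

  ## --- effective size ------------------------------------------------------
  ne_records <- list()
  ne_ld_by <- list()
  for (ck in c("CreekI", "CreekII")) {
    for (g in cfg$sample_generations) {
      gmx <- if (g == g_pre) creek_pre[[ck]] else creek_samples[[sprintf("%s_g%d", ck, g)]]
      est <- tryCatch(ne_ld(gmx), error = function(e) NULL)
      key <- sprintf("%s_g%d", ck, g)
      ne_ld_by[[key]] <- if (is.null(est)) NA_real_ else est$estimate
      if (!is.null(est))
        ne_records[[paste0("LD_", key)]] <- c(list(population = ck, generation = g),
                                              est[c("method", "estimate", "ci",
                                                    "r2", "r2_prime", "s",
                                                    "n_loci", "n_pairs")])
    }
  }
  periods <- list()
  gens <- cfg$sample_generations
  for (i in seq_len(length(gens) - 1)) for (j in seq(i + 1, length(gens)))
    periods[[length(periods) + 1]] <- c(gens[i], gens[j])
  ne_ind <- list()
  for (ck in c("CreekI", "CreekII")) {
    for (pr in periods) {
      gm0 <- if (pr[1] == g_pre) creek_pre[[ck]] else creek_samples[[sprintf("%s_g%d", ck, pr[1])]]
      gm1 <- creek_samples[[sprintf("%s_g%d", ck, pr[2])]]
      t_gen <- pr[2] - pr[1]
      est <- tryCatch(ne_temporal(gm0, gm1, t_gen), error = function(e) NULL)
      period <- sprintf("g%d-g%d", pr[1], pr[2])
      if (!is.null(est))
        ne_records[[sprintf("temporal_%s_%s", ck, period)]] <-
          c(list(population = ck, period = period),
            est[c("method", "estimate", "ci", "fs", "fs_prime", "t", "n_loci")])
      hm <- harmonic_mean_ne(c(ne_ld_by[[sprintf("%s_g%d", ck, pr[1])]],
                               ne_ld_by[[sprintf("%s_g%d", ck, pr[2])]]))
      ne_v <- if (is.null(est)) NA_real_ else est$estimate
      ne_ind[[sprintf("%s_%s", ck, period)]] <-
        list(population = ck, period = period, ne_v = ne_v,
             ne_ld = hm$harmonic_mean)
    }
  }
  stage_log("ne", "%d estimates", length(ne_records))

  ## --- indicators ----------------------------------------------------------
  statuses <- list()
  measures <- c("H_E", "H_O", "A_n", "A_R")
  for (ck in c("CreekI", "CreekII")) {
    for (pr in periods) {
      period <- sprintf("g%d-g%d", pr[1], pr[2])
      key0 <- sprintf("%s_g%d", ck, pr[1]); key1 <- sprintf("%s_g%d", ck, pr[2])
      lab0 <- if (pr[1] == g_pre) sprintf("%s_g0", ck) else key0
      d0 <- div[div$pop == lab0, ]; d1 <- div[div$pop == key1, ]
      for (ms in measures) {
        v0 <- d0[[ms]]; v1 <- d1[[ms]]
        pc <- paired_change_test(v0, v1, measure = ms)
        st <- delta_h_classify(mean(v0, na.rm = TRUE), mean(v1, na.rm = TRUE),
                               t_years = (pr[2] - pr[1]) * gl,
                               significant = pc$significant,
                               anthropogenic = cfg$anthropogenic,
                               measure = ms, period = period)
        st$population <- ck
        statuses[[length(statuses) + 1]] <- st
      }
      ni <- ne_ind[[sprintf("%s_%s", ck, period)]]
      st <- ne_classify(ni$ne_v, ni$ne_ld, period = period)
      st$population <- ck
      statuses[[length(statuses) + 1]] <- st
    }
  }
  # dFST between the two creeks per period, significance by locus-paired
  # Wilcoxon on per-locus theta
  for (pr in periods) {
    period <- sprintf("g%d-g%d", pr[1], pr[2])
    theta_at <- function(g) {
      gm2 <- combine_genotypes(
        list(if (g == g_pre) creek_pre$CreekI else creek_samples[[sprintf("CreekI_g%d", g)]],
             if (g == g_pre) creek_pre$CreekII else creek_samples[[sprintf("CreekII_g%d", g)]]),
        c("CreekI", "CreekII"))
      wc_fstats(gm2, pairwise = FALSE, n_perm = 0)
    }
    f0 <- theta_at(pr[1]); f1 <- theta_at(pr[2])
    pc <- paired_change_test(f0$per_locus$theta, f1$per_locus$theta,
                             measure = "theta")
    st <- delta_fst_classify(max(f0$overall$theta, 1e-4),
                             max(f1$overall$theta, 1e-4),
                             significant = pc$significant, period = period)
    st$population <- "CreekI~CreekII"
    statuses[[length(statuses) + 1]] <- st
  }
  report <- indicator_report(statuses)
  stage_log("indicators", "%d cells classified", nrow(report))

  ## --- artifacts -----------------------------------------------------------
  paths <- list(
    diversity = file.path(out_dir, "diversity.tsv"),
    fstats = file.path(out_dir, "fstats.tsv"),
    q_matrix = file.path(out_dir, "q_matrix.tsv"),
    group_calls = file.path(out_dir, "group_calls.tsv"),
    introgression = file.path(out_dir, "introgression.tsv"),
    ne = file.path(out_dir, "ne_estimates.json"),
    indicators = file.path(out_dir, "indicators.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    manifest = file.path(out_dir, "manifest.json"))
  write_tsv(as.data.frame(div), paths$diversity)
  pw <- fst$pairwise
  fst_df <- data.frame(pop1 = rownames(pw)[row(pw)[upper.tri(pw)]],
                       pop2 = colnames(pw)[col(pw)[upper.tri(pw)]],
                       theta = pw[upper.tri(pw)],
                       p_value = fst$pairwise_p[upper.tri(pw)],
                       stringsAsFactors = FALSE)
  write_tsv(fst_df, paths$fstats)
  write_tsv(q_all, paths$q_matrix)
  write_tsv(calls_all, paths$group_calls)
  write_tsv(intro, paths$introgression)
  jsonlite::write_json(ne_records, paths$ne, auto_unbox = TRUE, digits = NA,
                       na = "string")
  write_tsv(as.data.frame(report), paths$indicators)
  write_tree_newick(tree, paths$tree)
  digests <- vapply(paths[names(paths) != "manifest"],
                    function(p) unname(tools::md5sum(p)), character(1))
  manifest <- list(package = "troutmon",
                   version = as.character(utils::packageVersion("troutmon")),
                   seed = seed,
                   config_digest = unname(digest_object(cfg)),
                   files = as.list(digests))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  stage_log("done", "artifacts in %s (%.1f s)", out_dir,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(sim = sim, baselines = baselines, q = q_all,
                 calls = calls_all, introgression = intro, diversity = div,
                 fstats = fst, tree = tree, ne = ne_records, cline = cline,
                 report = report, manifest = manifest, paths = paths))
}

digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(x), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
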