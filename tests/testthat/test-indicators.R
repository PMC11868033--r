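test_that("heterozygosity loss per generation follows 1/(2Ne)", {
  expect_equal(het_loss_per_generation(10), 0.05)
  expect_equal(1 - het_loss_per_generation(10), 0.95)
  expect_equal(het_loss_per_generation(50), 0.01)
  expect_error(het_loss_per_generation(0), "ne > 0")
})

test_that("dH classification implements the retention bands", {
  # no change -> green, horizontal
  same <- delta_h_classify(0.3, 0.3, 30, significant = FALSE)
  expect_equal(same$status, "green")
  expect_equal(same$direction, "horizontal")
  expect_equal(same$metric, 1)
  # 0.30 -> 0.27 over 30 years: retention_100 = 0.9^(10/3) ~ 0.704 -> red
  red <- delta_h_classify(0.30, 0.27, 30, significant = TRUE)
  expect_equal(red$metric, 0.9^(10 / 3), tolerance = 1e-12)
  expect_lt(red$metric, 0.75)
  expect_equal(red$status, "red")
  expect_equal(red$direction, "down")
  # same magnitude of change but not significant -> green
  expect_equal(delta_h_classify(0.30, 0.27, 30, significant = FALSE)$status,
               "green")
  # significant increase with anthropogenic information -> yellow
  up <- delta_h_classify(0.25, 0.30, 20, significant = TRUE,
                         anthropogenic = TRUE)
  expect_equal(up$status, "yellow")
  expect_equal(up$direction, "up")
  # without anthropogenic attribution -> green with note
  up2 <- delta_h_classify(0.25, 0.30, 20, significant = TRUE)
  expect_equal(up2$status, "green")
  expect_match(up2$note, "increase")
  # band edges: retention exactly 0.95 green, just below yellow, 0.75 yellow
  r95 <- delta_h_classify(1, 0.95, 100, significant = TRUE)
  expect_equal(r95$status, "green")
  r75 <- delta_h_classify(1, 0.75, 100, significant = TRUE)
  expect_equal(r75$status, "yellow")
  r74 <- delta_h_classify(1, 0.7499, 100, significant = TRUE)
  expect_equal(r74$status, "red")
  expect_error(delta_h_classify(0, 0.3, 30, TRUE), "positive")
})

test_that("retention compounds consistently across sub-periods", {
  # classifying t -> t' then t' -> t'' at a constant rate equals direct t -> t''
  b <- 0.40; mid <- 0.38; a <- 0.361
  r1 <- retention_100(b, mid, 15)
  r2 <- retention_100(mid, a, 15)
  direct <- retention_100(b, a, 30)
  expect_equal((r1 * r2)^(1 / 2), direct, tolerance = 1e-12)
  # monotone in after/before and in 1/t
  expect_gt(retention_100(0.3, 0.29, 30), retention_100(0.3, 0.28, 30))
  expect_gt(retention_100(0.3, 0.27, 60), retention_100(0.3, 0.27, 30))
})

test_that("Ne indicator applies the max rule and the 50/500 thresholds", {
  # printed worked cases: max(79, 72) = 79 -> yellow; max(23, 13) = 23 -> red
  y <- ne_classify(79, 72)
  expect_equal(y$estimate, 79)
  expect_equal(y$status, "yellow")
  r <- ne_classify(23, 13)
  expect_equal(r$estimate, 23)
  expect_equal(r$status, "red")
  expect_equal(ne_classify(600, 100)$status, "green")
  # boundary conventions: exactly 50 red, exactly 500 yellow
  expect_equal(ne_classify(50, 10)$status, "red")
  expect_equal(ne_classify(500, 10)$status, "yellow")
  expect_equal(ne_classify(NA, 30)$estimate, 30)
  expect_error(ne_classify(NA, NA), "undefined")
})

test_that("dFST indicator maps FST to migrants and classifies the change", {
  # 0.21 -> 0.16 means ~ +40% migrants: below the 50% warning threshold
  g <- delta_fst_classify(0.21, 0.16, significant = TRUE)
  expect_equal(round(g$pct_change), 40)
  expect_equal(g$status, "green")
  expect_equal(g$nm_before, (1 / 0.21 - 1) / 4, tolerance = 1e-12)
  # no change -> green
  expect_equal(delta_fst_classify(0.2, 0.2, TRUE)$status, "green")
  # 0.20 -> 0.10: Nm 1.0 -> 2.25, +125% -> red
  r <- delta_fst_classify(0.20, 0.10, significant = TRUE)
  expect_equal(r$pct_change, 125, tolerance = 1e-9)
  expect_equal(r$status, "red")
  # yellow bands on both sides (0.20 -> 0.135 is ~ +60% gene flow)
  expect_equal(delta_fst_classify(0.2, 0.135, TRUE)$status, "yellow")
  expect_equal(delta_fst_classify(0.135, 0.2, TRUE)$status, "yellow") # ~ -37%
  expect_equal(delta_fst_classify(0.2, 0.5, TRUE)$status, "red")      # < -50%
  # non-significant changes never warn
  expect_equal(delta_fst_classify(0.20, 0.10, FALSE)$status, "green")
  expect_error(delta_fst_classify(0, 0.1, TRUE), "\\(0,1\\)")
  expect_error(delta_fst_classify(0.1, 1, TRUE), "\\(0,1\\)")
})

test_that("swapping before/after maps increases onto the reduction branch", {
  up <- delta_fst_classify(0.20, 0.12, TRUE)    # more gene flow
  dn <- delta_fst_classify(0.12, 0.20, TRUE)    # the mirrored reduction
  expect_gt(up$pct_change, 0)
  expect_lt(dn$pct_change, 0)
  expect_equal((1 + up$pct_change / 100) * (1 + dn$pct_change / 100), 1,
               tolerance = 1e-12)
})

test_that("indicator reports are complete, typed and deterministic", {
  sts <- list(delta_h_classify(0.3, 0.27, 30, TRUE, measure = "H_E",
                               period = "g0-g6"),
              ne_classify(79, 72, period = "g0-g6"),
              delta_fst_classify(0.21, 0.16, TRUE, period = "g0-g6"))
  sts <- lapply(sts, function(s) { s$population <- "CreekII"; s })
  rep1 <- indicator_report(sts)
  expect_equal(nrow(rep1), 3)
  expect_setequal(rep1$indicator, c("dH", "Ne", "dFST"))
  expect_true(all(rep1$status %in% c("green", "yellow", "red")))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_indicator_report(rep1, tsv = f1, json = f2)
  rep2 <- indicator_report(sts)
  f3 <- withr::local_tempfile()
  write_indicator_report(rep2, tsv = f3)
  expect_identical(readLines(f1), readLines(f3))
  expect_true(jsonlite::validate(paste(readLines(f2), collapse = "")))
})

test_that("classify_indicator_table routes rows to the matching classifier", {
  df <- data.frame(
    population = c("CreekII", "CreekII", "CreekI", "X"),
    period = "full",
    indicator = c("Ne", "Ne", "dH", "dFST"),
    measure = c(NA, NA, "H_E", NA),
    before = c(NA, NA, 0.30, NA),
    after = c(NA, NA, 0.27, NA),
    t_years = c(NA, NA, 30, NA),
    significant = c(NA, NA, TRUE, TRUE),
    anthropogenic = FALSE,
    ne_v = c(79, 23, NA, NA),
    ne_ld = c(72, 13, NA, NA),
    fst_before = c(NA, NA, NA, 0.21),
    fst_after = c(NA, NA, NA, 0.16),
    stringsAsFactors = FALSE)
  rep <- classify_indicator_table(df)
  expect_equal(rep$status, c("yellow", "red", "red", "green"))
  expect_equal(rep$metric[1], 79)
})
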