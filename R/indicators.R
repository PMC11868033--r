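# Traffic-light indicators for genetic diversity: dH (within-population
# change extrapolated to 100 years), Ne (50/500 thresholds on the max-rule
# estimate) and dFST (change in divergence mapped to change in gene flow).

#' Expected heterozygosity loss in one generation at effective size Ne
#'
#' The single-generation drift loss \eqn{1/(2N_e)}; e.g. at Ne = 10 only 5\%
#' is lost and 95\% retained.
#'
#' @param ne Effective population size (> 0).
#' @return Proportion of heterozygosity lost in one generation.
#' @export
het_loss_per_generation <- function(ne) {
  stopifnot(all(ne > 0))
  1 / (2 * ne)
}

#' 100-year retention under a constant proportional rate of change
#'
#' \deqn{retention_{100} = (after/before)^{100/t}}
#'
#' @param before,after Diversity measure at the two time points (before > 0).
#' @param t_years Years elapsed (> 0).
#' @return The projected 100-year retention (> 1 for increases).
#' @export
retention_100 <- function(before, after, t_years) {
  if (any(before <= 0) || any(after < 0) || any(t_years <= 0))
    stop("before and t_years must be positive, after non-negative")
  (after / before)^(100 / t_years)
}

indicator_status <- function(indicator, measure, period, before, after,
                             metric, significant, status, direction,
                             note = "") {
  structure(list(indicator = indicator, measure = measure, period = period,
                 before = before, after = after, metric = metric,
                 significant = significant, status = status,
                 direction = direction, note = note),
            class = "indicator_status")
}

#' @export
print.indicator_status <- function(x, ...) {
  cat(sprintf("%s [%s] %s: %s (metric %.3f, %s)\n", x$indicator,
              x$measure %||% "", x$period %||% "", x$status, x$metric,
              if (isTRUE(x$significant)) "significant" else "n.s."))
  invisible(x)
}

#' Classify the within-population diversity indicator (dH)
#'
#' The observed change over \code{t_years} is converted to a 100-year
#' retention assuming a constant proportional rate of change. A
#' non-significant change is green. A significant decrease is green when
#' retention over 100 years is >= 95\%, yellow in [75\%, 95\%), red below
#' 75\%. A significant increase is yellow when coupled with information on
#' anthropogenic activities, otherwise green with a note.
#'
#' @param before,after The diversity measure (H_E, H_O, A_n or A_R) at the
#'   two time points (before > 0).
#' @param t_years Monitoring period in years.
#' @param significant Is the locus-paired change significant (see
#'   \code{\link{paired_change_test}})?
#' @param anthropogenic Is there information attributing the change to
#'   anthropogenic activities? (External knowledge, supplied by the user.)
#' @param measure Measure label.
#' @param period Period label.
#' @return An \code{indicator_status} with the retention as \code{metric}.
#' @export
delta_h_classify <- function(before, after, t_years, significant,
                             anthropogenic = FALSE, measure = "H_E",
                             period = NA_character_) {
  ret <- retention_100(before, after, t_years)
  direction <- if (after > before) "up" else if (after < before) "down" else "horizontal"
  note <- ""
  if (!significant) {
    status <- "green"
  } else if (after < before) {
    status <- if (ret >= 0.95) "green" else if (ret >= 0.75) "yellow" else "red"
  } else if (after > before) {
    if (anthropogenic) {
      status <- "yellow"
      note <- "significant increase linked to anthropogenic activities"
    } else {
      status <- "green"
      note <- "significant increase, no anthropogenic attribution"
    }
  } else {
    status <- "green"
  }
  indicator_status("dH", measure, period, before, after, ret, significant,
                   status, direction, note)
}

#' Classify the effective-size indicator (50/500 rule, max rule)
#'
#' Because both the temporal and the LD estimator tend to underestimate the
#' inbreeding effective size in subdivided systems, the indicator
#' consistently uses the largest of the two estimates. Thresholds: > 500
#' green, (50, 500] yellow, <= 50 red.
#'
#' @param ne_v Temporal-method estimate (NA if unavailable).
#' @param ne_ld_harmonic Harmonic-mean LD estimate (NA if unavailable).
#' @param period Period label.
#' @return An \code{indicator_status}; \code{metric} is the max-rule
#'   estimate.
#' @export
ne_classify <- function(ne_v, ne_ld_harmonic, period = NA_character_) {
  vals <- c(ne_v, ne_ld_harmonic)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("both Ne estimates undefined")
  est <- max(vals)
  status <- if (est > 500) "green" else if (est > 50) "yellow" else "red"
  out <- indicator_status("Ne", "Ne", period, ne_v, ne_ld_harmonic, est,
                          NA, status, "horizontal")
  out$estimate <- est
  out
}

#' Classify the between-population divergence indicator (dFST)
#'
#' FST values are mapped to effective numbers of migrants with the island
#' model, \eqn{N_m = (1/F_{ST} - 1)/4}, and the percentage change in gene
#' flow is classified: a significant 50--100\% increase or 25--50\% reduction
#' is yellow; a > 100\% increase or > 50\% reduction is red; anything else
#' (or any non-significant change) is green.
#'
#' @param fst_before,fst_after FST between the monitored populations at the
#'   two time points (both in (0,1)).
#' @param significant Is the FST change significant?
#' @param period Period label.
#' @return An \code{indicator_status}; \code{metric} is the percent change
#'   in Nm, also exposed as \code{pct_change} (positive = more gene flow).
#' @export
delta_fst_classify <- function(fst_before, fst_after, significant,
                               period = NA_character_) {
  if (fst_before <= 0 || fst_before >= 1 || fst_after <= 0 || fst_after >= 1)
    stop("FST values must be in (0,1) for the island-model mapping")
  nm <- function(f) (1 / f - 1) / 4
  nm_b <- nm(fst_before); nm_a <- nm(fst_after)
  pct <- 100 * (nm_a / nm_b - 1)
  direction <- if (fst_after < fst_before) "down" else if (fst_after > fst_before) "up" else "horizontal"
  if (!significant) {
    status <- "green"
  } else if (pct > 100 || pct < -50) {
    status <- "red"
  } else if (pct >= 50 || pct <= -25) {
    status <- "yellow"
  } else {
    status <- "green"
  }
  out <- indicator_status("dFST", "FST", period, fst_before, fst_after, pct,
                          significant, status, direction)
  out$nm_before <- nm_b; out$nm_after <- nm_a; out$pct_change <- pct
  out
}

#' Assemble a machine-readable indicator report
#'
#' Flattens a list of \code{indicator_status} objects (tagged with their
#' population) into one row per population x period x indicator x measure.
#'
#' @param statuses Named or unnamed list of \code{indicator_status} objects;
#'   each may carry a \code{population} field (set by the caller).
#' @return A data.frame of class \code{indicator_report}.
#' @export
indicator_report <- function(statuses) {
  rows <- lapply(statuses, function(s) {
    data.frame(population = s$population %||% NA_character_,
               period = s$period %||% NA_character_,
               indicator = s$indicator, measure = s$measure %||% NA_character_,
               before = s$before %||% NA_real_, after = s$after %||% NA_real_,
               metric = s$metric,
               significant = s$significant %||% NA,
               status = s$status, direction = s$direction,
               note = s$note %||% "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("indicator_report", class(out))
  out
}

#' Write an indicator report as TSV and JSON
#'
#' @param report An \code{indicator_report}.
#' @param tsv,json Output paths (NULL to skip either).
#' @return Invisibly, the report.
#' @export
write_indicator_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) write_tsv(as.data.frame(report), tsv)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(report), json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

#' Classify a table of precomputed indicator inputs
#'
#' Routes each row of a statistics table to the matching classifier. The
#' table has columns \code{population, period, indicator} plus, depending on
#' the indicator: \code{measure, before, after, t_years, significant,
#' anthropogenic} (dH); \code{ne_v, ne_ld} (Ne); \code{fst_before,
#' fst_after, significant} (dFST).
#'
#' @param df Data.frame of indicator inputs (e.g. read from TSV).
#' @return An \code{indicator_report}.
#' @export
classify_indicator_table <- function(df) {
  statuses <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    s <- switch(as.character(r$indicator),
      dH = delta_h_classify(r$before, r$after, r$t_years,
                            isTRUE(as.logical(r$significant)),
                            isTRUE(as.logical(r$anthropogenic)),
                            measure = r$measure %||% "H_E",
                            period = as.character(r$period)),
      Ne = ne_classify(suppressWarnings(as.numeric(r$ne_v)),
                       suppressWarnings(as.numeric(r$ne_ld)),
                       period = as.character(r$period)),
      dFST = delta_fst_classify(r$fst_before, r$fst_after,
                                isTRUE(as.logical(r$significant)),
                                period = as.character(r$period)),
      stop(sprintf("unknown indicator '%s'", r$indicator)))
    s$population <- as.character(r$population)
    s
  })
  indicator_report(statuses)
}
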