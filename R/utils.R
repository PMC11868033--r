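`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed for a named pipeline stage
#'
#' Fans a single global seed out to per-stage seeds by hashing the stage
#' name, so that individual stages can be re-run reproducibly.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(seed) * 7919 + h) %% 2147483587L + 1L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
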