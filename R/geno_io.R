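# Genotype container and interchange-format readers/writers.
#
# Genotypes are stored as reference-allele dosages: an n_individuals x
# n_loci integer matrix with entries 0, 1, 2 or NA (missing). Missing data
# are always NA, never 0; downstream statistics are complete-case per locus.

#' Construct a diploid SNP genotype matrix
#'
#' The central data container of the package: individuals by biallelic loci,
#' coded as the dosage (0, 1, 2) of a designated reference allele per locus,
#' with \code{NA} for missing genotypes, plus per-individual population
#' labels, optional sampling years and optional metadata.
#'
#' @param dosage Integer matrix (individuals x loci) with entries in
#'   \{0, 1, 2, NA\}. Row names are individual ids, column names locus ids;
#'   defaults are generated when absent.
#' @param pop Character vector of population/locality labels, one per
#'   individual. Must be non-empty strings.
#' @param year Optional numeric vector of sampling years (NA allowed).
#' @param meta Optional data.frame of per-individual metadata (e.g.
#'   \code{distance_km}, \code{maturity}, \code{age}, \code{sex}).
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosage}, \code{pop}, \code{year}, \code{meta}.
#' @export
genotype_matrix <- function(dosage, pop, year = NULL, meta = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage); L <- ncol(dosage)
  if (n < 1L || L < 1L) stop("need at least one individual and one locus")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("ind", seq_len(n))
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("locus", seq_len(L))
  if (anyDuplicated(colnames(dosage))) stop("locus ids must be unique")
  pop <- as.character(pop)
  if (length(pop) != n) stop("pop must have one label per individual")
  if (any(is.na(pop) | !nzchar(pop))) stop("pop labels must be non-empty")
  if (is.null(year)) year <- rep(NA_real_, n)
  if (length(year) != n) stop("year must have one entry per individual")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != n) stop("meta must have one row per individual")
  }
  structure(list(dosage = dosage, pop = pop, year = as.numeric(year),
                 meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d population(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$pop))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param gm A \code{genotype_matrix}.
#' @return Integer count.
#' @export
n_individuals <- function(gm) nrow(gm$dosage)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix by individuals (and optionally loci)
#'
#' @param gm A \code{genotype_matrix}.
#' @param ind Indices or logical vector selecting individuals.
#' @param loci Optional indices/names selecting loci.
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(gm, ind, loci = NULL) {
  d <- gm$dosage[ind, , drop = FALSE]
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  genotype_matrix(d, gm$pop[ind], gm$year[ind],
                  if (!is.null(gm$meta)) gm$meta[ind, , drop = FALSE])
}

## ---------------------------------------------------------------- GENEPOP

genepop_allele_split <- function(tok) {
  w <- nchar(tok)
  if (!w %in% c(4L, 6L)) return(NULL)
  k <- w / 2L
  c(substr(tok, 1L, k), substr(tok, k + 1L, w))
}

is_missing_code <- function(code) grepl("^0+$", code)

#' Read a GENEPOP genotype file
#'
#' Supports the 2- and 3-digit diploid dialects: a title line, locus names
#' (one per line or a single comma-separated line), \code{POP} separators and
#' individual lines \code{"id , a1a2 a1a2 ..."}. Allele code 00/000 means
#' missing. Loci must be biallelic; the lexicographically smaller allele code
#' becomes the reference allele whose dosage is stored. If every individual
#' id in the file has the form \code{"pop|id"} the prefix is used as the
#' population label (the convention used by \code{\link{write_genepop}});
#' otherwise blocks are labelled POP1, POP2, ...
#'
#' @param path Path to a GENEPOP file.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  body <- lines[-1L]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP separator")
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L < 1L) stop("no locus names found")

  ids <- character(0); blocks <- integer(0)
  a1 <- list(); a2 <- list()
  block <- 0L
  for (i in seq(first_pop, length(body))) {
    if (is_pop[i]) { block <- block + 1L; next }
    line <- body[i]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L)
      stop(sprintf("malformed individual line %d: no comma", i + 1L))
    id <- trimws(substr(line, 1L, comma - 1L))
    toks <- strsplit(trimws(substring(line, comma + 1L)), "\\s+")[[1L]]
    if (length(toks) != L)
      stop(sprintf("malformed individual line %d: expected %d genotypes, got %d",
                   i + 1L, L, length(toks)))
    al <- lapply(toks, genepop_allele_split)
    if (any(vapply(al, is.null, logical(1))))
      stop(sprintf("malformed individual line %d: bad genotype token", i + 1L))
    ids <- c(ids, id); blocks <- c(blocks, block)
    a1[[length(a1) + 1L]] <- vapply(al, `[`, character(1), 1L)
    a2[[length(a2) + 1L]] <- vapply(al, `[`, character(1), 2L)
  }
  n <- length(ids)
  if (n == 0L) stop("no individuals found")
  A1 <- do.call(rbind, a1); A2 <- do.call(rbind, a2)
  dosage <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
  for (l in seq_len(L)) {
    x1 <- A1[, l]; x2 <- A2[, l]
    miss <- is_missing_code(x1) | is_missing_code(x2)
    codes <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(codes) > 2L)
      stop(sprintf("locus %s has more than two alleles (%s)",
                   loci[l], paste(codes, collapse = ", ")))
    if (length(codes) == 0L) next
    ref <- codes[1L]
    dosage[, l] <- (x1 == ref) + (x2 == ref)
    dosage[miss, l] <- NA_integer_
  }
  piped <- grepl("|", ids, fixed = TRUE)
  if (all(piped)) {
    pop <- sub("\\|.*$", "", ids)
    ids2 <- sub("^[^|]*\\|", "", ids)
    rownames(dosage) <- make.unique(ids2)
  } else {
    pop <- paste0("POP", blocks)
  }
  genotype_matrix(dosage, pop)
}

#' Write a genotype matrix as a GENEPOP file
#'
#' The reference allele is written as code 01, the alternate as 02 and
#' missing genotypes as 0000. Population labels are preserved by prefixing
#' each individual id with \code{"pop|"} (see \code{\link{read_genepop}}).
#' Note one format limitation: a locus monomorphic for the alternate allele
#' re-reads with flipped polarity (all dosage 2), because GENEPOP carries no
#' record of unobserved alleles; all frequency-based statistics are
#' unaffected.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param path Output file path.
#' @param title Title line.
#' @return Invisibly, \code{path}.
#' @export
write_genepop <- function(gm, path, title = "troutmon genotypes") {
  d <- gm$dosage
  tok <- matrix("0000", nrow(d), ncol(d))
  tok[!is.na(d) & d == 2L] <- "0101"
  tok[!is.na(d) & d == 1L] <- "0102"
  tok[!is.na(d) & d == 0L] <- "0202"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(d), con)
  pops <- unique(gm$pop)
  for (p in pops) {
    writeLines("POP", con)
    idx <- which(gm$pop == p)
    for (i in idx) {
      writeLines(paste0(p, "|", rownames(d)[i], " ,  ",
                        paste(tok[i, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

## ------------------------------------------------------------------- CSV

#' Read genotypes from a dosage CSV
#'
#' Expected header: \code{id,pop,year,<locus ids...>} (\code{year} optional);
#' genotype cells are 0, 1, 2 or NA.
#'
#' @param path Path to the CSV file.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_csv_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "pop") %in% names(df)))
    stop("CSV must have 'id' and 'pop' columns")
  year <- if ("year" %in% names(df)) df$year else NULL
  locus_cols <- setdiff(names(df), c("id", "pop", "year"))
  if (length(locus_cols) == 0L) stop("CSV contains no locus columns")
  d <- as.matrix(df[, locus_cols, drop = FALSE])
  vals <- suppressWarnings(as.integer(d))
  bad <- !is.na(d) & (is.na(vals) | !(vals %in% 0:2))
  if (any(bad)) stop("CSV dosage cells must be 0, 1, 2 or NA")
  d <- matrix(vals, nrow(df), length(locus_cols),
              dimnames = list(df$id, locus_cols))
  genotype_matrix(d, df$pop, year)
}

#' Write a genotype matrix as a dosage CSV
#'
#' Inverse of \code{\link{read_csv_genotypes}}.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_csv_genotypes <- function(gm, path) {
  df <- data.frame(id = rownames(gm$dosage), pop = gm$pop, year = gm$year,
                   gm$dosage, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

## -------------------------------------------------------------- STRUCTURE

#' Read a STRUCTURE two-row genotype file (read-only support)
#'
#' Each individual occupies two consecutive rows: \code{id pop a a a ...}
#' with one allele per locus per row, whitespace separated. An optional
#' header row gives the locus names. Loci must be biallelic; the smaller
#' allele code is the reference allele.
#'
#' @param path Path to the STRUCTURE file.
#' @param header Logical; does the first line hold locus names?
#' @param missing_code Allele code denoting missing data (default -9).
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_structure <- function(path, header = TRUE, missing_code = -9) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  loci <- NULL
  if (header) { loci <- toks[[1L]]; toks <- toks[-1L] }
  if (length(toks) %% 2L != 0L)
    stop("STRUCTURE two-row file must have an even number of genotype rows")
  n <- length(toks) / 2L
  L <- length(toks[[1L]]) - 2L
  if (L < 1L) stop("no locus columns found")
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  if (length(loci) != L) stop("header length does not match genotype rows")
  ids <- character(n); pop <- character(n)
  A1 <- matrix(NA_real_, n, L); A2 <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    r1 <- toks[[2L * i - 1L]]; r2 <- toks[[2L * i]]
    if (length(r1) != L + 2L || length(r2) != L + 2L)
      stop(sprintf("individual %d: row length mismatch", i))
    if (r1[1L] != r2[1L]) stop(sprintf("individual %d: id differs between rows", i))
    ids[i] <- r1[1L]; pop[i] <- r1[2L]
    A1[i, ] <- as.numeric(r1[-(1:2)]); A2[i, ] <- as.numeric(r2[-(1:2)])
  }
  A1[A1 == missing_code] <- NA; A2[A2 == missing_code] <- NA
  dosage <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
  for (l in seq_len(L)) {
    codes <- sort(unique(stats::na.omit(c(A1[, l], A2[, l]))))
    if (length(codes) > 2L)
      stop(sprintf("locus %s has more than two alleles", loci[l]))
    if (length(codes) == 0L) next
    ref <- codes[1L]
    dos <- (A1[, l] == ref) + (A2[, l] == ref)
    dos[is.na(A1[, l]) | is.na(A2[, l])] <- NA
    dosage[, l] <- as.integer(dos)
  }
  genotype_matrix(dosage, pop)
}

## ------------------------------------------------------ allele frequencies

#' Per-population allele frequency table
#'
#' @param freq Numeric matrix (populations x loci) of reference-allele
#'   frequencies; NA where no gene copies were typed.
#' @param copies Numeric matrix of non-missing gene copy counts
#'   (2 x typed individuals).
#' @return An object of class \code{allele_freq_table}.
#' @export
allele_freq_table <- function(freq, copies) {
  freq <- as.matrix(freq); copies <- as.matrix(copies)
  stopifnot(identical(dim(freq), dim(copies)))
  if (any(copies < 0, na.rm = TRUE)) stop("copies must be >= 0")
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) stop("freq must be in [0,1]")
  if (any(!is.na(freq) & copies == 0)) stop("freq defined where copies == 0")
  structure(list(freq = freq, copies = copies), class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d population(s) x %d loci\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

#' Compute per-group allele frequencies
#'
#' Reference-allele frequency and gene-copy counts per group and locus,
#' complete-case per locus (missing genotypes contribute no copies).
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param group Either a character scalar naming a grouping variable
#'   (\code{"pop"}, \code{"year"} or a column of \code{gm$meta}) or a vector
#'   of group labels, one per individual.
#' @return An \code{\link{allele_freq_table}} with one row per group, in
#'   order of first appearance.
#' @export
allele_frequencies <- function(gm, group = "pop") {
  g <- resolve_group(gm, group)
  groups <- unique(g)
  d <- gm$dosage
  typed <- !is.na(d)
  freq <- matrix(NA_real_, length(groups), ncol(d),
                 dimnames = list(groups, colnames(d)))
  copies <- matrix(0, length(groups), ncol(d),
                   dimnames = list(groups, colnames(d)))
  for (i in seq_along(groups)) {
    idx <- g == groups[i]
    cnt <- 2 * colSums(typed[idx, , drop = FALSE])
    tot <- colSums(d[idx, , drop = FALSE], na.rm = TRUE)
    copies[i, ] <- cnt
    freq[i, cnt > 0] <- tot[cnt > 0] / cnt[cnt > 0]
  }
  allele_freq_table(freq, copies)
}

resolve_group <- function(gm, group) {
  n <- n_individuals(gm)
  if (is.character(group) && length(group) == 1L) {
    if (group == "pop") return(gm$pop)
    if (group == "year") return(as.character(gm$year))
    if (!is.null(gm$meta) && group %in% names(gm$meta))
      return(as.character(gm$meta[[group]]))
    stop(sprintf("unknown group label '%s'", group))
  }
  if (length(group) != n) stop("group vector must match number of individuals")
  as.character(group)
}
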