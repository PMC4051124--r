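# Effect-class vocabulary for variant records.
EFFECT_CLASSES <- c("synonymous", "missense", "nonsense", "frameshift",
                    "splice", "other")

# Minimal TSV line reader shared by all table readers. Keeps the original
# file line number for every retained row so validation errors can name it.
# A header row is recognised by its first field matching `header_first`
# (case-insensitive); blank lines and '#' comments are skipped.
read_tsv_lines <- function(path, min_cols, header_first) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) > 0) {
    lines[1] <- sub("^﻿", "", lines[1])
  }
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  lineno <- which(keep)
  # sentinel keeps trailing empty fields that strsplit would drop
  fields <- strsplit(paste0(lines[lineno], "\tEOL"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  if (length(fields) > 0 &&
      tolower(trimws(fields[[1]][1])) == tolower(header_first)) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  bad <- which(lengths(fields) < min_cols)
  if (length(bad) > 0) {
    stop("malformed row at line ", lineno[bad[1]], " of '", path,
         "': expected at least ", min_cols, " tab-separated fields",
         call. = FALSE)
  }
  list(fields = fields, lineno = lineno)
}

field_col <- function(parsed, j) {
  trimws(vapply(parsed$fields, `[[`, character(1), j))
}

num_col <- function(parsed, j, path, what, missing_as = NA_real_) {
  raw <- field_col(parsed, j)
  empty <- raw == "" | toupper(raw) == "NA"
  x <- suppressWarnings(as.numeric(raw))
  if (!is.na(missing_as)) x[empty] <- missing_as
  bad <- which(is.na(x) & !empty)
  if (length(bad) > 0) {
    stop("non-numeric ", what, " '", raw[bad[1]], "' at line ",
         parsed$lineno[bad[1]], " of '", path, "'", call. = FALSE)
  }
  x
}

#' Read a pairwise interaction table
#'
#' Reads a tab-separated table of scored gene-gene interactions (columns:
#' gene A, gene B, confidence score), the edge source for [build_network()].
#' Scores are divided by `score_scale` (default 1000, the usual convention
#' for interaction-database confidence scores) so that downstream code only
#' ever sees confidences in (0, 1]. Gene symbols are upper-cased. Self-loops
#' are dropped (with a message giving the count); duplicate unordered pairs
#' are collapsed keeping the maximum score, so repeated evidence for a pair
#' can only shorten its distance.
#'
#' @param path Path to a TSV file with at least three columns: gene_a,
#'   gene_b, score. An optional header row (first field `gene_a`) is
#'   skipped; blank lines and `#` comments are ignored.
#' @param score_scale Positive number the raw scores are divided by.
#' @return A data.frame with columns `gene_a`, `gene_b`, `score` (one row
#'   per unordered pair, `gene_a < gene_b`, scores in (0, 1]), with
#'   attribute `self_loops_dropped`.
#' @examples
#' f <- tempfile()
#' writeLines(c("TLR3\tTICAM1\t900", "A\tB\t500", "B\tA\t700"), f)
#' read_interactions(f)
#' @export
read_interactions <- function(path, score_scale = 1000) {
  stopifnot(is.numeric(score_scale), length(score_scale) == 1, score_scale > 0)
  parsed <- read_tsv_lines(path, 3L, "gene_a")
  gene_a <- toupper(field_col(parsed, 1))
  gene_b <- toupper(field_col(parsed, 2))
  score <- num_col(parsed, 3, path, "score", missing_as = NA_real_)
  bad <- which(is.na(score) | score <= 0 | score > score_scale)
  if (length(bad) > 0) {
    stop("invalid score '", field_col(parsed, 3)[bad[1]], "' at line ",
         parsed$lineno[bad[1]], " of '", path,
         "': scores must be in (0, ", score_scale, "]", call. = FALSE)
  }
  self <- gene_a == gene_b
  n_self <- sum(self)
  if (n_self > 0) {
    message("read_interactions: dropped ", n_self, " self-loop row",
            if (n_self > 1) "s" else "")
  }
  gene_a <- gene_a[!self]
  gene_b <- gene_b[!self]
  score <- score[!self] / score_scale
  lo <- pmin(gene_a, gene_b)
  hi <- pmax(gene_a, gene_b)
  key <- paste(lo, hi, sep = "\t")
  best <- tapply(score, key, max)
  parts <- strsplit(names(best), "\t", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[[`, character(1), 1),
    gene_b = vapply(parts, `[[`, character(1), 2),
    score = as.numeric(best),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "self_loops_dropped") <- n_self
  out
}

#' Read a gene-alias table
#'
#' Reads a TSV with columns alias, canonical symbol, full gene name, and
#' builds the lookup used to resolve user-supplied symbols to network node
#' names and to annotate connectome records with full gene names (for
#' example "Toll-like receptor 3" for TLR3). Canonical rows are usually
#' present as identity entries (canonical -> canonical) carrying the full
#' name. Aliases and canonical symbols are upper-cased.
#'
#' @param path Path to a TSV with columns alias, canonical, full_name.
#'   An optional header row (first field `alias`) is skipped.
#' @return An object of class `alias_map`; see [resolve_alias()],
#'   [gene_full_name()].
#' @export
read_aliases <- function(path) {
  parsed <- read_tsv_lines(path, 3L, "alias")
  alias_map(
    alias = toupper(field_col(parsed, 1)),
    canonical = toupper(field_col(parsed, 2)),
    full_name = field_col(parsed, 3)
  )
}

#' Construct an alias map in memory
#'
#' @param alias,canonical,full_name Parallel character vectors; one row per
#'   alias entry. An alias mapping to two different canonical symbols is an
#'   error (the conflict is reported).
#' @return An `alias_map` object.
#' @export
alias_map <- function(alias, canonical, full_name = rep("", length(alias))) {
  alias <- toupper(trimws(alias))
  canonical <- toupper(trimws(canonical))
  tab <- unique(data.frame(alias = alias, canonical = canonical,
                           stringsAsFactors = FALSE))
  dup <- tab$alias[duplicated(tab$alias)]
  if (length(dup) > 0) {
    a <- dup[1]
    stop("conflicting alias '", a, "' maps to multiple canonical symbols: ",
         paste(sort(tab$canonical[tab$alias == a]), collapse = ", "),
         call. = FALSE)
  }
  a2c <- stats::setNames(tab$canonical, tab$alias)
  named <- nzchar(full_name)
  c2f <- stats::setNames(full_name[named], canonical[named])
  c2f <- c2f[!duplicated(names(c2f))]
  structure(list(alias = a2c, full_name = c2f), class = "alias_map")
}

#' Resolve symbols through an alias map
#'
#' Pure map lookup: returns the canonical symbol for each input, trying the
#' symbol as given and then upper-cased. Unknown symbols return `NA` (the
#' caller decides whether that is an error).
#'
#' @param map An `alias_map`.
#' @param symbols Character vector of gene symbols or aliases.
#' @return Character vector of canonical symbols, `NA` where unknown.
#' @export
resolve_alias <- function(map, symbols) {
  stopifnot(inherits(map, "alias_map"))
  vapply(symbols, function(s) {
    s <- trimws(s)
    if (s %in% names(map$alias)) return(unname(map$alias[[s]]))
    su <- toupper(s)
    if (su %in% names(map$alias)) return(unname(map$alias[[su]]))
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Full gene name for a canonical symbol
#'
#' @param map An `alias_map` (or `NULL`, in which case all names are `""`).
#' @param symbols Canonical gene symbols.
#' @return Character vector of full names; `""` where absent.
#' @export
gene_full_name <- function(map, symbols) {
  if (is.null(map)) return(rep("", length(symbols)))
  stopifnot(inherits(map, "alias_map"))
  out <- unname(map$full_name[toupper(symbols)])
  out[is.na(out)] <- ""
  out
}

#' @export
print.alias_map <- function(x, ...) {
  cat("<alias_map> ", length(x$alias), " aliases, ",
      length(x$full_name), " full names\n", sep = "")
  invisible(x)
}

#' Read a variant table
#'
#' Reads a TSV of candidate variants with columns gene, effect class, two
#' population-database frequencies (for example 1000 Genomes and an exome
#' variant server) and the frequency among patients of other disease
#' cohorts. Effect classes must be one of synonymous, missense, nonsense,
#' frameshift, splice, other.
#' Missing frequency fields parse as 0 so that the absence of a database
#' record never silently discards a rare variant.
#'
#' @param path Path to a TSV with columns gene, effect, freq_db1, freq_db2,
#'   cohort_freq. An optional header row (first field `gene`) is skipped.
#' @return A data.frame with those five columns; frequencies in \[0, 1\].
#' @export
read_variants <- function(path) {
  parsed <- read_tsv_lines(path, 5L, "gene")
  effect <- tolower(field_col(parsed, 2))
  bad <- which(!effect %in% EFFECT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown effect class '", field_col(parsed, 2)[bad[1]],
         "' at line ", parsed$lineno[bad[1]], " of '", path,
         "' (expected one of: ", paste(EFFECT_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  }
  out <- data.frame(
    gene = toupper(field_col(parsed, 1)),
    effect = effect,
    freq_db1 = num_col(parsed, 3, path, "frequency", missing_as = 0),
    freq_db2 = num_col(parsed, 4, path, "frequency", missing_as = 0),
    cohort_freq = num_col(parsed, 5, path, "frequency", missing_as = 0),
    stringsAsFactors = FALSE
  )
  for (col in c("freq_db1", "freq_db2", "cohort_freq")) {
    bad <- which(out[[col]] < 0 | out[[col]] > 1)
    if (length(bad) > 0) {
      stop("frequency out of [0, 1] at line ", parsed$lineno[bad[1]],
           " of '", path, "'", call. = FALSE)
    }
  }
  out
}

#' Read a candidate gene list
#'
#' One symbol per line; blank lines and `#` comments are skipped; symbols
#' are upper-cased. An empty file yields an empty vector, not an error.
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  if (length(lines) > 0) lines[1] <- sub("^﻿", "", lines[1])
  toupper(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a table as TSV
#'
#' Tab-separated, header row, UTF-8, LF line endings, `NA` for missing
#' values, numeric columns at full (round-trip) precision. Writing and
#' re-reading a variant table reproduces the records exactly.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}
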