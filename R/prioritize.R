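#' Resolve input symbols to network nodes
#'
#' Maps user-supplied gene symbols (possibly aliases, possibly mixed case)
#' to canonical network node names. Resolution order per symbol: exact
#' canonical match against the network, then alias-map lookup, then
#' case-normalized match. Symbols that resolve to nothing are returned in
#' `unresolved`, never silently dropped.
#'
#' @param symbols Character vector of gene symbols or aliases.
#' @param alias_map Optional `alias_map`.
#' @param net A `gene_network`.
#' @return A list with `resolved` (data.frame input, resolved) and
#'   `unresolved` (character vector of inputs that matched no node).
#' @export
resolve_symbols <- function(symbols, alias_map = NULL, net) {
  stopifnot(inherits(net, "gene_network"))
  nodes <- network_genes(net)
  resolve_one <- function(s) {
    s <- trimws(s)
    if (s %in% nodes) return(s)
    if (!is.null(alias_map)) {
      cand <- resolve_alias(alias_map, s)
      if (!is.na(cand) && cand %in% nodes) return(cand)
    }
    su <- toupper(s)
    if (su %in% nodes) return(su)
    NA_character_
  }
  res <- vapply(symbols, resolve_one, character(1), USE.NAMES = FALSE)
  ok <- !is.na(res)
  list(
    resolved = data.frame(input = symbols[ok], resolved = res[ok],
                          stringsAsFactors = FALSE),
    unresolved = symbols[!ok]
  )
}

#' Prioritize candidate genes against core genes
#'
#' Ranks a candidate gene list by its biological proximity to one or more
#' core genes, using distance, connectivity p-value or best reciprocal
#' p-value as the sorting metric. In `global` mode each candidate is
#' reported once, paired with the core gene minimizing the metric, and the
#' whole table is sorted by the metric ascending; in `per_core` mode every
#' (candidate, core) pair is kept, grouped by core and sorted within each
#' group. Ties are broken alphabetically. Candidates that match no network
#' node after alias resolution are listed in `unresolved` with a warning.
#'
#' @param net A `gene_network`.
#' @param candidates Character vector of candidate symbols (non-empty).
#' @param cores Character vector of core gene symbols (non-empty; at least
#'   one must resolve to a network node).
#' @param metric `"distance"`, `"p_value"` or `"brp"`.
#' @param mode `"global"` or `"per_core"`.
#' @param alias_map Optional `alias_map` for symbol resolution and full
#'   gene names.
#' @return An object of class `prioritization`: list with `table` (one row
#'   per retained (candidate, core) pair with all connectome annotations),
#'   `metric`, `mode` and `unresolved`.
#' @export
prioritize <- function(net, candidates, cores,
                       metric = c("distance", "p_value", "brp"),
                       mode = c("global", "per_core"),
                       alias_map = NULL) {
  stopifnot(inherits(net, "gene_network"))
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (length(candidates) == 0) {
    stop("candidate gene list is empty", call. = FALSE)
  }
  if (length(cores) == 0) stop("no core genes supplied", call. = FALSE)

  rcore <- resolve_symbols(cores, alias_map, net)
  if (nrow(rcore$resolved) == 0) {
    stop("none of the core genes (", paste(cores, collapse = ", "),
         ") could be resolved to a network gene", call. = FALSE)
  }
  if (length(rcore$unresolved) > 0) {
    warning("unresolvable core gene(s) dropped: ",
            paste(rcore$unresolved, collapse = ", "), call. = FALSE)
  }
  core_syms <- sort(unique(rcore$resolved$resolved))

  rcand <- resolve_symbols(candidates, alias_map, net)
  if (length(rcand$unresolved) > 0) {
    warning("unresolved candidate symbol(s): ",
            paste(unique(rcand$unresolved), collapse = ", "), call. = FALSE)
  }
  cand_syms <- sort(unique(rcand$resolved$resolved))

  D <- igraph::distances(net$graph, weights = igraph::E(net$graph)$distance)
  P <- pvalue_matrix(net, dist_matrix = D)

  blocks <- lapply(core_syms, function(co) {
    cx <- build_connectome(net, co, alias_map = alias_map,
                           dist_matrix = D, pval_matrix = P)
    rec <- cx$records
    idx <- match(setdiff(cand_syms, co), rec$target)
    sub <- rec[idx, , drop = FALSE]
    if (co %in% cand_syms) {
      # core queried against its own connectome: identity convention
      self <- data.frame(
        target = co, distance = 0, rank = 0L, p_value = 1 / cx$n_genes,
        brp = 1 / cx$n_genes, ratio_median = 0, ratio_mean = 0,
        sphere = 0L, route = co, degrees = 0L,
        full_name = gene_full_name(alias_map, co), stringsAsFactors = FALSE
      )
      sub <- rbind(self, sub)
    }
    if (nrow(sub) == 0) return(NULL)
    data.frame(candidate = sub$target, core = co,
               sub[, setdiff(names(sub), "target"), drop = FALSE],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, blocks)
  if (is.null(tab)) {
    tab <- empty_prioritization_table()
  } else {
    names(tab)[names(tab) == "rank"] <- "rank_in_core_connectome"
    m <- tab[[metric]]
    if (mode == "global") {
      keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$candidate),
                            function(i) i[order(m[i], tab$core[i])][1]),
                     use.names = FALSE)
      tab <- tab[keep, , drop = FALSE]
      tab <- tab[order(tab[[metric]], tab$candidate), , drop = FALSE]
    } else {
      tab <- tab[order(tab$core, m, tab$candidate), , drop = FALSE]
    }
    rownames(tab) <- NULL
  }
  structure(list(table = tab, metric = metric, mode = mode,
                 unresolved = unique(rcand$unresolved)),
            class = "prioritization")
}

empty_prioritization_table <- function() {
  data.frame(candidate = character(), core = character(),
             distance = numeric(), rank_in_core_connectome = integer(),
             p_value = numeric(), brp = numeric(),
             ratio_median = numeric(), ratio_mean = numeric(),
             sphere = integer(), route = character(), degrees = integer(),
             full_name = character(), stringsAsFactors = FALSE)
}

#' @export
print.prioritization <- function(x, ...) {
  cat("<prioritization> metric = ", x$metric, ", mode = ", x$mode, ", ",
      nrow(x$table), " row", if (nrow(x$table) != 1) "s", sep = "")
  if (length(x$unresolved) > 0) {
    cat(", ", length(x$unresolved), " unresolved: ",
        paste(x$unresolved, collapse = ", "), sep = "")
  }
  cat("\n")
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("... ", nrow(x$table) - 10, " more rows\n",
                              sep = "")
  invisible(x)
}
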