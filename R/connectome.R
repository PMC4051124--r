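#' Shortest biological distances and routes from a core gene
#'
#' Single-source weighted shortest paths (Dijkstra) over the gene network.
#' For every node the minimal total edge distance from the core and one
#' minimizing route are returned; nodes in other components get infinite
#' distance and an empty route.
#'
#' @param net A `gene_network`.
#' @param core Core gene symbol (must be a network node).
#' @return A list with `distance` (named numeric, one entry per node) and
#'   `route` (named list of character vectors; `character(0)` when
#'   unreachable; `c(core)` for the core itself).
#' @export
shortest_paths_from <- function(net, core) {
  stopifnot(inherits(net, "gene_network"))
  core <- toupper(core)
  syms <- network_genes(net)
  if (!core %in% syms) {
    stop("gene '", core, "' is not in the network", call. = FALSE)
  }
  g <- net$graph
  w <- igraph::E(g)$distance
  d <- igraph::distances(g, v = core, weights = w, algorithm = "dijkstra")[1, ]
  paths <- suppressWarnings(
    igraph::shortest_paths(g, from = core, to = igraph::V(g), weights = w,
                           output = "vpath")
  )$vpath
  routes <- lapply(paths, function(p) as.character(igraph::as_ids(p)))
  names(routes) <- names(d)
  list(distance = d[syms], route = routes[syms])
}

#' Minimal-distance route between two genes
#'
#' The ordered gene sequence realizing the minimal biological distance
#' (the "predicted route": the genes between the two endpoints, inclusive).
#'
#' @param net A `gene_network`.
#' @param a,b Gene symbols, both network nodes.
#' @return Character vector from `a` to `b`; `c(a)` when `a == b`;
#'   `character(0)` when the pair is unreachable (not an error).
#' @export
route_between <- function(net, a, b) {
  stopifnot(inherits(net, "gene_network"))
  a <- toupper(a); b <- toupper(b)
  syms <- network_genes(net)
  for (s in c(a, b)) {
    if (!s %in% syms) stop("gene '", s, "' is not in the network",
                           call. = FALSE)
  }
  if (a == b) return(a)
  p <- suppressWarnings(
    igraph::shortest_paths(net$graph, from = a, to = b,
                           weights = igraph::E(net$graph)$distance,
                           output = "vpath")
  )$vpath[[1]]
  as.character(igraph::as_ids(p))
}

#' Biological distance between two genes
#'
#' @param net A `gene_network`.
#' @param a,b Gene symbols, both network nodes.
#' @return Nonnegative number; `Inf` when unreachable.
#' @export
biological_distance <- function(net, a, b) {
  stopifnot(inherits(net, "gene_network"))
  a <- toupper(a); b <- toupper(b)
  syms <- network_genes(net)
  for (s in c(a, b)) {
    if (!s %in% syms) stop("gene '", s, "' is not in the network",
                           call. = FALSE)
  }
  igraph::distances(net$graph, v = a, to = b,
                    weights = igraph::E(net$graph)$distance)[1, 1]
}

#' Build a gene-specific connectome
#'
#' All non-core genes of the network ordered by their biological distance
#' to the core gene, with the full set of per-record annotations: distance,
#' rank, connectivity p-value, best reciprocal p-value, distance ratios to
#' the genome-wide median and mean distance, sphere (rank decile), the
#' predicted route, degrees of separation and the full gene name.
#'
#' Ordering is by (distance, target symbol) so equal distances are broken
#' alphabetically and output is reproducible; all unreachable targets sort
#' after all reachable ones and carry infinite distance, empty route,
#' `NA` degrees/ratios and p-value 1. Ratios are taken over finite
#' distances only.
#'
#' @param net A `gene_network`.
#' @param core Core gene symbol.
#' @param alias_map Optional `alias_map` used to annotate full gene names.
#' @param dist_matrix,pval_matrix Optional precomputed all-pairs distance
#'   and p-value matrices (see [pvalue_matrix()]); computed on demand when
#'   `NULL`. Callers building connectomes for several cores should compute
#'   them once and pass them in.
#' @return An object of class `connectome`: list with `core`, `n_genes`
#'   (N, the number of non-core genes) and `records` (data.frame ordered by
#'   rank with columns target, distance, rank, p_value, brp, ratio_median,
#'   ratio_mean, sphere, route, degrees, full_name).
#' @export
build_connectome <- function(net, core, alias_map = NULL,
                             dist_matrix = NULL, pval_matrix = NULL) {
  stopifnot(inherits(net, "gene_network"))
  core <- toupper(core)
  sp <- shortest_paths_from(net, core)
  syms <- network_genes(net)
  targets <- setdiff(syms, core)
  N <- length(targets)
  if (N == 0) stop("network has no genes other than the core", call. = FALSE)
  d <- sp$distance[targets]
  ord <- order(d, targets)
  targets <- targets[ord]
  d <- unname(d[ord])
  rnk <- seq_len(N)
  reachable <- is.finite(d)
  p <- rnk / N
  p[!reachable] <- 1
  if (is.null(pval_matrix)) {
    pval_matrix <- pvalue_matrix(net, dist_matrix = dist_matrix)
  }
  p_rev <- unname(pval_matrix[targets, core])
  brp <- pmin(p, p_rev)
  fin <- d[reachable]
  med <- if (length(fin) > 0) stats::median(fin) else NA_real_
  mn <- if (length(fin) > 0) mean(fin) else NA_real_
  routes <- sp$route[targets]
  records <- data.frame(
    target = targets,
    distance = d,
    rank = rnk,
    p_value = p,
    brp = brp,
    ratio_median = ifelse(reachable, d / med, NA_real_),
    ratio_mean = ifelse(reachable, d / mn, NA_real_),
    sphere = as.integer(ceiling(10 * rnk / N)),
    route = vapply(routes, paste, character(1), collapse = "->"),
    degrees = ifelse(reachable, lengths(routes) - 1L, NA_integer_),
    full_name = gene_full_name(alias_map, targets),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  structure(list(core = core, n_genes = N, records = records),
            class = "connectome")
}

#' Connectome records as a data.frame
#'
#' @param x A `connectome`.
#' @return The records data.frame (one row per non-core gene, ordered by
#'   rank), suitable for [write_table()].
#' @export
connectome_table <- function(x) {
  stopifnot(inherits(x, "connectome"))
  x$records
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> core ", x$core, ", N = ", x$n_genes, " target genes\n",
      sep = "")
  print(utils::head(x$records, 5))
  if (x$n_genes > 5) cat("... ", x$n_genes - 5, " more rows\n", sep = "")
  invisible(x)
}
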