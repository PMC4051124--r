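#' Build the weighted gene network
#'
#' Turns scored interaction records into an undirected weighted graph whose
#' edge weights are direct biological distances obtained by inverting the
#' confidence scores: high-confidence interactions become short edges.
#' Two inversion forms are provided:
#' \describe{
#'   \item{reciprocal (default)}{`d = 1/s`; penalizes weak interactions
#'     super-linearly and keeps distances unbounded above 1.}
#'   \item{complement}{`d = 1 - s + 1e-6`; bounded in (0, 1]; the epsilon
#'     keeps perfect-confidence edges at positive length.}
#' }
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `score`
#'   (scores in (0, 1]), as produced by [read_interactions()] or
#'   [generate_network()].
#' @param inversion `"reciprocal"` or `"complement"`.
#' @param genes Optional character vector of additional gene symbols to
#'   include as (possibly isolated) nodes, e.g. the full gene universe.
#' @return An object of class `gene_network` wrapping an igraph graph with
#'   edge attributes `score` and `distance`.
#' @examples
#' rec <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
#'                   score = c(0.9, 0.5))
#' net <- build_network(rec)
#' network_summary(net)
#' @export
build_network <- function(records,
                          inversion = c("reciprocal", "complement"),
                          genes = NULL) {
  inversion <- match.arg(inversion)
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot build a network from an empty interaction list",
         call. = FALSE)
  }
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(records)))
  s <- records$score
  if (any(!is.finite(s)) || any(s <= 0) || any(s > 1)) {
    stop("interaction scores must lie in (0, 1]", call. = FALSE)
  }
  a <- toupper(records$gene_a)
  b <- toupper(records$gene_b)
  if (any(a == b)) {
    stop("self-loop records are not allowed in a gene network", call. = FALSE)
  }
  d <- invert_score(s, inversion)
  nodes <- sort(unique(c(a, b, toupper(genes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, score = s, distance = d,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  structure(list(graph = g, inversion = inversion), class = "gene_network")
}

invert_score <- function(s, inversion) {
  switch(inversion,
         reciprocal = 1 / s,
         complement = 1 - s + 1e-6)
}

#' Network node symbols
#'
#' @param net A `gene_network`.
#' @return Sorted character vector of gene symbols in the network.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::V(net$graph)$name
}

#' Summarize a gene network
#'
#' @param net A `gene_network`.
#' @return A list with elements `nodes`, `edges`, `components`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  list(nodes = igraph::gorder(net$graph),
       edges = igraph::gsize(net$graph),
       components = igraph::count_components(net$graph))
}

#' Export a gene network as an edge-list TSV
#'
#' Columns gene_a, gene_b, score, distance; one row per edge.
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_data_frame(net$graph, what = "edges")
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  out <- data.frame(gene_a = a, gene_b = b, score = el$score,
                    distance = el$distance, stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  write_table(out, path)
}

#' @export
print.gene_network <- function(x, ...) {
  s <- network_summary(x)
  cat("<gene_network> ", s$nodes, " genes, ", s$edges, " interactions, ",
      s$components, " component", if (s$components != 1) "s", "; ",
      x$inversion, " inversion\n", sep = "")
  invisible(x)
}
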