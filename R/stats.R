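#' All-pairs connectivity p-value matrix
#'
#' The connectivity p-value of target gene t in the connectome of gene g is
#' its rank percentile: rank(t)/N, where rank orders the N non-core genes
#' by (biological distance to g, symbol) and N is the number of non-core
#' genes. Under a uniform draw of targets the p-value is exactly uniform on
#' \{1/N, 2/N, ..., 1\}. Unreachable targets get p = 1; the diagonal uses
#' the identity convention p = 1/N (the floor value).
#'
#' @param net A `gene_network`.
#' @param dist_matrix Optional precomputed all-pairs distance matrix with
#'   dimnames equal to the network genes.
#' @return Numeric matrix P with `P[g, t]` = p-value of t in g's
#'   connectome.
#' @export
pvalue_matrix <- function(net, dist_matrix = NULL) {
  stopifnot(inherits(net, "gene_network"))
  syms <- network_genes(net)
  if (is.null(dist_matrix)) {
    dist_matrix <- igraph::distances(net$graph,
                                     weights = igraph::E(net$graph)$distance)
  }
  D <- dist_matrix[syms, syms, drop = FALSE]
  n <- length(syms)
  N <- n - 1L
  P <- matrix(1 / N, n, n, dimnames = list(syms, syms))
  for (i in seq_len(n)) {
    d <- D[i, -i]
    p <- numeric(N)
    p[order(d, names(d))] <- seq_len(N) / N
    p[!is.finite(d)] <- 1
    P[i, -i] <- p
  }
  P
}

#' Connectivity p-value of a target in a connectome
#'
#' Rank-percentile p-value rank/N; 1 for unreachable targets; the core
#' queried against its own connectome returns the 1/N floor.
#'
#' @param connectome A `connectome`.
#' @param target Gene symbol.
#' @return p in (0, 1].
#' @export
connectivity_pvalue <- function(connectome, target) {
  stopifnot(inherits(connectome, "connectome"))
  target <- toupper(target)
  if (target == connectome$core) return(1 / connectome$n_genes)
  i <- match(target, connectome$records$target)
  if (is.na(i)) {
    stop("gene '", target, "' is not in the connectome of ",
         connectome$core, call. = FALSE)
  }
  connectome$records$p_value[i]
}

#' Best reciprocal p-value between two genes
#'
#' Computes both directed rank-percentile p-values — the p-value of b in
#' a's connectome and of a in b's — and returns their minimum (BRP). The
#' two directions differ when one gene is much more central than the
#' other; taking the minimum compensates for hub and isolated genes, and
#' makes the measure symmetric: `brp(a, b) == brp(b, a)`.
#'
#' @param net A `gene_network`.
#' @param a,b Gene symbols, both network nodes.
#' @param dist_matrix Optional precomputed all-pairs distance matrix.
#' @return A list with `p_core_to_target` (p of b in a's connectome),
#'   `p_target_to_core` (p of a in b's connectome) and `brp`.
#' @export
best_reciprocal_pvalue <- function(net, a, b, dist_matrix = NULL) {
  stopifnot(inherits(net, "gene_network"))
  a <- toupper(a); b <- toupper(b)
  syms <- network_genes(net)
  for (s in c(a, b)) {
    if (!s %in% syms) stop("gene '", s, "' is not in the network",
                           call. = FALSE)
  }
  N <- length(syms) - 1L
  if (a == b) {
    return(list(p_core_to_target = 1 / N, p_target_to_core = 1 / N,
                brp = 1 / N))
  }
  if (is.null(dist_matrix)) {
    dist_matrix <- igraph::distances(net$graph, v = c(a, b),
                                     weights = igraph::E(net$graph)$distance)
  }
  p_ab <- directed_pvalue(dist_matrix, a, b)
  p_ba <- directed_pvalue(dist_matrix, b, a)
  list(p_core_to_target = p_ab, p_target_to_core = p_ba,
       brp = min(p_ab, p_ba))
}

# rank-percentile p-value of `to` in the connectome of `from`, given a
# distance matrix whose rows include `from` and columns all genes
directed_pvalue <- function(D, from, to) {
  d <- D[from, colnames(D) != from]
  if (!is.finite(d[[to]])) return(1)
  N <- length(d)
  ord <- order(d, names(d))
  match(to, names(d)[ord]) / N
}

#' Combine per-patient p-values
#'
#' Combines independent per-patient connectivity p-values for the same
#' gene into one summary value. `product` multiplies them (the default;
#' for k patients whose causal gene ranks r_i among N_i candidates this is
#' the product of the rank percentiles). `fisher` returns the upper-tail
#' probability of -2 * sum(log p) under a chi-square law with 2k degrees
#' of freedom. Both are monotone in sum(log p) and therefore order lists
#' of equal length identically.
#'
#' @param ps Numeric vector of p-values in (0, 1]; must be non-empty.
#' @param method `"product"` or `"fisher"`.
#' @return Combined value: a probability for `fisher`; a product of
#'   probabilities (not itself calibrated as a p-value) for `product`.
#' @examples
#' combine_pvalues(c(0.25, 0.5))                    # 0.125
#' combine_pvalues(c(0.5, 0.5), method = "fisher")  # ~0.5966
#' @export
combine_pvalues <- function(ps, method = c("product", "fisher")) {
  method <- match.arg(method)
  if (length(ps) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  switch(method,
         product = prod(ps),
         fisher = stats::pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                                lower.tail = FALSE))
}
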