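# Shared fixtures and independent shortest-path oracles. The oracles
# deliberately avoid igraph: exhaustive simple-path enumeration for tiny
# graphs, Bellman-Ford edge relaxation for medium ones.

toy_records <- function() {
  data.frame(gene_a = c("A", "B", "A", "C"),
             gene_b = c("B", "C", "C", "D"),
             score = c(0.9, 0.5, 0.25, 0.8),
             stringsAsFactors = FALSE)
}

# scores A-B 0.9, B-C 0.5, A-C 0.25, C-D 0.8; E isolated
toy_network <- function(inversion = "reciprocal") {
  build_network(toy_records(), inversion = inversion, genes = "E")
}

d_from_score <- function(s, inversion = "reciprocal") {
  if (inversion == "reciprocal") 1 / s else 1 - s + 1e-6
}

random_records <- function(n, p = 0.3, score_range = c(0.1, 0.95)) {
  genes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(gene_a = genes[pairs[, 1]], gene_b = genes[pairs[, 2]],
             score = runif(nrow(pairs), score_range[1], score_range[2]),
             stringsAsFactors = FALSE)
}

oracle_adjacency <- function(records, genes, inversion) {
  adj <- setNames(vector("list", length(genes)), genes)
  for (i in seq_len(nrow(records))) {
    a <- records$gene_a[i]; b <- records$gene_b[i]
    d <- d_from_score(records$score[i], inversion)
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, d = d))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, d = d))
  }
  adj
}

# exhaustive enumeration of all simple paths from `from`; usable for
# graphs with <= ~10 nodes
oracle_enum_distances <- function(records, genes, from,
                                  inversion = "reciprocal") {
  adj <- oracle_adjacency(records, genes, inversion)
  best <- setNames(rep(Inf, length(genes)), genes)
  best[from] <- 0
  walk <- function(node, visited, acc) {
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$to[i]
      if (nxt %in% visited) next
      d <- acc + nb$d[i]
      if (d < best[[nxt]]) best[[nxt]] <<- d
      walk(nxt, c(visited, nxt), d)
    }
  }
  walk(from, from, 0)
  best
}

# Bellman-Ford repeated edge relaxation; usable for graphs with <= ~30
# nodes
oracle_relax_distances <- function(records, genes, from,
                                   inversion = "reciprocal") {
  d <- setNames(rep(Inf, length(genes)), genes)
  d[from] <- 0
  w <- d_from_score(records$score, inversion)
  for (round in seq_along(genes)) {
    changed <- FALSE
    for (i in seq_len(nrow(records))) {
      a <- records$gene_a[i]; b <- records$gene_b[i]
      if (d[[a]] + w[i] < d[[b]]) { d[[b]] <- d[[a]] + w[i]; changed <- TRUE }
      if (d[[b]] + w[i] < d[[a]]) { d[[a]] <- d[[b]] + w[i]; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# total edge distance along a reported route, looked up edge by edge
route_length <- function(records, route, inversion = "reciprocal") {
  if (length(route) < 2) return(0)
  key <- paste(pmin(records$gene_a, records$gene_b),
               pmax(records$gene_a, records$gene_b))
  w <- setNames(d_from_score(records$score, inversion), key)
  steps <- paste(pmin(route[-length(route)], route[-1]),
                 pmax(route[-length(route)], route[-1]))
  stopifnot(all(steps %in% names(w)))
  sum(w[steps])
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
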