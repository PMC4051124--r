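test_that("toy-graph shortest paths match the exhaustive enumeration oracle", {
  net <- toy_network()
  genes <- network_genes(net)
  oracle <- oracle_enum_distances(toy_records(), genes, "A")
  sp <- shortest_paths_from(net, "A")
  expect_equal(sp$distance[genes], oracle[genes], tolerance = 1e-12)
  # the indirect route through B beats the weak direct A-C edge (d = 4)
  expect_equal(unname(sp$distance[["C"]]), 1 / 0.9 + 1 / 0.5)
  expect_equal(sp$route[["C"]], c("A", "B", "C"))
  expect_equal(unname(sp$distance[["D"]]), 1 / 0.9 + 1 / 0.5 + 1 / 0.8)
  expect_equal(sp$route[["D"]], c("A", "B", "C", "D"))
  expect_equal(unname(sp$distance[["E"]]), Inf)
  expect_equal(sp$route[["E"]], character(0))
  expect_error(shortest_paths_from(net, "NOSUCH"), "'NOSUCH'")
})

test_that("routes between gene pairs follow the minimal-distance path", {
  net <- toy_network()
  expect_equal(route_between(net, "A", "D"), c("A", "B", "C", "D"))
  expect_equal(route_between(net, "A", "A"), "A")
  expect_equal(route_between(net, "A", "E"), character(0))
  expect_equal(rev(route_between(net, "D", "A")), route_between(net, "A", "D"))
  expect_equal(biological_distance(net, "A", "E"), Inf)
  expect_error(route_between(net, "A", "NOSUCH"), "'NOSUCH'")
})

test_that("the connectome of the toy core carries all derived annotations", {
  am <- alias_map(c("A", "TRIF"), c("A", "TICAM1"),
                  c("gene A full name", ""))
  cx <- build_connectome(toy_network(), "A", alias_map = am)
  rec <- connectome_table(cx)
  expect_equal(cx$n_genes, 4)
  expect_equal(rec$target, c("B", "C", "D", "E"))
  expect_equal(round(rec$distance, 4), c(1.1111, 3.1111, 4.3611, Inf))
  expect_equal(rec$rank, 1:4)
  expect_equal(rec$p_value, c(0.25, 0.5, 0.75, 1))
  expect_equal(round(rec$ratio_median[1], 4), 0.3571)
  expect_equal(round(rec$ratio_mean[1], 4), 0.3883)  # 1.1111 / 2.8611
  expect_equal(rec$sphere, c(3, 5, 8, 10))
  expect_equal(rec$degrees, c(1, 2, 3, NA))
  expect_equal(rec$route, c("A->B", "A->B->C", "A->B->C->D", ""))
  expect_true(all(is.na(rec$ratio_median[4])))
  expect_equal(rec$full_name, rep("", 4))  # targets have no names in the map
})

test_that("engine distances equal both oracles on random graphs", {
  withr::with_seed(101, {
    for (k in 1:15) {
      n <- sample(5:10, 1)
      rec <- random_records(n, p = 0.4)
      if (nrow(rec) == 0) next
      genes <- sort(unique(c(rec$gene_a, rec$gene_b)))
      net <- build_network(rec)
      from <- genes[1]
      sp <- shortest_paths_from(net, from)
      expect_equal(sp$distance[genes],
                   oracle_enum_distances(rec, genes, from),
                   tolerance = 1e-9)
    }
    for (k in 1:15) {
      n <- sample(15:30, 1)
      rec <- random_records(n, p = 0.15)
      if (nrow(rec) == 0) next
      genes <- sort(unique(c(rec$gene_a, rec$gene_b)))
      net <- build_network(rec)
      from <- sample(genes, 1)
      sp <- shortest_paths_from(net, from)
      expect_equal(sp$distance[genes],
                   oracle_relax_distances(rec, genes, from),
                   tolerance = 1e-9)
    }
  })
})

test_that("ranks are monotone in distance, routes sum to the reported distance", {
  withr::with_seed(202, {
    for (k in 1:10) {
      rec <- random_records(20, p = 0.12)
      if (nrow(rec) < 2) next
      genes <- sort(unique(c(rec$gene_a, rec$gene_b)))
      net <- build_network(rec, genes = c(genes, "ZZISOLATED"))
      core <- sample(genes, 1)
      cx <- build_connectome(net, core)
      tab <- connectome_table(cx)
      expect_equal(tab$rank, seq_len(nrow(tab)))
      expect_true(!is.unsorted(tab$distance))
      # all unreachable targets rank after all reachable ones
      expect_true(!is.unsorted(!is.finite(tab$distance)))
      reach <- is.finite(tab$distance)
      routes <- strsplit(tab$route[reach], "->", fixed = TRUE)
      sums <- vapply(routes, route_length, numeric(1), records = rec)
      expect_equal(sums, tab$distance[reach], tolerance = 1e-9)
      expect_equal(lengths(routes) - 1L, as.integer(tab$degrees[reach]))
      expect_true(all(tab$p_value[!reach] == 1))
    }
  })
})

test_that("biological distance is a metric on connected components", {
  withr::with_seed(303, {
    rec <- random_records(25, p = 0.2)
    net <- build_network(rec)
    D <- igraph::distances(net$graph, weights = igraph::E(net$graph)$distance)
    expect_true(all(diag(D) == 0))
    expect_equal(D, t(D))
    n <- nrow(D)
    for (k in 1:300) {
      ijk <- sample(n, 3)
      expect_lte(D[ijk[1], ijk[3]],
                 D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
    }
  })
})
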