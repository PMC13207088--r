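test_that("maximal clique enumeration matches hand-checked small graphs", {
  tri <- random_adjacency(3, 1, seed = 1)
  cl <- enumerate_maximal_cliques(adjacency_to_network(tri))
  expect_equal(cl, list(c("N01", "N02", "N03")))

  path3 <- matrix(0, 3, 3, dimnames = list(make_names(3), make_names(3)))
  path3["N01", "N02"] <- path3["N02", "N01"] <- 1
  path3["N02", "N03"] <- path3["N03", "N02"] <- 1
  cl2 <- enumerate_maximal_cliques(adjacency_to_network(path3))
  expect_setequal(lapply(cl2, paste, collapse = "-"), c("N01-N02", "N02-N03"))
})

test_that("clique enumeration matches the exhaustive subset oracle on random graphs", {
  for (seed in 1:12) {
    adj <- random_adjacency(10, runif(1, 0.2, 0.7), seed = seed)
    net <- adjacency_to_network(adj)
    got <- enumerate_maximal_cliques(net)
    want <- oracle_cliques(adj)
    expect_setequal(vapply(got, paste, character(1), collapse = "-"),
                    vapply(want, paste, character(1), collapse = "-"))
  }
})

test_that("MCC scores follow the factorial clique sum with the degree fallback", {
  # star K1,3: centre's neighborhood has no internal edge -> MCC = degree
  star <- matrix(0, 4, 4, dimnames = list(make_names(4), make_names(4)))
  star["N01", 2:4] <- star[2:4, "N01"] <- 1
  sc <- mcc_scores(adjacency_to_network(star))
  expect_equal(sc$mcc[sc$gene_symbol == "N01"], 3)
  expect_equal(sc$rank_mcc[sc$gene_symbol == "N01"], 1L)

  tri <- random_adjacency(3, 1, seed = 1)
  sc_tri <- mcc_scores(adjacency_to_network(tri))
  expect_equal(sc_tri$mcc, rep(2, 3))   # (3-1)! from the single clique

  for (seed in 20:24) {
    adj <- random_adjacency(9, 0.4, seed = seed)
    sc9 <- mcc_scores(adjacency_to_network(adj))
    want <- oracle_mcc(adj)
    expect_equal(setNames(sc9$mcc, sc9$gene_symbol)[names(want)], want)
  }
})

test_that("every connected node has MCC >= 1 and isolated nodes score 0", {
  adj <- random_adjacency(12, 0.25, seed = 31)
  sc <- mcc_scores(adjacency_to_network(adj))
  deg <- setNames(sc$degree, sc$gene_symbol)
  expect_true(all(sc$mcc[deg > 0] >= 1))
  expect_true(all(sc$mcc[deg == 0] == 0))
})

test_that("MCC is invariant under node relabelling", {
  adj <- random_adjacency(8, 0.45, seed = 47)
  perm <- sample(8)
  relabelled <- adj[perm, perm]
  dimnames(relabelled) <- list(make_names(8), make_names(8))
  m1 <- sort(mcc_scores(adjacency_to_network(adj))$mcc)
  m2 <- sort(mcc_scores(adjacency_to_network(relabelled))$mcc)
  expect_equal(m1, m2)
})

test_that("betweenness matches the exhaustive path-counting oracle", {
  for (seed in 5:14) {
    adj <- random_adjacency(8, runif(1, 0.25, 0.6), seed = seed)
    sc <- mcc_scores(adjacency_to_network(adj))
    want <- oracle_betweenness(adj)
    expect_equal(setNames(sc$betweenness, sc$gene_symbol)[names(want)],
                 want, tolerance = 1e-9)
  }
})

test_that("top-k selection is deterministic with guards at both extremes", {
  adj <- random_adjacency(6, 0.5, seed = 3)
  sc <- mcc_scores(adjacency_to_network(adj))
  expect_equal(nrow(top_hubs(sc, 3)), 3)
  expect_error(top_hubs(sc, 0), class = "bridgenet_validation_error")
  expect_warning(all6 <- top_hubs(sc, 50), "exceeds")
  expect_equal(nrow(all6), 6)

  # all-isolated graph: ties broken lexicographically
  iso <- matrix(0, 4, 4, dimnames = list(make_names(4), make_names(4)))
  sets <- disease_gene_sets(make_names(4), character(0))
  net <- build_network(sets, adjacency_to_edges(iso), 0.5)
  sc_iso <- mcc_scores(net)
  expect_equal(sc_iso$gene_symbol, sort(make_names(4)))
  expect_true(all(sc_iso$mcc == 0))
})

test_that("a planted dense clique dominates the MCC ranking", {
  set.seed(61)
  n <- 15
  adj <- random_adjacency(n, 0.15, seed = 61)
  clique_nodes <- make_names(n)[1:5]
  adj[clique_nodes, clique_nodes] <- 1
  diag(adj) <- 0
  sc <- mcc_scores(adjacency_to_network(adj))
  expect_true(sc$gene_symbol[1] %in% clique_nodes)
  expect_gte(sc$mcc[sc$gene_symbol %in% clique_nodes][1], factorial(4))
})
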