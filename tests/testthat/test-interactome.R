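test_that("score combination matches a direct evaluation of the formula", {
  cases <- list(c(0.3, 0.5, 0.4), c(0.9), c(0.041, 0.041), c(1, 1),
                c(0.07, 0.51, 0.4), c(0.2, 0, 0, 0, 0, 0, 0.15))
  for (ch in cases) {
    padded <- c(ch, rep(0, 7 - length(ch)))
    expect_equal(combine_channel_scores(padded),
                 oracle_combine(padded), tolerance = 1e-12)
  }
  expect_equal(combine_channel_scores(rep(0, 7)), 0)
  expect_equal(combine_channel_scores(c(0.9, rep(0, 6))), 0.9,
               tolerance = 1e-12)
})

test_that("score combination is monotone, bounded, and channel-permutation invariant", {
  set.seed(101)
  for (i in 1:50) {
    ch <- runif(7)
    base <- combine_channel_scores(ch)
    expect_gte(base, 0); expect_lt(base, 1)
    expect_equal(combine_channel_scores(sample(ch)), base, tolerance = 1e-12)
    j <- sample(7, 1)
    up <- ch
    up[j] <- min(1, ch[j] + runif(1, 0, 1 - ch[j]))
    expect_gte(combine_channel_scores(up) + 1e-12, base)
  }
})

test_that("network construction keeps inclusive-boundary edges and isolated nodes", {
  sets <- disease_gene_sets(c("A", "B", "C"), c("D"))
  df <- data.frame(gene_a = c("A", "A", "A", "E"),
                   gene_b = c("B", "C", "D", "A"),
                   stringsAsFactors = FALSE)
  for (ch in channel_names()) df[[ch]] <- 0
  df$experimental <- c(0.7, 0.699, 0.9, 0.95)
  df$combined_score <- df$experimental
  net <- build_network(sets, df, 0.7)
  expect_equal(nrow(net$edges), 2)          # 0.699 below; E outside the union
  expect_setequal(net$nodes, c("A", "B", "C", "D"))
  expect_error(build_network(disease_gene_sets(character(0), character(0)), df),
               class = "bridgenet_validation_error")
})

test_that("topology summary reproduces closed-form metrics on known graphs", {
  tri <- random_adjacency(3, 1, seed = 1)
  net <- adjacency_to_network(tri)
  s <- summarize_topology(net)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$average_degree, 2)

  path3 <- matrix(0, 3, 3, dimnames = list(make_names(3), make_names(3)))
  path3["N01", "N02"] <- path3["N02", "N01"] <- 1
  path3["N02", "N03"] <- path3["N03", "N02"] <- 1
  expect_equal(summarize_topology(adjacency_to_network(path3))$clustering_coefficient, 0)

  ps <- reference_scale_edges(n_edges = 280, seed = 7)
  s81 <- summarize_topology(build_network(ps$sets, ps$edges, 0.7))
  expect_equal(s81$n_nodes, 81)
  expect_equal(s81$n_edges, 280)
  expect_equal(round(s81$average_degree, 2), 6.91)
})

test_that("analytic enrichment reports fold and Poisson tail; p is monotone in E", {
  ps <- reference_scale_edges(n_edges = 280, seed = 7)
  net <- build_network(ps$sets, ps$edges, 0.7)
  enr <- ppi_enrichment(net, null_model_config("analytic_poisson"),
                        expected_edges = 45)
  expect_equal(round(enr$fold_enrichment, 1), 6.2)
  expect_lt(enr$p_value, 1e-16)
  # E = lambda: p near 0.5 within Poisson discreteness
  p_eq <- ppois(45 - 1, 45, lower.tail = FALSE)
  expect_gt(p_eq, 0.4); expect_lt(p_eq, 0.6)
  # monotone decrease in observed count at fixed lambda
  ps_small <- lapply(c(100, 200, 280), function(e) {
    pp <- reference_scale_edges(n_edges = e, seed = 7)
    ppi_enrichment(build_network(pp$sets, pp$edges, 0.7),
                   null_model_config("analytic_poisson"),
                   expected_edges = 45)$p_value
  })
  expect_true(all(diff(unlist(ps_small)) < 0))
})

test_that("degree-preserving rewiring preserves every node degree", {
  cfg <- synthetic_config(n_set_a = 20, n_set_b = 8, n_background_genes = 10,
                          seed = 13)
  gs <- generate_gene_sets(cfg)
  ie <- generate_interactome(cfg, gs$sets)
  nodes <- sort(unique(c(ie$gene_a, ie$gene_b)))
  deg0 <- table(factor(c(ie$gene_a, ie$gene_b), levels = nodes))
  set.seed(99)
  for (r in 1:10) {
    rw <- bridgenet:::rewire_candidates(ie, nodes, swaps_per_edge = 20)
    expect_equal(table(factor(c(rw$gene_a, rw$gene_b), levels = nodes)), deg0)
    expect_true(all(rw$gene_a != rw$gene_b))
    expect_false(anyDuplicated(paste(pmin(rw$gene_a, rw$gene_b),
                                     pmax(rw$gene_a, rw$gene_b))) > 0)
  }
})

test_that("permutation-null expected edge count matches exhaustive enumeration", {
  # 6-node graph, 2-node set B; enumerate every simple graph with the same
  # degree sequence and average the cross-set edge count.
  adj <- random_adjacency(6, 0.6, seed = 55)
  nodes <- rownames(adj)
  net <- adjacency_to_network(adj, cutoff = 0.5, n_set_b = 2)
  deg0 <- rowSums(adj)
  prs <- t(utils::combn(6, 2))
  m <- nrow(prs)
  inside_b <- nodes %in% net$gene_sets$set_b
  cross_vals <- c()
  for (code in 0:(2^m - 1)) {
    sel <- bitwAnd(code, 2^(seq_len(m) - 1)) > 0
    if (sum(sel) != sum(deg0) / 2) next
    deg <- tabulate(c(prs[sel, 1], prs[sel, 2]), nbins = 6)
    if (!all(deg == deg0)) next
    cross_vals <- c(cross_vals, sum(xor(inside_b[prs[sel, 1]],
                                        inside_b[prs[sel, 2]])))
  }
  expected_cross <- mean(cross_vals)

  # swap-null estimate of the same expectation
  ed <- net$edges
  set.seed(7)
  reps <- vapply(1:400, function(r) {
    rw <- bridgenet:::rewire_candidates(ed, nodes, swaps_per_edge = 30)
    a_in_b <- rw$gene_a %in% net$gene_sets$set_b
    b_in_b <- rw$gene_b %in% net$gene_sets$set_b
    sum(xor(a_in_b, b_in_b))
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected_cross), 3 * max(se, 0.02))
})

test_that("permutation mode yields a valid p-value and lambda flagging works", {
  cfg <- synthetic_config(n_set_a = 12, n_set_b = 5, n_background_genes = 15,
                          seed = 3)
  gs <- generate_gene_sets(cfg)
  ie <- generate_interactome(cfg, gs$sets)
  net <- build_network(gs$sets, ie, 0.7)
  enr <- ppi_enrichment(net, null_model_config("degree_preserving_swap",
                                               n_replicates = 50, seed = 2,
                                               swaps_per_edge = 10),
                        candidate_edges = ie)
  expect_gte(enr$p_value, 1 / 51)
  expect_lte(enr$p_value, 1)
  expect_length(enr$replicate_counts, 50)
})
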