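test_that("generated gene sets are disjoint, sized as configured, reproducible", {
  cfg <- synthetic_config(seed = 5)
  gs <- generate_gene_sets(cfg)
  expect_length(gs$sets$set_a, 64)
  expect_length(gs$sets$set_b, 17)
  expect_length(intersect(gs$sets$set_a, gs$sets$set_b), 0)
  gs2 <- generate_gene_sets(synthetic_config(seed = 5))
  expect_identical(gs$sets, gs2$sets)
  expect_identical(gs$associations, gs2$associations)

  empty_b <- generate_gene_sets(synthetic_config(n_set_b = 0,
                                                 n_planted_bridges = 0,
                                                 seed = 5))
  expect_length(empty_b$sets$set_b, 0)
})

test_that("exactly the intended members pass the tiered thresholds", {
  cfg <- synthetic_config(n_set_a = 30, n_set_b = 9, seed = 17)
  gs <- generate_gene_sets(cfg)
  # generator bookkeeping is the oracle: decoys are 2x members per disease
  expect_equal(sum(gs$associations$disease_label == "PD"), 90)
  kept <- filter_associations(gs$associations, "PD",
                              cfg$score_threshold_a, cfg$ei_threshold)
  expect_setequal(kept, gs$sets$set_a)
  kept_b <- filter_associations(gs$associations, "CKD",
                                cfg$score_threshold_b, cfg$ei_threshold)
  expect_setequal(kept_b, gs$sets$set_b)
})

test_that("channel decomposition recombines to the target within 1e-9", {
  targets <- c(0.883, 0.701, 0.970, 0.45, 0.1, 0.999)
  ch <- decompose_combined_score(targets)
  back <- combine_channel_scores(ch)
  expect_equal(back, targets, tolerance = 1e-9)
  # anchored rows really use two channels; low targets fall back to one
  expect_true(all(ch$textmining[targets >= 0.5] == 0.4))
  expect_true(all(ch$textmining[targets < 0.4] == 0))
  expect_error(decompose_combined_score(0.02),
               class = "bridgenet_validation_error")
})

test_that("the interactome plants exactly the configured bridges above the cutoff", {
  cfg <- synthetic_config(n_set_a = 20, n_set_b = 8, n_planted_bridges = 6,
                          seed = 23)
  gs <- generate_gene_sets(cfg)
  ie <- generate_interactome(cfg, gs$sets)
  expect_true(all(ie$combined_score >= 0 & ie$combined_score <= 1))
  expect_true(all(ie$gene_a != ie$gene_b))
  planted <- attr(ie, "planted_bridges")
  expect_equal(nrow(planted), 6)
  # recombination of stored channels reproduces every combined score
  expect_equal(combine_channel_scores(ie[channel_names()]),
               ie$combined_score, tolerance = 1e-9)
  # cross-set edges above the cutoff are exactly the planted ones
  net <- build_network(gs$sets, ie, cfg$confidence_cutoff)
  br <- extract_bridges(net, cfg$confidence_cutoff)
  got <- paste(pmin(br$source_set_gene, br$target_set_gene),
               pmax(br$source_set_gene, br$target_set_gene))
  expect_setequal(got, paste(planted$gene_a, planted$gene_b))
})

test_that("planting zero bridges leaves no cross-set edge above the cutoff", {
  cfg <- synthetic_config(n_set_a = 15, n_set_b = 6, n_planted_bridges = 0,
                          seed = 31)
  gs <- generate_gene_sets(cfg)
  ie <- generate_interactome(cfg, gs$sets)
  net <- build_network(gs$sets, ie, cfg$confidence_cutoff)
  expect_equal(nrow(extract_bridges(net, cfg$confidence_cutoff)), 0)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synthetic_config(n_set_a = 3, n_set_b = 2, n_planted_bridges = 7),
               "cross-set pairs", class = "bridgenet_validation_error")
  expect_error(synthetic_config(bridge_score_low = 0.65),
               "strictly above", class = "bridgenet_validation_error")
})

test_that("planted annotation term ranks first in ORA on its own members", {
  cfg <- synthetic_config(n_set_a = 25, n_set_b = 10, seed = 41)
  gs <- generate_gene_sets(cfg)
  genes <- union(gs$sets$set_a, gs$sets$set_b)
  planted <- genes[1:3]
  ann <- generate_annotations(genes, n_terms = 15, planted_term = planted,
                              seed = 42)
  res <- hypergeometric_ora(planted, ann, universe = genes)
  expect_equal(res$term_id[1], "PLANTED_TERM")
  expect_lt(res$p_value[1], min(res$p_value[-1]))
  # single-term GMT: FDR equals raw p
  one <- generate_annotations(genes, n_terms = 1, planted_term = planted,
                              seed = 42)
  res1 <- hypergeometric_ora(planted, one, universe = genes)
  expect_equal(res1$fdr, res1$p_value)
  # reproducibility: identical GMT bytes under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(ann, f1)
  write_gmt(generate_annotations(genes, n_terms = 15,
                                 planted_term = planted, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
})
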