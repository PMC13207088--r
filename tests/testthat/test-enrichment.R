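test_that("hypergeometric p equals exhaustive enumeration on a worked example", {
  # M=10, K=2, n=2, k=2: both query genes annotated -> 1/C(10,2) = 1/45
  universe <- make_names(10)
  terms <- list(T1 = universe[1:2])
  res <- hypergeometric_ora(universe[1:2], terms, universe)
  expect_equal(res$p_value, 1 / 45, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_tail(10, 2, 2, 2), tolerance = 1e-12)
})

test_that("hypergeometric p matches enumeration across all small configurations", {
  for (M in c(5, 8, 12)) {
    universe <- make_names(M)
    for (K in 1:M) for (n in 1:M) {
      kmax <- min(n, K)
      draws <- utils::combn(M, n)
      hits <- apply(draws, 2, function(d) sum(d <= K))
      for (k in 1:kmax) {
        want <- mean(hits >= k)
        got <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("ORA handles the saturated case and zero-overlap terms", {
  universe <- make_names(6)
  terms <- list(ALL = universe, NONE = make_names(8)[7:8],
                HALF = universe[1:3])
  res <- hypergeometric_ora(universe, terms, universe)
  sat <- res[res$term_id == "ALL", ]
  expect_equal(sat$p_value, 1)
  expect_equal(sat$strength, 0)
  expect_false("NONE" %in% res$term_id)  # < 2 members in universe: skipped
  expect_error(hypergeometric_ora("X", terms, character(0)),
               class = "bridgenet_validation_error")
  expect_error(hypergeometric_ora("Z9", terms, universe),
               "outside the universe", class = "bridgenet_validation_error")
})

test_that("ORA is invariant to term order and strength follows log10(obs/exp)", {
  universe <- make_names(12)
  set.seed(8)
  terms <- list(A = universe[1:4], B = universe[3:8], C = universe[c(1, 9:12)])
  query <- universe[1:5]
  r1 <- hypergeometric_ora(query, terms, universe)
  r2 <- hypergeometric_ora(query, rev(terms), universe)
  expect_equal(r1, r2)
  k <- r1$observed_count; K <- r1$term_size_in_universe
  expect_equal(r1$strength, log10(k / (length(query) * K / 12)))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.005, 0.04, 0.04, 0.6)
  expect_equal(bh_fdr(p), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.6))
  expect_equal(bh_fdr(0.2), 0.2)      # m = 1 unchanged
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 0)), class = "bridgenet_validation_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "bridgenet_validation_error")

  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) > -1e-12))
  }
})

test_that("vesicle catalog membership flags the expected cargo genes", {
  res <- vesicle_membership(c("APOA1", "SNCA", "NOVEL1"))
  expect_true(all(res$EXOSOME[res$gene_symbol %in% c("APOA1", "SNCA")]))
  novel <- res[res$gene_symbol == "NOVEL1", ]
  expect_false(any(unlist(novel[, setdiff(names(novel),
                                          c("gene_symbol", "catalogs"))])))
  expect_equal(novel$catalogs, "")
  expect_equal(nrow(vesicle_membership(character(0))), 0)
})

test_that("expression context reports per-tissue TPM and the argmax tissue", {
  expr <- read_expression_table(bridgenet_example("tissue_expression_synthetic.tsv"))
  ctx <- expression_context(c("SNCA", "UMOD", "GHOST"), expr)
  expect_equal(ctx$top_tissue[ctx$gene_symbol == "SNCA"], "substantia_nigra")
  expect_equal(ctx$top_tissue[ctx$gene_symbol == "UMOD"], "kidney_cortex")
  expect_true(is.na(ctx$top_tissue[ctx$gene_symbol == "GHOST"]))
  expect_equal(ctx$substantia_nigra[ctx$gene_symbol == "SNCA"], 20.81)

  # tie on the maximum: first tissue in the supplied order wins
  tie <- data.frame(gene_symbol = "G1", tissue = c("t1", "t2"), tpm = c(5, 5))
  expect_equal(expression_context("G1", tie, tissues = c("t2", "t1"))$top_tissue,
               "t2")
})
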