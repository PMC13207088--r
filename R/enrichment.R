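## Phase 4: hypergeometric over-representation analysis, BH-FDR, and the
## annotation joins (vesicle catalogs, tissue expression).

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (via `stats::p.adjust`) with input validation;
#' output order matches input order, values are monotone when re-sorted by
#' raw p and are capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.numeric(p_values)) || any(is.na(p_values)) ||
      any(p_values <= 0 | p_values > 1))
    stop_validation("p-values must lie in (0,1]")
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation in a query gene set
#' against a fixed universe. For a term with K members in the universe
#' (M genes) and k members in the query (n genes), the p-value is the
#' hypergeometric upper tail Pr(X >= k). BH-FDR is applied across all
#' tested terms in one family. Strength is log10(k / (n K / M)), the
#' log-ratio of observed to expected annotated genes; terms with k = 0
#' report p = 1 and strength `-Inf`. Terms with fewer than `min_term_size`
#' members in the universe are skipped.
#'
#' @param query Character vector of query gene symbols (must lie in the
#'   universe).
#' @param terms An `annotation_sets` list (see [read_gmt()]) or named list
#'   of member vectors.
#' @param universe Character vector of background gene symbols.
#' @param min_term_size Minimum in-universe term size to test; default 2.
#' @return A data.frame of class `enrichment_results`, one row per tested
#'   term, ordered by p-value: `term_id`, `term_name`, `observed_count`,
#'   `term_size_in_universe`, `query_size`, `universe_size`, `p_value`,
#'   `fdr`, `strength`.
#' @export
hypergeometric_ora <- function(query, terms, universe, min_term_size = 2) {
  universe <- unique(normalize_symbol(universe))
  if (length(universe) == 0) stop_validation("universe is empty")
  query <- unique(normalize_symbol(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    stop_validation("query gene(s) outside the universe: %s",
                    paste(utils::head(outside, 5), collapse = ", "))
  M <- length(universe); n <- length(query)
  ids <- names(terms)
  rows <- lapply(ids, function(id) {
    members <- intersect(unique(normalize_symbol(terms[[id]])), universe)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(members, query))
    p <- if (k == 0) 1 else phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    expected <- n * K / M
    strength <- if (k == 0) -Inf else log10(k / expected)
    desc <- attr(terms[[id]], "description")
    data.frame(term_id = id,
               term_name = if (is.null(desc)) id else desc,
               observed_count = k, term_size_in_universe = K,
               query_size = n, universe_size = M,
               p_value = p, strength = strength,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      observed_count = integer(0),
                      term_size_in_universe = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      strength = numeric(0))
    class(out) <- c("enrichment_results", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_name", "observed_count",
               "term_size_in_universe", "query_size", "universe_size",
               "p_value", "fdr", "strength")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Cross-reference genes against vesicle-cargo catalogs
#'
#' Flags, for each gene, membership in each supplied catalog (e.g. exosome
#' or extracellular-vesicle cargo sets in GMT form).
#'
#' @param genes Character vector of gene symbols.
#' @param catalogs An `annotation_sets` list or named list of member
#'   vectors; default is the packaged synthetic vesicle catalog fixture.
#' @return Data.frame with `gene_symbol`, one logical column per catalog,
#'   and `catalogs` (comma-separated ids of catalogs containing the gene).
#' @export
vesicle_membership <- function(genes,
                               catalogs = read_gmt(bridgenet_example("vesicle_catalogs_synthetic.gmt"))) {
  genes <- unique(normalize_symbol(genes))
  out <- data.frame(gene_symbol = genes, stringsAsFactors = FALSE)
  for (id in names(catalogs)) out[[id]] <- genes %in% catalogs[[id]]
  out$catalogs <- vapply(seq_along(genes), function(i) {
    hit <- names(catalogs)[vapply(names(catalogs),
                                  function(id) out[[id]][i], logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  if (length(genes) == 0) out$catalogs <- character(0)
  out
}

#' Tissue-expression context for a gene set
#'
#' Builds a wide gene-by-tissue TPM table and reports each gene's
#' highest-expressing tissue. Missing gene/tissue combinations are `NA`;
#' ties on the maximum are broken by the first tissue in `tissues` order.
#'
#' @param genes Character vector of gene symbols.
#' @param expr Long-format expression data.frame
#'   (see [read_expression_table()]).
#' @param tissues Optional ordered tissue vector fixing column order and the
#'   tie-break; defaults to order of first appearance in `expr`.
#' @return Data.frame with `gene_symbol`, one TPM column per tissue, and
#'   `top_tissue` (`NA` for genes with no expression rows).
#' @export
expression_context <- function(genes, expr, tissues = NULL) {
  genes <- unique(normalize_symbol(genes))
  if (is.null(tissues)) tissues <- unique(expr$tissue)
  out <- data.frame(gene_symbol = genes, stringsAsFactors = FALSE)
  for (tis in tissues) {
    out[[tis]] <- vapply(genes, function(g) {
      v <- expr$tpm[expr$gene_symbol == g & expr$tissue == tis]
      if (length(v) == 0) NA_real_ else max(v)
    }, numeric(1))
  }
  out$top_tissue <- vapply(seq_along(genes), function(i) {
    v <- as.numeric(out[i, tissues, drop = TRUE])
    if (all(is.na(v))) return(NA_character_)
    tissues[which.max(replace(v, is.na(v), -Inf))]
  }, character(1))
  if (length(genes) == 0) out$top_tissue <- character(0)
  out
}
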