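#' bridgenet: cross-disease interactome convergence analysis
#'
#' Tools for quantifying molecular convergence between two genetically
#' distinct disease gene sets at the protein-protein interaction (PPI) level:
#' tiered curation of gene-disease associations, STRING-convention evidence
#' score combination, confidence-thresholded network construction, edge
#' enrichment against Poisson and degree-preserving permutation nulls,
#' cross-set "molecular bridge" extraction and prioritization, Maximal
#' Clique Centrality hub ranking, hypergeometric over-representation
#' analysis, annotation joins, and threshold sensitivity analysis.
#'
#' The typical entry point is [run_pipeline()]; each stage is also exported
#' on its own. [synthetic_config()] / [generate_gene_sets()] /
#' [generate_interactome()] produce fully synthetic inputs with planted,
#' recoverable structure.
#'
#' @keywords internal
#' @importFrom stats ppois phyper p.adjust runif rnorm setNames
#' @importFrom utils read.delim write.table head
"_PACKAGE"

## The seven STRING-style evidence channels, in canonical column order.
CHANNELS <- c("experimental", "database", "textmining", "coexpression",
              "neighborhood", "fusion", "cooccurrence")

#' Evidence channel names
#'
#' The seven evidence channels recognised in edge tables, in canonical order:
#' experimental, database, textmining, coexpression, neighborhood, fusion,
#' cooccurrence.
#'
#' @return Character vector of channel names.
#' @export
#' @examples
#' channel_names()
channel_names <- function() CHANNELS

## --- internal validation helpers -------------------------------------------

stop_format <- function(msg, ...) {
  stop(structure(class = c("bridgenet_format_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

stop_validation <- function(msg, ...) {
  stop(structure(class = c("bridgenet_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

is_prob <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x <= 1

## Uppercase + strip whitespace; the only symbol normalisation performed.
normalize_symbol <- function(x) toupper(trimws(as.character(x)))

#' Construct a pair of labelled disease gene sets
#'
#' Container for the two disease-specific gene symbol sets the analysis
#' compares (by convention set A is the larger, e.g. PD, and set B the
#' smaller, e.g. CKD). Symbols are uppercased, whitespace-stripped and
#' deduplicated within each set.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param set_a_label,set_b_label Labels for the two sets.
#' @return An object of class `disease_gene_sets`: a list with elements
#'   `set_a`, `set_b`, `set_a_label`, `set_b_label`.
#' @export
#' @examples
#' disease_gene_sets(c("SNCA", "TNF"), c("UMOD", "FN1"))
disease_gene_sets <- function(set_a, set_b,
                              set_a_label = "PD", set_b_label = "CKD") {
  set_a <- unique(normalize_symbol(set_a))
  set_b <- unique(normalize_symbol(set_b))
  set_a <- set_a[nzchar(set_a)]
  set_b <- set_b[nzchar(set_b)]
  structure(list(set_a = set_a, set_b = set_b,
                 set_a_label = set_a_label, set_b_label = set_b_label),
            class = "disease_gene_sets")
}

#' @export
print.disease_gene_sets <- function(x, ...) {
  cat(sprintf("Disease gene sets: %s (n=%d) / %s (n=%d), overlap %d\n",
              x$set_a_label, length(x$set_a),
              x$set_b_label, length(x$set_b),
              length(intersect(x$set_a, x$set_b))))
  invisible(x)
}

## Union of both sets (the analysis universe by default).
gene_union <- function(sets) union(sets$set_a, sets$set_b)

## Assert a data.frame of edges has the canonical columns.
check_edge_frame <- function(edges) {
  needed <- c("gene_a", "gene_b", CHANNELS, "combined_score")
  missing <- setdiff(needed, names(edges))
  if (length(missing) > 0)
    stop_format("edge table lacks column(s): %s", paste(missing, collapse = ", "))
  invisible(edges)
}

## Empty canonical edge frame.
empty_edges <- function() {
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    stringsAsFactors = FALSE)
  for (ch in CHANNELS) out[[ch]] <- numeric(0)
  out$combined_score <- numeric(0)
  out
}

## Canonicalize: lexicographic endpoint order, merge duplicate unordered
## pairs keeping the per-channel maximum (combined recomputed as max too).
canonicalize_edges <- function(edges) {
  check_edge_frame(edges)
  if (nrow(edges) == 0) return(empty_edges())
  a <- normalize_symbol(edges$gene_a)
  b <- normalize_symbol(edges$gene_b)
  if (any(a == b))
    stop_validation("self-loop edge at row %d (%s)", which(a == b)[1], a[a == b][1])
  swap <- a > b
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  out <- data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  for (ch in CHANNELS) out[[ch]] <- as.numeric(edges[[ch]])
  out$combined_score <- as.numeric(edges$combined_score)
  key <- paste(out$gene_a, out$gene_b, sep = "\t")
  if (anyDuplicated(key)) {
    sp <- split(seq_len(nrow(out)), key)
    rows <- lapply(sp, function(idx) {
      r <- out[idx[1], , drop = FALSE]
      for (ch in c(CHANNELS, "combined_score")) r[[ch]] <- max(out[[ch]][idx])
      r
    })
    out <- do.call(rbind, rows)
  }
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Internal: run expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
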