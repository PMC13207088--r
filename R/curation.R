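## Phase 1: tiered, disease-specific filtering and the disjointness check.

#' Tiered filtering of gene-disease associations
#'
#' Retains the genes associated with `disease` whose association score and
#' evidence index both meet their thresholds (inclusive `>=` comparisons). A
#' gene appearing in several rows for the disease is retained if any row
#' passes. Raising either threshold can only shrink the returned set.
#'
#' @param assocs Association data.frame (see [read_association_table()]).
#' @param disease Disease label to filter on.
#' @param score_min Minimum association score in \[0, 1\].
#' @param ei_min Minimum evidence index in \[0, 1\].
#' @return Sorted character vector of unique gene symbols.
#' @export
#' @examples
#' df <- data.frame(gene_symbol = c("SNCA", "LRRK2"),
#'                  disease_label = "PD",
#'                  score = c(0.9, 0.5), evidence_index = c(0.9, 0.9))
#' filter_associations(df, "PD", 0.8, 0.4)
filter_associations <- function(assocs, disease, score_min, ei_min) {
  if (!is_prob(score_min) || !is_prob(ei_min))
    stop_validation("thresholds must lie in [0,1]")
  hit <- assocs$disease_label == disease
  if (!any(hit)) {
    warning(sprintf("no associations for disease label '%s'", disease))
    return(character(0))
  }
  keep <- hit & assocs$score >= score_min & assocs$evidence_index >= ei_min
  sort(unique(assocs$gene_symbol[keep]))
}

#' Overlap report for two disease gene sets
#'
#' Returns the intersection of the two sets and their Jaccard index
#' |A intersect B| / |A union B| (0 when both sets are empty).
#'
#' @param sets A [disease_gene_sets()] object.
#' @return List with `intersection`, `n_union`, `jaccard`.
#' @export
check_overlap <- function(sets) {
  stopifnot(inherits(sets, "disease_gene_sets"))
  inter <- intersect(sets$set_a, sets$set_b)
  uni <- gene_union(sets)
  list(intersection = sort(inter),
       n_union = length(uni),
       jaccard = if (length(uni) == 0) 0 else length(inter) / length(uni))
}
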