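## Phase 5: Maximal Clique Centrality hub analysis.

#' Enumerate maximal cliques of the network
#'
#' All maximal cliques of size >= 2 (pivoting Bron-Kerbosch, via igraph). A
#' returned node set is a clique with no strict clique superset.
#'
#' @param net A `disease_network`.
#' @return List of character vectors (each sorted), in no guaranteed order.
#' @export
enumerate_maximal_cliques <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  if (nrow(net$edges) == 0) return(list())
  g <- as_igraph(net)
  lapply(igraph::max_cliques(g, min = 2),
         function(v) sort(igraph::V(g)$name[v]))
}

#' Maximal Clique Centrality hub scores
#'
#' For each node v, MCC(v) is the sum over all maximal cliques C containing
#' v of (|C| - 1)!. For a node whose neighborhood contains no internal edge
#' every maximal clique through it is a single edge, so MCC equals its
#' degree; an isolated node scores 0. Degree and (unnormalized, unweighted
#' shortest-path, endpoints excluded) betweenness centrality are computed
#' alongside, and nodes are ranked by MCC descending with ties broken by
#' degree descending then gene symbol.
#'
#' MCC is accumulated in double precision; factorials of clique sizes up to
#' ~170 are representable, far beyond any network this package targets.
#'
#' @param net A `disease_network`.
#' @return A data.frame of class `hub_scores` with columns `gene_symbol`,
#'   `mcc`, `degree`, `betweenness`, `rank_mcc`, ordered by rank.
#' @export
mcc_scores <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  mcc <- setNames(numeric(length(nodes)), nodes)
  for (cl in enumerate_maximal_cliques(net)) {
    contrib <- factorial(length(cl) - 1)
    mcc[cl] <- mcc[cl] + contrib
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  out <- data.frame(gene_symbol = nodes,
                    mcc = as.numeric(mcc[nodes]),
                    degree = as.integer(deg[nodes]),
                    betweenness = as.numeric(btw[nodes]),
                    stringsAsFactors = FALSE)
  ord <- order(-out$mcc, -out$degree, out$gene_symbol)
  out <- out[ord, , drop = FALSE]
  out$rank_mcc <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("hub_scores", "data.frame")
  out
}

#' Top-k hub proteins
#'
#' @param scores A `hub_scores` data.frame from [mcc_scores()].
#' @param k Number of hubs to return (default 10); if `k` exceeds the node
#'   count all nodes are returned with a warning.
#' @return The first `k` rows by MCC rank.
#' @export
top_hubs <- function(scores, k = 10) {
  stopifnot(inherits(scores, "hub_scores"))
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop_validation("k must be a positive integer")
  if (k > nrow(scores)) {
    warning(sprintf("k = %d exceeds node count %d; returning all", k, nrow(scores)))
    k <- nrow(scores)
  }
  scores[seq_len(k), , drop = FALSE]
}

#' @export
print.hub_scores <- function(x, ...) {
  cat(sprintf("Hub scores for %d node(s) (MCC rank order)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}
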