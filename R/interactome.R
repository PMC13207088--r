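## Network construction and edge-enrichment statistics.

#' Combine evidence-channel scores into a single confidence score
#'
#' Implements the STRING probabilistic convention for integrating independent
#' evidence channels. Each channel score s is first corrected for the prior
#' probability p0 of a random pair interacting, s' = max(0, (s - p0)/(1 - p0));
#' the corrected scores are combined as independent probabilities,
#' S' = 1 - prod(1 - s'); and the prior is added back,
#' S = S'(1 - p0) + p0. A row in which no channel exceeds the prior scores 0.
#' A single channel therefore round-trips unchanged: combining (s, 0, ..., 0)
#' returns s whenever s > p0.
#'
#' @param channels A numeric vector of channel scores in \[0, 1\], or a
#'   data.frame/matrix with one column per channel (rows combined
#'   independently).
#' @param prior Prior probability p0 in \[0, 1); default 0.041.
#' @return Numeric vector of combined scores in \[0, 1).
#' @export
#' @examples
#' combine_channel_scores(c(0.9, 0, 0))          # 0.9
#' combine_channel_scores(c(0.3, 0.5, 0.4))
combine_channel_scores <- function(channels, prior = 0.041) {
  if (!is.numeric(prior) || length(prior) != 1 || prior < 0 || prior >= 1)
    stop_validation("prior must be a single value in [0,1)")
  m <- if (is.data.frame(channels) || is.matrix(channels))
    as.matrix(channels) else matrix(as.numeric(channels), nrow = 1)
  if (any(!is_prob(m)))
    stop_validation("channel scores must lie in [0,1]")
  corr <- (m - prior) / (1 - prior)
  corr[corr < 0] <- 0
  s_comb <- 1 - apply(1 - corr, 1, prod)
  out <- s_comb * (1 - prior) + prior
  out[apply(m <= prior, 1, all)] <- 0
  unname(out)
}

#' Build a two-set disease interaction network
#'
#' Restricts a scored edge collection to the union of the two disease gene
#' sets and to edges whose combined score meets the confidence cutoff
#' (inclusive, `>=`). Genes from either set with no surviving edge remain in
#' the network as isolated nodes.
#'
#' @param sets A [disease_gene_sets()] object.
#' @param edges Canonical edge data.frame (see [read_edge_table()]).
#' @param cutoff Confidence cutoff in \[0, 1\]; default 0.7.
#' @return An object of class `disease_network`: list with elements
#'   `gene_sets`, `edges`, `nodes`, `confidence_cutoff`.
#' @export
build_network <- function(sets, edges, cutoff = 0.7) {
  stopifnot(inherits(sets, "disease_gene_sets"))
  if (!is_prob(cutoff)) stop_validation("cutoff must lie in [0,1]")
  nodes <- gene_union(sets)
  if (length(nodes) == 0)
    stop_validation("both disease gene sets are empty")
  edges <- canonicalize_edges(edges)
  keep <- edges$gene_a %in% nodes & edges$gene_b %in% nodes &
    edges$combined_score >= cutoff
  structure(list(gene_sets = sets,
                 edges = edges[keep, , drop = FALSE],
                 nodes = sort(nodes),
                 confidence_cutoff = cutoff),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("Disease network: %d nodes (%s %d / %s %d), %d edges at cutoff >= %.3f\n",
              length(x$nodes),
              x$gene_sets$set_a_label, length(x$gene_sets$set_a),
              x$gene_sets$set_b_label, length(x$gene_sets$set_b),
              nrow(x$edges), x$confidence_cutoff))
  invisible(x)
}

## Internal: igraph view of a disease_network (keeps isolated nodes).
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = net$nodes))
}

#' Summarize network topology
#'
#' Computes node/edge counts, average degree (2E/N) and the network-level
#' clustering coefficient, defined as the unweighted mean over all nodes of
#' the local clustering coefficient, with nodes of degree < 2 contributing 0.
#'
#' @param net A `disease_network`.
#' @return An object of class `network_summary`: list with `n_nodes`,
#'   `n_edges`, `average_degree`, `clustering_coefficient` (null-model fields
#'   `expected_edges_null`, `fold_enrichment`, `ppi_enrichment_p` are `NA`
#'   until filled by [ppi_enrichment()]).
#' @export
summarize_topology <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  n <- length(net$nodes)
  if (n == 0) stop_validation("network has no nodes")
  e <- nrow(net$edges)
  g <- as_igraph(net)
  cc <- if (e == 0) 0 else
    mean(igraph::transitivity(g, type = "localaverage", isolates = "zero"))
  structure(list(n_nodes = n, n_edges = e,
                 average_degree = 2 * e / n,
                 clustering_coefficient = cc,
                 expected_edges_null = NA_real_,
                 fold_enrichment = NA_real_,
                 ppi_enrichment_p = NA_real_),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Nodes: %d  Edges: %d  Avg degree: %.2f  Clustering: %.3f\n",
              x$n_nodes, x$n_edges, x$average_degree, x$clustering_coefficient))
  if (!is.na(x$expected_edges_null))
    cat(sprintf("Expected edges (null): %.1f  Fold enrichment: %.1f  PPI enrichment p: %s\n",
                x$expected_edges_null, x$fold_enrichment,
                format(x$ppi_enrichment_p, digits = 3)))
  invisible(x)
}

#' Configure the edge-count null model
#'
#' @param method `"analytic_poisson"` (Poisson upper tail on the observed
#'   edge count, with the expected count supplied or estimated by the swap
#'   null) or `"degree_preserving_swap"` (permutation p-value across
#'   degree-preserving rewired replicates).
#' @param n_replicates Number of rewired replicates; default 1000.
#' @param swaps_per_edge Attempted double-edge swaps per edge per replicate;
#'   default 100.
#' @param seed RNG seed for the swap chain.
#' @param prior Evidence prior p0 carried for score recombination; default
#'   0.041.
#' @return A list of class `null_model_config`.
#' @export
null_model_config <- function(method = c("analytic_poisson", "degree_preserving_swap"),
                              n_replicates = 1000, swaps_per_edge = 100,
                              seed = 1L, prior = 0.041) {
  method <- match.arg(method)
  if (n_replicates < 1) stop_validation("n_replicates must be >= 1")
  structure(list(method = method, n_replicates = as.integer(n_replicates),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed), prior = prior),
            class = "null_model_config")
}

## Internal: one degree-preserving double-edge-swap pass over an integer
## edge matrix (m x 2). Rejected proposals (self-loop or multi-edge) leave
## the state unchanged, preserving the uniform stationary distribution.
double_edge_swap <- function(em, n_attempts) {
  m <- nrow(em)
  if (m < 2) return(em)
  key <- function(a, b) ifelse(a < b, a * 1e6 + b, b * 1e6 + a)
  have <- new.env(hash = TRUE, size = 2 * m)
  for (i in seq_len(m)) assign(as.character(key(em[i, 1], em[i, 2])), TRUE, envir = have)
  picks <- matrix(sample.int(m, 2 * n_attempts, replace = TRUE), ncol = 2)
  flips <- runif(n_attempts) < 0.5
  for (t in seq_len(n_attempts)) {
    i <- picks[t, 1]; j <- picks[t, 2]
    if (i == j) next
    a <- em[i, 1]; b <- em[i, 2]; c <- em[j, 1]; d <- em[j, 2]
    # two swap orientations: (a,d)(c,b) or (a,c)(b,d)
    if (flips[t]) { nb <- d; nd <- b } else { nb <- c; nd <- b; c <- d }
    # after: edge i = (a, nb), edge j = (c, nd)
    if (a == nb || c == nd) next
    k1 <- as.character(key(a, nb)); k2 <- as.character(key(c, nd))
    if (k1 == k2) next
    if (exists(k1, envir = have, inherits = FALSE) ||
        exists(k2, envir = have, inherits = FALSE)) next
    rm(list = c(as.character(key(em[i, 1], em[i, 2])),
                as.character(key(em[j, 1], em[j, 2]))), envir = have)
    em[i, ] <- c(a, nb); em[j, ] <- c(c, nd)
    assign(k1, TRUE, envir = have); assign(k2, TRUE, envir = have)
  }
  em
}

## Internal: rewire a candidate edge frame once, preserving every node's
## degree; per-edge scores travel with the (rewired) edges.
rewire_candidates <- function(edges, nodes, swaps_per_edge) {
  ids <- setNames(seq_along(nodes), nodes)
  em <- cbind(ids[edges$gene_a], ids[edges$gene_b])
  em2 <- double_edge_swap(em, n_attempts = swaps_per_edge * nrow(em))
  out <- edges
  out$gene_a <- nodes[em2[, 1]]
  out$gene_b <- nodes[em2[, 2]]
  out
}

#' Edge enrichment of the disease network against a null model
#'
#' Tests whether the network holds more high-confidence edges than expected
#' for a random network of the same size and degree distribution.
#'
#' In analytic mode the expected edge count lambda is taken from
#' `expected_edges` when supplied (e.g. a value reported by an external
#' platform) or estimated as the mean count across degree-preserving rewired
#' replicates of the candidate edge set; the p-value is the Poisson upper
#' tail Pr(X >= E | lambda). In permutation mode the p-value is
#' (1 + #\{replicates >= E\}) / (1 + n_replicates).
#'
#' The candidate edge set defaults to the network's own edges; passing the
#' unfiltered edge table (including sub-threshold and background-gene edges)
#' gives a more informative null, since rewiring can then move
#' high-confidence edges outside the disease union. Replicate counts are the
#' number of rewired edges with combined score >= the network cutoff and
#' both endpoints inside the disease union.
#'
#' @param net A `disease_network`.
#' @param null A [null_model_config()].
#' @param candidate_edges Optional canonical edge data.frame to rewire;
#'   default `net$edges`.
#' @param expected_edges Optional externally supplied expected edge count
#'   (analytic mode only).
#' @return List of class `ppi_enrichment` with `observed_edges`,
#'   `expected_edges`, `fold_enrichment`, `p_value`, `method`,
#'   `lambda_zero_flag`, and (permutation estimates) `replicate_counts`.
#' @export
ppi_enrichment <- function(net, null = null_model_config(),
                           candidate_edges = NULL, expected_edges = NULL) {
  stopifnot(inherits(net, "disease_network"), inherits(null, "null_model_config"))
  e_obs <- nrow(net$edges)
  if (length(net$nodes) == 0) stop_validation("network has no nodes")
  counts <- NULL
  if (is.null(expected_edges)) {
    cand <- if (is.null(candidate_edges)) net$edges
            else canonicalize_edges(candidate_edges)
    if (nrow(cand) == 0) {
      lambda <- 0
    } else {
      nodes_all <- sort(union(unique(c(cand$gene_a, cand$gene_b)), net$nodes))
      inside <- net$nodes
      counts <- with_seed(null$seed, vapply(seq_len(null$n_replicates), function(r) {
        rw <- rewire_candidates(cand, nodes_all, null$swaps_per_edge)
        sum(rw$combined_score >= net$confidence_cutoff &
              rw$gene_a %in% inside & rw$gene_b %in% inside)
      }, numeric(1)))
      lambda <- mean(counts)
    }
  } else {
    lambda <- expected_edges
  }
  flag <- FALSE
  if (null$method == "analytic_poisson") {
    if (lambda <= 0 && e_obs > 0) {
      p <- 1 / (1 + null$n_replicates); flag <- TRUE
    } else if (lambda <= 0) {
      p <- 1
    } else {
      p <- ppois(e_obs - 1, lambda, lower.tail = FALSE)
    }
  } else {
    if (is.null(counts))
      stop_validation("permutation mode requires candidate edges (no expected_edges override)")
    p <- (1 + sum(counts >= e_obs)) / (1 + null$n_replicates)
  }
  structure(list(observed_edges = e_obs,
                 expected_edges = lambda,
                 fold_enrichment = if (lambda > 0) e_obs / lambda else NA_real_,
                 p_value = p,
                 method = null$method,
                 lambda_zero_flag = flag,
                 replicate_counts = counts),
            class = "ppi_enrichment")
}

#' @export
print.ppi_enrichment <- function(x, ...) {
  cat(sprintf("Observed edges: %d  Expected (null): %.2f  Fold: %s  p: %s%s\n",
              x$observed_edges, x$expected_edges,
              ifelse(is.na(x$fold_enrichment), "NA",
                     sprintf("%.1f", x$fold_enrichment)),
              format(x$p_value, digits = 3),
              if (x$lambda_zero_flag) "  [lambda=0: p is an upper bound]" else ""))
  invisible(x)
}
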