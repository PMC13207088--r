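# Brute-force oracles, coded independently of the package internals (and of
# igraph), plus small graph-building helpers shared across test files.

# Direct scalar evaluation of the evidence-combination formula.
oracle_combine <- function(channels, prior = 0.041) {
  any_evidence <- FALSE
  residual <- 1
  for (s in channels) {
    if (s > prior) any_evidence <- TRUE
    corrected <- (s - prior) / (1 - prior)
    if (corrected < 0) corrected <- 0
    residual <- residual * (1 - corrected)
  }
  if (!any_evidence) return(0)
  (1 - residual) * (1 - prior) + prior
}

# Random simple graph as a symmetric adjacency matrix with letter names.
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(make_names(n), make_names(n))
  adj
}

make_names <- function(n) sprintf("N%02d", seq_len(n))

# Canonical edge frame from an adjacency matrix; every edge gets the same
# combined score (delivered via the experimental channel column for realism).
adjacency_to_edges <- function(adj, score = 0.9) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(adj)[idx[, 1]],
                   gene_b = colnames(adj)[idx[, 2]],
                   stringsAsFactors = FALSE)
  for (ch in channel_names()) df[[ch]] <- rep(0, nrow(df))
  df$experimental <- rep(score, nrow(df))
  df$combined_score <- rep(score, nrow(df))
  df
}

# disease_network over an adjacency matrix; nodes split between two sets.
adjacency_to_network <- function(adj, cutoff = 0.5, n_set_b = 0) {
  nodes <- rownames(adj)
  b <- if (n_set_b > 0) utils::tail(nodes, n_set_b) else character(0)
  a <- setdiff(nodes, b)
  build_network(disease_gene_sets(a, b), adjacency_to_edges(adj), cutoff)
}

# All maximal cliques of size >= 2 by exhaustive subset checking.
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  is_clique <- function(members) {
    if (length(members) < 2) return(FALSE)
    prs <- utils::combn(members, 2)
    all(adj[cbind(prs[1, ], prs[2, ])] > 0)
  }
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    members <- nodes[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    if (!is_clique(members)) next
    # maximal iff no outside vertex is adjacent to every member
    outside <- setdiff(nodes, members)
    extendable <- any(vapply(outside, function(v)
      all(adj[v, members] > 0), logical(1)))
    if (!extendable) cliques[[length(cliques) + 1]] <- sort(members)
  }
  cliques
}

oracle_mcc <- function(adj) {
  cliques <- oracle_cliques(adj)
  mcc <- setNames(numeric(nrow(adj)), rownames(adj))
  for (cl in cliques) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  mcc
}

# Unnormalized shortest-path betweenness by explicit path counting:
# BFS per source for distances/path counts, then the pair-sum formula.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) for (v in which(adj[u, ] > 0)) {
        if (is.infinite(dist[s, v])) {
          dist[s, v] <- dist[s, u] + 1
          nxt <- union(nxt, v)
        }
        if (dist[s, v] == dist[s, u] + 1)
          sigma[s, v] <- sigma[s, v] + sigma[s, u]
      }
      frontier <- nxt
    }
  }
  bt <- setNames(numeric(n), nodes)
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (s == v || t == v || s == t) next
    if (is.infinite(dist[s, t])) next
    if (dist[s, v] + dist[v, t] == dist[s, t])
      bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  bt
}

# Hypergeometric upper tail by exhaustive enumeration of all draws of size n
# from a universe of M genes containing K marked ones.
oracle_hyper_tail <- function(M, K, n, k) {
  draws <- utils::combn(M, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Hand-rolled BH step-up (independent of stats::p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Published bridge fixture edges plus helper fixtures, loaded once.
fixture_bridge_edges <- function() {
  read_edge_table(bridgenet_example("bridges_published.tsv"))
}

fixture_sets <- function() {
  assoc <- read_association_table(bridgenet_example("associations_synthetic.tsv"))
  disease_gene_sets(filter_associations(assoc, "PD", 0.8, 0.4),
                    filter_associations(assoc, "CKD", 0.6, 0.4))
}

# Reference-scale interactome: the fixture gene sets wired with exactly
# `n_edges` distinct above-cutoff edges (deterministic under seed).
reference_scale_edges <- function(n_edges = 280, seed = 42, score_lo = 0.7) {
  sets <- fixture_sets()
  nodes <- sort(union(sets$set_a, sets$set_b))
  set.seed(seed)
  prs <- t(utils::combn(nodes, 2))
  pick <- sample.int(nrow(prs), n_edges)
  df <- data.frame(gene_a = prs[pick, 1], gene_b = prs[pick, 2],
                   stringsAsFactors = FALSE)
  for (ch in channel_names()) df[[ch]] <- 0
  df$experimental <- round(runif(n_edges, score_lo, 0.99), 6)
  df$combined_score <- df$experimental
  list(sets = sets, edges = df)
}
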