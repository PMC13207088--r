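## Phase 6: threshold sensitivity analysis.

## Jaccard index over two character vectors of keys; two empty sets count
## as identical (1).
jaccard_keys <- function(x, y) {
  u <- union(x, y)
  if (length(u) == 0) return(1)
  length(intersect(x, y)) / length(u)
}

bridge_keys <- function(bridges) {
  paste(pmin(bridges$source_set_gene, bridges$target_set_gene),
        pmax(bridges$source_set_gene, bridges$target_set_gene), sep = "\t")
}

## One curation -> network -> bridges -> hubs pass at given thresholds.
grid_point_run <- function(assocs, edges, p) {
  set_a <- filter_associations(assocs, p$disease_a, p$score_min_a, p$ei_min_a)
  set_b <- filter_associations(assocs, p$disease_b, p$score_min_b, p$ei_min_b)
  sets <- disease_gene_sets(set_a, set_b, p$disease_a, p$disease_b)
  if (length(gene_union(sets)) == 0)
    return(list(bridges = character(0), hubs = character(0), n_bridges = 0L))
  net <- build_network(sets, edges, cutoff = p$cutoff)
  br <- extract_bridges(net, min_score = p$cutoff)
  hubs <- mcc_scores(net)
  k <- min(p$top_k, nrow(hubs))
  list(bridges = bridge_keys(br),
       hubs = hubs$gene_symbol[seq_len(k)],
       n_bridges = nrow(br))
}

#' Threshold sensitivity grid
#'
#' Re-runs curation, network construction, bridge extraction and hub ranking
#' across a factorial grid of offsets applied to the set-A association score
#' threshold, the set-B association score threshold, and the network
#' confidence cutoff (the bridge threshold moves with the cutoff). Each grid
#' point is compared against the baseline via the Jaccard index of bridge
#' sets and the overlap fraction of top-k hubs; the baseline point is
#' included and scores 1.0 on both by construction. Grid points whose
#' thresholds leave \[0, 1\] are skipped with a warning.
#'
#' @param assocs Association data.frame (see [read_association_table()]).
#' @param edges Canonical edge data.frame (unfiltered candidate set).
#' @param baseline Named list of baseline parameters: `disease_a`,
#'   `disease_b`, `score_min_a`, `ei_min_a`, `score_min_b`, `ei_min_b`,
#'   `cutoff`, `top_k`. Missing entries take the defaults 0.8/0.4 (A),
#'   0.6/0.4 (B), 0.7, 10.
#' @param deltas Offsets applied to each varied parameter;
#'   default `c(-0.1, 0, 0.1)` (27-point factorial grid).
#' @return A data.frame of class `sensitivity_report`: one row per evaluated
#'   grid point with the applied deltas, effective thresholds, bridge count,
#'   `bridge_jaccard`, `hub_overlap_topk`, and `is_baseline`.
#' @export
run_grid <- function(assocs, edges,
                     baseline = list(), deltas = c(-0.1, 0, 0.1)) {
  defaults <- list(disease_a = "PD", disease_b = "CKD",
                   score_min_a = 0.8, ei_min_a = 0.4,
                   score_min_b = 0.6, ei_min_b = 0.4,
                   cutoff = 0.7, top_k = 10)
  p0 <- utils::modifyList(defaults, baseline)
  edges <- canonicalize_edges(edges)
  base <- grid_point_run(assocs, edges, p0)
  grid <- expand.grid(delta_score_a = deltas, delta_score_b = deltas,
                      delta_cutoff = deltas, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    p <- p0
    p$score_min_a <- p0$score_min_a + grid$delta_score_a[i]
    p$score_min_b <- p0$score_min_b + grid$delta_score_b[i]
    p$cutoff <- p0$cutoff + grid$delta_cutoff[i]
    if (!all(is_prob(c(p$score_min_a, p$score_min_b, p$cutoff)))) {
      warning(sprintf("grid point %d skipped: threshold outside [0,1]", i))
      next
    }
    res <- grid_point_run(assocs, edges, p)
    k_eff <- max(1, min(p0$top_k, length(base$hubs)))
    rows[[length(rows) + 1L]] <- data.frame(
      delta_score_a = grid$delta_score_a[i],
      delta_score_b = grid$delta_score_b[i],
      delta_cutoff = grid$delta_cutoff[i],
      score_min_a = p$score_min_a, score_min_b = p$score_min_b,
      cutoff = p$cutoff,
      n_bridges = res$n_bridges,
      bridge_jaccard = jaccard_keys(res$bridges, base$bridges),
      hub_overlap_topk = if (length(base$hubs) == 0) 1
        else length(intersect(res$hubs, base$hubs)) / k_eff,
      is_baseline = grid$delta_score_a[i] == 0 &&
        grid$delta_score_b[i] == 0 && grid$delta_cutoff[i] == 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- p0
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity grid: %d point(s); bridge Jaccard %.2f-%.2f; hub overlap %.2f-%.2f\n",
              nrow(x), min(x$bridge_jaccard), max(x$bridge_jaccard),
              min(x$hub_overlap_topk), max(x$hub_overlap_topk)))
  invisible(x)
}
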