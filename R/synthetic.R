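## Synthetic input generator. Produces association tables, scored
## interactomes with planted cross-set bridges, and annotation sets with a
## planted enriched term, so the whole pipeline is testable offline with
## known ground truth.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate the study conditions the pipeline targets: a 64-gene
#' set A (e.g. PD) and a 17-gene set B (e.g. CKD), 15 planted cross-set
#' bridges with combined scores spanning 0.701-0.970 (the observed bridge
#' score range), a 0.700 confidence cutoff, and tiered curation thresholds
#' of 0.8/0.4 (set A) and 0.6/0.4 (set B) on score/evidence index.
#'
#' @param n_set_a,n_set_b Sizes of the two disease gene sets.
#' @param n_background_genes Genes outside both sets that carry edges (used
#'   to exercise network restriction and permutation nulls).
#' @param n_planted_bridges Number of cross-set bridges planted strictly
#'   above the confidence cutoff.
#' @param bridge_score_low,bridge_score_high Combined-score range for
#'   planted bridges; must lie strictly above `confidence_cutoff`.
#' @param within_set_edge_prob Probability of an above-cutoff edge for each
#'   within-set pair.
#' @param subthreshold_crossset_edge_prob Probability of a sub-cutoff
#'   distractor edge for each non-planted cross-set pair (also used for
#'   background-gene edges).
#' @param distractor_score_margin Gap between the confidence cutoff and the
#'   largest distractor cross-set score. The default 0.105 keeps distractors
#'   below every point of a +/-0.1 cutoff sensitivity grid, so threshold
#'   perturbations cannot promote a distractor into a bridge.
#' @param channel_noise_sd SD of the jitter applied to the text-mining
#'   anchor when decomposing combined scores into channels.
#' @param score_threshold_a,score_threshold_b,ei_threshold Curation
#'   thresholds the planted members are drawn to pass (and decoys to fail).
#' @param confidence_cutoff Network confidence cutoff the generator plants
#'   around.
#' @param decoy_factor Decoy association rows per passing member.
#' @param set_a_label,set_b_label Disease labels.
#' @param prior Evidence prior used for channel decomposition.
#' @param seed RNG seed; all outputs are reproducible given the config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_set_a = 64, n_set_b = 17,
                             n_background_genes = 20,
                             n_planted_bridges = 15,
                             bridge_score_low = 0.701,
                             bridge_score_high = 0.970,
                             within_set_edge_prob = 0.12,
                             subthreshold_crossset_edge_prob = 0.05,
                             distractor_score_margin = 0.105,
                             channel_noise_sd = 0.05,
                             score_threshold_a = 0.8,
                             score_threshold_b = 0.6,
                             ei_threshold = 0.4,
                             confidence_cutoff = 0.7,
                             decoy_factor = 2,
                             set_a_label = "PD", set_b_label = "CKD",
                             prior = 0.041,
                             seed = 1L) {
  cfg <- list(n_set_a = as.integer(n_set_a), n_set_b = as.integer(n_set_b),
              n_background_genes = as.integer(n_background_genes),
              n_planted_bridges = as.integer(n_planted_bridges),
              bridge_score_low = bridge_score_low,
              bridge_score_high = bridge_score_high,
              within_set_edge_prob = within_set_edge_prob,
              subthreshold_crossset_edge_prob = subthreshold_crossset_edge_prob,
              distractor_score_margin = distractor_score_margin,
              channel_noise_sd = channel_noise_sd,
              score_threshold_a = score_threshold_a,
              score_threshold_b = score_threshold_b,
              ei_threshold = ei_threshold,
              confidence_cutoff = confidence_cutoff,
              decoy_factor = decoy_factor,
              set_a_label = set_a_label, set_b_label = set_b_label,
              prior = prior, seed = as.integer(seed))
  if (cfg$n_set_a < 1 && cfg$n_set_b < 1)
    stop_validation("at least one gene set must be non-empty")
  probs <- c(cfg$bridge_score_low, cfg$bridge_score_high,
             cfg$within_set_edge_prob, cfg$subthreshold_crossset_edge_prob,
             cfg$score_threshold_a, cfg$score_threshold_b, cfg$ei_threshold,
             cfg$confidence_cutoff)
  if (cfg$distractor_score_margin < 0)
    stop_validation("distractor_score_margin must be non-negative")
  if (any(!is_prob(probs)))
    stop_validation("all probabilities and thresholds must lie in [0,1]")
  if (cfg$n_planted_bridges > 0 &&
      cfg$bridge_score_low <= cfg$confidence_cutoff)
    stop_validation("planted bridge range must lie strictly above the confidence cutoff")
  if (cfg$bridge_score_high < cfg$bridge_score_low)
    stop_validation("bridge_score_high must be >= bridge_score_low")
  if (cfg$n_planted_bridges > cfg$n_set_a * cfg$n_set_b)
    stop_validation("n_planted_bridges exceeds the number of cross-set pairs")
  structure(cfg, class = "synthetic_config")
}

## Internal: synthetic gene symbols for a set, e.g. PDG001..
syn_symbols <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf("%sG%03d", toupper(prefix), seq_len(n))
}

runif_open <- function(n, lo, hi) runif(n, lo, hi)

#' Generate disjoint disease gene sets and their association table
#'
#' Draws two disjoint synthetic gene sets of the configured sizes, plus an
#' association table in which exactly those members pass the tiered
#' thresholds: passing rows draw score/EI uniformly above their thresholds,
#' while `decoy_factor` decoy rows per member fail on either the score or
#' the evidence index.
#'
#' @param config A [synthetic_config()].
#' @return List with `sets` (a [disease_gene_sets()]) and `associations`
#'   (data.frame in [read_association_table()] layout).
#' @export
generate_gene_sets <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    sets <- disease_gene_sets(
      syn_symbols(config$set_a_label, config$n_set_a),
      syn_symbols(config$set_b_label, config$n_set_b),
      set_a_label = config$set_a_label, set_b_label = config$set_b_label)
    one_disease <- function(members, label, thr) {
      n <- length(members)
      if (n == 0)
        return(data.frame(gene_symbol = character(0),
                          disease_label = character(0),
                          score = numeric(0), evidence_index = numeric(0),
                          stringsAsFactors = FALSE))
      pass <- data.frame(gene_symbol = members, disease_label = label,
                         score = runif_open(n, thr + 1e-6, 1),
                         evidence_index = runif_open(n, config$ei_threshold + 1e-6, 1),
                         stringsAsFactors = FALSE)
      nd <- round(config$decoy_factor * n)
      if (nd == 0) return(pass)
      decoys <- sprintf("%sDECOY%03d", toupper(label), seq_len(nd))
      fail_score <- seq_len(nd) %% 2 == 0
      dec <- data.frame(
        gene_symbol = decoys, disease_label = label,
        score = ifelse(fail_score,
                       runif_open(nd, 0, max(thr - 1e-3, 0)),
                       runif_open(nd, thr + 1e-6, 1)),
        evidence_index = ifelse(fail_score,
                                runif_open(nd, config$ei_threshold + 1e-6, 1),
                                runif_open(nd, 0, max(config$ei_threshold - 1e-3, 0))),
        stringsAsFactors = FALSE)
      rbind(pass, dec)
    }
    assoc <- rbind(
      one_disease(sets$set_a, config$set_a_label, config$score_threshold_a),
      one_disease(sets$set_b, config$set_b_label, config$score_threshold_b))
    rownames(assoc) <- NULL
    list(sets = sets, associations = assoc)
  })
}

#' Decompose a combined score into evidence-channel scores
#'
#' Inverse of [combine_channel_scores()] with an exact algebraic guarantee:
#' where feasible the text-mining channel is fixed at `anchor` and the
#' experimental channel is solved so that recombination reproduces the
#' target combined score; otherwise the full score is carried by the
#' experimental channel alone. Recombining the returned channels yields the
#' target within 1e-9.
#'
#' @param scores Numeric vector of target combined scores, each in
#'   (`prior`, 1).
#' @param prior Evidence prior p0.
#' @param anchor Text-mining anchor value (default 0.400).
#' @return Data.frame with the seven channel columns.
#' @export
decompose_combined_score <- function(scores, prior = 0.041, anchor = 0.4) {
  if (any(scores <= prior | scores >= 1))
    stop_validation("combined scores must lie in (prior, 1) to be decomposable")
  n <- length(scores)
  out <- as.data.frame(matrix(0, nrow = n, ncol = length(CHANNELS),
                              dimnames = list(NULL, CHANNELS)))
  s_corr <- (scores - prior) / (1 - prior)
  t_corr <- (anchor - prior) / (1 - prior)
  use_anchor <- anchor > prior & s_corr > t_corr + 1e-6
  e_corr <- ifelse(use_anchor, 1 - (1 - s_corr) / (1 - t_corr), s_corr)
  out$experimental <- e_corr * (1 - prior) + prior
  out$textmining <- ifelse(use_anchor, anchor, 0)
  out
}

#' Generate a scored synthetic interactome with planted bridges
#'
#' Plants exactly `n_planted_bridges` distinct cross-set edges with combined
#' scores in the configured bridge range (strictly above the cutoff); adds
#' within-set edges at/above the cutoff with probability
#' `within_set_edge_prob`; adds cross-set distractor edges strictly below
#' the cutoff with probability `subthreshold_crossset_edge_prob`; and wires
#' background genes (outside both sets) at assorted scores. Channel scores
#' are decomposed so recombination reproduces each assigned combined score
#' within 1e-9.
#'
#' @param config A [synthetic_config()].
#' @param sets A [disease_gene_sets()]; the two sets must be disjoint.
#' @return Canonical edge data.frame with attribute `planted_bridges`, a
#'   two-column data.frame of the planted (canonical-order) pairs.
#' @export
generate_interactome <- function(config, sets) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(sets, "disease_gene_sets"))
  if (length(intersect(sets$set_a, sets$set_b)) > 0)
    stop_validation("gene sets must be disjoint")
  n_cross <- length(sets$set_a) * length(sets$set_b)
  if (config$n_planted_bridges > n_cross)
    stop_validation("n_planted_bridges exceeds available cross-set pairs")
  with_seed(config$seed + 1L, {
    lo_dis <- max(0.15, config$prior + 0.05)
    cross <- if (n_cross > 0)
      expand.grid(a = sets$set_a, b = sets$set_b,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      else data.frame(a = character(0), b = character(0))
    planted_idx <- if (config$n_planted_bridges > 0)
      sample.int(n_cross, config$n_planted_bridges) else integer(0)
    rows <- list()
    if (length(planted_idx) > 0)
      rows$planted <- data.frame(
        gene_a = cross$a[planted_idx], gene_b = cross$b[planted_idx],
        combined_score = runif_open(length(planted_idx),
                                    config$bridge_score_low,
                                    config$bridge_score_high),
        stringsAsFactors = FALSE)
    # sub-cutoff cross-set distractors on non-planted pairs
    rest <- setdiff(seq_len(n_cross), planted_idx)
    hi_dis <- config$confidence_cutoff - config$distractor_score_margin
    if (length(rest) > 0 && config$subthreshold_crossset_edge_prob > 0 &&
        hi_dis > lo_dis) {
      pick <- rest[runif(length(rest)) < config$subthreshold_crossset_edge_prob]
      if (length(pick) > 0)
        rows$distractor <- data.frame(
          gene_a = cross$a[pick], gene_b = cross$b[pick],
          combined_score = runif_open(length(pick), lo_dis, hi_dis),
          stringsAsFactors = FALSE)
    }
    # within-set edges at or above the cutoff
    within_pairs <- function(members) {
      if (length(members) < 2) return(NULL)
      pr <- t(utils::combn(members, 2))
      pick <- runif(nrow(pr)) < config$within_set_edge_prob
      if (!any(pick)) return(NULL)
      data.frame(gene_a = pr[pick, 1], gene_b = pr[pick, 2],
                 combined_score = runif_open(sum(pick),
                                             config$confidence_cutoff, 0.995),
                 stringsAsFactors = FALSE)
    }
    rows$within_a <- within_pairs(sets$set_a)
    rows$within_b <- within_pairs(sets$set_b)
    # background genes: edges among themselves and to set genes, any score
    if (config$n_background_genes > 0) {
      bg <- syn_symbols("BG", config$n_background_genes)
      others <- c(gene_union(sets), bg)
      n_bg_edges <- max(1L, round(config$subthreshold_crossset_edge_prob *
                                    config$n_background_genes * 10))
      ga <- sample(bg, n_bg_edges, replace = TRUE)
      gb <- sample(others, n_bg_edges, replace = TRUE)
      ok <- ga != gb
      if (any(ok))
        rows$background <- data.frame(
          gene_a = ga[ok], gene_b = gb[ok],
          combined_score = runif_open(sum(ok), lo_dis, 0.99),
          stringsAsFactors = FALSE)
    }
    all_rows <- do.call(rbind, rows)
    if (is.null(all_rows) || nrow(all_rows) == 0) {
      out <- empty_edges()
      attr(out, "planted_bridges") <- data.frame(gene_a = character(0),
                                                 gene_b = character(0))
      return(out)
    }
    anchors <- pmin(pmax(0.4 + rnorm(nrow(all_rows), 0, config$channel_noise_sd),
                         config$prior + 0.02), 0.95)
    ch <- do.call(rbind, lapply(seq_len(nrow(all_rows)), function(i)
      decompose_combined_score(all_rows$combined_score[i],
                               prior = config$prior, anchor = anchors[i])))
    edges <- cbind(all_rows[, c("gene_a", "gene_b")], ch,
                   combined_score = all_rows$combined_score)
    out <- canonicalize_edges(edges)
    planted <- if (length(planted_idx) > 0) {
      pa <- cross$a[planted_idx]; pb <- cross$b[planted_idx]
      data.frame(gene_a = pmin(pa, pb), gene_b = pmax(pa, pb),
                 stringsAsFactors = FALSE)
    } else data.frame(gene_a = character(0), gene_b = character(0))
    attr(out, "planted_bridges") <- planted[order(planted$gene_a, planted$gene_b), ,
                                            drop = FALSE]
    out
  })
}

#' Generate annotation sets with one planted enriched term
#'
#' Builds `n_terms` annotation sets over the given universe: one term
#' consisting exactly of the planted members, and the rest drawn uniformly
#' with sizes strictly larger than the planted term, which guarantees the
#' planted term attains the smallest hypergeometric p-value when queried
#' with its own members.
#'
#' @param universe Character vector of background genes (e.g. the network's
#'   gene union).
#' @param n_terms Total number of terms including the planted one.
#' @param planted_term Character vector of planted members (subset of
#'   `universe`).
#' @param seed RNG seed.
#' @param planted_id Term id for the planted set.
#' @return An `annotation_sets` list (see [read_gmt()]), planted term first.
#' @export
generate_annotations <- function(universe, n_terms = 20, planted_term,
                                 seed = 1L, planted_id = "PLANTED_TERM") {
  universe <- unique(normalize_symbol(universe))
  planted_term <- unique(normalize_symbol(planted_term))
  if (!all(planted_term %in% universe))
    stop_validation("planted term members must lie in the universe")
  if (length(planted_term) >= length(universe))
    stop_validation("planted term must be smaller than the universe")
  if (n_terms < 1) stop_validation("n_terms must be >= 1")
  with_seed(seed, {
    sets <- list()
    sets[[planted_id]] <- structure(planted_term,
                                    description = "planted enriched term")
    if (n_terms > 1) {
      lo <- max(2, length(planted_term) + 1)
      hi <- max(lo, min(length(universe) - 1, lo + 10))
      for (i in seq_len(n_terms - 1)) {
        sz <- sample(seq(lo, hi), 1)
        id <- sprintf("RAND_TERM_%03d", i)
        sets[[id]] <- structure(sort(sample(universe, sz)),
                                description = "random background term")
      }
    }
    structure(sets, class = "annotation_sets")
  })
}
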