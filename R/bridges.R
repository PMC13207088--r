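## Phase 3: cross-set bridge extraction, prioritization, theme tallies.

#' Extract cross-set molecular bridges
#'
#' A molecular bridge is a direct interaction whose endpoints belong to
#' different disease sets and whose combined confidence score is strictly
#' greater than `min_score` (the strict comparison mirrors the reporting
#' convention for bridges; network construction itself uses an inclusive
#' cutoff).
#'
#' @param net A `disease_network`.
#' @param min_score Bridge score threshold in \[0, 1\]; default 0.7.
#' @return A data.frame of class `bridge_set` with one row per bridge:
#'   `source_set_gene` (set B side), `target_set_gene` (set A side), the
#'   seven channel scores, `combined_score`, `evidence_channels_present`
#'   (comma-separated channels with score > 0) and `priority_rank` (`NA`
#'   until [prioritize_bridges()] is applied).
#' @export
extract_bridges <- function(net, min_score = 0.7) {
  stopifnot(inherits(net, "disease_network"))
  if (!is_prob(min_score)) stop_validation("min_score must lie in [0,1]")
  ed <- net$edges
  in_a <- function(g) g %in% net$gene_sets$set_a
  in_b <- function(g) g %in% net$gene_sets$set_b
  cross <- (in_a(ed$gene_a) & in_b(ed$gene_b)) |
           (in_b(ed$gene_a) & in_a(ed$gene_b))
  keep <- cross & ed$combined_score > min_score
  ed <- ed[keep, , drop = FALSE]
  b_side <- ifelse(in_b(ed$gene_a), ed$gene_a, ed$gene_b)
  a_side <- ifelse(in_b(ed$gene_a), ed$gene_b, ed$gene_a)
  chans <- apply(as.matrix(ed[CHANNELS]) > 0, 1, function(z)
    paste(CHANNELS[z], collapse = ","))
  out <- data.frame(source_set_gene = b_side, target_set_gene = a_side,
                    stringsAsFactors = FALSE)
  for (ch in CHANNELS) out[[ch]] <- ed[[ch]]
  out$combined_score <- ed$combined_score
  out$evidence_channels_present <- if (nrow(ed) > 0) chans else character(0)
  out$priority_rank <- rep(NA_integer_, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("bridge_set", "data.frame")
  out
}

#' Prioritize extracted bridges
#'
#' Stable total ordering of bridges by (1) combined score above the
#' high-confidence tier `high_score`; (2) evidence-channel consistency:
#' bridges supported by an experimental or curated-database channel rank
#' before those supported only by other channels, which rank before
#' text-mining-only bridges; (3) combined score, descending; (4)
#' lexicographic endpoint pair. Ranks 1..n are assigned.
#'
#' @param bridges A `bridge_set` from [extract_bridges()].
#' @param high_score High-confidence score tier; default 0.8.
#' @param preferred_channels Channels whose presence defines the top
#'   evidence tier; default `c("experimental", "database")`.
#' @return The `bridge_set` reordered with `priority_rank` filled in.
#' @export
prioritize_bridges <- function(bridges, high_score = 0.8,
                               preferred_channels = c("experimental", "database")) {
  stopifnot(inherits(bridges, "bridge_set"))
  if (nrow(bridges) == 0) return(bridges)
  pref <- as.matrix(bridges[, preferred_channels, drop = FALSE]) > 0
  other <- setdiff(CHANNELS, c(preferred_channels, "textmining"))
  oth <- as.matrix(bridges[, other, drop = FALSE]) > 0
  evidence_tier <- ifelse(apply(pref, 1, any), 1L,
                          ifelse(apply(oth, 1, any), 2L, 3L))
  score_tier <- ifelse(bridges$combined_score > high_score, 0L, 1L)
  ord <- order(score_tier, evidence_tier, -bridges$combined_score,
               bridges$source_set_gene, bridges$target_set_gene)
  out <- bridges[ord, , drop = FALSE]
  out$priority_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.bridge_set <- function(x, ...) {
  cat(sprintf("%d molecular bridge(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    show <- data.frame(rank = x$priority_rank,
                       bridge = paste(x$source_set_gene, x$target_set_gene, sep = "-"),
                       combined = round(x$combined_score, 3),
                       evidence = x$evidence_channels_present)
    print.data.frame(utils::head(show, 20), row.names = FALSE)
    if (nrow(x) > 20) cat(sprintf("... and %d more\n", nrow(x) - 20))
  }
  invisible(x)
}

#' Default functional theme map for bridge endpoints
#'
#' The packaged assignment of the named bridge genes to three non-mutually
#' exclusive functional themes: inflammatory signaling / extracellular
#' matrix dysregulation, metabolic / renin-angiotensin system integration,
#' and lipid / protein homeostasis.
#'
#' @return Data.frame with columns `gene_symbol`, `theme`.
#' @export
default_theme_map <- function() {
  read.delim(bridgenet_example("bridge_themes.tsv"), sep = "\t",
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Tally bridges by functional theme
#'
#' Counts how many bridges touch each theme; a bridge counts toward a theme
#' when either endpoint is assigned to it, and may count in several themes.
#' Bridges with no themed endpoint are tallied under `"unassigned"` with a
#' warning.
#'
#' @param bridges A `bridge_set`.
#' @param theme_map Data.frame with columns `gene_symbol`, `theme`;
#'   default [default_theme_map()].
#' @return Named integer vector of per-theme bridge counts.
#' @export
theme_tally <- function(bridges, theme_map = default_theme_map()) {
  stopifnot(inherits(bridges, "bridge_set"))
  themes <- sort(unique(theme_map$theme))
  counts <- setNames(integer(length(themes)), themes)
  unassigned <- 0L
  for (i in seq_len(nrow(bridges))) {
    hit <- unique(theme_map$theme[theme_map$gene_symbol %in%
                                    c(bridges$source_set_gene[i],
                                      bridges$target_set_gene[i])])
    if (length(hit) == 0) unassigned <- unassigned + 1L
    else counts[hit] <- counts[hit] + 1L
  }
  if (unassigned > 0) {
    warning(sprintf("%d bridge(s) with no themed endpoint counted as unassigned",
                    unassigned))
    counts <- c(counts, unassigned = unassigned)
  }
  counts
}
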