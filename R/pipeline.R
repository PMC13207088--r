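## End-to-end orchestration and reporting.

#' Run the full cross-disease convergence analysis
#'
#' Orchestrates the pipeline: tiered curation of both disease gene sets,
#' disjointness check, confidence-thresholded network construction, topology
#' summary, edge enrichment against the configured null, bridge extraction
#' and prioritization, MCC hub ranking, optional over-representation
#' analysis / annotation joins, and optional threshold sensitivity analysis.
#'
#' @param associations Association table: a data.frame or a TSV path
#'   (see [read_association_table()]).
#' @param edges Candidate edge table: a data.frame or a TSV path
#'   (see [read_edge_table()]).
#' @param annotations Optional `annotation_sets` (or GMT path) for ORA.
#' @param expression Optional expression table (data.frame or TSV path).
#' @param vesicle_catalogs Optional `annotation_sets` (or GMT path) of
#'   vesicle-cargo catalogs.
#' @param theme_map Optional data.frame (`gene_symbol`, `theme`) for the
#'   bridge theme tally; `NULL` skips it.
#' @param disease_a,disease_b Disease labels (set A / set B).
#' @param score_min_a,ei_min_a,score_min_b,ei_min_b Tiered curation
#'   thresholds; defaults 0.8/0.4 and 0.6/0.4.
#' @param cutoff Network confidence cutoff (inclusive); default 0.7.
#' @param bridge_min Bridge extraction threshold (strict); default `cutoff`.
#' @param high_score Bridge prioritization high-confidence tier; default 0.8.
#' @param top_k Hubs to report; default 10.
#' @param expected_edges Optional externally supplied expected edge count
#'   for the analytic null.
#' @param null A [null_model_config()]; default analytic Poisson seeded from
#'   `seed`.
#' @param sensitivity Logical: run the threshold sensitivity grid.
#' @param deltas Sensitivity offsets; default `c(-0.1, 0, 0.1)`.
#' @param seed Integer seed forwarded to every stochastic stage.
#' @return An object of class `convergence_analysis`; see
#'   [print.convergence_analysis()], [summary.convergence_analysis()],
#'   [plot.convergence_analysis()] and [write_report()].
#' @export
run_pipeline <- function(associations, edges,
                         annotations = NULL, expression = NULL,
                         vesicle_catalogs = NULL, theme_map = NULL,
                         disease_a = "PD", disease_b = "CKD",
                         score_min_a = 0.8, ei_min_a = 0.4,
                         score_min_b = 0.6, ei_min_b = 0.4,
                         cutoff = 0.7, bridge_min = cutoff,
                         high_score = 0.8, top_k = 10,
                         expected_edges = NULL,
                         null = null_model_config(seed = seed),
                         sensitivity = FALSE, deltas = c(-0.1, 0, 0.1),
                         seed = 1L) {
  if (is.character(associations)) associations <- read_association_table(associations)
  if (is.character(edges)) edges <- read_edge_table(edges)
  if (is.character(annotations)) annotations <- read_gmt(annotations)
  if (is.character(expression)) expression <- read_expression_table(expression)
  if (is.character(vesicle_catalogs)) vesicle_catalogs <- read_gmt(vesicle_catalogs)
  edges <- canonicalize_edges(edges)

  set_a <- filter_associations(associations, disease_a, score_min_a, ei_min_a)
  set_b <- filter_associations(associations, disease_b, score_min_b, ei_min_b)
  sets <- disease_gene_sets(set_a, set_b, disease_a, disease_b)
  overlap <- check_overlap(sets)

  net <- build_network(sets, edges, cutoff = cutoff)
  summ <- summarize_topology(net)
  enr <- ppi_enrichment(net, null = null, candidate_edges = edges,
                        expected_edges = expected_edges)
  summ$expected_edges_null <- enr$expected_edges
  summ$fold_enrichment <- enr$fold_enrichment
  summ$ppi_enrichment_p <- enr$p_value

  br <- prioritize_bridges(extract_bridges(net, min_score = bridge_min),
                           high_score = high_score)
  themes <- if (!is.null(theme_map)) theme_tally(br, theme_map) else NULL

  hubs <- mcc_scores(net)
  tops <- top_hubs(hubs, k = min(top_k, nrow(hubs)))

  bridge_genes <- unique(c(br$source_set_gene, br$target_set_gene))
  ora <- if (!is.null(annotations) && length(bridge_genes) > 0)
    hypergeometric_ora(bridge_genes, annotations, universe = net$nodes)
    else NULL
  ves <- if (!is.null(vesicle_catalogs) && length(bridge_genes) > 0)
    vesicle_membership(bridge_genes, vesicle_catalogs) else NULL
  expr_ctx <- if (!is.null(expression) && length(bridge_genes) > 0)
    expression_context(bridge_genes, expression) else NULL

  sens <- if (isTRUE(sensitivity))
    run_grid(associations, edges,
             baseline = list(disease_a = disease_a, disease_b = disease_b,
                             score_min_a = score_min_a, ei_min_a = ei_min_a,
                             score_min_b = score_min_b, ei_min_b = ei_min_b,
                             cutoff = cutoff, top_k = top_k),
             deltas = deltas)
    else NULL

  structure(list(gene_sets = sets, overlap = overlap, network = net,
                 summary = summ, enrichment = enr,
                 bridges = br, themes = themes,
                 hubs = hubs, top_hubs = tops,
                 ora = ora, vesicles = ves, expression = expr_ctx,
                 sensitivity = sens,
                 params = list(disease_a = disease_a, disease_b = disease_b,
                               score_min_a = score_min_a, ei_min_a = ei_min_a,
                               score_min_b = score_min_b, ei_min_b = ei_min_b,
                               cutoff = cutoff, bridge_min = bridge_min,
                               high_score = high_score, top_k = top_k,
                               expected_edges = expected_edges,
                               null_method = null$method, seed = seed)),
            class = "convergence_analysis")
}

#' @describeIn run_pipeline Compact console report of the fitted analysis.
#' @param x,object A `convergence_analysis`.
#' @param ... Ignored.
#' @export
print.convergence_analysis <- function(x, ...) {
  cat("Cross-disease interactome convergence analysis\n")
  print(x$gene_sets)
  print(x$summary)
  cat(sprintf("Bridges (> %.3f): %d", x$params$bridge_min, nrow(x$bridges)))
  if (nrow(x$bridges) > 0)
    cat(sprintf("; top: %s-%s (%.3f)",
                x$bridges$source_set_gene[1], x$bridges$target_set_gene[1],
                x$bridges$combined_score[1]))
  cat("\n")
  if (nrow(x$top_hubs) > 0)
    cat("Top hubs (MCC): ", paste(x$top_hubs$gene_symbol, collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$ora) && nrow(x$ora) > 0)
    cat(sprintf("Top enriched term: %s (p=%.3g, FDR=%.3g)\n",
                x$ora$term_id[1], x$ora$p_value[1], x$ora$fdr[1]))
  if (!is.null(x$sensitivity))
    print(x$sensitivity)
  invisible(x)
}

#' @describeIn run_pipeline Key quantities as a named list.
#' @export
summary.convergence_analysis <- function(object, ...) {
  s <- object$summary
  out <- list(n_set_a = length(object$gene_sets$set_a),
              n_set_b = length(object$gene_sets$set_b),
              overlap_size = length(object$overlap$intersection),
              n_nodes = s$n_nodes, n_edges = s$n_edges,
              average_degree = s$average_degree,
              clustering_coefficient = s$clustering_coefficient,
              expected_edges_null = s$expected_edges_null,
              fold_enrichment = s$fold_enrichment,
              ppi_enrichment_p = s$ppi_enrichment_p,
              n_bridges = nrow(object$bridges),
              top_hubs = object$top_hubs$gene_symbol)
  class(out) <- "summary.convergence_analysis"
  out
}

#' @export
print.summary.convergence_analysis <- function(x, ...) {
  cat(sprintf(paste0("Sets: %d + %d (overlap %d)\nNetwork: %d nodes, %d edges, ",
                     "avg degree %.2f, clustering %.3f\n"),
              x$n_set_a, x$n_set_b, x$overlap_size,
              x$n_nodes, x$n_edges, x$average_degree, x$clustering_coefficient))
  if (!is.na(x$expected_edges_null))
    cat(sprintf("Null: expected %.1f edges, fold %.1f, p %s\n",
                x$expected_edges_null, x$fold_enrichment,
                format(x$ppi_enrichment_p, digits = 3)))
  cat(sprintf("Bridges: %d\nTop hubs: %s\n", x$n_bridges,
              paste(x$top_hubs, collapse = ", ")))
  invisible(x)
}

#' @describeIn run_pipeline Plot the network; set-A nodes are circles,
#'   set-B nodes squares, bridge edges drawn heavier.
#' @export
plot.convergence_analysis <- function(x, ...) {
  net <- x$network
  g <- as_igraph(net)
  in_b <- igraph::V(g)$name %in% net$gene_sets$set_b
  ek <- paste(net$edges$gene_a, net$edges$gene_b)
  bk <- paste(pmin(x$bridges$source_set_gene, x$bridges$target_set_gene),
              pmax(x$bridges$source_set_gene, x$bridges$target_set_gene))
  is_bridge <- ek %in% bk
  igraph::plot.igraph(
    g,
    vertex.shape = ifelse(in_b, "square", "circle"),
    vertex.color = ifelse(in_b, "lightsalmon", "lightsteelblue"),
    vertex.size = 6, vertex.label.cex = 0.5,
    edge.width = ifelse(is_bridge, 2.5, 0.6),
    edge.color = ifelse(is_bridge, "firebrick", "grey70"), ...)
  invisible(x)
}

## --- reporting -------------------------------------------------------------

#' Write the deterministic TSV report of a pipeline run
#'
#' Writes `summary.tsv`, `bridges.tsv`, `hubs.tsv`, `enrichment.tsv` and
#' (when computed) `sensitivity.tsv` into `path`. Every file carries a '#'
#' provenance header with the run parameters and seed; identical inputs and
#' seed produce byte-identical files. Rounding follows the reporting
#' convention: combined scores 3 decimals, average degree 2, clustering 3.
#'
#' @param results A `convergence_analysis` from [run_pipeline()].
#' @param path Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(inherits(results, "convergence_analysis"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_format("cannot create output directory '%s'", path)
  }
  if (file.access(path, 2) != 0)
    stop_format("output directory '%s' is not writable", path)
  p <- results$params
  prov <- c(sprintf("bridgenet report; seed=%d", p$seed),
            sprintf("thresholds: %s score>=%.3f EI>=%.3f; %s score>=%.3f EI>=%.3f; cutoff>=%.3f; bridge>%.3f",
                    p$disease_a, p$score_min_a, p$ei_min_a,
                    p$disease_b, p$score_min_b, p$ei_min_b,
                    p$cutoff, p$bridge_min))
  written <- character(0)
  s <- results$summary
  sum_df <- data.frame(
    metric = c("n_set_a", "n_set_b", "overlap_size", "n_nodes", "n_edges",
               "average_degree", "clustering_coefficient",
               "expected_edges_null", "fold_enrichment", "ppi_enrichment_p",
               "n_bridges"),
    value = c(length(results$gene_sets$set_a), length(results$gene_sets$set_b),
              length(results$overlap$intersection), s$n_nodes, s$n_edges,
              formatC(s$average_degree, digits = 2, format = "f"),
              formatC(s$clustering_coefficient, digits = 3, format = "f"),
              formatC(s$expected_edges_null, digits = 2, format = "f"),
              formatC(s$fold_enrichment, digits = 1, format = "f"),
              format(s$ppi_enrichment_p, digits = 4),
              nrow(results$bridges)),
    stringsAsFactors = FALSE)
  f <- file.path(path, "summary.tsv")
  write_tsv_det(sum_df, f, prov); written <- c(written, f)

  br <- as.data.frame(results$bridges)
  for (ch in c(CHANNELS, "combined_score"))
    if (nrow(br) > 0) br[[ch]] <- formatC(br[[ch]], digits = 3, format = "f")
  f <- file.path(path, "bridges.tsv")
  write_tsv_det(br, f, prov); written <- c(written, f)

  hb <- as.data.frame(results$hubs)
  if (nrow(hb) > 0) {
    hb$mcc <- format(hb$mcc, digits = 15, trim = TRUE, scientific = FALSE)
    hb$betweenness <- formatC(hb$betweenness, digits = 4, format = "f")
  }
  f <- file.path(path, "hubs.tsv")
  write_tsv_det(hb, f, prov); written <- c(written, f)

  en <- if (is.null(results$ora)) data.frame(
    term_id = character(0), term_name = character(0),
    observed_count = integer(0), term_size_in_universe = integer(0),
    query_size = integer(0), universe_size = integer(0),
    p_value = character(0), fdr = character(0), strength = character(0))
  else {
    e <- as.data.frame(results$ora)
    e$p_value <- format(e$p_value, digits = 6)
    e$fdr <- format(e$fdr, digits = 6)
    e$strength <- formatC(e$strength, digits = 3, format = "f")
    e
  }
  f <- file.path(path, "enrichment.tsv")
  write_tsv_det(en, f, prov); written <- c(written, f)

  if (!is.null(results$sensitivity)) {
    sv <- as.data.frame(results$sensitivity)
    for (cc in c("bridge_jaccard", "hub_overlap_topk"))
      sv[[cc]] <- formatC(sv[[cc]], digits = 4, format = "f")
    f <- file.path(path, "sensitivity.tsv")
    write_tsv_det(sv, f, prov); written <- c(written, f)
  }
  invisible(written)
}

## --- flat-config runner ----------------------------------------------------

## Parse a flat key=value config file ('#' comments, blank lines allowed).
parse_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad) > 0) stop_format("config line %d is not key=value", bad[1])
  out <- lapply(kv, function(m) {
    v <- trimws(m[3])
    if (grepl("^-?[0-9.eE+-]+$", v) && !is.na(suppressWarnings(as.numeric(v))))
      v <- as.numeric(v)
    else if (tolower(v) %in% c("true", "false")) v <- tolower(v) == "true"
    v
  })
  setNames(out, vapply(kv, `[`, character(1), 2))
}

#' Run the whole pipeline from a flat config file
#'
#' Executes the full workflow described by a `key = value` config file and
#' writes the TSV report. Recognised keys: `seed`, `out_dir`, `simulate`
#' (generate synthetic inputs instead of reading files), `associations`,
#' `edges`, `annotations`, `expression`, `vesicle_catalogs` (paths),
#' `disease_a`, `disease_b`, `score_min_a`, `ei_min_a`, `score_min_b`,
#' `ei_min_b`, `cutoff`, `bridge_min`, `high_score`, `top_k`,
#' `expected_edges`, `sensitivity`, and the [synthetic_config()] fields
#' (prefixed `sim_`, e.g. `sim_n_planted_bridges`) when simulating.
#'
#' @param config Path to the config file, or a named list of the same keys.
#' @param out_dir Output directory override.
#' @param seed Seed override.
#' @return The `convergence_analysis` object, invisibly; the report is
#'   written to the output directory.
#' @export
run_all <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) parse_config(config) else config
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  seed <- as.integer(if (!is.null(seed)) seed else pick("seed", 1))
  out_dir <- if (!is.null(out_dir)) out_dir else pick("out_dir", "bridgenet_report")
  if (isTRUE(pick("simulate", FALSE))) {
    sim_keys <- names(cfg)[startsWith(names(cfg), "sim_")]
    sim_args <- setNames(cfg[sim_keys], sub("^sim_", "", sim_keys))
    sim_args$seed <- seed
    sc <- do.call(synthetic_config, sim_args)
    gs <- generate_gene_sets(sc)
    associations <- gs$associations
    edges <- generate_interactome(sc, gs$sets)
  } else {
    if (is.null(cfg$associations) || is.null(cfg$edges))
      stop_format("config must name 'associations' and 'edges' files (or set simulate=true)")
    associations <- cfg$associations
    edges <- cfg$edges
  }
  res <- run_pipeline(
    associations, edges,
    annotations = cfg$annotations, expression = cfg$expression,
    vesicle_catalogs = cfg$vesicle_catalogs,
    disease_a = pick("disease_a", "PD"), disease_b = pick("disease_b", "CKD"),
    score_min_a = pick("score_min_a", 0.8), ei_min_a = pick("ei_min_a", 0.4),
    score_min_b = pick("score_min_b", 0.6), ei_min_b = pick("ei_min_b", 0.4),
    cutoff = pick("cutoff", 0.7),
    bridge_min = pick("bridge_min", pick("cutoff", 0.7)),
    high_score = pick("high_score", 0.8), top_k = pick("top_k", 10),
    expected_edges = cfg$expected_edges,
    sensitivity = isTRUE(pick("sensitivity", FALSE)),
    seed = seed)
  write_report(res, out_dir)
  invisible(res)
}
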