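## Readers and writers for the tabular dialects the pipeline touches.
## Dialect: UTF-8, tab-separated, '#'-prefixed comment lines ignored,
## header row required. Gene symbols are uppercased and whitespace-stripped
## on ingest; no alias resolution is attempted.

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character", blank.lines.skip = TRUE,
             fileEncoding = "UTF-8")
}

## Find one column by any of several case-insensitive aliases.
find_col <- function(df, aliases, what) {
  hit <- which(tolower(names(df)) %in% tolower(aliases))
  if (length(hit) == 0)
    stop_format("missing required column '%s' (accepted names: %s)",
                what, paste(aliases, collapse = "/"))
  hit[1]
}

## Parse a numeric column, reporting the first malformed row.
parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0 || anyNA(out))
    stop_validation("unparseable %s value '%s' at data row %d",
                    what, x[c(bad, which(is.na(x)))[1]],
                    c(bad, which(is.na(x)))[1])
  out
}

#' Read a gene-disease association table
#'
#' Reads a DisGeNET-style tab-separated table with one row per gene-disease
#' pair. Required columns (case-insensitive): `gene` (or `gene_symbol`),
#' `disease` (or `disease_label`), `score`, `ei` (or `evidence_index`).
#' Scores and evidence indices must lie in \[0, 1\]; gene symbols are
#' uppercased and whitespace-stripped.
#'
#' @param path Path to a TSV file ('#' comment lines ignored).
#' @return A data.frame with columns `gene_symbol`, `disease_label`,
#'   `score`, `evidence_index`.
#' @seealso [filter_associations()] for the tiered curation step.
#' @export
read_association_table <- function(path) {
  df <- read_tsv_raw(path)
  gi <- find_col(df, c("gene", "gene_symbol", "genesymbol"), "gene")
  di <- find_col(df, c("disease", "disease_label", "diseaselabel"), "disease")
  si <- find_col(df, c("score", "disease_score"), "score")
  ei <- find_col(df, c("ei", "evidence_index", "evidenceindex"), "EI")
  out <- data.frame(
    gene_symbol    = normalize_symbol(df[[gi]]),
    disease_label  = trimws(df[[di]]),
    score          = parse_num(df[[si]], "score"),
    evidence_index = parse_num(df[[ei]], "EI"),
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene_symbol)))
    stop_validation("empty gene symbol at data row %d",
                    which(!nzchar(out$gene_symbol))[1])
  bad <- which(!is_prob(out$score))
  if (length(bad) > 0)
    stop_validation("score %s outside [0,1] at data row %d",
                    format(out$score[bad[1]]), bad[1])
  bad <- which(!is_prob(out$evidence_index))
  if (length(bad) > 0)
    stop_validation("evidence_index %s outside [0,1] at data row %d",
                    format(out$evidence_index[bad[1]]), bad[1])
  out
}

#' Write a gene-disease association table
#'
#' Inverse of [read_association_table()]; writes the canonical four-column
#' TSV dialect.
#'
#' @param assocs Data.frame as returned by [read_association_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(assocs, path) {
  df <- data.frame(gene = assocs$gene_symbol, disease = assocs$disease_label,
                   score = format_score(assocs$score),
                   ei = format_score(assocs$evidence_index),
                   stringsAsFactors = FALSE)
  write_tsv_det(df, path)
}

#' Read a scored interaction edge table
#'
#' Reads a STRING-style edge table: two endpoint columns (`gene_a`/`gene_b`,
#' aliases `protein_a`/`protein_b`, `protein1`/`protein2`, `node1`/`node2`),
#' one column per evidence channel (see [channel_names()]; absent channels
#' default to 0), and an optional `combined_score` column. Edges are
#' canonicalized to lexicographic endpoint order; duplicate unordered pairs
#' are merged keeping the per-channel maximum. When `combined_score` is
#' absent it is computed with [combine_channel_scores()].
#'
#' @param path Path to a TSV file.
#' @param prior Evidence prior used when the combined score must be computed
#'   (see [combine_channel_scores()]).
#' @return A data.frame with columns `gene_a`, `gene_b`, the seven channels,
#'   and `combined_score`; one row per unordered pair.
#' @export
read_edge_table <- function(path, prior = 0.041) {
  df <- read_tsv_raw(path)
  ai <- find_col(df, c("gene_a", "protein_a", "protein1", "node1"), "gene_a")
  bi <- find_col(df, c("gene_b", "protein_b", "protein2", "node2"), "gene_b")
  n <- nrow(df)
  out <- data.frame(gene_a = normalize_symbol(df[[ai]]),
                    gene_b = normalize_symbol(df[[bi]]),
                    stringsAsFactors = FALSE)
  for (ch in CHANNELS) {
    hit <- which(tolower(names(df)) == ch)
    out[[ch]] <- if (length(hit) > 0) parse_num(df[[hit[1]]], ch) else rep(0, n)
    bad <- which(!is_prob(out[[ch]]))
    if (length(bad) > 0)
      stop_validation("%s score outside [0,1] at data row %d", ch, bad[1])
  }
  ci <- which(tolower(names(df)) %in% c("combined_score", "combined", "score"))
  if (length(ci) > 0) {
    out$combined_score <- parse_num(df[[ci[1]]], "combined_score")
    bad <- which(!is_prob(out$combined_score))
    if (length(bad) > 0)
      stop_validation("combined_score outside [0,1] at data row %d", bad[1])
  } else {
    out$combined_score <- combine_channel_scores(out[CHANNELS], prior = prior)
  }
  if (n == 0) return(empty_edges())
  canonicalize_edges(out)
}

#' Write a scored interaction edge table
#'
#' Inverse of [read_edge_table()]; scores are written at full precision so
#' that write-then-read round-trips the canonical edge frame exactly.
#'
#' @param edges Canonical edge data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  check_edge_frame(edges)
  df <- edges
  for (ch in c(CHANNELS, "combined_score")) df[[ch]] <- format_score(df[[ch]])
  write_tsv_det(df, path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `term_id TAB description TAB member...`.
#' Members are uppercased and deduplicated within a line.
#'
#' @param path Path to a GMT file.
#' @return A named list of class `annotation_sets`; each element is a
#'   character vector of members with attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_format("GMT line %d has %d field(s); need term, description, >=1 member",
                  i, length(parts))
    members <- unique(normalize_symbol(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop_format("GMT line %d has no members", i)
    id <- trimws(parts[1])
    sets[[id]] <- structure(members, description = trimws(parts[2]))
  }
  structure(sets, class = "annotation_sets")
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of member vectors (as from [read_gmt()]); a
#'   `description` attribute per element is used when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    desc <- attr(sets[[id]], "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, as.character(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a tissue-expression table
#'
#' Reads a long-format TSV with columns (case-insensitive) `gene`, `tissue`,
#' `tpm` (transcripts per million). TPM must be non-negative.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `gene_symbol`, `tissue`, `tpm`.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_raw(path)
  gi <- find_col(df, c("gene", "gene_symbol"), "gene")
  ti <- find_col(df, "tissue", "tissue")
  pi <- find_col(df, c("tpm", "expression"), "TPM")
  out <- data.frame(gene_symbol = normalize_symbol(df[[gi]]),
                    tissue = trimws(df[[ti]]),
                    tpm = parse_num(df[[pi]], "TPM"),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$tpm) | out$tpm < 0)
  if (length(bad) > 0)
    stop_validation("negative TPM at data row %d", bad[1])
  out
}

## --- deterministic TSV output ----------------------------------------------

## Full-precision decimal representation: reading the printed value back
## recovers the identical double, so write-then-read round-trips exactly.
format_score <- function(x, digits = NULL) {
  if (is.null(digits))
    vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE),
           character(1))
  else
    ifelse(is.finite(x), formatC(x, digits = digits, format = "f"), as.character(x))
}

write_tsv_det <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines) > 0)
    writeLines(paste0("# ", header_lines), con, sep = "\n", useBytes = TRUE)
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' Convenience wrapper around `system.file()` for the plain-text fixtures
#' shipped under `inst/extdata/`: `bridges_published.tsv` (the 15 printed
#' cross-disease bridge edges), `associations_synthetic.tsv` (a synthetic
#' association table whose tiered filtering yields 64 + 17 disjoint genes),
#' `vesicle_catalogs_synthetic.gmt`, `tissue_expression_synthetic.tsv`, and
#' `bridge_themes.tsv`.
#'
#' @param name File name under `extdata/`; empty lists the directory.
#' @return Absolute path to the file.
#' @export
#' @examples
#' bridgenet_example("bridges_published.tsv")
bridgenet_example <- function(name = "") {
  if (name == "")
    return(dir(system.file("extdata", package = "bridgenet")))
  p <- system.file("extdata", name, package = "bridgenet")
  if (p == "") stop_format("no packaged file '%s'", name)
  p
}
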