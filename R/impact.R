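# Gene-impact prioritization: every edge's score, in every sample, is
# credited in full to both endpoint genes; per-gene totals over the cohort
# rank the most impactful losses (ascending) and gains (descending). Ties
# break by |score| descending, then gene symbol ascending (deterministic).

#' Per-gene summed edge-score impact
#'
#' Edge scores are computed for every sample (raw, unnormalized), summed over
#' the cohort, and each edge's total is credited in full to both endpoints.
#' Hub genes therefore accumulate impact across all their incident edges —
#' the behaviour that ranks highly interactive, frequently deleted genes
#' (TP53-like) first for loss.
#'
#' @param network A scorable `pathway_network`.
#' @param matrix A discrete `cn_matrix`.
#' @param scorer An [edge_scorer()] or its name.
#' @param normalized Divide by the module's absolute minimum
#'   haploinsufficient score (off by default; raw scores match the summing
#'   convention).
#' @return A `gene_impact_table`: data.frame (pathway, gene, score,
#'   rank_loss, rank_gain, gds, n_incident_edges).
#' @export
gene_impact_scores <- function(network, matrix,
                               scorer = haptrig_defaults()$scorer,
                               normalized = FALSE) {
  if (!network$scorable) stop_config("network '", network$name, "' is unscorable")
  scorer <- as_scorer(scorer)
  calls <- network_calls(network, matrix)
  es <- edge_score_matrix(network, calls, scorer)
  per_edge <- rowSums(es)
  if (normalized)
    per_edge <- per_edge / abs(min_haploinsufficient_score(network, scorer))
  genes <- network$nodes
  score <- setNames(rep(0, length(genes)), genes)
  add_a <- rowsum(per_edge, network$edges$a)
  add_b <- rowsum(per_edge, network$edges$b)
  score[rownames(add_a)] <- score[rownames(add_a)] + add_a[, 1]
  score[rownames(add_b)] <- score[rownames(add_b)] + add_b[, 1]
  deg <- setNames(rep(0L, length(genes)), genes)
  tab <- table(c(network$edges$a, network$edges$b))
  deg[names(tab)] <- as.integer(tab)
  out <- data.frame(
    pathway = network$name, gene = genes, score = unname(score),
    gds = unname(network$gds[genes]), n_incident_edges = unname(deg),
    stringsAsFactors = FALSE)
  # ties: |score| descending then symbol ascending
  o_loss <- order(out$score, -abs(out$score), out$gene)
  o_gain <- order(-out$score, -abs(out$score), out$gene)
  out$rank_loss <- match(seq_len(nrow(out)), o_loss)
  out$rank_gain <- match(seq_len(nrow(out)), o_gain)
  structure(out[, c("pathway", "gene", "score", "rank_loss", "rank_gain",
                    "gds", "n_incident_edges")],
            scorer = scorer$name, normalized = normalized,
            class = c("gene_impact_table", "data.frame"))
}

#' Top-k impact genes
#'
#' @param table A `gene_impact_table`.
#' @param k Number of genes (>= 1); the method's conventions are k = 5 for
#'   pathway summaries and k = 10 for QC tables. `k` beyond the gene count
#'   returns all genes.
#' @param direction `"loss"` (most negative first) or `"gain"` (most
#'   positive first).
#' @return Character vector of gene symbols in rank order.
#' @export
top_impact_genes <- function(table, k, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  if (k < 1) stop_config("k must be >= 1")
  rk <- if (direction == "loss") table$rank_loss else table$rank_gain
  table$gene[order(rk)][seq_len(min(k, nrow(table)))]
}

#' QC efficiency against a reference driver set
#'
#' Efficiency is the percentage of possible hits recovered: `possible_hits`
#' is the reference genes present in the universe of genes eligible for any
#' top table, `found` is those appearing in the union of the supplied top
#' tables. An empty intersection with the universe yields efficiency 0,
#' flagged degenerate. The alternative denominator (distinct genes the
#' tables actually contain) is reported alongside when it differs.
#'
#' @param top_tables Named list (pathway -> character vector of top-k genes).
#' @param reference Character vector of reference driver genes (e.g. COSMIC
#'   tumour suppressors, STOP/GO sets).
#' @param universe Character vector: all genes eligible to appear in any top
#'   table.
#' @return A `qc_report`: list with `efficiency` (percent), `found`,
#'   `possible_hits`, `k_capacity`, `efficiency_capacity`, `degenerate`.
#' @export
qc_efficiency <- function(top_tables, reference, universe) {
  reference <- unique(norm_symbols(reference))
  universe <- unique(norm_symbols(universe))
  in_tables <- unique(norm_symbols(unlist(top_tables, use.names = FALSE)))
  possible <- length(intersect(reference, universe))
  found <- length(intersect(reference, in_tables))
  eff <- if (possible == 0) 0 else 100 * found / possible
  structure(list(
    efficiency = eff, found = found, possible_hits = possible,
    k_capacity = length(in_tables),
    efficiency_capacity = if (length(in_tables) == 0) 0
                          else 100 * found / length(in_tables),
    n_pathways = length(top_tables),
    degenerate = possible == 0
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> efficiency=", round(x$efficiency, 1), "% (", x$found,
      "/", x$possible_hits, " possible hits",
      if (x$degenerate) "; DEGENERATE: reference disjoint from universe",
      ")\n", sep = "")
  invisible(x)
}

#' Write a gene impact table as TSV
#' @param x A `gene_impact_table`.
#' @param path Output file.
#' @export
write_impact_table <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# scorer=", attr(x, "scorer"),
                    " normalized=", attr(x, "normalized"),
                    " ties=|score| desc, symbol asc"), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
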