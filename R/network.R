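# Per-pathway interaction networks and GDS-weighted edge scoring.
#
# An edge between genes G1 and G2 with GISTIC calls (c1, c2) and GDS weights
# (g1, g2) is scored in one of two branches:
#   deletion branch (either call < 0):  min(c1,0)*g1 + min(c2,0)*g2
#   gain branch     (both calls >= 0):  c1*g1 + c2*g2
# so deletion-branch scores are <= 0, gain-branch scores are >= 0, and a
# haploinsufficient (high-GDS) gene weighs more. The scorer is a pluggable
# strategy: "gds_linear" (default, amplified partner suppressed in the
# deletion branch) or "gds_linear_mixed" (partner's positive term retained).

#' Edge-score strategies
#'
#' @param name `"gds_linear"` (default; in the deletion branch an amplified
#'   partner's positive term is suppressed, preserving the branch sign
#'   invariant) or `"gds_linear_mixed"` (the positive term is retained, so
#'   mixed edges may score either sign).
#' @return An `edge_scorer` object usable wherever a `scorer` argument is
#'   accepted.
#' @export
edge_scorer <- function(name = c("gds_linear", "gds_linear_mixed")) {
  name <- match.arg(name)
  fun <- switch(name,
    gds_linear = function(c1, c2, g1, g2) {
      del <- c1 < 0 | c2 < 0
      ifelse(del, pmin(c1, 0) * g1 + pmin(c2, 0) * g2, c1 * g1 + c2 * g2)
    },
    gds_linear_mixed = function(c1, c2, g1, g2) c1 * g1 + c2 * g2
  )
  structure(list(name = name, fun = fun), class = "edge_scorer")
}

as_scorer <- function(scorer) {
  if (inherits(scorer, "edge_scorer")) scorer else edge_scorer(scorer)
}

#' Score a single edge
#'
#' @param call1,call2 GISTIC calls in \{-2..2\} (vectorized).
#' @param gds1,gds2 GDS weights in \{1, 2, 3\}.
#' @param scorer An [edge_scorer()] or its name.
#' @return List with `value` (signed real) and `branch` (`"deletion"` if
#'   either call is negative, else `"gain"`).
#' @export
score_edge <- function(call1, call2, gds1, gds2,
                       scorer = haptrig_defaults()$scorer) {
  if (any(!(c(call1, call2) %in% -2:2)))
    stop_validation("GISTIC calls must lie in {-2..2}")
  if (any(!(c(gds1, gds2) %in% 1:3)))
    stop_validation("GDS weights must lie in {1, 2, 3}")
  scorer <- as_scorer(scorer)
  list(value = scorer$fun(call1, call2, gds1, gds2),
       branch = ifelse(call1 < 0 | call2 < 0, "deletion", "gain"))
}

#' Build a pathway's interaction network
#'
#' Retains interactome edges by one of four policies:
#' * `intrinsic` — both endpoints in the pathway gene set;
#' * `cross_pathway` — at least one endpoint in the pathway, the other in the
#'   pathway or in a companion-set universe (`cross_universe`);
#' * `expand1` — pathway genes plus their direct interactors, with all edges
#'   among them;
#' * `expand2` — one further interaction step.
#'
#' Every node carries its GDS weight and a membership flag (in the seed
#' pathway set). A network whose edge set is empty is returned flagged
#' unscorable, not an error.
#'
#' @param pathway Character vector of pathway gene symbols.
#' @param interactions An [interaction_set()].
#' @param gds A [gds_map()].
#' @param mode Edge-retention policy (see above).
#' @param cross_universe Companion gene symbols; required for
#'   `mode = "cross_pathway"`.
#' @param name Pathway name stored on the network.
#' @return A `pathway_network`.
#' @export
build_pathway_network <- function(pathway, interactions, gds,
                                  mode = c("intrinsic", "cross_pathway",
                                           "expand1", "expand2"),
                                  cross_universe = NULL, name = "pathway") {
  mode <- match.arg(mode)
  stopifnot(inherits(interactions, "interaction_set"), inherits(gds, "gds_map"))
  members <- unique(norm_symbols(pathway))
  a <- interactions$a; b <- interactions$b

  keep_nodes <- function(nodes) {
    keep <- a %in% nodes & b %in% nodes
    data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  }
  if (mode == "intrinsic") {
    edges <- keep_nodes(members)
    nodes <- members
  } else if (mode == "cross_pathway") {
    if (is.null(cross_universe))
      stop_config("mode 'cross_pathway' requires cross_universe")
    univ <- union(members, norm_symbols(cross_universe))
    keep <- (a %in% members | b %in% members) & a %in% univ & b %in% univ
    edges <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
    nodes <- union(members, unique(c(edges$a, edges$b)))
  } else {
    steps <- if (mode == "expand1") 1L else 2L
    nodes <- members
    for (s in seq_len(steps)) {
      touch <- a %in% nodes | b %in% nodes
      nodes <- union(nodes, unique(c(a[touch], b[touch])))
    }
    edges <- keep_nodes(nodes)
  }
  pathway_network(name = name, nodes = nodes, edges = edges, gds = gds,
                  members = members, mode = mode)
}

#' Construct a pathway network directly
#'
#' @param name Pathway name.
#' @param nodes Character vector of node gene symbols.
#' @param edges data.frame with columns `a`, `b` (endpoints must be nodes).
#' @param gds A [gds_map()] (weights are looked up per node).
#' @param members Gene symbols of the seed pathway set (defaults to all
#'   nodes).
#' @param mode Edge-mode tag.
#' @return A `pathway_network`: list with `name`, `nodes`, `gds` (named
#'   weights), `edges`, `mode`, `member` (named flags), `scorable`.
#' @export
pathway_network <- function(name, nodes, edges, gds, members = nodes,
                            mode = "intrinsic") {
  nodes <- unique(norm_symbols(nodes))
  edges <- as.data.frame(edges)[, c("a", "b")]
  edges$a <- norm_symbols(edges$a); edges$b <- norm_symbols(edges$b)
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  ok <- lo != hi & !duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(a = lo[ok], b = hi[ok], stringsAsFactors = FALSE)
  if (!all(c(edges$a, edges$b) %in% nodes))
    stop_validation("network edges reference unknown nodes")
  w <- if (inherits(gds, "gds_map")) gds_weight(gds, nodes)
       else { x <- unclass(gds)[nodes]; x[is.na(x)] <- 1L; unname(x) }
  structure(list(
    name = name,
    nodes = nodes,
    gds = setNames(as.integer(w), nodes),
    edges = edges,
    mode = mode,
    member = setNames(nodes %in% norm_symbols(members), nodes),
    scorable = nrow(edges) > 0
  ), class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("<pathway_network> ", x$name, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges, mode=", x$mode,
      if (!x$scorable) " (unscorable)", "\n", sep = "")
  invisible(x)
}

# Edge endpoint indices / weights, precomputed once per network.
edge_index <- function(network) {
  list(i1 = match(network$edges$a, network$nodes),
       i2 = match(network$edges$b, network$nodes),
       g1 = unname(network$gds[network$edges$a]),
       g2 = unname(network$gds[network$edges$b]))
}

# Node x sample call matrix for a network: genes absent from the cohort
# matrix get call 0 (absence of evidence must not simulate alteration).
network_calls <- function(network, matrix) {
  idx <- match(network$nodes, rownames(matrix))
  calls <- base::matrix(0, length(network$nodes), ncol(matrix),
                        dimnames = list(network$nodes, colnames(matrix)))
  hit <- !is.na(idx)
  calls[hit, ] <- unclass(matrix)[idx[hit], , drop = FALSE]
  attr(calls, "n_missing_genes") <- sum(!hit)
  calls
}

# Edge x sample matrix of edge scores; the vectorized core of the method.
edge_score_matrix <- function(network, calls, scorer) {
  ei <- edge_index(network)
  c1 <- calls[ei$i1, , drop = FALSE]
  c2 <- calls[ei$i2, , drop = FALSE]
  v <- scorer$fun(c1, c2, ei$g1, ei$g2)
  base::matrix(v, nrow = length(ei$i1), ncol = ncol(calls),
               dimnames = list(NULL, colnames(calls)))
}

#' Module score for one sample
#'
#' The sum of edge scores over all network edges under one sample's calls.
#' Genes absent from `sample_calls` are treated as unaltered (call 0).
#'
#' @param network A `pathway_network`.
#' @param sample_calls Named numeric vector of GISTIC calls.
#' @param scorer An [edge_scorer()] or its name.
#' @return Signed raw module score.
#' @export
score_module <- function(network, sample_calls,
                         scorer = haptrig_defaults()$scorer) {
  scorer <- as_scorer(scorer)
  calls <- setNames(rep(0, length(network$nodes)), network$nodes)
  hit <- intersect(names(sample_calls), network$nodes)
  calls[hit] <- sample_calls[hit]
  ei <- edge_index(network)
  sum(scorer$fun(calls[ei$i1], calls[ei$i2], ei$g1, ei$g2))
}

#' Minimum possible haploinsufficient score
#'
#' The module score under the hypothetical assignment of a monoallelic loss
#' (call -1) to every node; the normalization anchor. Under the default
#' scorer this equals `-sum(gds1 + gds2)` over edges. Zero for edgeless
#' networks.
#'
#' @param network A `pathway_network`.
#' @param scorer An [edge_scorer()] or its name.
#' @return Signed real (<= 0).
#' @export
min_haploinsufficient_score <- function(network,
                                        scorer = haptrig_defaults()$scorer) {
  if (!network$scorable) return(0)
  score_module(network, setNames(rep(-1, length(network$nodes)),
                                 network$nodes), scorer)
}

#' Normalized module scores across a cohort
#'
#' Per sample, the raw module score (sum of edge scores) divided by the
#' absolute minimum possible haploinsufficient score, so a cohort in which
#' every gene carries a monoallelic loss scores exactly -1. The cohort mean
#' normalized score is attached. Unscorable (edgeless) networks yield a table
#' of `NA` scores flagged for downstream exclusion.
#'
#' @param network A `pathway_network`.
#' @param matrix A discrete `cn_matrix`.
#' @param scorer An [edge_scorer()] or its name.
#' @return A `module_score_table`: data.frame (pathway, sample, raw,
#'   normalized) with attributes `min_score`, `mean_normalized`, `scorable`,
#'   `scorer`.
#' @export
normalized_module_scores <- function(network, matrix,
                                     scorer = haptrig_defaults()$scorer) {
  stopifnot(inherits(matrix, "cn_matrix"))
  if (cn_mode(matrix) != "discrete")
    stop_config("normalized_module_scores expects a discrete matrix")
  scorer <- as_scorer(scorer)
  samples <- colnames(matrix)
  if (!network$scorable) {
    out <- data.frame(pathway = network$name, sample = samples,
                      raw = NA_real_, normalized = NA_real_)
    return(structure(out, min_score = 0, mean_normalized = NA_real_,
                     scorable = FALSE, scorer = scorer$name,
                     class = c("module_score_table", "data.frame")))
  }
  calls <- network_calls(network, matrix)
  raw <- colSums(edge_score_matrix(network, calls, scorer))
  min_score <- min_haploinsufficient_score(network, scorer)
  normalized <- raw / abs(min_score)
  out <- data.frame(pathway = network$name, sample = samples,
                    raw = unname(raw), normalized = unname(normalized))
  structure(out, min_score = min_score,
            mean_normalized = mean(normalized), scorable = TRUE,
            scorer = scorer$name,
            n_missing_genes = attr(calls, "n_missing_genes"),
            class = c("module_score_table", "data.frame"))
}

#' Write a module score table as TSV
#' @param x A `module_score_table`.
#' @param path Output file.
#' @export
write_module_scores <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# scorer=", attr(x, "scorer"),
                    " min_score=", attr(x, "min_score"),
                    " scorable=", attr(x, "scorable")), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
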