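# Cohort-level representative network with the published visual-encoding
# rules: node fill blue (losses more common) / red (gains) / green (mutation
# rate above the cut), node shade = prevalence of the most frequent SCNA
# event, outlines cyan-coded by GDS provenance, PPI edges drawn when an
# endpoint's SCNA prevalence exceeds the cut (blue/red if directions agree,
# purple if antagonistic, green if mutation-disrupted), and grey edges tying
# member genes to a pathway hub node.

#' Build the cohort summary graph
#'
#' @param network A `pathway_network`.
#' @param matrix A discrete `cn_matrix`.
#' @param mut Optional [mutation_freq()] map (genes absent count as 0).
#' @param scna_edge_cut PPI edges are styled when an endpoint's alteration
#'   prevalence is strictly greater than this (default 1/3, the ">33%" rule).
#' @param mut_cut Mutation-rate cut for green encoding (default 0.10).
#' @param endpoint_rule `"either"` (default; one qualifying endpoint draws
#'   the edge) or `"both"`.
#' @return A `cohort_graph`: list of `nodes` and `edges` data.frames.
#' @export
cohort_summary_graph <- function(network, matrix, mut = NULL,
                                 scna_edge_cut = haptrig_defaults()$scna_edge_cut,
                                 mut_cut = haptrig_defaults()$mut_cut,
                                 endpoint_rule = c("either", "both")) {
  endpoint_rule <- match.arg(endpoint_rule)
  stopifnot(inherits(matrix, "cn_matrix"))
  calls <- network_calls(network, matrix)
  genes <- network$nodes
  loss_prev <- rowMeans(calls < 0)
  gain_prev <- rowMeans(calls > 0)
  alt_prev <- rowMeans(calls != 0)
  mfreq <- setNames(rep(0, length(genes)), genes)
  if (!is.null(mut)) {
    hit <- intersect(names(mut), genes)
    mfreq[hit] <- unclass(mut)[hit]
  }
  # fill: the more prevalent SCNA direction (ties favour loss, the dominant
  # event class); mutation green overrides
  dir_loss <- loss_prev >= gain_prev
  fill <- ifelse(mfreq > mut_cut, "mutated_green",
                 ifelse(dir_loss, "loss_blue", "gain_red"))
  shade <- pmax(loss_prev, gain_prev)
  prov <- attr(network, "provenance") %||% NULL
  outline <- vapply(network$gds[genes], function(w)
    switch(as.character(w), "3" = "mouse_cyan", "2" = "yeast_lightcyan",
           "none"), character(1))
  nodes <- data.frame(
    gene = genes, fill = unname(fill), shade = unname(shade),
    size = unname(alt_prev), outline = unname(outline),
    member = unname(network$member[genes]),
    loss_prevalence = unname(loss_prev), gain_prevalence = unname(gain_prev),
    mutation_frequency = unname(mfreq), stringsAsFactors = FALSE)

  ea <- network$edges$a; eb <- network$edges$b
  qa <- alt_prev[ea] > scna_edge_cut
  qb <- alt_prev[eb] > scna_edge_cut
  # mutation-disrupted edges are drawn regardless of SCNA prevalence
  mq <- mfreq[ea] > mut_cut | mfreq[eb] > mut_cut
  drawn <- (if (endpoint_rule == "either") qa | qb else qa & qb) | mq
  cat_of <- function(i) {
    a <- ea[i]; b <- eb[i]
    if (mfreq[a] > mut_cut || mfreq[b] > mut_cut) return("mutation_green")
    if (qa[i] && qb[i]) {
      if (dir_loss[a] == dir_loss[b])
        return(if (dir_loss[a]) "loss_blue" else "gain_red")
      return("antagonistic_purple")
    }
    g <- if (qa[i]) a else b
    if (dir_loss[g]) "loss_blue" else "gain_red"
  }
  idx <- which(drawn)
  ppi_edges <- data.frame(
    a = ea[idx], b = eb[idx],
    category = vapply(idx, cat_of, character(1)),
    stringsAsFactors = FALSE)
  hub <- paste0("PATHWAY:", network$name)
  members <- genes[network$member[genes]]
  grey_edges <- data.frame(
    a = members, b = rep(hub, length(members)),
    category = rep("pathway_membership_grey", length(members)),
    stringsAsFactors = FALSE)
  if (length(members)) {
    nodes <- rbind(nodes, data.frame(
      gene = hub, fill = "pathway_hub", shade = 0, size = 0,
      outline = "none", member = FALSE, loss_prevalence = 0,
      gain_prevalence = 0, mutation_frequency = 0, stringsAsFactors = FALSE))
  }
  edges <- rbind(ppi_edges, grey_edges)
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(name = network$name, nodes = nodes, edges = edges,
                 scna_edge_cut = scna_edge_cut, mut_cut = mut_cut),
            class = "cohort_graph")
}

#' @export
print.cohort_graph <- function(x, ...) {
  cat("<cohort_graph> ", x$name, ": ", nrow(x$nodes), " nodes, ",
      sum(x$edges$category != "pathway_membership_grey"), " styled PPI edges, ",
      sum(x$edges$category == "pathway_membership_grey"),
      " membership edges\n", sep = "")
  invisible(x)
}

#' Export a cohort summary graph for Cytoscape
#'
#' Writes GraphML (via igraph) or Cytoscape JSON (`.cyjs` dialect), with all
#' style attributes as node/edge data columns. Both formats round-trip
#' through [read_graph_file()].
#'
#' @param graph A `cohort_graph`.
#' @param path Output file.
#' @param format `"graphml"` or `"cytoscape_json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "cytoscape_json")) {
  if (!is.character(format) ||
      !format[1] %in% c("graphml", "cytoscape_json"))
    stop_config("unknown graph format '", format[1], "'")
  format <- match.arg(format)
  nodes <- graph$nodes; edges <- graph$edges
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edges)) edges else
        data.frame(a = character(), b = character(), category = character()),
      directed = FALSE,
      vertices = data.frame(name = nodes$gene,
                            nodes[, setdiff(names(nodes), "gene")],
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    doc <- list(
      format_version = "1.0",
      data = list(name = graph$name,
                  scna_edge_cut = graph$scna_edge_cut,
                  mut_cut = graph$mut_cut),
      elements = list(
        nodes = lapply(seq_len(nrow(nodes)), function(i)
          list(data = c(list(id = nodes$gene[i]),
                        as.list(nodes[i, setdiff(names(nodes), "gene")])))),
        edges = lapply(seq_len(nrow(edges)), function(i)
          list(data = list(source = edges$a[i], target = edges$b[i],
                           category = edges$category[i])))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back an exported cohort summary graph
#'
#' @param path File written by [export_graph()].
#' @param format `"graphml"` or `"cytoscape_json"`.
#' @return A `cohort_graph` (the `name` and cuts are only recovered from the
#'   JSON dialect).
#' @export
read_graph_file <- function(path, format = c("graphml", "cytoscape_json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- data.frame(gene = va$name, fill = va$fill,
                        shade = as.numeric(va$shade),
                        size = as.numeric(va$size), outline = va$outline,
                        member = as.logical(va$member),
                        loss_prevalence = as.numeric(va$loss_prevalence),
                        gain_prevalence = as.numeric(va$gain_prevalence),
                        mutation_frequency = as.numeric(va$mutation_frequency),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(a = el[, 1], b = el[, 2],
                        category = igraph::edge_attr(g, "category") %||%
                          character(0),
                        stringsAsFactors = FALSE)
    name <- sub("^PATHWAY:", "",
                nodes$gene[nodes$fill == "pathway_hub"][1] %||% NA)
    cuts <- list(scna = NA_real_, mut = NA_real_)
  } else {
    doc <- jsonlite::read_json(path)
    nodes <- do.call(rbind, lapply(doc$elements$nodes, function(n) {
      d <- n$data
      data.frame(gene = d$id, fill = d$fill, shade = as.numeric(d$shade),
                 size = as.numeric(d$size), outline = d$outline,
                 member = as.logical(d$member),
                 loss_prevalence = as.numeric(d$loss_prevalence),
                 gain_prevalence = as.numeric(d$gain_prevalence),
                 mutation_frequency = as.numeric(d$mutation_frequency),
                 stringsAsFactors = FALSE)
    }))
    edges <- do.call(rbind, lapply(doc$elements$edges, function(e)
      data.frame(a = e$data$source, b = e$data$target,
                 category = e$data$category, stringsAsFactors = FALSE)))
    if (is.null(edges)) edges <- data.frame(a = character(), b = character(),
                                            category = character())
    if (is.null(nodes)) nodes <- data.frame()
    name <- doc$data$name
    cuts <- list(scna = doc$data$scna_edge_cut, mut = doc$data$mut_cut)
  }
  structure(list(name = name, nodes = nodes, edges = edges,
                 scna_edge_cut = cuts$scna, mut_cut = cuts$mut),
            class = "cohort_graph")
}
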