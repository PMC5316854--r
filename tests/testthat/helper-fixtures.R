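# Shared fixtures and the independent brute-force scoring oracle.

# Independent restatement of the edge-score rule, scalar and branch-explicit;
# deliberately not sharing code with edge_scorer().
oracle_edge_score <- function(c1, c2, g1, g2) {
  if (c1 < 0 || c2 < 0) {
    s <- 0
    if (c1 < 0) s <- s + c1 * g1
    if (c2 < 0) s <- s + c2 * g2
    s
  } else {
    c1 * g1 + c2 * g2
  }
}

# Brute-force module score: explicit loop over enumerated edges.
oracle_module_score <- function(network, calls) {
  total <- 0
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$a[i]; b <- network$edges$b[i]
    ca <- if (a %in% names(calls)) calls[[a]] else 0
    cb <- if (b %in% names(calls)) calls[[b]] else 0
    total <- total + oracle_edge_score(ca, cb, network$gds[[a]],
                                       network$gds[[b]])
  }
  total
}

# A-B-C path with GDS weights 1, 2, 3: min haploinsufficient score -8.
toy_network <- function() {
  pathway_network("TOY", c("A", "B", "C"),
                  data.frame(a = c("A", "B"), b = c("B", "C")),
                  gds_map(yeast = "B", mouse = "C"))
}

toy_matrix <- function(calls_by_sample) {
  # calls_by_sample: named list sample -> named call vector
  genes <- unique(unlist(lapply(calls_by_sample, names)))
  m <- matrix(0, length(genes), length(calls_by_sample),
              dimnames = list(genes, names(calls_by_sample)))
  for (s in names(calls_by_sample))
    m[names(calls_by_sample[[s]]), s] <- calls_by_sample[[s]]
  cn_matrix(m, mode = "discrete")
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Random small network + discrete matrix for property checks.
random_network <- function(n_nodes, p_edge = 0.6) {
  genes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  pathway_network("RAND", genes,
                  data.frame(a = pairs[keep, 1], b = pairs[keep, 2]),
                  gds_map(yeast = sample(genes, 1), mouse = sample(genes, 1)))
}
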