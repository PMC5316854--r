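# Readers for the five external inputs. All readers accept plain or
# gzip-compressed files (connections handle both transparently) and attach a
# machine-readable load report recording dropped / collapsed / imputed items.

open_lines <- function(path) {
  if (!file.exists(path)) stop_format(basename(path), ": file not found")
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

load_report <- function(x) attr(x, "load_report")

#' Read pathway gene sets (GMT dialect)
#'
#' Parses a Broad-style GMT file: tab-separated lines of
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are uppercased,
#' whitespace-trimmed, and deduplicated preserving first occurrence. Optional
#' manual curation adds genes to named pathways after parsing (the hook used
#' to add MAP1LC3B to the KEGG autophagy set).
#'
#' @param path GMT file (optionally gzipped).
#' @param curation Optional named list: pathway name -> character vector of
#'   gene symbols to append.
#' @return A `pathway_collection`: named list of gene-symbol vectors with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path, curation = NULL) {
  lines <- open_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_format("gene sets: line ", i, " has no genes (GMT needs name, description, genes...)")
    name <- trimws(f[[1]])
    genes <- norm_symbols(f[-(1:2)])
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0)
      stop_format("gene sets: line ", i, " (", name, ") has an empty gene set")
    if (name %in% names(sets))
      stop_format("gene sets: duplicate pathway name '", name, "' at line ", i)
    sets[[name]] <- genes
    desc[[name]] <- f[[2]]
  }
  pathway_collection(sets, descriptions = desc, curation = curation)
}

#' Construct a pathway collection
#'
#' @param sets Named list of gene-symbol character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @param curation Optional named list of genes to append per pathway.
#' @return A `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL, curation = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_format("pathway names must be present and unique")
  sets <- lapply(sets, function(g) unique(norm_symbols(g)))
  if (!is.null(curation)) {
    for (nm in names(curation)) {
      if (!nm %in% names(sets))
        stop_config("curation names unknown pathway '", nm, "'")
      sets[[nm]] <- unique(c(sets[[nm]], norm_symbols(curation[[nm]])))
    }
  }
  if (any(lengths(sets) == 0)) stop_format("every gene set must be non-empty")
  structure(sets, descriptions = descriptions, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("<pathway_collection> ", length(x), " pathways, ",
      length(unique(unlist(x))), " distinct genes\n", sep = "")
  invisible(x)
}

#' Write a pathway collection as GMT
#' @param x A `pathway_collection`.
#' @param path Output file.
#' @export
write_gene_sets <- function(x, path) {
  desc <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read undirected protein-protein interactions
#'
#' Reads a headered TSV (BioGRID-export compatible) and keeps only an
#' unordered gene-pair abstraction: symbols are uppercased, self-loops are
#' dropped, and duplicate pairs (in either orientation) are collapsed. Counts
#' of both are recorded in the load report.
#'
#' @param path TSV file with header (optionally gzipped).
#' @param columns Length-2 character (column names) or integer (indices)
#'   vector locating the two gene-symbol columns. Defaults to columns 1:2.
#' @return An `interaction_set`: data.frame with columns `a`, `b`
#'   (lexicographically ordered within each pair), plus a load report.
#' @export
read_interactions <- function(path, columns = c(1L, 2L)) {
  if (!file.exists(path)) stop_format(basename(path), ": file not found")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (length(columns) != 2) stop_config("interactions: 'columns' must have length 2")
  if (is.character(columns)) {
    if (!all(columns %in% names(df)))
      stop_config("interactions: columns ", paste(setdiff(columns, names(df)), collapse = ", "),
                  " not found in header")
  } else if (any(columns > ncol(df))) {
    stop_config("interactions: column indices out of range")
  }
  interaction_set(df[[columns[[1]]]], df[[columns[[2]]]])
}

#' Construct an interaction set from two symbol vectors
#'
#' @param a,b Equal-length character vectors of gene symbols (one edge per
#'   position).
#' @return An `interaction_set` (undirected, deduplicated, self-loop free).
#' @export
interaction_set <- function(a = character(), b = character()) {
  a <- norm_symbols(a); b <- norm_symbols(b)
  stopifnot(length(a) == length(b))
  lo <- pmin(a, b); hi <- pmax(a, b)
  self <- lo == hi
  lo <- lo[!self]; hi <- hi[!self]
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  edges <- data.frame(a = lo[!dup], b = hi[!dup], stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("interaction_set", "data.frame"),
            load_report = list(n_edges = nrow(edges),
                               self_loops_dropped = sum(self),
                               duplicates_collapsed = sum(dup)))
}

#' @export
print.interaction_set <- function(x, ...) {
  r <- load_report(x)
  cat("<interaction_set> ", nrow(x), " undirected edges (",
      r$self_loops_dropped, " self-loops dropped, ",
      r$duplicates_collapsed, " duplicates collapsed)\n", sep = "")
  invisible(x)
}

#' Write an interaction set as TSV
#' @param x An `interaction_set`.
#' @param path Output file.
#' @export
write_interactions <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene dose-sensitivity annotations
#'
#' Each file lists one human gene symbol per row (orthologue mapping from
#' yeast/mouse screens is assumed done upstream). Weights follow the GDS
#' convention: 1 for no information, 2 for yeast information, 3 for mouse
#' information; mouse evidence overrides yeast when a gene appears in both.
#'
#' @param yeast_path,mouse_path One-symbol-per-row TSVs (may be empty or
#'   `NULL` for no annotations of that provenance).
#' @return A `gds_map`.
#' @export
read_dose_sensitivity <- function(yeast_path = NULL, mouse_path = NULL) {
  read_one <- function(p) {
    if (is.null(p)) return(character())
    lines <- open_lines(p)
    # first tab-separated field of each non-empty row
    syms <- vapply(strsplit(lines, "\t", fixed = TRUE),
                   function(f) if (length(f)) f[[1]] else "", character(1))
    unique(norm_symbols(syms[nzchar(trimws(syms))]))
  }
  gds_map(yeast = read_one(yeast_path), mouse = read_one(mouse_path))
}

#' Construct a dose-sensitivity map
#'
#' @param yeast,mouse Character vectors of gene symbols with evidence of that
#'   provenance. Mouse overrides yeast.
#' @return A `gds_map`: named integer vector of weights in \{2, 3\} with a
#'   `provenance` attribute; genes absent from the map weigh 1.
#' @export
gds_map <- function(yeast = character(), mouse = character()) {
  yeast <- unique(norm_symbols(yeast)); mouse <- unique(norm_symbols(mouse))
  yeast <- setdiff(yeast, mouse)
  w <- c(setNames(rep.int(2L, length(yeast)), yeast),
         setNames(rep.int(3L, length(mouse)), mouse))
  prov <- c(setNames(rep("yeast", length(yeast)), yeast),
            setNames(rep("mouse", length(mouse)), mouse))
  structure(w, provenance = prov, class = "gds_map")
}

#' Look up GDS weights
#'
#' @param gds A `gds_map`.
#' @param genes Character vector of gene symbols.
#' @return Integer weights; unknown genes return 1.
#' @export
gds_weight <- function(gds, genes) {
  stopifnot(inherits(gds, "gds_map"))
  w <- unclass(gds)[norm_symbols(genes)]
  w[is.na(w)] <- 1L
  unname(w)
}

#' GDS provenance lookup
#' @param gds A `gds_map`.
#' @param genes Gene symbols.
#' @return `"none"`, `"yeast"` or `"mouse"` per gene.
#' @export
gds_provenance <- function(gds, genes) {
  p <- attr(gds, "provenance")[norm_symbols(genes)]
  p[is.na(p)] <- "none"
  unname(p)
}

#' @export
print.gds_map <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("<gds_map> ", sum(p == "yeast"), " yeast-, ", sum(p == "mouse"),
      " mouse-annotated genes (all others weigh 1)\n", sep = "")
  invisible(x)
}

#' Read a gene-level copy-number matrix
#'
#' TSV with gene symbols in the first column and one column per sample.
#' Discrete mode validates GISTIC calls against \{-2, -1, 0, 1, 2\};
#' continuous mode accepts any finite real (log2 segmented values, to be
#' discretized with [threshold_log2()]). Missing cells are imputed to 0 (no
#' somatic change) and counted in the load report.
#'
#' @param path TSV file (optionally gzipped).
#' @param mode `"discrete"` or `"continuous"`.
#' @return A `cn_matrix`: numeric genes x samples matrix with a `mode`
#'   attribute.
#' @export
read_copy_number <- function(path, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_format(basename(path), ": file not found")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  genes <- norm_symbols(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  n_imputed <- sum(is.na(m))
  m[is.na(m)] <- 0
  out <- cn_matrix(m, mode = mode)
  attr(out, "load_report") <- list(n_genes = nrow(m), n_samples = ncol(m),
                                   imputed_cells = n_imputed)
  out
}

#' Construct a copy-number matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param mode `"discrete"` (GISTIC calls) or `"continuous"` (log2 values).
#' @return A `cn_matrix`.
#' @export
cn_matrix <- function(values, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("copy number: gene and sample names are required")
  rownames(values) <- norm_symbols(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop_validation("copy number: duplicate gene symbol '",
                    rownames(values)[duplicated(rownames(values))][1], "'")
  if (anyDuplicated(colnames(values)))
    stop_validation("copy number: duplicate sample id '",
                    colnames(values)[duplicated(colnames(values))][1], "'")
  if (any(!is.finite(values)))
    stop_validation("copy number: non-finite cells after imputation")
  if (mode == "discrete") {
    bad <- which(!(values %in% -2:2))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(values))
      stop_validation("copy number: value ", values[bad[1]], " for gene ",
                      rownames(values)[i[1]], ", sample ",
                      colnames(values)[i[2]], " outside {-2..2}")
    }
  }
  structure(values, mode = mode, class = c("cn_matrix", "matrix", "array"))
}

cn_mode <- function(x) attr(x, "mode")

#' @export
print.cn_matrix <- function(x, ...) {
  cat("<cn_matrix> ", nrow(x), " genes x ", ncol(x), " samples, mode=",
      cn_mode(x), "\n", sep = "")
  invisible(x)
}

#' Write a copy-number matrix as TSV
#' @param x A `cn_matrix`.
#' @param path Output file.
#' @export
write_copy_number <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Discretize a continuous log2 copy-number matrix
#'
#' Maps log2 segmented values onto the GISTIC call scale with four strictly
#' ordered cuts. Boundaries are assigned outward, toward the alteration: a
#' value exactly at a cut is called altered.
#'
#' @param matrix A continuous `cn_matrix`.
#' @param cuts Numeric length-4 vector `(t_del2, t_del1, t_amp1, t_amp2)`
#'   with `t_del2 < t_del1 < 0 < t_amp1 < t_amp2`. Defaults to
#'   `c(-1.3, -0.3, 0.3, 1.3)`.
#' @return A discrete `cn_matrix`.
#' @export
threshold_log2 <- function(matrix, cuts = haptrig_defaults()$log2_cuts) {
  if (!inherits(matrix, "cn_matrix") || cn_mode(matrix) != "continuous")
    stop_config("threshold_log2 expects a continuous cn_matrix")
  cuts <- as.numeric(cuts)
  if (length(cuts) != 4 || is.unsorted(cuts, strictly = TRUE) ||
      cuts[2] >= 0 || cuts[3] <= 0)
    stop_config("thresholds must satisfy t_del2 < t_del1 < 0 < t_amp1 < t_amp2")
  v <- unclass(matrix)
  calls <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  calls[v <= cuts[2]] <- -1
  calls[v <= cuts[1]] <- -2
  calls[v >= cuts[3]] <- 1
  calls[v >= cuts[4]] <- 2
  cn_matrix(calls, mode = "discrete")
}

#' Read per-gene mutation frequencies
#'
#' Two-column TSV: gene symbol, fraction of cohort mutated. Used only for
#' cohort-network visualization (green encoding above the 10% cut).
#'
#' @param path TSV file, no header required (a header row whose second field
#'   is non-numeric is skipped).
#' @return Named numeric vector in \[0, 1\] (class `mutation_freq`).
#' @export
read_mutation_frequencies <- function(path) {
  lines <- open_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(mutation_freq(setNames(numeric(0), character(0))))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (length(f[[1]]) >= 2 && is.na(suppressWarnings(as.numeric(f[[1]][[2]]))))
    f <- f[-1]
  genes <- vapply(f, `[[`, character(1), 1)
  vals <- suppressWarnings(as.numeric(vapply(f, `[[`, character(1), 2)))
  if (anyNA(vals)) stop_validation("mutation frequencies: non-numeric value")
  mutation_freq(setNames(vals, genes))
}

#' Construct a mutation-frequency map
#' @param freq Named numeric vector, gene symbol -> fraction in \[0, 1\].
#' @return A `mutation_freq` object.
#' @export
mutation_freq <- function(freq) {
  names(freq) <- norm_symbols(names(freq))
  bad <- which(freq < 0 | freq > 1)
  if (length(bad))
    stop_validation("mutation frequencies: value ", freq[bad[1]], " for gene ",
                    names(freq)[bad[1]], " outside [0, 1]")
  structure(freq, class = "mutation_freq")
}

#' Write mutation frequencies as TSV
#' @param x A `mutation_freq` object.
#' @param path Output file.
#' @export
write_mutation_frequencies <- function(x, path) {
  writeLines(c("gene\tfrequency",
               paste(names(x), sprintf("%.17g", unclass(x)), sep = "\t")),
             path)
  invisible(path)
}
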