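# Synthetic cohorts with known ground truth. The generator emulates a
# GISTIC-called tumour cohort: i.i.d. background SCNA noise per gene and
# sample (conditional on alteration, 95% of events are monoallelic, matching
# the observed dominance of single-copy changes), plus planted pathways whose
# genes are altered in a chosen direction at a chosen penetrance. Genes are
# independent; no chromosome/arm linkage structure is simulated.

#' Describe a planted pathway
#'
#' @param name Pathway name.
#' @param n_genes Number of genes (>= 2).
#' @param density Internal Erdős–Rényi edge density in \[0, 1\].
#' @param penetrance Per-sample probability that each pathway gene carries
#'   the planted event.
#' @param direction `"deletion"` (call -1) or `"gain"` (call +1); events are
#'   monoallelic.
#' @param gds_fraction Fraction of pathway genes given dose-sensitivity
#'   annotations.
#' @param mouse_fraction Of the annotated genes, the fraction labelled mouse
#'   (weight 3); the rest are yeast (weight 2).
#' @param hub Plant a high-GDS hub gene with elevated degree and penetrance.
#' @param hub_degree Minimum degree wired for the hub gene.
#' @param hub_penetrance Per-sample event probability for the hub gene.
#' @return A `planted_pathway` description.
#' @export
planted_pathway <- function(name, n_genes = 20L, density = 0.3,
                            penetrance = 0.6,
                            direction = c("deletion", "gain"),
                            gds_fraction = 0.5, mouse_fraction = 0.5,
                            hub = FALSE, hub_degree = 4L,
                            hub_penetrance = 0.7) {
  direction <- match.arg(direction)
  if (n_genes < 2) stop_config("planted pathway needs >= 2 genes")
  for (v in c(density, penetrance, gds_fraction, mouse_fraction,
              hub_penetrance))
    if (v < 0 || v > 1) stop_config("rates and penetrances must lie in [0, 1]")
  structure(list(name = name, n_genes = as.integer(n_genes),
                 density = density, penetrance = penetrance,
                 direction = direction, gds_fraction = gds_fraction,
                 mouse_fraction = mouse_fraction, hub = hub,
                 hub_degree = as.integer(hub_degree),
                 hub_penetrance = hub_penetrance),
            class = "planted_pathway")
}

#' Simulation configuration
#'
#' @param n_samples Cohort size.
#' @param n_background_genes Genes outside any planted pathway.
#' @param background_rate Per-cell probability of a background SCNA.
#' @param background_mix Probabilities of calls (-2, -1, +1, +2) conditional
#'   on a background alteration; default puts 95% of mass on monoallelic
#'   events, split evenly between loss and gain.
#' @param planted List of [planted_pathway()] descriptions.
#' @param decoy_pathways Number of additional random (non-planted) pathways
#'   sampled from the background genes.
#' @param decoy_size,decoy_density Size and internal edge density of decoys.
#' @param background_density Edge density among background genes.
#' @param seed Mandatory integer seed; all output is reproducible from it.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200L, n_background_genes = 1000L,
                              background_rate = 0.1,
                              background_mix = c(`-2` = 0.025, `-1` = 0.475,
                                                 `1` = 0.475, `2` = 0.025),
                              planted = list(), decoy_pathways = 0L,
                              decoy_size = 20L, decoy_density = 0.3,
                              background_density = 0.002, seed) {
  if (missing(seed)) stop_config("a seed is mandatory")
  if (background_rate < 0 || background_rate > 1)
    stop_config("background_rate must lie in [0, 1]")
  if (abs(sum(background_mix) - 1) > 1e-9)
    stop_config("background_mix must sum to 1")
  if (inherits(planted, "planted_pathway")) planted <- list(planted)
  structure(list(n_samples = as.integer(n_samples),
                 n_background_genes = as.integer(n_background_genes),
                 background_rate = background_rate,
                 background_mix = background_mix,
                 planted = planted,
                 decoy_pathways = as.integer(decoy_pathways),
                 decoy_size = as.integer(decoy_size),
                 decoy_density = decoy_density,
                 background_density = background_density,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

er_edges <- function(genes, density) {
  n <- length(genes)
  if (n < 2 || density <= 0)
    return(data.frame(a = character(), b = character()))
  pairs <- utils::combn(genes, 2)
  keep <- runif(ncol(pairs)) < density
  data.frame(a = pairs[1, keep], b = pairs[2, keep], stringsAsFactors = FALSE)
}

#' Simulate a cohort with known ground truth
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort`: list with `matrix` (discrete `cn_matrix`),
#'   `pathways` (`pathway_collection` of planted + decoy sets),
#'   `interactions`, `gds`, `mutations` (low-frequency background map) and
#'   `truth` (planted names/directions, hub genes, per-gene event
#'   probabilities).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  S <- config$n_samples
  samples <- sprintf("TUMOR_%03d", seq_len(S))

  sets <- list(); edge_a <- character(); edge_b <- character()
  yeast <- character(); mouse <- character()
  hubs <- character()
  gene_probs <- numeric()
  planted_calls <- list()

  for (pw in config$planted) {
    genes <- sprintf("%s_G%02d", toupper(pw$name), seq_len(pw$n_genes))
    sets[[pw$name]] <- genes
    e <- er_edges(genes, pw$density)
    pen <- rep(pw$penetrance, pw$n_genes)
    if (pw$hub) {
      hub_gene <- genes[1]
      hubs <- c(hubs, hub_gene)
      pen[1] <- pw$hub_penetrance
      partners <- genes[-1][seq_len(min(pw$hub_degree, pw$n_genes - 1L))]
      e <- rbind(e, data.frame(a = hub_gene, b = partners,
                               stringsAsFactors = FALSE))
      mouse <- c(mouse, hub_gene)
    }
    edge_a <- c(edge_a, e$a); edge_b <- c(edge_b, e$b)
    n_gds <- round(pw$gds_fraction * pw$n_genes)
    annotated <- sample(genes, n_gds)
    n_mouse <- round(pw$mouse_fraction * n_gds)
    mouse <- c(mouse, annotated[seq_len(n_mouse)])
    yeast <- c(yeast, setdiff(annotated, mouse))
    call_val <- if (pw$direction == "deletion") -1 else 1
    m <- matrix(rbinom(pw$n_genes * S, 1L, rep(pen, S)) * call_val,
                nrow = pw$n_genes, dimnames = list(genes, samples))
    planted_calls[[pw$name]] <- m
    gene_probs[genes] <- pen
  }

  bg <- sprintf("BG_%05d", seq_len(config$n_background_genes))
  if (config$n_background_genes > 0) {
    altered <- rbinom(config$n_background_genes * S, 1L,
                      config$background_rate) == 1L
    vals <- integer(config$n_background_genes * S)
    vals[altered] <- sample(c(-2L, -1L, 1L, 2L), sum(altered), replace = TRUE,
                            prob = config$background_mix)
    bg_m <- matrix(vals, nrow = config$n_background_genes,
                   dimnames = list(bg, samples))
    gene_probs[bg] <- config$background_rate
    e <- er_edges(bg, config$background_density)
    edge_a <- c(edge_a, e$a); edge_b <- c(edge_b, e$b)
  } else {
    bg_m <- matrix(integer(0), nrow = 0, ncol = S,
                   dimnames = list(NULL, samples))
  }

  for (d in seq_len(config$decoy_pathways)) {
    nm <- sprintf("DECOY_%02d", d)
    genes <- sample(bg, min(config$decoy_size, length(bg)))
    sets[[nm]] <- genes
    e <- er_edges(genes, config$decoy_density)
    edge_a <- c(edge_a, e$a); edge_b <- c(edge_b, e$b)
  }

  values <- rbind(do.call(rbind, planted_calls), bg_m)
  storage.mode(values) <- "double"
  matrix <- cn_matrix(values, mode = "discrete")
  truth <- list(
    planted = data.frame(
      name = vapply(config$planted, `[[`, character(1), "name"),
      direction = vapply(config$planted, `[[`, character(1), "direction"),
      penetrance = vapply(config$planted, `[[`, numeric(1), "penetrance"),
      stringsAsFactors = FALSE),
    hubs = hubs,
    gene_probs = gene_probs)
  mutations <- mutation_freq(setNames(runif(nrow(values), 0, 0.05),
                                      rownames(values)))
  structure(list(
    matrix = matrix,
    pathways = if (length(sets)) pathway_collection(sets) else
      structure(list(), class = "pathway_collection"),
    interactions = interaction_set(edge_a, edge_b),
    gds = gds_map(yeast = yeast, mouse = mouse),
    mutations = mutations,
    truth = truth,
    config = config
  ), class = "synthetic_cohort")
}

#' Simulate a null cohort (no planted pathways)
#'
#' Identical to [simulate_cohort()] with the planted list emptied; decoy
#' pathways (random gene sets over background genes) are kept so calibration
#' runs have pathways to test.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` with empty `truth$planted`.
#' @export
null_cohort <- function(config) {
  config$planted <- list()
  simulate_cohort(config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples; ", length(x$pathways), " pathways (",
      nrow(x$truth$planted), " planted); seed=", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in the input dialects
#'
#' Writes the five inputs exactly as the readers expect them (GMT gene sets,
#' TSV interactions / GDS lists / copy-number matrix / mutation
#' frequencies), plus the ground truth as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gene_sets = file.path(dir, "gene_sets.gmt"),
    interactions = file.path(dir, "interactions.tsv"),
    gds_yeast = file.path(dir, "gds_yeast.tsv"),
    gds_mouse = file.path(dir, "gds_mouse.tsv"),
    copy_number = file.path(dir, "copy_number.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_gene_sets(cohort$pathways, paths[["gene_sets"]])
  write_interactions(cohort$interactions, paths[["interactions"]])
  prov <- attr(cohort$gds, "provenance")
  writeLines(names(prov)[prov == "yeast"], paths[["gds_yeast"]])
  writeLines(names(prov)[prov == "mouse"], paths[["gds_mouse"]])
  write_copy_number(cohort$matrix, paths[["copy_number"]])
  write_mutation_frequencies(cohort$mutations, paths[["mutations"]])
  jsonlite::write_json(
    list(planted = cohort$truth$planted, hubs = cohort$truth$hubs,
         gene_probs = as.list(cohort$truth$gene_probs),
         seed = cohort$config$seed),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
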