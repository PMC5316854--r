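# Tumour-paired permutation null and significance calls.
#
# The null preserves each tumour's own SCNA burden: within every sample the
# multiset of calls over all genes is kept but reassigned to genes by a
# uniform random permutation. Observed and per-replicate null score
# distributions are compared by a two-sample t-test across samples; the
# replicate log10 p-values are averaged and back-transformed (geometric mean
# of p), then Bonferroni-corrected.

#' Shuffle a cohort's gene labels within each tumour
#'
#' For each sample independently, gene calls are permuted uniformly at
#' random, preserving the sample's call histogram exactly. Draws from the
#' current RNG state.
#'
#' @param matrix A discrete `cn_matrix`.
#' @return A discrete `cn_matrix` with identical genes, samples and
#'   per-sample call histograms.
#' @export
shuffle_cohort <- function(matrix) {
  stopifnot(inherits(matrix, "cn_matrix"))
  if (cn_mode(matrix) != "discrete")
    stop_config("shuffle_cohort expects a discrete matrix")
  v <- unclass(matrix)
  n <- nrow(v)
  for (j in seq_len(ncol(v))) v[, j] <- v[sample.int(n), j]
  cn_matrix(v, mode = "discrete")
}

#' Bonferroni correction
#'
#' @param p Probability in (0, 1\].
#' @param m Number of comparisons (>= 1); presets for the published analyses
#'   are available via [bonferroni_preset()].
#' @return `min(1, p * m)`.
#' @export
#' @examples
#' adjust_bonferroni(1e-4, bonferroni_preset("pan_kegg"))
adjust_bonferroni <- function(p, m) {
  if (any(m < 1)) stop_config("Bonferroni m must be >= 1")
  pmin(1, p * m)
}

# Vectorized Welch (or pooled Student) two-sided t-test of one observed
# vector against each column of a null matrix; returns log10 p per column.
# Degenerate comparisons (zero standard error) yield log10 p = 0 (p = 1).
t_log10p <- function(obs, null_mat, var_equal = FALSE) {
  n1 <- length(obs); n2 <- nrow(null_mat)
  m1 <- mean(obs); v1 <- stats::var(obs)
  m2 <- colMeans(null_mat)
  v2 <- (colSums(null_mat^2) - n2 * m2^2) / (n2 - 1)
  v2[v2 < 0] <- 0  # numerical guard
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m2))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  degenerate <- se2 <= 0 | !is.finite(df)
  tstat <- (m1 - m2) / sqrt(se2)
  # log-space survival function keeps extreme p-values finite in log10
  lp <- log(2) + stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE)
  l10 <- pmin(lp / log(10), 0)
  l10[degenerate] <- 0
  floor10 <- log10(.Machine$double.xmin)
  l10[l10 < floor10] <- floor10
  list(log10p = l10, null_means = m2, degenerate = degenerate)
}

# Shared engine: one cohort shuffle per replicate scores every network, so a
# pan-pathway run costs O(n_reps) shuffles and all pathways see the same
# nulls. Replicate r draws from a sub-seed derived once from `seed`, making
# results invariant to pathway iteration order and replicate order.
permutation_engine <- function(networks, matrix, n_reps, seed,
                               scorer, var_equal = FALSE) {
  scorer <- as_scorer(scorer)
  networks <- Filter(function(n) n$scorable, networks)
  if (length(networks) == 0)
    return(list(networks = networks, obs = list(), log10p = list(),
                null_means = list(), degenerate = list(), scorer = scorer))
  pre <- lapply(networks, function(nw) {
    idx <- match(nw$nodes, rownames(matrix))
    list(idx = idx, hit = !is.na(idx), ei = edge_index(nw),
         minabs = abs(min_haploinsufficient_score(nw, scorer)),
         n_nodes = length(nw$nodes))
  })
  score_matrix <- function(vals) {
    lapply(pre, function(p) {
      calls <- base::matrix(0, p$n_nodes, ncol(vals))
      calls[p$hit, ] <- vals[p$idx[p$hit], , drop = FALSE]
      c1 <- calls[p$ei$i1, , drop = FALSE]
      c2 <- calls[p$ei$i2, , drop = FALSE]
      v <- scorer$fun(c1, c2, p$ei$g1, p$ei$g2)
      colSums(base::matrix(v, nrow = length(p$ei$i1))) / p$minabs
    })
  }
  vals <- unclass(matrix)
  obs <- score_matrix(vals)
  rep_seeds <- derive_seeds(seed, n_reps)
  n_genes <- nrow(vals)
  K <- length(networks)
  log10p <- base::matrix(NA_real_, n_reps, K)
  null_means <- base::matrix(NA_real_, n_reps, K)
  degenerate <- base::matrix(FALSE, n_reps, K)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    shuf <- vals
    for (j in seq_len(ncol(shuf))) shuf[, j] <- shuf[sample.int(n_genes), j]
    null_scores <- score_matrix(shuf)
    for (k in seq_len(K)) {
      tt <- t_log10p(obs[[k]], base::matrix(null_scores[[k]], ncol = 1),
                     var_equal = var_equal)
      log10p[r, k] <- tt$log10p
      null_means[r, k] <- tt$null_means
      degenerate[r, k] <- tt$degenerate
    }
  }
  list(networks = networks, obs = obs, log10p = log10p,
       null_means = null_means, degenerate = degenerate, scorer = scorer)
}

result_from_engine <- function(eng, k, n_reps, alpha, m_comparisons, seed) {
  nw <- eng$networks[[k]]
  l10 <- eng$log10p[, k]
  p <- 10^mean(l10)
  q <- adjust_bonferroni(p, m_comparisons)
  mean_obs <- mean(eng$obs[[k]])
  mean_null <- mean(eng$null_means[, k])
  delta <- mean_obs - mean_null
  direction <- if (q > alpha || delta == 0) "none"
               else if (delta < 0) "deletion_enriched" else "amplification_enriched"
  structure(list(
    pathway = nw$name, n_edges = nrow(nw$edges),
    observed = eng$obs[[k]],
    log10p = l10, p = p, q = q,
    direction = direction,
    mean_observed = mean_obs, mean_null = mean_null,
    n_reps = n_reps, n_degenerate = sum(eng$degenerate[, k]),
    alpha = alpha, m_comparisons = m_comparisons, seed = seed,
    scorer = eng$scorer$name
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$pathway, ": p=", signif(x$p, 3),
      " q=", signif(x$q, 3), " direction=", x$direction,
      " (", x$n_reps, " reps, ", x$n_degenerate, " degenerate)\n", sep = "")
  invisible(x)
}

#' Permutation test for one pathway network
#'
#' For each of `n_reps` replicates the cohort is shuffled (tumour-paired),
#' normalized module scores are recomputed, and the observed per-sample
#' scores are compared with that replicate's null scores by a two-sided
#' t-test. The aggregated p is the back-transformed mean of the replicate
#' log10 p-values; Bonferroni correction uses `m_comparisons`. Direction is
#' the sign of the mean observed-minus-null difference, gated to `"none"`
#' when `q > alpha`. Degenerate (zero-variance) replicates contribute p = 1
#' and are counted.
#'
#' @param network A scorable `pathway_network`.
#' @param matrix A discrete `cn_matrix`.
#' @param n_reps Number of shuffle replicates (default 1000).
#' @param alpha Significance level for the direction gate.
#' @param m_comparisons Bonferroni comparison count.
#' @param seed Integer seed; all replicate randomness derives from it.
#' @param scorer An [edge_scorer()] or its name.
#' @param var_equal Use pooled-variance Student instead of Welch.
#' @return A `permutation_result`.
#' @export
permutation_test <- function(network, matrix,
                             n_reps = haptrig_defaults()$n_reps,
                             alpha = haptrig_defaults()$alpha,
                             m_comparisons = 1L, seed = 1L,
                             scorer = haptrig_defaults()$scorer,
                             var_equal = FALSE) {
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  if (!network$scorable) stop_config("network '", network$name, "' is unscorable")
  eng <- permutation_engine(list(network), matrix, n_reps, seed, scorer,
                            var_equal)
  result_from_engine(eng, 1L, n_reps, alpha, m_comparisons, seed)
}

#' Pan-pathway permutation run
#'
#' Builds one network per pathway in the collection, runs the shared-shuffle
#' permutation test (one cohort shuffle per replicate scores every pathway),
#' and Bonferroni-corrects with `m_comparisons` defaulting to the number of
#' scorable pathways tested.
#'
#' @param collection A `pathway_collection`.
#' @param interactions An [interaction_set()].
#' @param gds A [gds_map()].
#' @param matrix A discrete `cn_matrix`.
#' @param mode Edge-retention policy (see [build_pathway_network()]).
#' @param n_reps Number of shuffle replicates.
#' @param alpha Significance level.
#' @param m_comparisons Bonferroni count; `NULL` = number of scorable
#'   pathways.
#' @param seed Integer seed.
#' @param scorer An [edge_scorer()] or its name.
#' @param var_equal Use pooled-variance Student instead of Welch.
#' @return A `pan_pathway_result`: list with `results` (one
#'   `permutation_result` per scorable pathway), `unscorable` (names), and a
#'   `table` data.frame sortable by q.
#' @export
run_pan_pathway <- function(collection, interactions, gds, matrix,
                            mode = "intrinsic",
                            n_reps = haptrig_defaults()$n_reps,
                            alpha = haptrig_defaults()$alpha,
                            m_comparisons = NULL, seed = 1L,
                            scorer = haptrig_defaults()$scorer,
                            var_equal = FALSE) {
  stopifnot(inherits(collection, "pathway_collection"))
  all_genes <- unique(unlist(collection))
  networks <- lapply(names(collection), function(nm) {
    build_pathway_network(collection[[nm]], interactions, gds, mode = mode,
                          cross_universe = if (mode == "cross_pathway")
                            setdiff(all_genes, collection[[nm]]) else NULL,
                          name = nm)
  })
  scorable <- vapply(networks, function(n) n$scorable, logical(1))
  unscorable <- vapply(networks[!scorable], function(n) n$name, character(1))
  m <- m_comparisons %||% max(1L, sum(scorable))
  eng <- permutation_engine(networks[scorable], matrix, n_reps, seed, scorer,
                            var_equal)
  results <- lapply(seq_along(eng$networks), function(k)
    result_from_engine(eng, k, n_reps, alpha, m, seed))
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    pathway = r$pathway, n_edges = r$n_edges,
    mean_norm_score = r$mean_observed, p = r$p, q = r$q,
    direction = r$direction, n_degenerate_reps = r$n_degenerate,
    stringsAsFactors = FALSE)))
  if (is.null(tab)) tab <- data.frame(
    pathway = character(), n_edges = integer(), mean_norm_score = numeric(),
    p = numeric(), q = numeric(), direction = character(),
    n_degenerate_reps = integer(), stringsAsFactors = FALSE)
  tab <- tab[order(tab$q, tab$pathway), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(results = results, unscorable = unscorable, table = tab,
                 n_reps = n_reps, alpha = alpha, m_comparisons = m,
                 seed = seed, scorer = as_scorer(scorer)$name, mode = mode),
            class = "pan_pathway_result")
}

#' @export
print.pan_pathway_result <- function(x, ...) {
  cat("<pan_pathway_result> ", length(x$results), " scorable pathways (",
      length(x$unscorable), " unscorable), m=", x$m_comparisons,
      ", n_reps=", x$n_reps, "\n", sep = "")
  print(utils::head(x$table, 10))
  invisible(x)
}
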