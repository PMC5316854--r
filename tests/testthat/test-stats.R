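test_that("shuffle_cohort preserves per-sample call histograms exactly", {
  set.seed(11)
  m <- cn_matrix(matrix(sample(-2:2, 50 * 8, replace = TRUE), 50, 8,
                        dimnames = list(sprintf("G%02d", 1:50),
                                        sprintf("S%d", 1:8))),
                 "discrete")
  for (i in 1:5) {
    sh <- shuffle_cohort(m)
    expect_equal(dimnames(sh), dimnames(m))
    for (j in seq_len(ncol(m)))
      expect_equal(sort(unname(unclass(sh)[, j])),
                   sort(unname(unclass(m)[, j])))
  }
  # degenerate cases: constant and single-gene matrices are fixed points
  const <- cn_matrix(matrix(0, 5, 3, dimnames = list(paste0("G", 1:5),
                                                     paste0("S", 1:3))),
                     "discrete")
  expect_equal(unclass(shuffle_cohort(const))[, ], unclass(const)[, ])
  one <- cn_matrix(matrix(-1, 1, 3, dimnames = list("G1", paste0("S", 1:3))),
                   "discrete")
  expect_equal(unclass(shuffle_cohort(one))[, ], unclass(one)[, ])
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(adjust_bonferroni(0.0001, 187), 0.0187)
  expect_equal(adjust_bonferroni(0.5, 126), 1)
  expect_equal(adjust_bonferroni(0.2, 1), 0.2)
  expect_error(adjust_bonferroni(0.1, 0), class = "haptrig_config_error")
})

test_that("constant cohort gives p = q = 1 and direction none", {
  nw <- toy_network()
  m <- cn_matrix(matrix(0, 3, 10, dimnames = list(c("A", "B", "C"),
                                                  sprintf("S%d", 1:10))),
                 "discrete")
  r <- permutation_test(nw, m, n_reps = 5, m_comparisons = 3, seed = 1)
  expect_equal(r$p, 1)
  expect_equal(r$q, 1)
  expect_equal(r$direction, "none")
  expect_equal(r$n_degenerate, 5)
})

test_that("n_reps = 1 aggregation is that replicate's p; order invariance", {
  sc <- simulation_config(n_samples = 40, n_background_genes = 60,
                          planted = planted_pathway("PW", penetrance = 0.5),
                          seed = 5)
  co <- simulate_cohort(sc)
  nw <- build_pathway_network(co$pathways$PW, co$interactions, co$gds,
                              name = "PW")
  r1 <- permutation_test(nw, co$matrix, n_reps = 1, seed = 9)
  expect_equal(r1$p, 10^r1$log10p[1])
  r20 <- permutation_test(nw, co$matrix, n_reps = 20, seed = 9)
  expect_equal(10^mean(r20$log10p), r20$p)
  expect_equal(10^mean(rev(r20$log10p)), r20$p)  # replicate-order invariant
})

test_that("permutation test is deterministic in the seed", {
  sc <- simulation_config(n_samples = 30, n_background_genes = 50,
                          planted = planted_pathway("PW"), seed = 2)
  co <- simulate_cohort(sc)
  nw <- build_pathway_network(co$pathways$PW, co$interactions, co$gds,
                              name = "PW")
  a <- permutation_test(nw, co$matrix, n_reps = 10, seed = 4)
  b <- permutation_test(nw, co$matrix, n_reps = 10, seed = 4)
  c <- permutation_test(nw, co$matrix, n_reps = 10, seed = 5)
  expect_identical(a$log10p, b$log10p)
  expect_identical(a$p, b$p)
  expect_false(identical(a$log10p, c$log10p))
})

test_that("a planted deleted pathway is detected as deletion_enriched", {
  sc <- simulation_config(
    n_samples = 200, n_background_genes = 1000, background_rate = 0.1,
    planted = planted_pathway("PW", n_genes = 20, penetrance = 0.6),
    seed = 101)
  co <- simulate_cohort(sc)
  nw <- build_pathway_network(co$pathways$PW, co$interactions, co$gds,
                              name = "PW")
  r <- permutation_test(nw, co$matrix, n_reps = 200, m_comparisons = 10,
                        seed = 202)
  expect_lte(r$q, 0.05)
  expect_equal(r$direction, "deletion_enriched")
})

test_that("pan-pathway run ranks the planted pathway first and is reproducible", {
  sc <- simulation_config(
    n_samples = 100, n_background_genes = 400,
    planted = planted_pathway("PLANTED", penetrance = 0.6),
    decoy_pathways = 2, seed = 31)
  co <- simulate_cohort(sc)
  res <- run_pan_pathway(co$pathways, co$interactions, co$gds, co$matrix,
                         n_reps = 50, seed = 77)
  expect_equal(res$m_comparisons, length(res$results))
  expect_equal(res$table$pathway[1], "PLANTED")
  expect_equal(res$table$direction[1], "deletion_enriched")
  res2 <- run_pan_pathway(co$pathways, co$interactions, co$gds, co$matrix,
                          n_reps = 50, seed = 77)
  expect_identical(res$table, res2$table)
})

test_that("pan-pathway run reports unscorable pathways separately", {
  pc <- pathway_collection(list(P1 = c("A", "B"), P2 = c("C", "D"),
                                P3 = c("E", "F")))
  is <- interaction_set(character(), character())
  m <- cn_matrix(matrix(0, 6, 4, dimnames = list(LETTERS[1:6],
                                                 paste0("S", 1:4))),
                 "discrete")
  res <- run_pan_pathway(pc, is, gds_map(), m, n_reps = 2, seed = 1)
  expect_length(res$results, 0)
  expect_setequal(res$unscorable, c("P1", "P2", "P3"))
  expect_equal(nrow(res$table), 0)
})

test_that("type-I error never exceeds alpha (aggregation is conservative-valid)", {
  # The geometric-mean aggregation of replicate p-values is conservative
  # under the null; the valid one-sided property is that the realized
  # type-I rate does not exceed alpha + 3 MC SE.
  ps <- numeric(0)
  for (i in 1:12) {
    sc <- simulation_config(n_samples = 60, n_background_genes = 200,
                            decoy_pathways = 5, seed = 4000 + i)
    co <- null_cohort(sc)
    res <- run_pan_pathway(co$pathways, co$interactions, co$gds, co$matrix,
                           n_reps = 40, seed = 5000 + i)
    ps <- c(ps, res$table$p)
  }
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("power is monotone in planted penetrance (seed-paired)", {
  p_at <- function(pen, seed) {
    sc <- simulation_config(n_samples = 100, n_background_genes = 300,
                            planted = planted_pathway("PW", penetrance = pen),
                            seed = seed)
    co <- simulate_cohort(sc)
    nw <- build_pathway_network(co$pathways$PW, co$interactions, co$gds,
                                name = "PW")
    permutation_test(nw, co$matrix, n_reps = 30, seed = seed + 1)$p
  }
  # compare a clearly weak and a clearly strong signal across paired seeds;
  # Monte-Carlo tolerance: strong must win on a majority and on the median
  lo <- vapply(1:6, function(s) p_at(0.15, 600 + s), numeric(1))
  hi <- vapply(1:6, function(s) p_at(0.60, 600 + s), numeric(1))
  expect_lt(median(hi), median(lo))
  expect_gte(sum(hi <= lo), 4)
})
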