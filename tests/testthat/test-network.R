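test_that("edge modes retain the right edges", {
  is <- interaction_set(c("A", "B", "X"), c("B", "X", "Y"))
  gds <- gds_map()
  pw <- c("A", "B", "C")

  intr <- build_pathway_network(pw, is, gds, mode = "intrinsic")
  expect_equal(intr$edges, data.frame(a = "A", b = "B"))
  expect_true(all(intr$member))
  expect_setequal(intr$nodes, pw)

  cross <- build_pathway_network(pw, is, gds, mode = "cross_pathway",
                                 cross_universe = "X")
  expect_setequal(paste(cross$edges$a, cross$edges$b), c("A B", "B X"))
  expect_false(cross$member[["X"]])
  expect_error(build_pathway_network(pw, is, gds, mode = "cross_pathway"),
               class = "haptrig_config_error")

  e1 <- build_pathway_network(pw, is, gds, mode = "expand1")
  expect_setequal(e1$nodes, c("A", "B", "C", "X"))
  expect_setequal(paste(e1$edges$a, e1$edges$b), c("A B", "B X"))

  e2 <- build_pathway_network(pw, is, gds, mode = "expand2")
  expect_setequal(e2$nodes, c("A", "B", "C", "X", "Y"))
  expect_equal(nrow(e2$edges), 3)

  empty <- build_pathway_network(c("Q", "R"), is, gds)
  expect_false(empty$scorable)
})

test_that("score_edge matches hand computations and validates domains", {
  expect_equal(score_edge(-1, 0, 3, 1),
               list(value = -3, branch = "deletion"))
  expect_equal(score_edge(0, 0, 3, 2), list(value = 0, branch = "gain"))
  expect_equal(score_edge(-2, 1, 2, 1),
               list(value = -4, branch = "deletion"))  # gain term suppressed
  expect_equal(score_edge(1, 2, 1, 2), list(value = 5, branch = "gain"))
  expect_error(score_edge(-3, 0, 1, 1), class = "haptrig_validation_error")
  expect_error(score_edge(0, 0, 4, 1), class = "haptrig_validation_error")
  # mixed strategy keeps the amplified partner's term
  expect_equal(score_edge(-2, 1, 2, 1, scorer = "gds_linear_mixed")$value, -3)
})

test_that("score_edge branch sign invariants and swap symmetry hold", {
  calls <- -2:2
  for (c1 in calls) for (c2 in calls) for (g1 in 1:3) for (g2 in 1:3) {
    s <- score_edge(c1, c2, g1, g2)
    if (s$branch == "deletion") expect_lte(s$value, 0)
    if (s$branch == "gain") expect_gte(s$value, 0)
    swapped <- score_edge(c2, c1, g2, g1)
    expect_identical(s$value, swapped$value)
  }
})

test_that("min haploinsufficient score is -sum(gds1+gds2) over edges", {
  expect_equal(min_haploinsufficient_score(toy_network()), -8)
  single <- pathway_network("S", c("A", "B"),
                            data.frame(a = "A", b = "B"), gds_map())
  expect_equal(min_haploinsufficient_score(single), -2)
  edgeless <- pathway_network("E", c("A", "B"),
                              data.frame(a = character(), b = character()),
                              gds_map())
  expect_equal(min_haploinsufficient_score(edgeless), 0)
})

test_that("score_module sums edge scores; absent genes count as unaltered", {
  single <- pathway_network("S", c("A", "B"),
                            data.frame(a = "A", b = "B"), gds_map())
  expect_equal(score_module(single, c(A = -1, B = -1)), -2)
  expect_equal(score_module(single, c(A = 0, B = 0)), 0)
  path3 <- pathway_network("P", c("A", "B", "C"),
                           data.frame(a = c("A", "B"), b = c("B", "C")),
                           gds_map())
  expect_equal(score_module(path3, c(A = -1, B = 0, C = 1)), 0)
  # gene missing from the calls: treated as 0
  expect_equal(score_module(path3, c(A = -1)), -1)
})

test_that("score_module equals the brute-force oracle on exhaustive and sampled grids", {
  set.seed(42)
  # exhaustive: every network on <= 3 nodes, all 5^n assignments
  for (rep in 1:5) {
    nw <- random_network(3)
    grid <- expand.grid(A = -2:2, B = -2:2, C = -2:2)
    for (i in seq_len(nrow(grid))) {
      calls <- setNames(as.numeric(grid[i, ]), names(grid))
      expect_equal(score_module(nw, calls), oracle_module_score(nw, calls))
    }
  }
  # sampled assignments for n = 4, 5
  for (n in 4:5) {
    nw <- random_network(n)
    for (i in 1:50) {
      calls <- setNames(sample(-2:2, n, replace = TRUE), nw$nodes)
      expect_equal(score_module(nw, calls), oracle_module_score(nw, calls))
    }
  }
})

test_that("module score is monotone in single-call changes", {
  set.seed(7)
  for (rep in 1:20) {
    nw <- random_network(4)
    calls <- setNames(sample(-2:2, 4, replace = TRUE), nw$nodes)
    g <- sample(nw$nodes, 1)
    base <- score_module(nw, calls)
    down <- calls; down[g] <- max(-2, calls[g] - 1)
    up <- calls; up[g] <- min(2, calls[g] + 1)
    expect_lte(score_module(nw, down), base)
    expect_gte(score_module(nw, up), base)
  }
})

test_that("deleted-edge score is non-increasing in either GDS weight", {
  for (g in 1:2) {
    lo <- score_edge(-1, -1, g, 1)$value
    hi <- score_edge(-1, -1, g + 1, 1)$value
    expect_lte(hi, lo)
  }
})

test_that("normalized scores anchor at -1 and divide raw by |min|", {
  nw <- toy_network()
  m <- toy_matrix(list(
    S1 = c(A = -1, B = -1, C = -1),  # the minimum itself
    S2 = c(A = 0, B = 0, C = 0),
    S3 = c(A = -1, B = -1, C = 0)))  # raw -3 + -2 = ... hand: edges AB=-3, BC=-2 -> -5
  st <- normalized_module_scores(nw, m)
  expect_equal(st$normalized[st$sample == "S1"], -1)
  expect_equal(st$normalized[st$sample == "S2"], 0)
  expect_equal(st$raw[st$sample == "S3"], -5)
  expect_equal(st$normalized[st$sample == "S3"], -5 / 8)
  expect_equal(attr(st, "min_score"), -8)
  expect_equal(attr(st, "mean_normalized"), mean(st$normalized))

  # positive scores may exceed the anchor's magnitude
  m2 <- toy_matrix(list(S1 = c(A = 2, B = 2, C = 2)))
  st2 <- normalized_module_scores(nw, m2)
  expect_gt(st2$normalized, 1)

  edgeless <- pathway_network("E", c("A", "B"),
                              data.frame(a = character(), b = character()),
                              gds_map())
  st3 <- normalized_module_scores(edgeless, m)
  expect_false(attr(st3, "scorable"))
  expect_true(all(is.na(st3$normalized)))
})
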