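test_that("column_normalize produces the expected transition matrices", {
  two <- gene_network(data.frame(from = "a", to = "b"))
  W2 <- column_normalize(two)
  expect_equal(as.matrix(W2$W),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"),
                                                        c("a", "b"))))
  # star K_{1,3}: the centre's column spreads 1/3 to each leaf
  star <- gene_network(data.frame(from = "c", to = c("l1", "l2", "l3")))
  Ws <- column_normalize(star)
  expect_equal(unname(as.matrix(Ws$W)[, "c"]),
               c(0, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(Matrix::colSums(Ws$W)), rep(1, 4))

  # k-regular graph: W is symmetric with entries 1/k
  ring <- ring_network(8)
  Wr <- as.matrix(column_normalize(ring)$W)
  expect_equal(Wr, t(Wr))
  expect_true(all(Wr[Wr > 0] == 0.5))

  disconnected <- gene_network(data.frame(from = c("a", "x"),
                                          to = c("b", "y")))
  expect_error(column_normalize(disconnected), "connected component")
})

test_that("make_seed_vector scores 1/2 and normalizes to a distribution", {
  nodes <- c("g1", "g2", "g3", "g4")
  sv <- make_seed_vector(nodes, group_b = c("g1", "g3"), group_c = "g3")
  expect_equal(unname(sv$raw_scores), c(1L, 0L, 2L, 0L))
  expect_equal(unname(sv$p0), c(1 / 3, 0, 2 / 3, 0))
  expect_equal(sum(sv$p0), 1)

  single <- make_seed_vector(nodes, group_b = "g2")
  expect_equal(unname(single$p0), c(0, 1, 0, 0))

  expect_message(out <- make_seed_vector(nodes, group_b = c("g1", "far")),
                 "1 group gene")
  expect_equal(sum(out$raw_scores), 1)
  expect_error(make_seed_vector(nodes, group_b = "nowhere"), "no seeds")
})

test_that("the walk hits the 2-node closed form and the r = 1 limit", {
  two <- column_normalize(gene_network(data.frame(from = "a", to = "b")))
  res <- random_walk_restart(two, c(a = 1, b = 0), r = 0.7)
  # fixed point of p = 0.3 W p + 0.7 e_a: (0.7/0.91, 0.21/0.91)
  expect_equal(unname(res$p_inf), c(0.7 / 0.91, 0.21 / 0.91),
               tolerance = 1e-9)
  expect_true(res$converged)

  res1 <- random_walk_restart(two, c(a = 1, b = 0), r = 1)
  expect_equal(unname(res1$p_inf), c(1, 0))
  expect_equal(res1$iterations, 1L)
})

test_that("a uniform seed on a regular graph is the fixed point", {
  ring <- column_normalize(ring_network(10))
  p0 <- rep(1 / 10, 10)
  res <- random_walk_restart(ring, p0)
  expect_equal(unname(res$p_inf), p0, tolerance = 1e-10)
})

test_that("iteration equals the direct linear solve and conserves mass", {
  for (i in 1:6) {
    net <- random_connected_network(sample(20:120, 1), seed = 20 + i)
    tm <- column_normalize(net)
    n <- length(tm$nodes)
    set.seed(30 + i)
    seeds <- sample(tm$nodes, min(10, n))
    sv <- make_seed_vector(tm$nodes, group_b = seeds)
    r <- c(0.3, 0.5, 0.7, 0.9)[(i - 1) %% 4 + 1]
    res <- random_walk_restart(tm, sv, r = r)
    direct <- solve(diag(n) - (1 - r) * as.matrix(tm$W), r * sv$p0)
    expect_lt(max(abs(res$p_inf - direct)), 1e-8)
    expect_lt(res$max_mass_dev, 1e-12)
    expect_equal(sum(res$p_inf), 1, tolerance = 1e-9)
  }
})

test_that("steady-state probability decays with distance along a path", {
  n <- 9
  ids <- sprintf("p%02d", 1:n)
  path <- gene_network(data.frame(from = ids[-n], to = ids[-1]))
  tm <- column_normalize(path)
  sv <- make_seed_vector(tm$nodes, group_b = ids[1])
  p <- random_walk_restart(tm, sv)$p_inf
  expect_true(all(diff(p[ids]) < 0))
})

test_that("permutation p-values are reproducible and chunk-invariant", {
  net <- random_connected_network(60, seed = 40)
  tm <- column_normalize(net)
  sv <- make_seed_vector(tm$nodes, group_b = sample(tm$nodes, 8))
  a <- permutation_pvalues(tm, sv, B = 200, seed = 5)
  b <- permutation_pvalues(tm, sv, B = 200, seed = 5)
  expect_identical(a$perm_p, b$perm_p)
  c3 <- permutation_pvalues(tm, sv, B = 200, seed = 5, chunk_size = 7)
  expect_identical(a$perm_p, c3$perm_p)
  expect_true(all(a$perm_p > 0 & a$perm_p <= 1))
})

test_that("the two p-value estimators behave at the extreme", {
  # a dominant seed node beats every permutation: the plug-in p can be 0,
  # the pseudocount estimator returns 1/(B+1)
  star <- gene_network(data.frame(from = "hub",
                                  to = sprintf("l%02d", 1:12)))
  res_plugin <- rwr_significance(star, group_b = "hub", B = 100,
                                 p_mode = "plugin", seed = 6)
  res_pc <- rwr_significance(star, group_b = "hub", B = 100,
                             p_mode = "pseudocount", seed = 6)
  expect_equal(res_plugin$perm_p[res_plugin$gene_id == "hub"], 0)
  pc <- res_pc$perm_p[res_pc$gene_id == "hub"]
  expect_gte(pc, 1 / 101) # the pseudocount floor, never exactly zero
  # permutations that land the seed back on the hub tie rather than beat it
  expect_lt(pc, 0.25)
})

test_that("select_significant uses a strict cut and deterministic ranking", {
  tbl <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    raw_score = 0L,
    steady_prob = c(0.4, 0.3, 0.2, 0.1),
    perm_p = c(0.005, 0.01, 0.009, 0.5)
  )
  sel <- select_significant(tbl, alpha = 0.01)
  expect_identical(sel$gene_id, c("a", "c")) # 0.01 exactly is excluded
  expect_identical(sel$rank, 1:2)

  none <- select_significant(dplyr::mutate(tbl, perm_p = 1))
  expect_equal(nrow(none), 0)

  ties <- tibble::tibble(gene_id = c("z", "y"), raw_score = 0L,
                         steady_prob = c(0.2, 0.2), perm_p = 0.001)
  expect_identical(select_significant(ties)$gene_id, c("y", "z"))
})

test_that("permutation significance is calibrated when nothing is planted", {
  # exchangeable null: randomly placed seeds, no planted structure
  fp <- vapply(1:3, function(i) {
    net <- random_connected_network(150, seed = 60 + i)
    set.seed(70 + i)
    seeds <- sample(net$nodes, 20)
    res <- rwr_significance(net, group_b = seeds, B = 500, seed = 80 + i)
    mean(res$perm_p[!res$gene_id %in% seeds] < 0.01)
  }, numeric(1))
  expect_lte(mean(fp), 0.02)
})
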