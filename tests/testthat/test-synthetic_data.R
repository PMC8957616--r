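# Synthetic generator: topologies, precision construction, count sampling.

test_that("band topology with width 1 is a path; zero density is empty", {
  adj <- generate_true_network(5, "band", band_width = 1)
  expect_equal(sum(adj) / 2, 4)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(igraph::diameter(g), 4)  # path graph on 5 nodes
  empty <- generate_true_network(3, "erdos_renyi", edge_density = 0)
  expect_equal(sum(empty), 0)
})

test_that("erdos_renyi realizes the exact rounded edge count", {
  adj <- generate_true_network(30, "erdos_renyi", edge_density = 0.1,
                               seed = 7)
  expect_equal(sum(adj) / 2, round(0.1 * 30 * 29 / 2))
  expect_true(isSymmetric(unname(adj)))
  expect_equal(diag(adj), setNames(rep(0L, 30), rownames(adj)))
})

test_that("all topologies give symmetric zero-diagonal binary adjacencies", {
  for (topo in c("band", "scale_free", "cluster", "erdos_renyi")) {
    adj <- generate_true_network(20, topo, edge_density = 0.12, seed = 3)
    expect_true(isSymmetric(unname(adj)), info = topo)
    expect_true(all(diag(adj) == 0), info = topo)
    expect_true(all(adj %in% c(0, 1)), info = topo)
  }
})

test_that("precision matrix is positive definite with support = adjacency", {
  # tridiagonal magnitude-0.3 path on 3 nodes: eigenvalues 1 and 1 +/- 0.3*sqrt(2)
  adj <- generate_true_network(3, "band", band_width = 1)
  p0 <- adj * 0.3 + diag(3)
  ev <- eigen(p0, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), sort(c(1 - 0.3 * sqrt(2), 1, 1 + 0.3 * sqrt(2))),
               tolerance = 1e-12)

  for (topo in c("band", "erdos_renyi")) {
    adj <- generate_true_network(15, topo, edge_density = 0.15, seed = 2)
    prec <- network_to_precision(adj, condition_target = 10)
    ev <- eigen(prec, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lte(max(ev) / min(ev), 10 * 1.5)  # rescale perturbs mildly
    supp <- (abs(prec) > 1e-12) * 1L; diag(supp) <- 0L
    expect_equal(unname(supp), unname(adj * 1L))
    # inverting the covariance recovers the same sparsity pattern
    prec_back <- solve(solve(prec))
    supp_back <- (abs(prec_back) > 1e-8) * 1L; diag(supp_back) <- 0L
    expect_equal(unname(supp_back), unname(adj * 1L))
  }
  empty <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  prec <- network_to_precision(empty)
  expect_equal(unname(prec), diag(4))
})

test_that("sampled counts honour the cohort design", {
  adj <- generate_true_network(10, "band", band_width = 1)
  model <- true_model(adj, network_to_precision(adj))
  design <- cohort_design()  # study defaults: 36 + 34, printed depth range
  tab <- sample_counts(model, design, seed = 4)
  expect_s3_class(tab, "count_table")
  expect_equal(nrow(tab$counts), 70)
  expect_equal(as.vector(table(tab$metadata$timepoint)[c("baseline", "post")]),
               c(36, 34))
  depths <- rowSums(tab$counts)
  expect_true(all(depths >= design$depth_min & depths <= design$depth_max))
  expect_true(all(tab$counts == round(tab$counts) & tab$counts >= 0))
  # pure function of (parameters, seed)
  tab2 <- sample_counts(model, design, seed = 4)
  expect_identical(tab$counts, tab2$counts)
  tab3 <- sample_counts(model, design, seed = 5)
  expect_false(identical(tab$counts, tab3$counts))
})

test_that("identity precision with equal base composition gives exchangeable taxa", {
  p <- 6
  adj <- matrix(0L, p, p, dimnames = list(sprintf("t%d", 1:p),
                                          sprintf("t%d", 1:p)))
  model <- true_model(adj, network_to_precision(adj),
                      base_composition = rep(1 / p, p))
  design <- cohort_design(n_baseline = 2500, n_post = 2500,
                          depth_mean = 5000, depth_min = 5000,
                          depth_max = 5000, seed = 1)
  tab <- sample_counts(model, design, seed = 8)
  rel <- colMeans(tab$counts / rowSums(tab$counts))
  # all taxa share the same marginal law; Monte-Carlo error ~ sd/sqrt(n)
  expect_true(all(abs(rel - 1 / p) < 0.01))
})

test_that("latent covariance converges to the precision inverse", {
  adj <- generate_true_network(8, "band", band_width = 1)
  prec <- network_to_precision(adj)
  sigma <- solve(prec)
  frob <- sapply(c(100, 5000), function(n) {
    set.seed(42)
    z <- MASS::mvrnorm(n, mu = rep(0, 8), Sigma = sigma)
    norm(stats::cov(z) * (n - 1) / n - sigma, "F")
  })
  # Monte-Carlo error shrinks like 1/sqrt(n): 50x more samples should cut
  # the Frobenius distance well below half
  expect_lt(frob[2], frob[1] / 2)
})

test_that("two-arm dataset has a strictly denser post-arm truth", {
  design <- cohort_design(n_baseline = 10, n_post = 10, seed = 1)
  arm <- two_arm_dataset(30, 0.05, 0.15, design, seed = 1)
  e_base <- sum(arm$model_baseline$adjacency) / 2
  e_post <- sum(arm$model_post$adjacency) / 2
  expect_gt(e_post, e_base)
  expect_equal(2 * e_base / 30, mean(colSums(arm$model_baseline$adjacency)))
  expect_lt(mean(colSums(arm$model_baseline$adjacency)),
            mean(colSums(arm$model_post$adjacency)))
  # post truth is a superset: shared ecological core
  expect_true(all(arm$model_post$adjacency >= arm$model_baseline$adjacency))
  arm2 <- two_arm_dataset(30, 0.05, 0.15, design, seed = 1)
  expect_identical(arm$table$counts, arm2$table$counts)
  expect_error(two_arm_dataset(30, 0.15, 0.15, design),
               "strictly greater")
})
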