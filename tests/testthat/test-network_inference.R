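# Neighbourhood lasso, StARS selection and network assembly.

test_that("lambda_max yields the empty model and matches the max correlation", {
  cohort <- band_cohort(p = 10, n = 40, seed = 2)
  clr <- clr_transform(cohort$table)
  path <- lambda_path(clr)
  xs <- scale(clr$values) * sqrt(nrow(clr$values) /
                                 (nrow(clr$values) - 1))
  cc <- crossprod(xs) / nrow(xs)
  expect_equal(path$lambda_max, max(abs(cc[upper.tri(cc)])),
               tolerance = 1e-10)
  b <- neighborhood_fit(clr, path$lambda_max * 1.0001)
  expect_true(all(b == 0))
  expect_equal(length(path$lambdas), 20)
  expect_equal(path$lambdas[20] / path$lambdas[1], 0.01, tolerance = 1e-10)
  expect_true(all(diff(path$lambdas) < 0))
})

test_that("lasso coefficients agree with a coordinate-descent oracle", {
  # two taxa with identical CLR profiles plus independent noise taxa:
  # the pair must select each other and the oracle must agree everywhere
  set.seed(10)
  n <- 200
  z <- rnorm(n)
  x <- cbind(z, z, matrix(rnorm(n * 3), n, 3))
  counts <- round(exp(x - min(x) + 2) * 50)
  colnames(counts) <- sprintf("t%d", 1:5)
  clr <- clr_transform(count_table(counts))
  lam <- 0.2
  b <- neighborhood_fit(clr, lam)
  expect_true(b["t1", "t2"] != 0 && b["t2", "t1"] != 0)
  expect_true(all(b[3:5, 1:2] == 0))
  xs <- apply(clr$values, 2, function(v) (v - mean(v)) /
                sqrt(mean((v - mean(v))^2)))
  # with the duplicated pair among the predictors the lasso solution is not
  # unique coefficient-wise, so compare only the well-posed regressions
  for (j in 1:2) {
    oracle <- cd_lasso_oracle(xs[, -j, drop = FALSE], xs[, j], lam)
    expect_equal(unname(b[-j, j]), oracle, tolerance = 1e-3)
  }

  # general random design: oracle agreement for every neighbourhood
  set.seed(33)
  counts2 <- matrix(round(exp(matrix(rnorm(120 * 6, 5, 1), 120, 6))), 120, 6)
  colnames(counts2) <- sprintf("u%d", 1:6)
  clr2 <- clr_transform(count_table(counts2))
  xs2 <- apply(clr2$values, 2, function(v) (v - mean(v)) /
                 sqrt(mean((v - mean(v))^2)))
  b2 <- neighborhood_fit(clr2, 0.1)
  for (j in 1:6) {
    oracle <- cd_lasso_oracle(xs2[, -j, drop = FALSE], xs2[, j], 0.1)
    expect_equal(unname(b2[-j, j]), oracle, tolerance = 1e-3)
  }
})

test_that("active-set coefficient magnitudes shrink as lambda grows", {
  cohort <- band_cohort(p = 8, n = 150, seed = 6)
  clr <- clr_transform(cohort$table)
  path <- lambda_path(clr, n_lambda = 10)
  mags <- sapply(path$lambdas, function(l)
    sum(abs(neighborhood_fit(clr, l))))
  expect_true(all(diff(mags) >= -1e-10))  # lambdas decrease along the path
})

test_that("stars instability follows 2*theta*(1-theta) and selection is stable", {
  cohort <- band_cohort(p = 8, n = 60, seed = 9)
  clr <- clr_transform(cohort$table)
  st <- stars_select(clr, n_subsamples = 20, seed = 1)
  p <- ncol(clr$values)
  ut <- upper.tri(matrix(0, p, p))
  for (l in c(1, st$selected_index, length(st$path$lambdas))) {
    th <- st$selection_freq[, , l][ut]
    expect_equal(st$instability[l], mean(2 * th * (1 - th)),
                 tolerance = 1e-12)
  }
  # near lambda_max selection is rare (a subsample's own max correlation
  # can slightly exceed the full-data lambda_max, so not exactly zero)
  expect_lt(st$instability[1], 0.05)
  # a hypothetical edge selected in exactly half the subsamples would
  # contribute the maximal 2 * 0.5 * 0.5 = 0.5
  expect_true(all(st$instability >= 0 & st$instability <= 0.5))
  expect_true(all(diff(st$instability_monotone) >= 0))
  expect_true(st$selected_lambda %in% st$path$lambdas)
  expect_lte(st$instability_monotone[st$selected_index],
             st$stability_threshold)
  if (st$selected_index < length(st$path$lambdas))
    expect_gt(st$instability_monotone[st$selected_index + 1],
              st$stability_threshold)
  st2 <- stars_select(clr, n_subsamples = 20, seed = 1)
  expect_identical(st$selection_freq, st2$selection_freq)
})

test_that("edge count is monotone along the path and symmetrization rules hold", {
  cohort <- band_cohort(p = 10, n = 80, seed = 4)
  clr <- clr_transform(cohort$table)
  path <- lambda_path(clr, n_lambda = 8)
  counts <- sapply(path$lambdas, function(l) {
    b <- neighborhood_fit(clr, l)
    sum((b != 0 | t(b != 0))[upper.tri(b)])
  })
  expect_true(all(diff(counts) >= 0))

  # OR vs AND arithmetic on a constructed coefficient matrix
  b <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  b["a", "b"] <- 0.4  # a predicts b, not vice versa
  net_or <- mnpnet:::coefs_to_network(b, 0.1, "OR")
  net_and <- mnpnet:::coefs_to_network(b, 0.1, "AND")
  expect_equal(nrow(net_or$edges), 1)
  expect_equal(net_or$edges$weight, 0.2)
  expect_equal(nrow(net_and$edges), 0)
  b["b", "a"] <- 0.3; b["a", "b"] <- 0.3
  net_sym <- mnpnet:::coefs_to_network(b, 0.1, "AND")
  expect_equal(net_sym$edges$weight, 0.3)
  # all-zero coefficients give an empty network on the full node set
  net0 <- mnpnet:::coefs_to_network(b * 0, 0.1, "OR")
  expect_equal(net0$nodes, c("a", "b", "c"))
  expect_equal(nrow(net0$edges), 0)
})

test_that("band-graph data is recovered with F1 >= 0.7 (p=20, n=400)", {
  adj <- generate_true_network(20, "band", band_width = 1)
  model <- true_model(adj, network_to_precision(adj))
  design <- cohort_design(n_baseline = 200, n_post = 200,
                          depth_mean = 50000, depth_min = 50000,
                          depth_max = 50000, seed = 1)
  tab <- sample_counts(model, design, seed = 21)
  clr <- clr_transform(filter_taxa(tab))
  st <- stars_select(clr, seed = 2)
  net <- infer_network(clr, st)
  scores <- edge_f1(net, adj)
  expect_gte(scores["f1"], 0.7)
})

test_that("column-permuted data yields near-empty networks at the data-selected lambda", {
  cohort <- band_cohort(p = 12, n = 100, seed = 12)
  clr <- clr_transform(filter_taxa(cohort$table))
  st <- stars_select(clr, n_subsamples = 30, seed = 3)
  net <- infer_network(clr, st)
  e0 <- max(nrow(net$edges), 1)
  perm_edges <- sapply(1:10, function(r) {
    set.seed(100 + r)
    vp <- apply(clr$values, 2, sample)
    clr_p <- clr
    clr_p$values <- vp
    nrow(fit_network(clr_p, st$selected_lambda)$edges)
  })
  expect_lte(mean(perm_edges), 0.05 * e0 + 0.5)
})

test_that("inference is reproducible end to end under a fixed seed", {
  cohort <- band_cohort(p = 10, n = 30, seed = 8)
  cfg <- mnp_config(seed = 99, n_subsamples = 15)
  n1 <- compute_mnp(cohort$table, cfg)
  n2 <- compute_mnp(cohort$table, cfg)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$lambda, n2$lambda)
})
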