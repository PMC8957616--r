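# Connectivity metrics, natural connectivity, fragility and robustness AUC.

ring_graph <- function(n) igraph::make_ring(n)

named_graph <- function(edges, nodes) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

test_that("basic metrics satisfy the 2E/N identity", {
  tri <- named_graph(c("a","b","b","c","a","c"), c("a","b","c"))
  m <- basic_metrics(tri)
  expect_equal(m$mean_degree, 2); expect_equal(m$edge_number, 3)
  expect_equal(m$node_number, 3)
  p4 <- named_graph(c("a","b","b","c","c","d"), letters[1:4])
  m4 <- basic_metrics(p4)
  expect_equal(m4$mean_degree, 1.5)
  empty5 <- named_graph(character(0), letters[1:5])
  m5 <- basic_metrics(empty5)
  expect_equal(m5$mean_degree, 0); expect_equal(m5$node_number, 5)
  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(12, 0.3)
    ms <- basic_metrics(g)
    expect_equal(ms$mean_degree, 2 * ms$edge_number / ms$node_number)
  }
})

test_that("natural connectivity matches closed forms", {
  expect_equal(natural_connectivity(named_graph(character(0), letters[1:7])),
               0)
  e2 <- named_graph(c("a", "b"), c("a", "b"))
  expect_equal(natural_connectivity(e2), log(cosh(1)), tolerance = 1e-12)
  tri <- named_graph(c("a","b","b","c","a","c"), c("a","b","c"))
  expect_equal(natural_connectivity(tri),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)
  expect_equal(natural_connectivity(tri), 0.996311, tolerance = 1e-5)
  for (n in 3:10) {
    kn <- igraph::make_full_graph(n)
    expect_equal(natural_connectivity(kn),
                 log((exp(n - 1) + (n - 1) * exp(-1)) / n),
                 tolerance = 1e-9, info = paste("K", n))
  }
})

test_that("natural connectivity strictly increases under edge addition", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.7))
    non_edges <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    if (nrow(non_edges) == 0) next
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, pick)
    expect_gt(natural_connectivity(g2), natural_connectivity(g))
  }
})

test_that("targeted attack removes the most central nodes first", {
  path3 <- named_graph(c("a","b","b","c"), c("a","b","c"))
  fc <- fragility_curve(path3)
  expect_equal(fc$removal_order[1], "b")  # unique betweenness maximum
  expect_equal(fc$steps$lcc_size[2], 1)
  star <- named_graph(c("hub","l1","hub","l2","hub","l3","hub","l4"),
                      c("hub", "l1", "l2", "l3", "l4"))
  fs <- fragility_curve(star)
  expect_equal(fs$removal_order[1], "hub")
  expect_equal(fs$steps$lcc_size[1:2], c(5, 1))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("d", "a", "c", "b")
  fk <- fragility_curve(k4)
  expect_equal(fk$removal_order, c("a", "b", "c", "d"))  # all keys tie
  expect_equal(fk$steps$lcc_size, c(4, 3, 2, 1, 0))
})

test_that("fragility curves are monotone with uniform removal fractions", {
  set.seed(31)
  for (i in 1:10) {
    g <- igraph::sample_gnp(10, 0.35)
    igraph::V(g)$name <- sprintf("n%02d", 1:10)
    fc <- fragility_curve(g)
    expect_true(all(diff(fc$steps$lcc_size) <= 0))
    expect_equal(fc$steps$fraction_removed, (0:10) / 10)
  }
})

test_that("robustness AUC behaves at the extremes and ranks densities", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- letters[1:4]
  p4 <- named_graph(c("a","b","b","c","c","d"), letters[1:4])
  auc_k4 <- robustness_auc(fragility_curve(k4), "lcc_fraction")
  auc_p4 <- robustness_auc(fragility_curve(p4), "lcc_fraction")
  expect_gt(auc_k4, auc_p4)
  # constant response integrates to exactly 1
  fake <- structure(list(steps = data.frame(
    fraction_removed = seq(0, 1, 0.25), lcc_size = rep(4, 5),
    natural_connectivity = rep(2, 5))), class = "fragility_curve")
  expect_equal(robustness_auc(fake, "natural_connectivity"), 1)
  expect_equal(robustness_auc(fake, "lcc_fraction"), 1)
  # immediate collapse drives the AUC toward 0
  drop <- structure(list(steps = data.frame(
    fraction_removed = c(0, 1e-3, seq(0.1, 1, 0.1)),
    lcc_size = c(100, rep(0, 11)),
    natural_connectivity = c(5, rep(0, 11)))), class = "fragility_curve")
  expect_lt(robustness_auc(drop), 0.01)
  # zero initial response cannot be normalized
  z <- structure(list(steps = data.frame(
    fraction_removed = c(0, 1), lcc_size = c(0, 0),
    natural_connectivity = c(0, 0))), class = "fragility_curve")
  expect_equal(as.numeric(robustness_auc(z)), 0)
  expect_true(attr(robustness_auc(z), "undefined"))
})

test_that("complete graphs are at least as robust as sparse connected graphs", {
  # under the LCC response this is a theorem: K_n keeps lcc = n - k after
  # k removals while any other graph can only do worse
  for (n in 4:8) {
    kn <- igraph::make_full_graph(n)
    igraph::V(kn)$name <- sprintf("v%d", 1:n)
    auc_kn <- robustness_auc(fragility_curve(kn), "lcc_fraction")
    expect_equal(auc_kn, 0.5, tolerance = 1e-12)
    set.seed(n)
    for (rep in 1:3) {
      tr <- igraph::sample_tree(n)
      igraph::V(tr)$name <- sprintf("v%d", 1:n)
      expect_gte(auc_kn + 1e-12,
                 robustness_auc(fragility_curve(tr), "lcc_fraction"))
    }
  }
})

test_that("metric_set bundles fragility as the robustness complement", {
  cohort <- band_cohort(p = 10, n = 30, seed = 2)
  net <- compute_mnp(cohort$table, mnp_config(seed = 3, n_subsamples = 10))
  ms <- metric_set(net)
  expect_equal(ms$fragility, 1 - ms$robustness)
  expect_equal(ms$mean_degree, 2 * ms$edge_number / ms$node_number)
  expect_equal(ms$natural_connectivity_initial, natural_connectivity(net))
})
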