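# Shared fixtures and independent oracles, all built in code at test time.

# Tiny deterministic count table for preprocessing tests.
toy_table <- function() {
  counts <- rbind(c(980, 10, 10),
                  c(990, 5, 5),
                  c(1000, 0, 0))
  count_table(counts,
              sample_ids = c("s1", "s2", "s3"),
              taxon_ids = c("t1", "t2", "t3"))
}

# Synthetic cohort with a known band network; small enough for fast tests.
band_cohort <- function(p = 15, n = 20, seed = 1L, depth = 20000) {
  adj <- generate_true_network(p, "band", band_width = 1)
  model <- true_model(adj, network_to_precision(adj),
                      topology_name = "band")
  half <- ceiling(n / 2)
  design <- cohort_design(n_baseline = half, n_post = n - half,
                          depth_mean = depth, depth_min = depth,
                          depth_max = depth, seed = seed)
  list(table = sample_counts(model, design, seed = seed), model = model)
}

# Independent coordinate-descent lasso oracle: minimizes
# (1/2n)||y - Xb||^2 + lambda * ||b||_1 by cyclic soft-thresholding.
cd_lasso_oracle <- function(X, y, lambda, tol = 1e-12, maxit = 100000) {
  n <- nrow(X); p <- ncol(X)
  b <- numeric(p)
  xx <- colSums(X^2) / n
  for (it in seq_len(maxit)) {
    b_old <- b
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% b[-j]
      z <- sum(X[, j] * r) / n
      b[j] <- sign(z) * max(abs(z) - lambda, 0) / xx[j]
    }
    if (max(abs(b - b_old)) < tol) return(b)
  }
  b
}

# Exact two-sided signed-rank p-value by full enumeration of sign vectors
# (midranks, zeros already removed). Feasible for n <= 12.
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs + 1e-9),
                 mean(v_all >= v_obs - 1e-9)))
}

# Edge set of a network as sorted "a|b" keys.
edge_key_set <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  paste(pmin(net$edges$from, net$edges$to),
        pmax(net$edges$from, net$edges$to), sep = "|")
}

# Edge keys of a binary adjacency matrix.
adj_key_set <- function(adj) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  paste(rownames(adj)[idx[, 1]], colnames(adj)[idx[, 2]], sep = "|")
}

# Precision/recall/F1 of an inferred edge set against a true adjacency.
edge_f1 <- function(net, adj) {
  est <- edge_key_set(net)
  truth <- adj_key_set(adj)
  tp <- length(intersect(est, truth))
  if (length(est) == 0 || length(truth) == 0 || tp == 0)
    return(c(precision = 0, recall = 0, f1 = 0))
  pr <- tp / length(est); rc <- tp / length(truth)
  c(precision = pr, recall = rc, f1 = 2 * pr * rc / (pr + rc))
}
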