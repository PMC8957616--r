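# Synthetic compositional count tables with a known association network.
# Logistic-normal -> multinomial generator: latent taxon abundances follow a
# multivariate normal whose precision matrix carries the true network, the
# softmax maps them to a composition, and reads are drawn multinomially at a
# log-normal per-sample depth.

#' Generate a ground-truth association network
#'
#' Builds a symmetric, zero-diagonal binary adjacency matrix over `n_taxa`
#' taxa under one of four standard topologies used in graphical-model
#' recovery studies.
#'
#' * `band`: each taxon is linked to its `band_width` nearest index
#'   neighbours (band width 1 is a path). If `band_width` is `NULL` it is the
#'   smallest width whose edge count reaches `edge_density`.
#' * `erdos_renyi`: exactly `round(edge_density * n_taxa*(n_taxa-1)/2)` edges
#'   sampled uniformly without replacement, so the realized density is
#'   deterministic.
#' * `scale_free`: Barabasi-Albert preferential attachment.
#' * `cluster`: three-block stochastic block model with dense blocks and
#'   sparse between-block links, matched in expectation to `edge_density`.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param topology one of `"band"`, `"scale_free"`, `"cluster"`,
#'   `"erdos_renyi"`.
#' @param edge_density target fraction of the `n_taxa*(n_taxa-1)/2` possible
#'   edges. Zero yields an empty adjacency for any topology.
#' @param seed integer RNG seed (random topologies).
#' @param band_width band topology: links to the `band_width` nearest index
#'   neighbours on each side.
#' @return binary adjacency matrix with taxon dimnames.
#' @export
generate_true_network <- function(n_taxa, topology = c("band", "scale_free",
                                                       "cluster", "erdos_renyi"),
                                  edge_density = 0.1, seed = 1L,
                                  band_width = NULL) {
  topology <- match.arg(topology)
  stopifnot(n_taxa >= 3, edge_density >= 0, edge_density < 1)
  ids <- sprintf("taxon_%03d", seq_len(n_taxa))
  adj <- matrix(0L, n_taxa, n_taxa, dimnames = list(ids, ids))
  n_possible <- n_taxa * (n_taxa - 1) / 2
  m_target <- round(edge_density * n_possible)
  if (edge_density == 0 && is.null(band_width)) return(adj)

  if (topology == "band") {
    k <- band_width
    if (is.null(k)) {
      # smallest band width reaching the target edge count
      counts <- vapply(seq_len(n_taxa - 1),
                       function(k) k * n_taxa - k * (k + 1) / 2, numeric(1))
      k <- which(counts >= m_target)[1]
      if (is.na(k))
        stop("density infeasible for band topology at this n_taxa")
    }
    stopifnot(k >= 1, k <= n_taxa - 1)
    for (d in seq_len(k)) {
      i <- seq_len(n_taxa - d)
      adj[cbind(i, i + d)] <- 1L
      adj[cbind(i + d, i)] <- 1L
    }
    return(adj)
  }

  if (topology == "erdos_renyi") {
    if (m_target == 0) return(adj)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    pick <- with_seed(derive_seed(seed, "erdos_renyi"),
                      sample.int(nrow(pairs), m_target))
    adj[pairs[pick, , drop = FALSE]] <- 1L
    adj[pairs[pick, c(2, 1), drop = FALSE]] <- 1L
    return(adj)
  }

  if (topology == "scale_free") {
    m <- max(1L, round(m_target / n_taxa))
    g <- with_seed(derive_seed(seed, "scale_free"),
                   igraph::sample_pa(n_taxa, m = m, directed = FALSE))
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    a[a > 1] <- 1L
    dimnames(a) <- list(ids, ids)
    return(a)
  }

  # cluster: 3 blocks, within-block probability 10x between-block, matched in
  # expectation to the target edge count
  sizes <- diff(round(seq(0, n_taxa, length.out = 4)))
  n_within <- sum(sizes * (sizes - 1) / 2)
  n_between <- n_possible - n_within
  p_w <- min(0.95, m_target / (n_within + n_between / 10))
  pm <- matrix(p_w / 10, 3, 3); diag(pm) <- p_w
  g <- with_seed(derive_seed(seed, "cluster"),
                 igraph::sample_sbm(n_taxa, pref.matrix = pm,
                                    block.sizes = sizes))
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(a) <- list(ids, ids)
  a
}

#' Build a positive-definite precision matrix on a given support
#'
#' Places a constant magnitude on the adjacency support, then shifts the
#' diagonal so the condition number is at most `condition_target` (and the
#' smallest eigenvalue at least 0.01), and finally rescales to unit diagonal.
#' The off-diagonal support of the result equals the adjacency exactly, so
#' the matrix serves as the ground-truth precision (inverse covariance) of
#' the latent abundances.
#'
#' @param adjacency symmetric binary adjacency with zero diagonal.
#' @param condition_target upper bound for the condition number (default 10).
#' @param magnitude off-diagonal magnitude before shifting (default 0.3).
#' @param sign `"positive"` for a constant positive off-diagonal, `"mixed"`
#'   for random +/- signs (drawn under `seed`).
#' @param seed RNG seed, used only for `sign = "mixed"`.
#' @return symmetric positive-definite precision matrix, unit diagonal.
#' @export
network_to_precision <- function(adjacency, condition_target = 10,
                                 magnitude = 0.3,
                                 sign = c("positive", "mixed"), seed = 1L) {
  sign <- match.arg(sign)
  stopifnot(isSymmetric(unname(adjacency)), all(diag(adjacency) == 0),
            condition_target > 1, magnitude > 0)
  p <- nrow(adjacency)
  s <- adjacency * magnitude
  if (sign == "mixed") {
    flip <- with_seed(derive_seed(seed, "precision_signs"), {
      f <- matrix(sample(c(-1, 1), p * p, replace = TRUE), p, p)
      f[lower.tri(f)] <- t(f)[lower.tri(f)]
      f
    })
    s <- s * flip
  }
  prec <- s + diag(p)
  ev <- eigen(prec, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev); lmax <- max(ev)
  floor_ev <- 0.01
  shift <- max(0,
               (lmax - condition_target * lmin) / (condition_target - 1),
               floor_ev - lmin)
  prec <- prec + diag(shift, p)
  # unit diagonal; preserves support and positive definiteness
  d <- 1 / sqrt(diag(prec))
  prec <- prec * outer(d, d)
  dimnames(prec) <- dimnames(adjacency)
  prec
}

#' Cohort design for the synthetic generator
#'
#' Encodes the sampling design the generator emulates: two timepoints with
#' the study's group sizes, and per-sample read depths following a log-normal
#' law truncated to the printed depth range. The log-normal parameters are
#' fitted so the untruncated mean matches `depth_mean` and the bounds sit at
#' the expected extreme order statistics of `n_baseline + n_post` draws.
#'
#' @param n_baseline,n_post samples per arm (defaults 36 and 34).
#' @param depth_mean,depth_min,depth_max mean and bounds of per-sample read
#'   depth (defaults 326333, 63892 and 975103 reads).
#' @param seed integer master seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_baseline = 36, n_post = 34,
                          depth_mean = 326333, depth_min = 63892,
                          depth_max = 975103, seed = 1L) {
  stopifnot(n_baseline >= 3, n_post >= 3,
            depth_min > 0, depth_min <= depth_max,
            depth_mean >= depth_min, depth_mean <= depth_max)
  n <- n_baseline + n_post
  z <- stats::qnorm(n / (n + 1))
  sdlog <- (log(depth_max) - log(depth_min)) / (2 * z)
  meanlog <- log(depth_mean) - sdlog^2 / 2
  structure(list(n_baseline = n_baseline, n_post = n_post,
                 depth_meanlog = meanlog, depth_sdlog = sdlog,
                 depth_min = depth_min, depth_max = depth_max, seed = seed),
            class = "cohort_design")
}

# Truncated log-normal depths: resample out-of-bounds draws (with a small
# tolerance so degenerate min = max designs are exact, not rejected by
# floating-point error).
draw_depths <- function(n, design, seed) {
  lo <- design$depth_min * (1 - 1e-9)
  hi <- design$depth_max * (1 + 1e-9)
  with_seed(seed, {
    d <- numeric(0)
    while (length(d) < n) {
      x <- stats::rlnorm(n, design$depth_meanlog, design$depth_sdlog)
      d <- c(d, x[x >= lo & x <= hi])
    }
    pmin(pmax(round(d[seq_len(n)]), design$depth_min), design$depth_max)
  })
}

# One arm of logistic-normal-multinomial counts. Returns an integer matrix.
sample_arm <- function(precision, base_composition, depths, seed) {
  p <- nrow(precision)
  n <- length(depths)
  sigma <- solve(precision)
  mu <- log(base_composition)
  z <- with_seed(derive_seed(seed, "latent"),
                 MASS::mvrnorm(n, mu = mu, Sigma = sigma))
  z <- matrix(z, nrow = n)
  comp <- exp(z - apply(z, 1, max))
  comp <- comp / rowSums(comp)
  counts <- with_seed(derive_seed(seed, "multinomial"), {
    t(vapply(seq_len(n),
             function(i) as.integer(stats::rmultinom(1, depths[i], comp[i, ])),
             integer(p)))
  })
  colnames(counts) <- rownames(precision)
  counts
}

#' Sample a compositional count table from a true model
#'
#' Draws `n_baseline + n_post` samples from the logistic-normal-multinomial
#' model: latent log-abundances from a multivariate normal with covariance
#' `solve(model$precision)` and mean `log(model$base_composition)`, softmax
#' to a composition, and a multinomial read draw at a per-sample depth from
#' the design's truncated log-normal law. Row sums equal the drawn depths
#' exactly; the generator is a pure function of (parameters, seed).
#'
#' @param model a `true_model` as returned by [true_model()].
#' @param design a `cohort_design`.
#' @param seed integer seed; defaults to the design's seed.
#' @return a `count_table` with timepoint labels `baseline` / `post` and
#'   paired subject ids.
#' @export
sample_counts <- function(model, design, seed = design$seed) {
  stopifnot(inherits(model, "true_model"), inherits(design, "cohort_design"))
  if (design$depth_min < 1)
    warning("depth bounds below one read; rarefaction will be infeasible")
  n <- design$n_baseline + design$n_post
  depths <- draw_depths(n, design, derive_seed(seed, "depths"))
  counts <- sample_arm(model$precision, model$base_composition, depths,
                       derive_seed(seed, "arm"))
  make_cohort_table(counts, design)
}

make_cohort_table <- function(counts, design) {
  nb <- design$n_baseline; np <- design$n_post
  sample_id <- c(sprintf("S%03d_baseline", seq_len(nb)),
                 sprintf("S%03d_post", seq_len(np)))
  md <- data.frame(
    sample_id = sample_id,
    subject = c(sprintf("subj_%03d", seq_len(nb)),
                sprintf("subj_%03d", seq_len(np))),
    timepoint = rep(c("baseline", "post"), c(nb, np)),
    stringsAsFactors = FALSE)
  rownames(counts) <- sample_id
  count_table(counts, md)
}

#' Bundle a ground-truth model
#'
#' @param adjacency binary adjacency (the true network).
#' @param precision conformable positive-definite precision matrix whose
#'   off-diagonal support equals the adjacency.
#' @param base_composition positive vector summing to 1; mean relative
#'   abundances on the latent scale. Default: geometric decay over taxa,
#'   emulating the skewed abundance profile of skin 16S communities.
#' @param topology_name label of the generating topology.
#' @return an object of class `true_model`.
#' @export
true_model <- function(adjacency, precision, base_composition = NULL,
                       topology_name = "custom") {
  p <- nrow(adjacency)
  if (is.null(base_composition)) {
    base_composition <- 0.85^seq_len(p)
    base_composition <- base_composition / sum(base_composition)
  }
  stopifnot(nrow(precision) == p, length(base_composition) == p,
            all(base_composition > 0),
            abs(sum(base_composition) - 1) < 1e-8,
            all(diag(adjacency) == 0))
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(min(ev) > 0)
  supp <- abs(precision) > 1e-12; diag(supp) <- FALSE
  if (!identical(unname(supp * 1L), unname((adjacency != 0) * 1L)))
    stop("off-diagonal support of precision must equal adjacency support")
  structure(list(adjacency = adjacency, precision = precision,
                 base_composition = base_composition,
                 topology_name = topology_name),
            class = "true_model")
}

#' Two-arm synthetic dataset with a denser post-intervention network
#'
#' Generates a baseline and a post arm over the same taxa from two ground
#' truths, the post-arm network being a strict superset of the baseline
#' network (shared ecological core plus intervention-associated links), so
#' the post truth is strictly denser by construction.
#'
#' @param n_taxa number of taxa.
#' @param baseline_density,post_density true edge densities; `post_density`
#'   must exceed `baseline_density`.
#' @param design a `cohort_design`.
#' @param topology topology of the baseline network (extra post edges are
#'   uniform over non-edges).
#' @param seed integer master seed; defaults to the design's seed.
#' @return list with elements `table` (a `count_table` with both arms),
#'   `model_baseline` and `model_post`.
#' @export
two_arm_dataset <- function(n_taxa, baseline_density, post_density, design,
                            topology = "erdos_renyi", seed = design$seed) {
  if (post_density <= baseline_density)
    stop("post_density must be strictly greater than baseline_density")
  adj_b <- generate_true_network(n_taxa, topology,
                                 edge_density = baseline_density,
                                 seed = derive_seed(seed, "arm_baseline"))
  n_possible <- n_taxa * (n_taxa - 1) / 2
  m_extra <- round(post_density * n_possible) - sum(adj_b) / 2
  adj_p <- adj_b
  if (m_extra > 0) {
    free <- which(upper.tri(adj_p) & adj_p == 0, arr.ind = TRUE)
    pick <- with_seed(derive_seed(seed, "arm_post_extra"),
                      sample.int(nrow(free), min(m_extra, nrow(free))))
    adj_p[free[pick, , drop = FALSE]] <- 1L
    adj_p[free[pick, c(2, 1), drop = FALSE]] <- 1L
  }
  model_b <- true_model(adj_b, network_to_precision(adj_b, seed = seed),
                        topology_name = topology)
  model_p <- true_model(adj_p, network_to_precision(adj_p, seed = seed),
                        base_composition = model_b$base_composition,
                        topology_name = paste0(topology, "+densified"))
  n <- design$n_baseline + design$n_post
  depths <- draw_depths(n, design, derive_seed(seed, "depths"))
  cb <- sample_arm(model_b$precision, model_b$base_composition,
                   depths[seq_len(design$n_baseline)],
                   derive_seed(seed, "counts_baseline"))
  cp <- sample_arm(model_p$precision, model_p$base_composition,
                   depths[design$n_baseline + seq_len(design$n_post)],
                   derive_seed(seed, "counts_post"))
  list(table = make_cohort_table(rbind(cb, cp), design),
       model_baseline = model_b, model_post = model_p)
}
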