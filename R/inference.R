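# Sparse association-network inference on CLR-transformed counts:
# per-taxon L1-penalized neighbourhood regressions (Meinshausen-Buhlmann)
# with StARS stability-based selection of the regularization strength.

# Column-standardize to mean 0 and population (1/n) unit variance.
# Zero-variance columns are left at zero and reported.
standardize_cols <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd_n <- sqrt(colMeans(xc^2))
  zv <- sd_n < 1e-12
  sd_n[zv] <- 1
  xs <- sweep(xc, 2, sd_n, "/")
  xs[, zv] <- 0
  attr(xs, "zero_variance") <- zv
  xs
}

#' Build a log-spaced regularization path
#'
#' The path starts at the data-derived `lambda_max` (the smallest penalty at
#' which every neighbourhood regression is empty: the largest absolute
#' pairwise correlation of the standardized CLR columns) and decreases
#' log-linearly to `lambda_min_ratio * lambda_max`.
#'
#' @param clr a `clr_matrix`.
#' @param n_lambda number of penalty values (default 20).
#' @param lambda_min_ratio ratio of the smallest to the largest penalty
#'   (default 0.01).
#' @return an object of class `lambda_path` with fields `lambdas`
#'   (strictly decreasing), `lambda_max`, `n_lambda`, `lambda_min_ratio`.
#' @export
lambda_path <- function(clr, n_lambda = 20, lambda_min_ratio = 0.01) {
  stopifnot(inherits(clr, "clr_matrix"), n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  xs <- standardize_cols(clr$values)
  n <- nrow(xs)
  cc <- crossprod(xs) / n
  lmax <- max(abs(cc[upper.tri(cc)]))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  structure(list(
    lambdas = exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = n_lambda)),
    lambda_max = lmax, n_lambda = n_lambda,
    lambda_min_ratio = lambda_min_ratio), class = "lambda_path")
}

# Coefficient array of the node-wise lasso along a decreasing lambda
# sequence. xs is pre-standardized; returns p x p x L with [i, j, l] the
# coefficient of predictor i in the regression of column j at lambdas[l].
mb_path_coefs <- function(xs, lambdas, tol = 1e-8, maxit = 100000L) {
  n <- nrow(xs); p <- ncol(xs); L <- length(lambdas)
  zv <- attr(xs, "zero_variance") %||% rep(FALSE, p)
  arr <- array(0, dim = c(p, p, L))
  for (j in seq_len(p)) {
    if (zv[j]) next
    pred <- setdiff(which(!zv), j)
    if (length(pred) == 0) next
    y <- xs[, j]
    if (length(pred) == 1) {
      # univariate lasso in closed form: soft-threshold the correlation
      r <- sum(xs[, pred] * y) / n
      b <- sign(r) * pmax(abs(r) - lambdas, 0)
      arr[pred, j, ] <- b
    } else {
      fit <- glmnet::glmnet(xs[, pred, drop = FALSE], y, family = "gaussian",
                            lambda = lambdas, standardize = FALSE,
                            intercept = FALSE, thresh = tol, maxit = maxit)
      beta <- as.matrix(fit$beta)
      if (ncol(beta) < L) {
        # carry the last converged solution forward rather than reporting
        # spuriously empty models for unconverged path tails
        beta <- cbind(beta, beta[, rep(ncol(beta), L - ncol(beta)),
                                 drop = FALSE])
      }
      arr[pred, j, ] <- beta
    }
  }
  arr
}

#' Node-wise lasso neighbourhood fit at a single penalty
#'
#' Regresses each taxon's standardized CLR profile on all other taxa with an
#' L1 penalty `lambda` (coordinate descent, standardized predictors, no
#' intercept). Column `j` of the result holds the lasso coefficients of
#' taxon `j`'s neighbourhood regression; the diagonal is zero. At
#' `lambda >= lambda_max` all coefficients are exactly zero.
#'
#' @param clr a `clr_matrix` with at least 3 samples.
#' @param lambda positive penalty.
#' @return p x p numeric matrix of signed coefficients (predictor in rows,
#'   response in columns), taxon dimnames attached.
#' @export
neighborhood_fit <- function(clr, lambda) {
  stopifnot(inherits(clr, "clr_matrix"), lambda > 0)
  if (nrow(clr$values) < 3) stop("need at least 3 samples")
  xs <- standardize_cols(clr$values)
  zv <- attr(xs, "zero_variance")
  if (any(zv))
    warning("excluding zero-variance taxa from regressions: ",
            paste(colnames(clr$values)[zv], collapse = ", "))
  n <- nrow(xs)
  cc <- crossprod(xs) / n
  lmax <- max(abs(cc[upper.tri(cc)]), lambda)
  # warm-started descent along a short path ending exactly at lambda
  lambdas <- if (lmax > lambda * (1 + 1e-12))
    unique(c(exp(seq(log(lmax), log(lambda), length.out = 10)), lambda))
  else lambda
  arr <- mb_path_coefs(xs, lambdas)
  b <- arr[, , length(lambdas)]
  dimnames(b) <- list(colnames(clr$values), colnames(clr$values))
  b
}

#' StARS: stability-based selection of the regularization strength
#'
#' Fits the neighbourhood lasso path on `n_subsamples` random subsamples
#' (without replacement, fraction `subsample_fraction` of samples) and
#' measures, for each penalty, the edge-selection instability
#' `mean over edges of 2 * theta * (1 - theta)` where `theta` is the edge's
#' selection frequency across subsamples. The instability is monotonized
#' (running maximum as lambda decreases) and the selected penalty is the
#' smallest lambda -- the densest model -- whose monotonized instability
#' stays at or below `stability_threshold`; ties break toward the larger
#' (sparser) lambda.
#'
#' @param clr a `clr_matrix`.
#' @param path a `lambda_path` (default: [lambda_path()] on `clr`).
#' @param n_subsamples number of subsamples (default 50).
#' @param subsample_fraction fraction of samples per subsample (default 0.8).
#' @param stability_threshold instability bound (default 0.05).
#' @param seed integer RNG seed.
#' @param symmetrization edge rule used when counting selections.
#' @return an object of class `stars_result`: the path, per-lambda
#'   instability (raw and monotonized), per-edge selection frequencies
#'   (p x p x n_lambda array), `selected_lambda`, `selected_index`, settings
#'   and a `no_stable_lambda` flag.
#' @export
stars_select <- function(clr, path = NULL, n_subsamples = 50,
                         subsample_fraction = 0.8,
                         stability_threshold = 0.05, seed = 1L,
                         symmetrization = c("OR", "AND")) {
  stopifnot(inherits(clr, "clr_matrix"), n_subsamples >= 2,
            subsample_fraction > 0, subsample_fraction <= 1)
  symmetrization <- match.arg(symmetrization)
  if (is.null(path)) path <- lambda_path(clr)
  lambdas <- path$lambdas
  n <- nrow(clr$values); p <- ncol(clr$values); L <- length(lambdas)
  b <- floor(subsample_fraction * n)
  if (b < 3) stop("subsample size below 3; increase subsample_fraction or n")
  freq <- array(0, dim = c(p, p, L))
  for (s in seq_len(n_subsamples)) {
    idx <- with_seed(derive_seed(seed, "stars_subsample", s),
                     sample.int(n, b))
    xs <- standardize_cols(clr$values[idx, , drop = FALSE])
    arr <- mb_path_coefs(xs, lambdas)
    sel <- arr != 0
    for (l in seq_len(L)) {
      a <- if (symmetrization == "OR") sel[, , l] | t(sel[, , l])
           else sel[, , l] & t(sel[, , l])
      freq[, , l] <- freq[, , l] + a
    }
  }
  theta <- freq / n_subsamples
  ut <- upper.tri(matrix(0, p, p))
  instab <- vapply(seq_len(L), function(l) {
    th <- theta[, , l][ut]
    mean(2 * th * (1 - th))
  }, numeric(1))
  mono <- cummax(instab)
  ok <- which(mono <= stability_threshold)
  flag <- length(ok) == 0
  k <- if (flag) 1L else max(ok)
  structure(list(path = path, instability = instab,
                 instability_monotone = mono, selection_freq = theta,
                 selected_lambda = lambdas[k], selected_index = k,
                 n_subsamples = n_subsamples,
                 subsample_fraction = subsample_fraction,
                 stability_threshold = stability_threshold,
                 symmetrization = symmetrization,
                 no_stable_lambda = flag,
                 taxon_ids = colnames(clr$values)),
            class = "stars_result")
}

#' @export
print.stars_result <- function(x, ...) {
  cat(sprintf(
    "stars_result: %d lambdas, %d subsamples @ %.0f%%; selected lambda %.4g (index %d)\n",
    length(x$path$lambdas), x$n_subsamples, 100 * x$subsample_fraction,
    x$selected_lambda, x$selected_index))
  if (x$no_stable_lambda)
    cat("  warning: no lambda met the stability threshold; sparsest used\n")
  invisible(x)
}

# Construct an mb_network from a coefficient matrix. stability may be NA or
# a p x p matrix of selection frequencies.
coefs_to_network <- function(b, lambda, symmetrization, stability = NULL) {
  p <- nrow(b)
  nodes <- colnames(b)
  nz <- b != 0
  present <- if (symmetrization == "OR") nz | t(nz) else nz & t(nz)
  w <- (b + t(b)) / 2
  idx <- which(upper.tri(present) & present, arr.ind = TRUE)
  edges <- data.frame(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    weight = w[idx],
    stability = if (is.null(stability)) rep(NA_real_, nrow(idx))
                else stability[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, lambda = lambda,
                 symmetrization = symmetrization),
            class = "mb_network")
}

#' Assemble the association network at the selected penalty
#'
#' Refits the neighbourhood lasso on the full data at the StARS-selected
#' penalty and symmetrizes the two directed coefficients per taxon pair:
#' under `OR` an edge is kept when either coefficient is nonzero, under
#' `AND` when both are. The edge weight is the mean of the two coefficients
#' (an absent direction counts as 0) and the edge stability is its StARS
#' selection frequency at the selected penalty.
#'
#' @param clr the `clr_matrix` the StARS result was computed on.
#' @param stars a `stars_result`.
#' @param symmetrization `"OR"` (default) or `"AND"`.
#' @return an object of class `mb_network` with fields `nodes`, `edges`
#'   (data.frame `from`, `to`, `weight`, `stability`), `lambda`,
#'   `symmetrization`.
#' @export
infer_network <- function(clr, stars, symmetrization = c("OR", "AND")) {
  symmetrization <- match.arg(symmetrization)
  stopifnot(inherits(clr, "clr_matrix"), inherits(stars, "stars_result"))
  if (!identical(colnames(clr$values), stars$taxon_ids))
    stop("taxon sets of clr matrix and stars result do not match")
  b <- neighborhood_fit(clr, stars$selected_lambda)
  stab <- stars$selection_freq[, , stars$selected_index]
  coefs_to_network(b, stars$selected_lambda, symmetrization, stab)
}

#' Point-estimate network at a pinned penalty
#'
#' Subsample-free fit: the neighbourhood lasso on the full data at a given
#' penalty, symmetrized as in [infer_network()]. Used for leave-one-out and
#' bootstrap fits where the penalty selected on the full data is reused.
#'
#' @inheritParams infer_network
#' @param lambda positive penalty.
#' @return an `mb_network` (edge stabilities are `NA`).
#' @export
fit_network <- function(clr, lambda, symmetrization = c("OR", "AND")) {
  symmetrization <- match.arg(symmetrization)
  b <- neighborhood_fit(clr, lambda)
  coefs_to_network(b, lambda, symmetrization)
}

#' @export
print.mb_network <- function(x, ...) {
  cat(sprintf("mb_network: %d nodes, %d edges (lambda %.4g, %s rule)\n",
              length(x$nodes), nrow(x$edges), x$lambda, x$symmetrization))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param x an `mb_network` or `mni_network`.
#' @param ... unused.
#' @return an undirected simple `igraph` graph; `mb_network` edges carry
#'   `weight` and `stability` attributes, `mni_network` edges carry `status`
#'   and `delta_weight`.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.mb_network <- function(x, ...) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x$nodes), name = x$nodes)
  if (nrow(x$edges) > 0) {
    g <- igraph::add_edges(g, rbind(x$edges$from, x$edges$to),
                           weight = x$edges$weight,
                           stability = x$edges$stability)
  }
  g
}
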