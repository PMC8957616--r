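# Connectivity metrics, targeted-attack fragility simulation and the AUC
# robustness score. All metrics are computed on the unweighted topology.

# Coerce any supported network representation to an unweighted igraph.
as_unweighted_igraph <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  for (a in igraph::edge_attr_names(g)) g <- igraph::delete_edge_attr(g, a)
  igraph::simplify(g)
}

#' Basic connectivity metrics
#'
#' Node count (isolated nodes included), undirected edge count and mean
#' degree `2E/N`.
#'
#' @param net an `mb_network`, `mni_network` or `igraph` graph.
#' @return named list with `node_number`, `edge_number`, `mean_degree` and a
#'   logical `empty` flag (all-zero result for an empty node set).
#' @export
basic_metrics <- function(net) {
  g <- as_unweighted_igraph(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n == 0)
    return(list(node_number = 0, edge_number = 0, mean_degree = 0,
                empty = TRUE))
  list(node_number = n, edge_number = e, mean_degree = 2 * e / n,
       empty = FALSE)
}

#' Natural connectivity of a graph
#'
#' `ln((1/n) * sum_i exp(lambda_i))` over the eigenvalues `lambda_i` of the
#' unweighted symmetric adjacency matrix: the log of the average weighted
#' count of closed walks, a spectral robustness measure that strictly
#' increases whenever an edge is added. Zero for an empty graph; defined as
#' 0 for an empty node set.
#'
#' @param net an `mb_network`, `mni_network` or `igraph` graph.
#' @return a single real value.
#' @export
natural_connectivity <- function(net) {
  g <- as_unweighted_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  if (igraph::ecount(g) == 0) return(0)
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(ev)
}

#' Targeted-attack fragility curve
#'
#' Removes nodes one at a time in decreasing order of a centrality key
#' computed once on the intact graph (static attack), recording after each
#' removal the size of the largest connected component and the natural
#' connectivity of the remaining graph. The default ordering ranks by
#' betweenness centrality with node degree as secondary key; remaining ties
#' break lexicographically on node id.
#'
#' @param net an `mb_network`, `mni_network` or `igraph` graph with at least
#'   2 nodes.
#' @param ordering attack ordering: `"betweenness_then_degree"` (default),
#'   `"betweenness"` or `"degree"` (secondary key betweenness).
#' @param recompute recompute the ordering key on the shrinking graph after
#'   every removal (adaptive attack) instead of the default static ranking.
#' @return an object of class `fragility_curve`: data.frame `steps` with
#'   columns `step`, `node_removed`, `fraction_removed`, `lcc_size`,
#'   `natural_connectivity` (step 0 describes the intact graph), plus the
#'   `removal_order`.
#' @export
fragility_curve <- function(net,
                            ordering = c("betweenness_then_degree",
                                         "betweenness", "degree"),
                            recompute = FALSE) {
  ordering <- match.arg(ordering)
  g0 <- as_unweighted_igraph(net)
  n <- igraph::vcount(g0)
  if (n < 2) stop("fragility curve requires at least 2 nodes")
  rank_nodes <- function(g) {
    bt <- igraph::betweenness(g, directed = FALSE, weights = NA)
    dg <- igraph::degree(g)
    key <- switch(ordering,
                  betweenness = order(-bt, igraph::V(g)$name),
                  degree = order(-dg, -bt, igraph::V(g)$name),
                  betweenness_then_degree = order(-bt, -dg,
                                                  igraph::V(g)$name))
    igraph::V(g)$name[key]
  }
  lcc <- function(g) {
    if (igraph::vcount(g) == 0) return(0L)
    max(igraph::components(g)$csize)
  }
  removal_order <- character(n)
  steps <- data.frame(step = 0L, node_removed = NA_character_,
                      fraction_removed = 0, lcc_size = lcc(g0),
                      natural_connectivity = natural_connectivity(g0),
                      stringsAsFactors = FALSE)
  g <- g0
  static_order <- if (recompute) NULL else rank_nodes(g0)
  for (k in seq_len(n)) {
    victim <- if (recompute) rank_nodes(g)[1] else static_order[k]
    removal_order[k] <- victim
    g <- igraph::delete_vertices(g, victim)
    steps <- rbind(steps, data.frame(
      step = k, node_removed = victim, fraction_removed = k / n,
      lcc_size = lcc(g),
      natural_connectivity = if (igraph::vcount(g) > 0)
        natural_connectivity(g) else 0,
      stringsAsFactors = FALSE))
  }
  structure(list(steps = steps, removal_order = removal_order,
                 ordering = ordering, recompute = recompute, n_nodes = n),
            class = "fragility_curve")
}

#' Robustness score: area under the fragility curve
#'
#' Trapezoidal area under the attack-response trajectory against the
#' fraction of nodes removed, with the response normalized by its value on
#' the intact graph so the score lies in [0, 1] for non-increasing curves.
#' Larger values mean the network degrades more slowly under targeted
#' attack.
#'
#' @param curve a `fragility_curve`.
#' @param response `"natural_connectivity"` (default) or `"lcc_fraction"`
#'   (largest-component size).
#' @return a single real value; 0 with attribute `undefined = TRUE` when the
#'   intact-graph response is 0 and the curve cannot be normalized.
#' @export
robustness_auc <- function(curve, response = c("natural_connectivity",
                                               "lcc_fraction")) {
  response <- match.arg(response)
  stopifnot(inherits(curve, "fragility_curve"), nrow(curve$steps) >= 2)
  y <- switch(response,
              natural_connectivity = curve$steps$natural_connectivity,
              lcc_fraction = curve$steps$lcc_size)
  if (y[1] == 0) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  trapz(curve$steps$fraction_removed, y / y[1])
}

#' Full metric set of a network
#'
#' Bundles the basic connectivity metrics with the targeted-attack
#' robustness AUC, its complement (`fragility = 1 - robustness`, so a more
#' robust network is less fragile) and the intact-graph natural
#' connectivity.
#'
#' @param net an `mb_network`, `mni_network` or `igraph` graph.
#' @param ordering,response passed to [fragility_curve()] and
#'   [robustness_auc()].
#' @return an object of class `metric_set`: a named list with fields
#'   `mean_degree`, `edge_number`, `node_number`, `robustness`, `fragility`,
#'   `natural_connectivity_initial` and the `empty` flag.
#' @export
metric_set <- function(net, ordering = "betweenness_then_degree",
                       response = "natural_connectivity") {
  bm <- basic_metrics(net)
  nc0 <- natural_connectivity(net)
  if (bm$node_number < 2 || bm$edge_number == 0) {
    # degenerate graphs cannot be attacked or normalized: flagged zeros
    rob <- 0
  } else {
    rob <- as.numeric(robustness_auc(
      fragility_curve(net, ordering = ordering), response = response))
  }
  structure(list(mean_degree = bm$mean_degree,
                 edge_number = bm$edge_number,
                 node_number = bm$node_number,
                 robustness = rob, fragility = 1 - rob,
                 natural_connectivity_initial = nc0,
                 empty = bm$empty),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "metric_set: N=%d, E=%d, mean degree %.3f, robustness %.3f, fragility %.3f, NC0 %.3f\n",
    x$node_number, x$edge_number, x$mean_degree, x$robustness, x$fragility,
    x$natural_connectivity_initial))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(mean_degree = x$mean_degree, edge_number = x$edge_number,
             node_number = x$node_number, robustness = x$robustness,
             fragility = x$fragility,
             natural_connectivity_initial = x$natural_connectivity_initial)
}
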