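# Population networks (MNP), leave-one-out single-sample networks (MNI)
# and bootstrap network ensembles.

#' Configuration of the network pipeline
#'
#' Collects every tunable of the filter -> CLR -> inference -> comparison
#' pipeline with defaults matching the study protocol where one is stated
#' (0.01% relative abundance, 37% prevalence, 50,000-read rarefaction depth,
#' 80% resampling, 20-value path to 0.01 of lambda_max, StARS threshold
#' 0.05) and canonical choices elsewhere. All fields are validated here,
#' before any stage runs.
#'
#' @param rel_abund_min,prevalence_min,abund_stat taxon filter settings, see
#'   [filter_taxa()].
#' @param rarefy logical; rarefy before the CLR transform (default `FALSE`:
#'   rarefaction is aimed at diversity analyses, the CLR works on raw
#'   counts).
#' @param rarefy_depth reads per sample when `rarefy = TRUE`.
#' @param pseudocount CLR pseudocount.
#' @param n_lambda,lambda_min_ratio regularization path, see [lambda_path()].
#' @param n_subsamples,subsample_fraction,stars_threshold StARS settings,
#'   see [stars_select()].
#' @param symmetrization `"OR"` or `"AND"` edge rule.
#' @param mni_lambda `"pinned"` (leave-one-out fits reuse the full-data
#'   selected penalty, so MNI differences reflect the removed sample) or
#'   `"free"` (each parent re-runs StARS).
#' @param ensemble_lambda same choice for bootstrap replicates.
#' @param ordering,response targeted-attack settings, see
#'   [fragility_curve()] and [robustness_auc()].
#' @param seed integer master seed.
#' @return a validated list of class `mnp_config`.
#' @export
mnp_config <- function(rel_abund_min = 1e-4, prevalence_min = 0.37,
                       abund_stat = "mean", rarefy = FALSE,
                       rarefy_depth = 50000, pseudocount = 1,
                       n_lambda = 20, lambda_min_ratio = 0.01,
                       n_subsamples = 50, subsample_fraction = 0.8,
                       stars_threshold = 0.05,
                       symmetrization = c("OR", "AND"),
                       mni_lambda = c("pinned", "free"),
                       ensemble_lambda = c("pinned", "free"),
                       ordering = "betweenness_then_degree",
                       response = "natural_connectivity", seed = 1L) {
  symmetrization <- match.arg(symmetrization)
  mni_lambda <- match.arg(mni_lambda)
  ensemble_lambda <- match.arg(ensemble_lambda)
  stopifnot(rel_abund_min >= 0, rel_abund_min <= 1,
            prevalence_min >= 0, prevalence_min <= 1,
            abund_stat %in% c("mean", "max"),
            is.logical(rarefy), rarefy_depth > 0, pseudocount > 0,
            n_lambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            n_subsamples >= 2, subsample_fraction > 0,
            subsample_fraction <= 1,
            stars_threshold > 0, stars_threshold <= 0.5,
            ordering %in% c("betweenness_then_degree", "betweenness",
                            "degree"),
            response %in% c("natural_connectivity", "lcc_fraction"))
  structure(list(rel_abund_min = rel_abund_min,
                 prevalence_min = prevalence_min, abund_stat = abund_stat,
                 rarefy = rarefy, rarefy_depth = rarefy_depth,
                 pseudocount = pseudocount, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 n_subsamples = n_subsamples,
                 subsample_fraction = subsample_fraction,
                 stars_threshold = stars_threshold,
                 symmetrization = symmetrization, mni_lambda = mni_lambda,
                 ensemble_lambda = ensemble_lambda, ordering = ordering,
                 response = response, seed = as.integer(seed)),
            class = "mnp_config")
}

# filter -> (rarefy) -> clr, shared by MNP/MNI/bootstrap entry points
prepare_clr <- function(table, config) {
  ft <- filter_taxa(table, config$rel_abund_min, config$prevalence_min,
                    config$abund_stat)
  if (config$rarefy)
    ft <- rarefy(ft, depth = config$rarefy_depth,
                 seed = derive_seed(config$seed, "rarefy"))
  list(filtered = ft, clr = clr_transform(ft, config$pseudocount))
}

#' Microbiome network of the population (MNP)
#'
#' Full inference pipeline on all samples of a table: taxon filtering,
#' optional rarefaction, CLR transform, StARS-selected neighbourhood lasso.
#' Deterministic given the config seed.
#'
#' @param table a `count_table` with at least 4 samples after filtering.
#' @param config an `mnp_config`.
#' @return an `mb_network`; the `stars_result`, the CLR matrix and the
#'   filtered table are attached as fields `stars`, `clr` and `filtered` for
#'   reuse by downstream leave-one-out and bootstrap fits.
#' @export
compute_mnp <- function(table, config = mnp_config()) {
  stopifnot(inherits(table, "count_table"))
  prep <- prepare_clr(table, config)
  if (nrow(prep$clr$values) < 4)
    stop("need at least 4 samples after filtering")
  path <- lambda_path(prep$clr, config$n_lambda, config$lambda_min_ratio)
  stars <- stars_select(prep$clr, path, config$n_subsamples,
                        config$subsample_fraction, config$stars_threshold,
                        seed = derive_seed(config$seed, "stars"),
                        symmetrization = config$symmetrization)
  net <- infer_network(prep$clr, stars, config$symmetrization)
  net$stars <- stars
  net$clr <- prep$clr
  net$filtered <- prep$filtered
  net$config <- config
  net
}

#' Microbiome network of an individual (MNI)
#'
#' Subtracts the population network refitted with one sample left out from
#' the population network of the whole sample set, yielding a network
#' specific to that sample: edges of MNP(all) absent from MNP(all minus the
#' sample) are `gained`, edges only in the leave-one-out network are `lost`,
#' and shared edges carry the signed weight difference. By default both
#' parents are subsample-free point fits at the full-data StARS-selected
#' penalty (pinned mode), so the difference reflects the removed sample
#' rather than re-selection noise.
#'
#' @param table a `count_table`.
#' @param sample_id sample to leave out (must be present; at least 4 samples
#'   must remain).
#' @param config an `mnp_config`.
#' @param mnp optional precomputed [compute_mnp()] result for `table` under
#'   the same config, to avoid refitting the full-data parent.
#' @return an object of class `mni_network` with fields `sample_id`,
#'   `nodes` (union of both parents' node sets), `gained`, `lost` (edge
#'   data.frames with the parent weight), `changed` (shared edges with
#'   `weight_all`, `weight_minus`, `delta`), and the parent penalties.
#' @export
compute_mni <- function(table, sample_id, config = mnp_config(),
                        mnp = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (!sample_id %in% rownames(table$counts))
    stop("sample_id not present: ", sample_id)
  if (nrow(table$counts) - 1 < 4)
    stop("need at least 4 samples after removal")
  if (is.null(mnp)) mnp <- compute_mnp(table, config)
  keep <- setdiff(rownames(mnp$filtered$counts), sample_id)
  sub <- subset_samples(mnp$filtered, keep)
  clr_minus <- clr_transform(sub, config$pseudocount)
  if (config$mni_lambda == "pinned") {
    net_all <- mnp
    net_minus <- fit_network(clr_minus, mnp$lambda, config$symmetrization)
  } else {
    path <- lambda_path(clr_minus, config$n_lambda, config$lambda_min_ratio)
    stars_minus <- stars_select(clr_minus, path, config$n_subsamples,
                                config$subsample_fraction,
                                config$stars_threshold,
                                seed = derive_seed(config$seed, "stars_loo"),
                                symmetrization = config$symmetrization)
    net_all <- mnp
    net_minus <- infer_network(clr_minus, stars_minus,
                               config$symmetrization)
  }
  subtract_networks(net_all, net_minus, sample_id)
}

edge_keys <- function(edges) paste(edges$from, edges$to, sep = "\r")

# net_all - net_minus as a signed difference object
subtract_networks <- function(net_all, net_minus, sample_id) {
  ea <- net_all$edges; em <- net_minus$edges
  ka <- edge_keys(ea); km <- edge_keys(em)
  gained <- ea[!(ka %in% km), c("from", "to", "weight"), drop = FALSE]
  lost <- em[!(km %in% ka), c("from", "to", "weight"), drop = FALSE]
  shared <- ea[ka %in% km, c("from", "to", "weight"), drop = FALSE]
  names(shared)[3] <- "weight_all"
  shared$weight_minus <- em$weight[match(edge_keys(shared), km)]
  shared$delta <- shared$weight_all - shared$weight_minus
  rownames(gained) <- rownames(lost) <- rownames(shared) <- NULL
  structure(list(sample_id = sample_id,
                 nodes = union(net_all$nodes, net_minus$nodes),
                 gained = gained, lost = lost, changed = shared,
                 lambda_all = net_all$lambda,
                 lambda_minus = net_minus$lambda),
            class = "mni_network")
}

#' Patch a leave-one-out network with an MNI
#'
#' Reconstruction identity of the subtraction: adding the gained edges,
#' removing the lost edges and applying the signed weight deltas to
#' MNP(all minus sample) reproduces MNP(all) exactly.
#'
#' @param net_minus the leave-one-out `mb_network`.
#' @param mni the `mni_network` of the removed sample.
#' @return an `mb_network` equal to the full-data parent (stabilities are
#'   not reconstructed).
#' @export
mni_patch <- function(net_minus, mni) {
  stopifnot(inherits(net_minus, "mb_network"), inherits(mni, "mni_network"))
  em <- net_minus$edges
  em <- em[!(edge_keys(em) %in% edge_keys(mni$lost)), , drop = FALSE]
  kc <- edge_keys(mni$changed)
  hit <- match(edge_keys(em), kc)
  em$weight[!is.na(hit)] <- em$weight[!is.na(hit)] +
    mni$changed$delta[hit[!is.na(hit)]]
  if (nrow(mni$gained) > 0) {
    g <- mni$gained
    g$stability <- NA_real_
    em <- rbind(em[, c("from", "to", "weight", "stability")], g)
  }
  em <- em[order(em$from, em$to), , drop = FALSE]
  rownames(em) <- NULL
  structure(list(nodes = mni$nodes, edges = em, lambda = mni$lambda_all,
                 symmetrization = net_minus$symmetrization),
            class = "mb_network")
}

#' @export
print.mni_network <- function(x, ...) {
  cat(sprintf(
    "mni_network [%s]: %d gained, %d lost, %d shared edges (%d with weight change)\n",
    x$sample_id, nrow(x$gained), nrow(x$lost), nrow(x$changed),
    sum(abs(x$changed$delta) > 1e-12)))
  invisible(x)
}

#' @export
as_igraph.mni_network <- function(x, include_changed = TRUE, ...) {
  gained <- x$gained; lost <- x$lost
  changed <- if (include_changed)
    x$changed[abs(x$changed$delta) > 1e-12, , drop = FALSE]
  else x$changed[0, , drop = FALSE]
  ed <- rbind(
    if (nrow(gained)) data.frame(from = gained$from, to = gained$to,
                                 status = "gained",
                                 delta_weight = gained$weight),
    if (nrow(lost)) data.frame(from = lost$from, to = lost$to,
                               status = "lost",
                               delta_weight = -lost$weight),
    if (nrow(changed)) data.frame(from = changed$from, to = changed$to,
                                  status = "changed",
                                  delta_weight = changed$delta))
  nodes <- if (is.null(ed)) character(0) else
    sort(unique(c(ed$from, ed$to)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(ed) && nrow(ed) > 0)
    g <- igraph::add_edges(g, rbind(ed$from, ed$to), status = ed$status,
                           delta_weight = ed$delta_weight)
  g
}

#' Summary metrics of an MNI
#'
#' Computes the [metric_set()] of the MNI's difference network. The default
#' support is the full signed difference: gained edges, lost edges and
#' shared edges whose weight changed -- every edge affected by the
#' subtraction, which is what subtracting two weighted networks leaves
#' behind. Alternative supports restrict to the presence changes only
#' (`"symmetric_difference"`) or to the gained edges (`"gained"`). Nodes
#' are those incident to at least one supporting edge; topological metrics
#' are unweighted.
#'
#' @param mni an `mni_network`.
#' @param ordering,response passed to [metric_set()].
#' @param support which edges form the MNI's metric graph.
#' @return a `metric_set`.
#' @export
mni_metrics <- function(mni, ordering = "betweenness_then_degree",
                        response = "natural_connectivity",
                        support = c("signed", "symmetric_difference",
                                    "gained")) {
  support <- match.arg(support)
  ed <- switch(support,
    signed = NULL,  # handled by as_igraph with changed edges included
    symmetric_difference = rbind(mni$gained[, c("from", "to")],
                                 mni$lost[, c("from", "to")]),
    gained = mni$gained[, c("from", "to")])
  g <- if (support == "signed") {
    as_igraph(mni, include_changed = TRUE)
  } else {
    nodes <- sort(unique(c(ed$from, ed$to)))
    gg <- igraph::make_empty_graph(0, directed = FALSE)
    gg <- igraph::add_vertices(gg, length(nodes), name = nodes)
    if (nrow(ed) > 0) gg <- igraph::add_edges(gg, rbind(ed$from, ed$to))
    gg
  }
  metric_set(g, ordering = ordering, response = response)
}

#' Bootstrap ensemble of population networks
#'
#' Repeatedly re-infers the population network on random subsets of samples
#' drawn without replacement at `subsample_fraction` (the "resampled at the
#' 80% level" scheme) and records each replicate network's metric set.
#' Replicates are seeded by draw index against the alphabetically sorted
#' sample ids, so the ensemble does not depend on the row order of the
#' input. In pinned mode (default) replicates are point fits at the
#' full-data selected penalty.
#'
#' @param table a `count_table`.
#' @param n_networks number of replicate networks (default 1000).
#' @param subsample_fraction fraction of samples per replicate (default 0.8).
#' @param config an `mnp_config`.
#' @param seed integer seed (default: the config seed).
#' @param mnp optional precomputed full-data [compute_mnp()] result.
#' @return an object of class `bootstrap_ensemble`: data.frame `metrics`
#'   (one row per replicate: `replicate`, `mean_degree`, `edge_number`,
#'   `node_number`, `robustness`, `fragility`,
#'   `natural_connectivity_initial`) plus the settings.
#' @export
bootstrap_mnp <- function(table, n_networks = 1000,
                          subsample_fraction = 0.8, config = mnp_config(),
                          seed = config$seed, mnp = NULL) {
  stopifnot(inherits(table, "count_table"), n_networks >= 1)
  if (is.null(mnp)) mnp <- compute_mnp(table, config)
  ids <- sort(rownames(mnp$filtered$counts))
  n <- length(ids)
  b <- floor(subsample_fraction * n)
  if (b < 4) stop("subsample size below 4; increase subsample_fraction or n")
  rows <- vector("list", n_networks)
  for (r in seq_len(n_networks)) {
    idx <- with_seed(derive_seed(seed, "bootstrap", r), sample.int(n, b))
    sub <- subset_samples(mnp$filtered, ids[idx])
    clr_sub <- clr_transform(sub, config$pseudocount)
    net <- if (config$ensemble_lambda == "pinned") {
      fit_network(clr_sub, mnp$lambda, config$symmetrization)
    } else {
      path <- lambda_path(clr_sub, config$n_lambda, config$lambda_min_ratio)
      st <- stars_select(clr_sub, path, config$n_subsamples,
                         config$subsample_fraction, config$stars_threshold,
                         seed = derive_seed(seed, "bootstrap_stars", r),
                         symmetrization = config$symmetrization)
      infer_network(clr_sub, st, config$symmetrization)
    }
    ms <- metric_set(net, ordering = config$ordering,
                     response = config$response)
    rows[[r]] <- cbind(replicate = r, as.data.frame(ms))
  }
  structure(list(metrics = do.call(rbind, rows), n_networks = n_networks,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap_ensemble: %d networks @ %.0f%% resampling\n",
              x$n_networks, 100 * x$subsample_fraction))
  print(summary(x$metrics[, c("mean_degree", "edge_number", "robustness")]))
  invisible(x)
}
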