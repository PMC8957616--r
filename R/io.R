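# Reading and writing the package's table, network and result formats:
# TSV count tables (+ metadata), BIOM-style JSON, GraphML and edge-list
# networks, StARS results as JSON, metric tables as CSV.

write_header_lines <- function(path, lines) {
  if (length(lines) > 0)
    writeLines(paste0("# ", lines), path)
}

#' Write a count table to TSV
#'
#' Samples as rows, taxa as columns, first column `sample_id`. Filter and
#' other provenance settings are echoed as `#` comment headers. Metadata
#' (sample id, subject, timepoint) goes to a companion TSV.
#'
#' @param table a `count_table`.
#' @param path output TSV path.
#' @param metadata_path optional metadata TSV path (default:
#'   `<path>` with a `.metadata.tsv` suffix).
#' @param header_lines extra provenance lines for the `#` header.
#' @return invisibly, the paths written.
#' @export
write_count_table <- function(table, path,
                              metadata_path = paste0(path, ".metadata.tsv"),
                              header_lines = character(0)) {
  stopifnot(inherits(table, "count_table"))
  prov <- character(0)
  if (!is.null(table$provenance$filter)) {
    f <- table$provenance$filter
    prov <- c(prov, sprintf("filter: rel_abund>=%g(%s), prevalence>=%g",
                            f$rel_abund_min, f$abund_stat, f$prevalence_min))
  }
  if (!is.null(table$provenance$rarefy))
    prov <- c(prov, sprintf("rarefy: depth=%d seed=%d",
                            table$provenance$rarefy$depth,
                            table$provenance$rarefy$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(header_lines, prov)), con)
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Read a count table
#'
#' TSV: first column `sample_id`, remaining columns taxon counts, `#` lines
#' ignored. BIOM-style JSON is parsed through the biomformat package.
#' Validation rejects duplicate ids and negative or non-integer counts,
#' naming the offending cell.
#'
#' @param path count-table file.
#' @param format `"tsv"` or `"biom_json"`.
#' @param metadata_path optional metadata TSV (columns `sample_id`,
#'   `subject`, `timepoint`) which must cover every sample; when absent a
#'   placeholder single-group metadata is attached.
#' @return a validated `count_table`.
#' @export
read_count_table <- function(path, format = c("tsv", "biom_json"),
                             metadata_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("cannot parse '", path, "': ",
                               conditionMessage(e)))
    if (ncol(df) < 2 || names(df)[1] != "sample_id")
      stop("malformed count table '", path,
           "': first column must be 'sample_id'")
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df$sample_id
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for biom_json input")
    b <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(b)))
  }
  storage.mode(counts) <- "double"
  md <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  }
  count_table(counts, md)
}

#' Write a count table as BIOM-style JSON
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_count_table_biom <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for biom_json output")
  b <- biomformat::make_biom(t(table$counts))
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Write a network to GraphML or edge-list TSV
#'
#' GraphML carries the taxon id as node attribute and `weight`/`stability`
#' (or `status`/`delta_weight` for an MNI) as edge attributes. The edge list
#' is a sorted (`from < to`) TSV. Edge ordering is stable, so identical
#' networks serialize identically.
#'
#' @param net an `mb_network` or `mni_network`.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @param config_hash optional provenance hash stored as a graph attribute
#'   (GraphML) or header line (TSV).
#' @return invisibly, the path.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist_tsv"),
                          config_hash = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    if (!is.null(config_hash))
      g <- igraph::set_graph_attr(g, "config_hash", config_hash)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  ed <- if (inherits(net, "mni_network")) {
    g <- as_igraph(net)
    data.frame(igraph::as_data_frame(g, what = "edges"))
  } else {
    net$edges
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config: ", config_hash), con)
  utils::write.table(ed[order(ed$from, ed$to), , drop = FALSE], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path GraphML file written by [write_network()].
#' @return an `mb_network` (weights and stabilities restored; networks
#'   written from an `mni_network` come back with `status` and
#'   `delta_weight` edge columns instead).
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::V(g)$name
  if ("status" %in% names(ed)) {
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    rownames(ed) <- NULL
    return(structure(list(nodes = nodes, edges = ed), class = "mni_edges"))
  }
  if (nrow(ed) > 0) {
    swap <- ed$from > ed$to
    tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  }
  if (!"weight" %in% names(ed)) ed$weight <- numeric(nrow(ed))
  if (!"stability" %in% names(ed)) ed$stability <- rep(NA_real_, nrow(ed))
  rownames(ed) <- NULL
  structure(list(nodes = nodes,
                 edges = ed[, c("from", "to", "weight", "stability"),
                            drop = FALSE],
                 lambda = NA_real_, symmetrization = NA_character_),
            class = "mb_network")
}

#' Write a StARS result as JSON
#'
#' Serializes the path, per-lambda instability (raw and monotonized), the
#' selected penalty and the settings (selection frequencies are omitted for
#' size).
#'
#' @param stars a `stars_result`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_stars <- function(stars, path) {
  stopifnot(inherits(stars, "stars_result"))
  jsonlite::write_json(list(
    lambdas = stars$path$lambdas,
    lambda_max = stars$path$lambda_max,
    lambda_min_ratio = stars$path$lambda_min_ratio,
    instability = stars$instability,
    instability_monotone = stars$instability_monotone,
    selected_lambda = stars$selected_lambda,
    selected_index = stars$selected_index,
    n_subsamples = stars$n_subsamples,
    subsample_fraction = stars$subsample_fraction,
    stability_threshold = stars$stability_threshold,
    no_stable_lambda = stars$no_stable_lambda),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a fragility curve as CSV
#'
#' @param curve a `fragility_curve`.
#' @param path output CSV path.
#' @param config_hash optional provenance header.
#' @return invisibly, the path.
#' @export
write_fragility_curve <- function(curve, path, config_hash = NULL) {
  stopifnot(inherits(curve, "fragility_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config: ", config_hash), con)
  utils::write.csv(curve$steps, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write bootstrap-ensemble metrics as long-format CSV
#'
#' Columns `replicate`, `metric`, `value`.
#'
#' @param ensemble a `bootstrap_ensemble`.
#' @param path output CSV path.
#' @param config_hash optional provenance header.
#' @return invisibly, the path.
#' @export
write_ensemble <- function(ensemble, path, config_hash = NULL) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  m <- ensemble$metrics
  metric_cols <- setdiff(names(m), "replicate")
  long <- do.call(rbind, lapply(metric_cols, function(mc)
    data.frame(replicate = m$replicate, metric = mc, value = m[[mc]])))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config: ", config_hash), con)
  utils::write.csv(long[order(long$replicate, long$metric), ], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
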