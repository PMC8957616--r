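# Pipeline driver: runs the full analysis reproducibly and records a
# manifest of configuration, stages and output checksums.

#' Hash a pipeline configuration
#'
#' MD5 of the canonical JSON serialization of an [mnp_config()]; embedded in
#' every output's provenance so results can be traced to their settings.
#'
#' @param config an `mnp_config`.
#' @return a character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full network-analysis pipeline
#'
#' Executes, in order: read and validate the count table; taxon filtering
#' (and optional rarefaction) with the CLR transform; population network
#' inference (StARS-selected neighbourhood lasso); leave-one-out MNI
#' computation for every sample; network metrics (metric set and fragility
#' curve of the MNP, per-sample MNI metrics); and, when the metadata has
#' two timepoints, the between-timepoint comparison of MNI metrics. All
#' outputs carry the config hash; a JSON manifest lists every stage with
#' the checksums of its outputs. A failure in any stage aborts the run with
#' the stage named.
#'
#' @param table_path count-table TSV (see [read_count_table()]).
#' @param out_dir output directory (created if needed).
#' @param config an `mnp_config`.
#' @param metadata_path optional metadata TSV.
#' @param n_resamples resamples for the comparison stage.
#' @return invisibly, the manifest (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(table_path, out_dir, config = mnp_config(),
                         metadata_path = NULL, n_resamples = 10000) {
  stopifnot(inherits(config, "mnp_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stages <- list()
  outputs_of <- function(files) {
    lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages[[length(stages) + 1]] <<- list(
      name = name, outputs = outputs_of(res$files %||% character(0)))
    res$value
  }

  table <- run_stage("read", function() {
    list(value = read_count_table(table_path, "tsv", metadata_path))
  })

  mnp <- NULL
  filtered <- run_stage("preprocess", function() {
    prep <- prepare_clr(table, config)
    f <- file.path(out_dir, "filtered_counts.tsv")
    write_count_table(prep$filtered, f,
                      header_lines = paste0("config: ", hash))
    list(value = prep$filtered,
         files = c(f, paste0(f, ".metadata.tsv")))
  })

  mnp <- run_stage("mnp", function() {
    net <- compute_mnp(table, config)
    f1 <- file.path(out_dir, "mnp.graphml")
    f2 <- file.path(out_dir, "mnp_edges.tsv")
    f3 <- file.path(out_dir, "stars.json")
    write_network(net, f1, "graphml", config_hash = hash)
    write_network(net, f2, "edgelist_tsv", config_hash = hash)
    write_stars(net$stars, f3)
    list(value = net, files = c(f1, f2, f3))
  })

  two_arms <- length(unique(table$metadata$timepoint)) == 2
  groups <- run_stage("mni", function() {
    grp <- compute_group_networks(table, config, by_timepoint = two_arms)
    files <- character(0)
    for (tp in names(grp)) {
      d <- file.path(out_dir, "mni", tp)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, paste0("mnp_", tp, ".graphml"))
      write_network(grp[[tp]]$mnp, f, "graphml", config_hash = hash)
      files <- c(files, f)
      for (s in names(grp[[tp]]$mnis)) {
        f <- file.path(d, paste0(s, ".graphml"))
        write_network(grp[[tp]]$mnis[[s]], f, "graphml",
                      config_hash = hash)
        files <- c(files, f)
      }
    }
    list(value = grp, files = files)
  })

  metrics <- run_stage("metrics", function() {
    ms <- metric_set(mnp, ordering = config$ordering,
                     response = config$response)
    fc <- fragility_curve(mnp, ordering = config$ordering)
    f1 <- file.path(out_dir, "mnp_metrics.json")
    f2 <- file.path(out_dir, "mnp_fragility.csv")
    f3 <- file.path(out_dir, "mni_metrics.csv")
    jsonlite::write_json(c(list(config_hash = hash),
                           unclass(ms)[!vapply(unclass(ms), is.logical,
                                               logical(1))]),
                         f1, auto_unbox = TRUE, digits = NA)
    write_fragility_curve(fc, f2, config_hash = hash)
    per <- mni_metric_table(groups, config)
    con <- file(f3, "w")
    writeLines(paste0("# config: ", hash), con)
    utils::write.csv(per, con, row.names = FALSE, quote = FALSE)
    close(con)
    list(value = list(mnp = ms, per_sample = per),
         files = c(f1, f2, f3))
  })

  comparison <- NULL
  if (two_arms) {
    comparison <- run_stage("compare", function() {
      cmp <- compare_mni_metrics(table, config, n_resamples = n_resamples,
                                 groups = groups)
      f <- file.path(out_dir, "comparison.csv")
      rows <- do.call(rbind, lapply(names(cmp$tests), function(m) {
        tst <- cmp$tests[[m]]
        data.frame(metric = m, statistic = tst$statistic,
                   p_value = tst$p_value, method = tst$method,
                   n_resamples = tst$n_resamples)
      }))
      con <- file(f, "w")
      writeLines(paste0("# config: ", hash), con)
      utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
      close(con)
      list(value = cmp, files = f)
    })
  }

  stages[[length(stages) + 1]] <- list(
    name = "manifest",
    outputs = list(list(file = "manifest.json", md5 = NA)))
  manifest <- list(
    config_hash = hash,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("mnpnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
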