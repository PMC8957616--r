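# Count-table container and compositional preprocessing:
# taxon filtering, rarefaction and the centered log-ratio transform.

#' Construct a count table of samples by taxa
#'
#' The basic container of the package: an integer matrix of read counts with
#' samples as rows and species-collapsed taxa as columns, plus per-sample
#' metadata (subject identifier and timepoint label). Mirrors a QIIME2-style
#' species-collapsed ASV table.
#'
#' @param counts numeric matrix, samples x taxa, non-negative integers. Row
#'   names are sample ids, column names taxon ids (supplied via `sample_ids`
#'   and `taxon_ids` if missing).
#' @param metadata data.frame with columns `sample_id`, `subject`,
#'   `timepoint`, covering every sample. If `NULL`, a single-group placeholder
#'   is created.
#' @param sample_ids,taxon_ids optional character vectors overriding dimnames.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, metadata = NULL, sample_ids = NULL,
                        taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(taxon_ids)) colnames(counts) <- taxon_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sample_%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("taxon_%03d", seq_len(ncol(counts)))
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(counts),
                           subject = rownames(counts),
                           timepoint = "all",
                           stringsAsFactors = FALSE)
  }
  obj <- structure(list(counts = counts, metadata = metadata,
                        provenance = list()),
                   class = "count_table")
  validate_count_table(obj)
}

validate_count_table <- function(x) {
  counts <- x$counts
  md <- x$metadata
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: sample '%s', taxon '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  need <- c("sample_id", "subject", "timepoint")
  if (!all(need %in% names(md)))
    stop("metadata must have columns sample_id, subject, timepoint")
  missing <- setdiff(rownames(counts), md$sample_id)
  if (length(missing) > 0)
    stop("metadata missing samples: ", paste(missing, collapse = ", "))
  x$metadata <- md[match(rownames(counts), md$sample_id), , drop = FALSE]
  rownames(x$metadata) <- NULL
  x
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  depth: min %s, median %s, max %s\n",
              format(min(rowSums(x$counts)), big.mark = ","),
              format(stats::median(rowSums(x$counts)), big.mark = ","),
              format(max(rowSums(x$counts)), big.mark = ",")))
  tp <- table(x$metadata$timepoint)
  cat("  timepoints:", paste(sprintf("%s (n=%d)", names(tp), tp),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count table by sample ids
#'
#' @param table a `count_table`.
#' @param sample_ids character vector of sample ids to keep (order preserved
#'   as given).
#' @return a `count_table` restricted to the requested samples.
#' @export
subset_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "count_table"))
  missing <- setdiff(sample_ids, rownames(table$counts))
  if (length(missing) > 0)
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  out <- table
  out$counts <- table$counts[sample_ids, , drop = FALSE]
  out$metadata <- table$metadata[match(sample_ids, table$metadata$sample_id), ,
                                 drop = FALSE]
  rownames(out$metadata) <- NULL
  out
}

#' Filter taxa on relative abundance and prevalence
#'
#' Retains taxa that satisfy BOTH criteria: summary relative abundance across
#' samples at or above `rel_abund_min` (summary statistic `mean` by default,
#' `max` available) AND presence (count > 0) in at least a fraction
#' `prevalence_min` of samples. Defaults reproduce the 0.01% relative
#' abundance and 37% prevalence thresholds used for skin 16S tables.
#'
#' @param table a `count_table`.
#' @param rel_abund_min minimum relative abundance (fraction, default 1e-4).
#' @param prevalence_min minimum prevalence (fraction of samples, default 0.37).
#' @param abund_stat how relative abundance is summarised across samples.
#' @return a `count_table` with the retained taxa, sample set unchanged,
#'   taxon order preserved.
#' @export
filter_taxa <- function(table, rel_abund_min = 1e-4, prevalence_min = 0.37,
                        abund_stat = c("mean", "max")) {
  stopifnot(inherits(table, "count_table"),
            rel_abund_min >= 0, rel_abund_min <= 1,
            prevalence_min >= 0, prevalence_min <= 1)
  abund_stat <- match.arg(abund_stat)
  counts <- table$counts
  depth <- rowSums(counts)
  rel <- counts / ifelse(depth == 0, 1, depth)
  ab <- switch(abund_stat,
               mean = colMeans(rel),
               max = apply(rel, 2, max))
  prev <- colMeans(counts > 0)
  keep_ab <- ab >= rel_abund_min
  keep_prev <- prev >= prevalence_min
  keep <- keep_ab & keep_prev
  if (!any(keep)) {
    stricter <- if (sum(!keep_ab) >= sum(!keep_prev))
      sprintf("relative abundance >= %g (%s)", rel_abund_min, abund_stat)
    else
      sprintf("prevalence >= %g", prevalence_min)
    stop("all taxa removed by filtering; stricter criterion: ", stricter)
  }
  out <- table
  out$counts <- counts[, keep, drop = FALSE]
  out$provenance <- c(table$provenance, list(filter = list(
    rel_abund_min = rel_abund_min, prevalence_min = prevalence_min,
    abund_stat = abund_stat, n_taxa_in = ncol(counts),
    n_taxa_out = sum(keep))))
  out
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement down to `depth`.
#' Samples whose total is below `depth` are dropped with a message (reads
#' cannot be subsampled beyond the total). The default depth of 50,000 reads
#' matches common practice for skin 16S surveys.
#'
#' @param table a `count_table`.
#' @param depth target reads per sample (default 50000).
#' @param seed integer RNG seed.
#' @return a `count_table` whose rows each sum exactly to `depth`. Dropped
#'   sample ids are recorded in `attr(, "dropped_samples")`.
#' @export
rarefy <- function(table, depth = 50000, seed = 1L) {
  stopifnot(inherits(table, "count_table"), depth > 0)
  totals <- rowSums(table$counts)
  low <- totals < depth
  if (all(low))
    stop(sprintf("all %d samples have fewer than %d reads; cannot rarefy",
                 nrow(table$counts), depth))
  if (any(low))
    message(sprintf("rarefy: dropping %d sample(s) below depth %d: %s",
                    sum(low), depth,
                    paste(rownames(table$counts)[low], collapse = ", ")))
  kept <- table$counts[!low, , drop = FALSE]
  rare <- with_seed(derive_seed(seed, "rarefy"),
                    vegan::rrarefy(kept, sample = depth))
  out <- subset_samples(table, rownames(kept))
  out$counts <- rare
  out$provenance <- c(out$provenance,
                      list(rarefy = list(depth = depth, seed = seed,
                                         n_dropped = sum(low))))
  attr(out, "dropped_samples") <- rownames(table$counts)[low]
  out
}

#' Centered log-ratio transform
#'
#' Maps each sample's counts to `log(count + pseudocount)` centered by the
#' sample's mean log value, i.e. the log of each part relative to the
#' geometric mean of the (pseudocounted) sample. Removes the compositional
#' closure of sequencing counts; every transformed row sums to zero.
#'
#' @param table a `count_table`.
#' @param pseudocount positive value added to every count before the log
#'   (default 1).
#' @return an object of class `clr_matrix` with fields `values` (samples x
#'   taxa real matrix), `pseudocount` and `provenance`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "count_table"), pseudocount > 0)
  lc <- log(table$counts + pseudocount)
  values <- lc - rowMeans(lc)
  structure(list(values = values, pseudocount = pseudocount,
                 metadata = table$metadata,
                 provenance = c(table$provenance,
                                list(clr = list(pseudocount = pseudocount)))),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("clr_matrix: %d samples x %d taxa (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}
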