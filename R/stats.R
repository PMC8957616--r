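# Cohort-level statistics: bootstrap comparison of network metrics, paired
# Wilcoxon signed-rank tests for lipid classes, Pearson correlation for
# hydration-lipid association, and fold/percent change summaries.

new_test_result <- function(statistic, p_value, method, n = NULL,
                            n_resamples = NA_integer_, flag = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, n_resamples = n_resamples, flag = flag),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.na(x$n_resamples)) cat(sprintf(" (%d resamples)", x$n_resamples))
  if (isTRUE(x$flag)) cat(" [flag]")
  cat("\n")
  invisible(x)
}

# content-derived stream seed so the test is exactly symmetric in its
# arguments: swapping the groups swaps the streams along with the data
group_stream_seed <- function(seed, values) {
  h <- sum(sin(values * seq_along(values))) * 1e6
  as.integer(abs(h + as.numeric(seed) * 9973) %% 2147483646) + 1L
}

#' Bootstrap hypothesis test for a difference in group means
#'
#' Two-sided test of equal means. Both groups are shifted to the pooled
#' mean (the resampling null), resampled with replacement within groups
#' `n_resamples` times, and the achieved significance level is the fraction
#' of resampled absolute mean differences at or above the observed one,
#' with the (1 + k)/(B + 1) small-sample correction. Each group's resampling
#' stream is seeded from its own values, so swapping the groups flips the
#' sign of the statistic and leaves the p-value unchanged.
#'
#' @param values_a,values_b numeric vectors (at least 3 values each).
#' @param n_resamples bootstrap resamples (default 10000).
#' @param seed integer RNG seed.
#' @param alternative `"two.sided"` (default), `"greater"`
#'   (mean of `values_a` exceeds mean of `values_b`) or `"less"`.
#' @return a `cohort_test` with `statistic = mean(values_a) - mean(values_b)`.
#' @export
bootstrap_mean_test <- function(values_a, values_b, n_resamples = 10000,
                                seed = 1L,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values_a) >= 3, length(values_b) >= 3, n_resamples >= 1)
  na <- length(values_a); nb <- length(values_b)
  obs <- mean(values_a) - mean(values_b)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0 && obs == 0)
    return(new_test_result(0, 1, "bootstrap mean test", c(na, nb),
                           n_resamples, flag = TRUE))
  pooled <- mean(c(values_a, values_b))
  a0 <- values_a - mean(values_a) + pooled
  b0 <- values_b - mean(values_b) + pooled
  ra <- with_seed(group_stream_seed(seed, sort(a0)),
                  matrix(sample(a0, na * n_resamples, replace = TRUE),
                         nrow = n_resamples))
  rb <- with_seed(group_stream_seed(seed, sort(b0)),
                  matrix(sample(b0, nb * n_resamples, replace = TRUE),
                         nrow = n_resamples))
  d <- rowMeans(ra) - rowMeans(rb)
  k <- switch(alternative,
              two.sided = sum(abs(d) >= abs(obs) - 1e-15),
              greater = sum(d >= obs - 1e-15),
              less = sum(d <= obs + 1e-15))
  p <- (1 + k) / (n_resamples + 1)
  new_test_result(obs, p,
                  paste0("bootstrap mean test (", alternative, ")"),
                  c(na, nb), n_resamples)
}

# Exact null distribution of the signed-rank sum over doubled midranks via
# the generating function prod_i (1 + x^r_i); returns P(V2 = s) for
# s = 0..sum(r2). Handles tied (half-integer) midranks exactly.
signed_rank_null <- function(r2) {
  total <- sum(r2)
  poly <- numeric(total + 1)
  poly[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), poly[seq_len(total + 1 - r)])
    poly <- poly + shifted
  }
  poly / 2^length(r2)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `after - before`. Zero differences
#' are dropped (Wilcoxon's rule; `zero_handling = "pratt"` ranks them first
#' and then discards their contribution); tied absolute differences receive
#' midranks. The null distribution of the positive-rank sum is exact for up
#' to 25 nonzero pairs -- including under ties, via a generating-function
#' convolution over doubled midranks -- and a normal approximation with tie
#' and continuity correction is used above that.
#'
#' @param before,after numeric vectors of equal length.
#' @param zero_handling `"drop"` (default) or `"pratt"`.
#' @return a `cohort_test`; `statistic` is the positive-rank sum V.
#' @export
paired_wilcoxon <- function(before, after,
                            zero_handling = c("drop", "pratt")) {
  zero_handling <- match.arg(zero_handling)
  stopifnot(length(before) == length(after))
  d <- after - before
  if (all(d == 0))
    return(new_test_result(0, 1, "paired Wilcoxon signed-rank",
                           length(d), flag = TRUE))
  if (zero_handling == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < 5)
    warning("fewer than 5 nonzero differences; p-value is unreliable")
  v <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    pmf <- signed_rank_null(r2)
    v2 <- as.integer(round(2 * v))
    lower <- sum(pmf[seq_len(v2 + 1)])
    upper <- sum(pmf[(v2 + 1):length(pmf)])
    p <- min(1, 2 * min(lower, upper))
    method <- "paired Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "paired Wilcoxon signed-rank (normal approx.)"
  }
  new_test_result(v, p, method, n)
}

#' Pearson correlation with Student's t significance
#'
#' Correlation coefficient `r` with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return a `cohort_test` with `statistic = r` and field `t_value`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  out <- new_test_result(r, p, "Pearson correlation (t-test)", n)
  out$t_value <- t
  out
}

#' Fold change and percent change between two group means
#'
#' Follow-up relative to baseline: `fold_change = followup / baseline` and
#' `percent_change = 100 * (followup - baseline) / baseline`, so
#' `percent_change = 100 * (fold_change - 1)` exactly. Rounding (two
#' decimals for fold change, integer percent) happens only in the print
#' method.
#'
#' @param baseline_mean positive baseline group mean.
#' @param followup_mean follow-up group mean.
#' @return an object of class `change_summary`.
#' @export
change_summary <- function(baseline_mean, followup_mean) {
  if (!is.finite(baseline_mean) || baseline_mean <= 0)
    stop("baseline_mean must be positive")
  structure(list(baseline_mean = baseline_mean,
                 followup_mean = followup_mean,
                 fold_change = followup_mean / baseline_mean,
                 percent_change =
                   100 * (followup_mean - baseline_mean) / baseline_mean),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("change_summary: %.4g -> %.4g  (fold change %.2f, %+d%%)\n",
              x$baseline_mean, x$followup_mean, round(x$fold_change, 2),
              round(x$percent_change)))
  invisible(x)
}

#' Per-group population networks and single-sample networks
#'
#' For each timepoint group of a table, runs the full MNP pipeline on that
#' group's samples and derives the MNI of every sample within its group.
#' This is the single-sample-network design of the study: population
#' networks are inferred per timepoint and each sample's network is its
#' leave-one-out difference from its own group's MNP.
#'
#' @param table a `count_table`.
#' @param config an `mnp_config`.
#' @param by_timepoint split by the metadata timepoint (default); `FALSE`
#'   treats the whole table as one group.
#' @return named list (one element per group) of lists with fields `mnp`
#'   (the group's `mb_network`) and `mnis` (named list of `mni_network`s).
#' @export
compute_group_networks <- function(table, config = mnp_config(),
                                   by_timepoint = TRUE) {
  stopifnot(inherits(table, "count_table"))
  groups <- if (by_timepoint) unique(table$metadata$timepoint) else "all"
  out <- lapply(groups, function(tp) {
    ids <- if (by_timepoint)
      table$metadata$sample_id[table$metadata$timepoint == tp]
    else rownames(table$counts)
    sub <- subset_samples(table, ids)
    mnp <- compute_mnp(sub, config)
    kept <- rownames(mnp$filtered$counts)
    mnis <- lapply(kept, function(s) compute_mni(sub, s, config, mnp = mnp))
    names(mnis) <- kept
    list(mnp = mnp, mnis = mnis)
  })
  names(out) <- groups
  out
}

#' Per-sample MNI metric table
#'
#' @param groups result of [compute_group_networks()].
#' @param config an `mnp_config` (attack ordering/response settings).
#' @return data.frame with `sample_id`, `timepoint` and the [metric_set()]
#'   columns of every sample's MNI.
#' @export
mni_metric_table <- function(groups, config = mnp_config()) {
  do.call(rbind, lapply(names(groups), function(tp) {
    g <- groups[[tp]]
    do.call(rbind, lapply(names(g$mnis), function(s)
      cbind(sample_id = s, timepoint = tp,
            as.data.frame(mni_metrics(g$mnis[[s]],
                                      ordering = config$ordering,
                                      response = config$response)))))
  }))
}

#' Compare per-sample MNI metrics between two timepoints
#'
#' The single-sample-network comparison: population networks are inferred
#' per timepoint, each sample's MNI metric set is computed within its group,
#' and every metric is tested between the two groups (follow-up minus
#' baseline, groups in sorted timepoint order).
#'
#' @param table a `count_table` whose metadata has exactly two timepoints.
#' @param config an `mnp_config`.
#' @param metrics character vector of metric names to test.
#' @param test `"bootstrap"` ([bootstrap_mean_test()]) or `"wilcoxon"`
#'   (paired on subjects present at both timepoints).
#' @param n_resamples bootstrap resamples.
#' @param alternative passed to [bootstrap_mean_test()]; `"greater"` tests
#'   the directional hypothesis that the follow-up group is higher.
#' @param seed integer seed (default: config seed).
#' @param groups optional precomputed [compute_group_networks()] result.
#' @return list with `per_sample` (data.frame of per-sample metric values),
#'   `tests` (named list of `cohort_test`s, one per metric), `groups` and
#'   the timepoint labels.
#' @export
compare_mni_metrics <- function(table, config = mnp_config(),
                                metrics = c("mean_degree", "edge_number",
                                            "node_number", "robustness"),
                                test = c("bootstrap", "wilcoxon"),
                                n_resamples = 10000,
                                alternative = "two.sided",
                                seed = config$seed, groups = NULL) {
  test <- match.arg(test)
  tps <- sort(unique(table$metadata$timepoint))
  if (length(tps) != 2)
    stop("table must have exactly two timepoints, found: ",
         paste(tps, collapse = ", "))
  if (is.null(groups))
    groups <- compute_group_networks(table, config, by_timepoint = TRUE)
  per <- mni_metric_table(groups, config)
  tests <- lapply(metrics, function(metric) {
    a <- per[per$timepoint == tps[1], metric]
    b <- per[per$timepoint == tps[2], metric]
    if (test == "bootstrap") {
      bootstrap_mean_test(b, a, n_resamples = n_resamples,
                          seed = derive_seed(seed, paste0("cmp_", metric)),
                          alternative = alternative)
    } else {
      sub <- table$metadata
      paired <- intersect(sub$subject[sub$timepoint == tps[1]],
                          sub$subject[sub$timepoint == tps[2]])
      key <- function(tp) per[[metric]][match(
        sub$sample_id[sub$timepoint == tp][
          match(paired, sub$subject[sub$timepoint == tp])],
        per$sample_id)]
      paired_wilcoxon(key(tps[1]), key(tps[2]))
    }
  })
  names(tests) <- metrics
  list(per_sample = per, tests = tests, groups = groups,
       timepoints = c(baseline = tps[1], followup = tps[2]))
}
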