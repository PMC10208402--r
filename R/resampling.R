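# Sample-size robustness: bootstrap subsampling of the ROI group analysis
# across decreasing per-group sizes with a majority-significance criterion,
# plus stability summaries via the coefficient of quartile variation.

#' Coefficient of quartile variation
#'
#' \eqn{CQV = (Q_3 - Q_1)/(Q_3 + Q_1) \cdot 100} (percent), with quartiles
#' under the type-7 (linear interpolation) convention.  Robust relative
#' dispersion: invariant under positive rescaling of the data.
#'
#' @param values Numeric vector with at least 4 values.
#' @return A list of class `cqv_result` with `q1`, `q3`, `cqv` (percent);
#'   `cqv` is NA when Q1 + Q3 <= 0.
#' @export
cqv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("CQV needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  out <- if (q[1L] + q[2L] <= 0) NA_real_ else
    (q[2L] - q[1L]) / (q[2L] + q[1L]) * 100
  structure(list(q1 = q[1L], q3 = q[2L], cqv = out), class = "cqv_result")
}

# Row-wise CQV of a matrix of subsample draws (one subsample per row).
row_cqv <- function(V) {
  q1 <- row_quantile(V, 0.25)
  q3 <- row_quantile(V, 0.75)
  out <- (q3 - q1) / (q3 + q1) * 100
  out[q3 + q1 <= 0] <- NA_real_
  out
}

#' Plan a subsampling experiment
#'
#' Per-group sample sizes decrease from the full (smallest) group size down
#' to `min_size` in steps of `step`; at each size, `B` random subsamples of
#' distinct subjects are drawn per group and the two-group tests repeated.
#' A test is flagged significant at a size when at least `ceiling(B/2)`
#' subsamples give p below `alpha` (the majority criterion; 2,501 of 5,001
#' at the default B).
#'
#' @param n_full Full per-group sample size the sizes descend from.
#' @param min_size Smallest size (default 10).
#' @param step Size decrement (default 5).
#' @param B Subsamples per size (default 5001).
#' @param alpha Per-test significance level (default 0.05).
#' @param base_seed Seed of the subsample schedule; every (size, iteration)
#'   draw is reconstructible in isolation from it.
#' @param with_replacement Draw subjects with replacement (default FALSE:
#'   reduced-size subsamples of distinct subjects).
#' @return A list of class `resampling_plan` with `sizes` (strictly
#'   decreasing), `B`, `threshold`, `alpha`, `base_seed`,
#'   `with_replacement`.
#' @export
resampling_plan <- function(n_full, min_size = 10L, step = 5L, B = 5001L,
                            alpha = 0.05, base_seed = 1L,
                            with_replacement = FALSE) {
  if (min_size < 2L) stop("min_size must be at least 2")
  if (n_full < min_size) stop("n_full must be at least min_size")
  sizes <- seq(as.integer(n_full), as.integer(min_size), by = -as.integer(step))
  structure(list(sizes = sizes, B = as.integer(B),
                 threshold = as.integer(ceiling(B / 2)), alpha = alpha,
                 base_seed = as.integer(base_seed),
                 with_replacement = with_replacement),
            class = "resampling_plan")
}

# Subsample index matrix (B x n) into 1..n_group for one (size, group),
# reproducible row by row from the plan seed.
subsample_indices <- function(plan, size, group_index, n_group) {
  if (size > n_group)
    stop("plan size ", size, " exceeds group size ", n_group)
  idx <- matrix(0L, plan$B, size)
  for (b in seq_len(plan$B)) {
    set.seed(seed_for(plan$base_seed, size * 101L + group_index, b))
    idx[b, ] <- sample.int(n_group, size,
                           replace = plan$with_replacement)
  }
  idx
}

#' Run the subsampling experiment over an ROI table
#'
#' For every plan size, draws `B` per-group subsamples and repeats the
#' pooled t-test for each retained (ROI, metric, pair) test.  By default
#' only the tests significant in the full-sample reference comparisons are
#' retained, as the experiment asks whether reference findings survive
#' smaller samples.  Per (size, group, ROI, metric), the CQV of each
#' subsample is summarized by its median and 95% CI (2.5 / 97.5 percentiles
#' over the B subsample CQVs).
#'
#' @param rt A `roi_table`.
#' @param plan A [resampling_plan()].
#' @param pairs Group pairs (default: all, as in [roi_comparison_table()]).
#' @param restrict_to Optional data.frame with columns pair, roi, metric
#'   naming the tests to track; default: reference-significant tests.
#' @param compute_cqv Compute CQV summaries (default TRUE, over the ROIs and
#'   metrics of the tracked tests, for every group).
#' @return A list of class `resampling_result`: `counts` (size, roi, metric,
#'   pair, count, significant), `cqv` (size, group, roi, metric, median,
#'   ci_low, ci_high), `reference` (full-sample comparison table), `plan`.
#' @export
subsample_experiment <- function(rt, plan, pairs = NULL, restrict_to = NULL,
                                 compute_cqv = TRUE) {
  stopifnot(inherits(rt, "roi_table"), inherits(plan, "resampling_plan"))
  if (is.null(pairs)) pairs <- default_group_pairs(levels(rt$group))
  reference <- roi_comparison_table(rt, pairs, alpha = plan$alpha)
  if (is.null(restrict_to))
    restrict_to <- reference[reference$significant,
                             c("pair", "roi", "metric")]
  group_levels <- levels(rt$group)
  group_rows <- lapply(group_levels, function(g) which(rt$group == g))
  names(group_rows) <- group_levels
  for (g in group_levels)
    if (max(plan$sizes) > length(group_rows[[g]]))
      stop("plan size ", max(plan$sizes), " exceeds size of group ", g,
           " (", length(group_rows[[g]]), ")")
  col_key <- paste(rt$roi, rt$metric)
  counts <- list(); cqv_rows <- list()
  cqv_cols <- unique(restrict_to[, c("roi", "metric")])
  for (size in plan$sizes) {
    draws <- lapply(seq_along(group_levels), function(gi)
      subsample_indices(plan, size, gi, length(group_rows[[gi]])))
    names(draws) <- group_levels
    if (nrow(restrict_to)) for (k in seq_len(nrow(restrict_to))) {
      pr <- strsplit(restrict_to$pair[k], "-", fixed = TRUE)[[1L]]
      j <- match(paste(restrict_to$roi[k], restrict_to$metric[k]), col_key)
      va <- rt$values[group_rows[[pr[1L]]], j]
      vb <- rt$values[group_rows[[pr[2L]]], j]
      A <- matrix(va[draws[[pr[1L]]]], plan$B)
      Bm <- matrix(vb[draws[[pr[2L]]]], plan$B)
      p <- row_pooled_t_p(A, Bm)
      cnt <- sum(p < plan$alpha)
      counts[[length(counts) + 1L]] <- data.frame(
        size = size, roi = restrict_to$roi[k],
        metric = restrict_to$metric[k], pair = restrict_to$pair[k],
        count = cnt, significant = cnt >= plan$threshold)
    }
    if (compute_cqv && nrow(cqv_cols)) {
      for (g in group_levels) for (k in seq_len(nrow(cqv_cols))) {
        j <- match(paste(cqv_cols$roi[k], cqv_cols$metric[k]), col_key)
        v <- rt$values[group_rows[[g]], j]
        V <- matrix(v[draws[[g]]], plan$B)
        cq <- row_cqv(V)
        qs <- stats::quantile(cq, c(0.5, 0.025, 0.975), names = FALSE,
                              na.rm = TRUE, type = 7)
        cqv_rows[[length(cqv_rows) + 1L]] <- data.frame(
          size = size, group = g, roi = cqv_cols$roi[k],
          metric = cqv_cols$metric[k], median = qs[1L], ci_low = qs[2L],
          ci_high = qs[3L])
      }
    }
  }
  structure(list(
    counts = if (length(counts)) do.call(rbind, counts) else
      data.frame(size = integer(), roi = integer(), metric = character(),
                 pair = character(), count = integer(),
                 significant = logical()),
    cqv = if (length(cqv_rows)) do.call(rbind, cqv_rows) else NULL,
    reference = reference, plan = plan), class = "resampling_result")
}

# Vectorized pooled-t two-tailed p-values for row-paired matrices of draws.
row_pooled_t_p <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  p[sp2 <= 0 & (ma - mb) == 0] <- 1
  p[sp2 <= 0 & (ma - mb) != 0] <- 0
  p
}

#' Significant-ROI count against sample size
#'
#' Number of ROIs flagged by the majority criterion at each size, per
#' metric and group pair.  Monotonicity is reported, not enforced.
#'
#' @param result A `resampling_result`.
#' @return data.frame with pair, metric, size, n_significant.
#' @export
significance_vs_size_curve <- function(result) {
  stopifnot(inherits(result, "resampling_result"))
  x <- result$counts
  if (!nrow(x))
    return(data.frame(pair = character(), metric = character(),
                      size = integer(), n_significant = integer()))
  agg <- stats::aggregate(significant ~ pair + metric + size, data = x,
                          FUN = sum)
  names(agg)[4L] <- "n_significant"
  agg[order(agg$pair, agg$metric, -agg$size), ]
}

#' Write a resampling result as TSV + JSON summary
#'
#' @param result A `resampling_result`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_resampling_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "subsample_counts.tsv")
  utils::write.table(result$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- counts_path
  if (!is.null(result$cqv)) {
    cqv_path <- file.path(dir, "cqv_summary.tsv")
    utils::write.table(result$cqv, cqv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, cqv_path)
  }
  curve <- significance_vs_size_curve(result)
  json_path <- file.path(dir, "resampling_summary.json")
  jsonlite::write_json(list(
    plan = result$plan[c("sizes", "B", "threshold", "alpha", "base_seed")],
    curve = curve), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, json_path))
}
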