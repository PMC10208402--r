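# Skeleton-restricted trimmed ROI summaries and the two-group statistics
# (pooled-variance t-test, Cohen's D, contingency chi-square).

#' ROI extraction settings
#'
#' @param low,high Trim percentiles (defaults 2 and 98): per ROI, values
#'   outside the open interval between these percentile bounds are dropped
#'   before averaging.
#' @param skeleton_restrict Restrict ROIs to the skeleton mask
#'   (default TRUE).
#' @param global_bounds Compute the trim bounds over the whole skeleton
#'   rather than per ROI-skeleton intersection (default FALSE).
#' @return A list of class `roi_extraction_spec`.
#' @export
roi_extraction_spec <- function(low = 2, high = 98, skeleton_restrict = TRUE,
                                global_bounds = FALSE) {
  if (!(low >= 0 && low < high && high <= 100))
    stop("need 0 <= low < high <= 100")
  structure(list(low = low, high = high,
                 skeleton_restrict = skeleton_restrict,
                 global_bounds = global_bounds),
            class = "roi_extraction_spec")
}

# Row-wise type-7 quantile of a matrix (linear interpolation between order
# statistics), vectorized across rows.
row_quantile <- function(V, p) {
  n <- ncol(V)
  o <- order(row(V), V)
  Vs <- matrix(V[o], nrow = nrow(V), byrow = TRUE)
  h <- (n - 1) * p + 1
  lo <- floor(h); fr <- h - lo
  q <- Vs[, lo]
  if (fr > 0) q <- q * (1 - fr) + Vs[, min(lo + 1, n)] * fr
  q
}

# Trimmed mean per row: average of values strictly inside the (low, high)
# percentile bounds; falls back to the closed interval when the open one is
# empty (e.g. constant rows), and to the plain mean as a last resort.
row_trimmed_mean <- function(V, low = 2, high = 98) {
  qlo <- row_quantile(V, low / 100)
  qhi <- row_quantile(V, high / 100)
  open <- V > qlo & V < qhi
  nopen <- rowSums(open)
  out <- rowSums(V * open) / nopen
  fix <- which(nopen == 0 | !is.finite(out))
  if (length(fix)) {
    closed <- V[fix, , drop = FALSE] >= qlo[fix] & V[fix, , drop = FALSE] <= qhi[fix]
    ncl <- rowSums(closed)
    alt <- rowSums(V[fix, , drop = FALSE] * closed) / ncl
    alt[ncl == 0] <- rowMeans(V[fix, , drop = FALSE])[ncl == 0]
    out[fix] <- alt
  }
  out
}

#' Trimmed mean of a scalar map over an ROI
#'
#' Restricts the map to the ROI (intersected with the skeleton when
#' requested), computes the `low`/`high` percentile bounds of those values,
#' and averages the values strictly inside the bounds (the bounds themselves
#' are excluded; if nothing lies strictly inside, the closed interval is
#' used so constant regions return their value).
#'
#' @param map Numeric vector or 3D array of voxel values.
#' @param roi_mask Logical vector/array selecting the ROI.
#' @param skeleton Optional logical skeleton mask.
#' @param spec A [roi_extraction_spec()].
#' @return Scalar; NA with a warning when the intersection is empty.
#' @export
trimmed_roi_mean <- function(map, roi_mask, skeleton = NULL,
                             spec = roi_extraction_spec()) {
  map <- as.numeric(map)
  sel <- as.logical(roi_mask)
  if (length(sel) != length(map))
    stop("grid mismatch between map and ROI mask")
  if (!is.null(skeleton) && spec$skeleton_restrict) {
    skeleton <- as.logical(skeleton)
    if (length(skeleton) != length(map))
      stop("grid mismatch between map and skeleton mask")
    sel <- sel & skeleton
  }
  v <- map[sel]
  v <- v[is.finite(v)]
  if (!length(v)) {
    warning("empty ROI-skeleton intersection; returning NA")
    return(NA_real_)
  }
  bsrc <- if (spec$global_bounds && !is.null(skeleton))
    map[as.logical(skeleton)] else v
  bsrc <- bsrc[is.finite(bsrc)]
  qs <- stats::quantile(bsrc, c(spec$low, spec$high) / 100, names = FALSE,
                        type = 7)
  inside <- v[v > qs[1L] & v < qs[2L]]
  if (!length(inside)) inside <- v[v >= qs[1L] & v <= qs[2L]]
  if (!length(inside)) inside <- v
  mean(inside)
}

# Construct a roi_table object.
new_roi_table <- function(values, roi, metric, subject, group) {
  stopifnot(ncol(values) == length(roi), length(roi) == length(metric),
            nrow(values) == length(subject), length(subject) == length(group))
  structure(list(values = values, roi = as.integer(roi),
                 metric = as.character(metric),
                 subject = as.character(subject), group = as.factor(group)),
            class = "roi_table")
}

#' @export
print.roi_table <- function(x, ...) {
  cat("ROI table:", nrow(x$values), "subjects x", length(unique(x$roi)),
      "ROIs x", length(unique(x$metric)), "metrics; groups:",
      paste(levels(x$group), table(x$group), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Build an ROI table from per-subject metric maps
#'
#' One row per subject; one column per (ROI, metric) pair holding the
#' skeleton-restricted trimmed mean.  ROI id 0 is the full-skeleton
#' pseudo-ROI (union of all region skeletons).
#'
#' @param maps List (one element per subject) of n_voxels x n_metrics
#'   matrices with column names, all on the atlas grid.
#' @param atlas A [toy_atlas()], or a list with `labels` and `skeleton`
#'   arrays on the map grid.
#' @param design data.frame with `subject_id` and `group`.
#' @param spec A [roi_extraction_spec()].
#' @return A `roi_table`.
#' @export
roi_table_from_maps <- function(maps, atlas, design,
                                spec = roi_extraction_spec()) {
  stopifnot(length(maps) == nrow(design))
  labels <- as.integer(atlas$labels)
  skel <- as.logical(atlas$skeleton)
  rois <- sort(unique(labels[labels > 0L]))
  metrics <- colnames(maps[[1L]])
  sel_for <- function(r) if (r == 0L) skel else
    (labels == r) & (if (spec$skeleton_restrict) skel else TRUE)
  roi_ids <- c(0L, rois)
  cols <- expand.grid(metric = metrics, roi = roi_ids,
                      stringsAsFactors = FALSE)
  nsub <- length(maps)
  values <- matrix(NA_real_, nsub, nrow(cols))
  sel_list <- lapply(roi_ids, sel_for)
  for (s in seq_len(nsub)) {
    m <- maps[[s]]
    for (j in seq_len(nrow(cols))) {
      sel <- sel_list[[match(cols$roi[j], roi_ids)]]
      values[s, j] <- trimmed_roi_mean(m[, cols$metric[j]], sel,
                                       skeleton = NULL, spec = spec)
    }
  }
  new_roi_table(values, cols$roi, cols$metric, design$subject_id,
                design$group)
}

#' ROI table straight from a cohort specification
#'
#' Streams the cohort: generates each subject's signal in memory (in
#' batches), computes the 11 metric maps, and reduces them to
#' skeleton-restricted trimmed ROI means.  Avoids materializing any volumes
#' on disk; deterministic in the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [qspace_config()].
#' @param extraction A [roi_extraction_spec()].
#' @param batch_size Subjects fitted per batch (default 64).
#' @return A `roi_table`.
#' @export
cohort_roi_table <- function(spec, config = qspace_config(),
                             extraction = roi_extraction_spec(),
                             batch_size = 64L) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- spec$atlas
  nvox <- prod(atlas$dims)
  nsub <- nrow(spec$design)
  labels <- as.integer(atlas$labels)
  skel <- as.logical(atlas$skeleton)
  roi_ids <- c(0L, seq_len(atlas$n_regions))
  sel_list <- lapply(roi_ids, function(r)
    which(if (r == 0L) skel else
      (labels == r) & (if (extraction$skeleton_restrict) skel else TRUE)))
  metrics <- metric_names()
  cols <- expand.grid(metric = metrics, roi = roi_ids,
                      stringsAsFactors = FALSE)
  values <- matrix(NA_real_, nsub, nrow(cols))
  mask1 <- labels != 0L
  for (start in seq(1L, nsub, by = batch_size)) {
    subs <- start:min(start + batch_size - 1L, nsub)
    sig <- do.call(rbind, lapply(subs, function(s) subject_signal(spec, s)))
    mm <- compute_metric_maps(sig, spec$scheme,
                              mask = rep(mask1, length(subs)),
                              config = config)
    for (j in seq_len(nrow(cols))) {
      vr <- sel_list[[match(cols$roi[j], roi_ids)]]
      V <- matrix(mm[rep((seq_along(subs) - 1L) * nvox, each = length(vr)) +
                       vr, cols$metric[j]],
                  nrow = length(subs), byrow = TRUE)
      values[subs, j] <- row_trimmed_mean(V, extraction$low, extraction$high)
    }
  }
  new_roi_table(values, cols$roi, cols$metric, spec$design$subject_id,
                spec$design$group)
}

#' Two-sample pooled-variance t-test
#'
#' Classical equal-variance two-tailed t-test with
#' df = n_a + n_b - 2.  Degenerate zero-variance input returns t = 0, p = 1
#' when the means agree and p = 0 otherwise.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `p`, `df`.
#' @export
pooled_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least two values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(dm) * Inf, p = 0, df = df))
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Cohen's D with pooled standard deviation
#'
#' \eqn{D = (\bar a - \bar b)/s_p} with the (n-1)-weighted pooled SD.
#'
#' @param a,b Numeric vectors.
#' @return Scalar; NA when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least two values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Pearson chi-square statistic of a contingency table
#'
#' \eqn{\sum (O - E)^2 / E} without continuity correction,
#' df = (r - 1)(c - 1).
#'
#' @param table Numeric matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column marginal in contingency table")
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df,
                                                    lower.tail = FALSE))
}

# Default two-by-two group pairs in reporting order, e.g. for levels
# (HC, EM, CM): EM-HC, CM-HC, CM-EM.
default_group_pairs <- function(levels) {
  if (length(levels) < 2L) stop("need at least two groups")
  pairs <- list()
  for (j in 2:length(levels)) for (i in seq_len(j - 1L))
    pairs[[length(pairs) + 1L]] <- c(levels[j], levels[i])
  pairs
}

#' Pairwise group comparisons over every ROI and metric
#'
#' One record per (group pair, ROI, metric) — including the full-skeleton
#' pseudo-ROI 0 — with the pooled t statistic, two-tailed p, Cohen's D
#' (sign = first group mean minus second) and the significance flag at
#' `alpha`.  No multiple-comparison correction is applied by default; set
#' `p_adjust = "fdr"` for an optional Benjamini-Hochberg variant.
#'
#' @param rt A `roi_table`.
#' @param pairs List of 2-vectors of group labels; defaults to all pairs in
#'   the order (2nd vs 1st, 3rd vs 1st, 3rd vs 2nd) of the group levels.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust p.adjust method applied per metric/pair across ROIs
#'   (default "none").
#' @return data.frame with columns pair, group_a, group_b, roi, metric,
#'   n_a, n_b, t, p, cohens_d, significant.
#' @export
roi_comparison_table <- function(rt, pairs = NULL, alpha = 0.05,
                                 p_adjust = "none") {
  stopifnot(inherits(rt, "roi_table"))
  if (is.null(pairs)) pairs <- default_group_pairs(levels(rt$group))
  out <- list()
  for (pr in pairs) {
    if (!all(pr %in% levels(rt$group)))
      stop("unknown group label in pair: ", paste(pr, collapse = "-"))
    ia <- rt$group == pr[1L]; ib <- rt$group == pr[2L]
    if (sum(ia) < 2L || sum(ib) < 2L)
      stop("need at least two subjects per group for pair ",
           paste(pr, collapse = "-"))
    n <- ncol(rt$values)
    t <- p <- d <- numeric(n)
    for (j in seq_len(n)) {
      a <- rt$values[ia, j]; b <- rt$values[ib, j]
      tt <- pooled_t_test(a, b)
      t[j] <- tt$t; p[j] <- tt$p; d[j] <- cohens_d(a, b)
    }
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(pr, collapse = "-"), group_a = pr[1L], group_b = pr[2L],
      roi = rt$roi, metric = rt$metric, n_a = sum(ia), n_b = sum(ib),
      t = t, p = p, cohens_d = d)
  }
  out <- do.call(rbind, out)
  if (p_adjust != "none") {
    key <- interaction(out$pair, out$metric, drop = TRUE)
    out$p_adjusted <- stats::ave(out$p, key,
                                 FUN = function(x) stats::p.adjust(x, p_adjust))
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p < alpha
  }
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}

#' Count significant ROIs per metric and pair
#'
#' @param comparisons Output of [roi_comparison_table()].
#' @param include_full_wm Count the full-skeleton pseudo-ROI 0
#'   (default FALSE).
#' @return data.frame with pair, metric, n_significant.
#' @export
significant_counts <- function(comparisons, include_full_wm = FALSE) {
  x <- comparisons
  if (!include_full_wm) x <- x[x$roi != 0L, ]
  agg <- stats::aggregate(significant ~ pair + metric, data = x, FUN = sum)
  names(agg)[3L] <- "n_significant"
  agg$metric <- factor(agg$metric, levels = metric_names())
  agg[order(agg$pair, agg$metric), ]
}

#' Write / read an ROI table as TSV
#'
#' Long format with a one-line header: subject_id, group, roi, metric,
#' value.
#'
#' @param rt A `roi_table`.
#' @param path Output path.
#' @export
write_roi_table <- function(rt, path) {
  stopifnot(inherits(rt, "roi_table"))
  nsub <- nrow(rt$values)
  long <- data.frame(
    subject_id = rep(rt$subject, times = ncol(rt$values)),
    group = rep(as.character(rt$group), times = ncol(rt$values)),
    roi = rep(rt$roi, each = nsub),
    metric = rep(rt$metric, each = nsub),
    value = as.numeric(rt$values))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @param path TSV path written by [write_roi_table()].
#' @return A `roi_table`.
#' @export
read_roi_table <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  subjects <- unique(long$subject_id)
  cols <- unique(long[, c("roi", "metric")])
  values <- matrix(NA_real_, length(subjects), nrow(cols))
  key_col <- paste(long$roi, long$metric)
  key_u <- paste(cols$roi, cols$metric)
  values[cbind(match(long$subject_id, subjects),
               match(key_col, key_u))] <- long$value
  grp <- long$group[match(subjects, long$subject_id)]
  new_roi_table(values, cols$roi, cols$metric, subjects, grp)
}
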