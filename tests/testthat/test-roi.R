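test_that("trimmed ROI means follow the percentile convention", {
  spec <- roi_extraction_spec()
  # trimming is a no-op on constant regions
  expect_equal(trimmed_roi_mean(rep(4.2, 50), rep(TRUE, 50), spec = spec), 4.2)
  # a single extreme outlier is excluded by the 98% bound
  v <- c(rep(1, 99), 100)
  expect_equal(trimmed_roi_mean(v, rep(TRUE, 100), spec = spec), 1)
  # permutation invariance and monotone shift
  set.seed(7)
  v2 <- stats::rlnorm(200)
  m0 <- trimmed_roi_mean(v2, rep(TRUE, 200), spec = spec)
  expect_equal(trimmed_roi_mean(sample(v2), rep(TRUE, 200), spec = spec), m0)
  expect_equal(trimmed_roi_mean(v2 + 3, rep(TRUE, 200), spec = spec),
               m0 + 3, tolerance = 1e-12)
  # skeleton restriction and empty intersection
  expect_warning(
    out <- trimmed_roi_mean(v2, rep(TRUE, 200), skeleton = rep(FALSE, 200)),
    "empty")
  expect_true(is.na(out))
  expect_error(roi_extraction_spec(98, 2), "low < high")
})

test_that("vectorized row trimmed means agree with the scalar path", {
  set.seed(11)
  V <- matrix(stats::rlnorm(40 * 25), 40)
  rv <- amura:::row_trimmed_mean(V, 2, 98)
  sv <- apply(V, 1, function(x)
    trimmed_roi_mean(x, rep(TRUE, length(x))))
  expect_equal(rv, sv, tolerance = 1e-12)
  # row quantiles match the type-7 convention
  expect_equal(amura:::row_quantile(V, 0.25),
               apply(V, 1, stats::quantile, 0.25, type = 7),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pooled t-test matches the textbook formula and stats::t.test", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- pooled_t_test(a, b)
  # direct formula oracle
  sp2 <- ((4 * stats::var(a)) + (4 * stats::var(b))) / 8
  t_direct <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 5))
  expect_equal(res$t, t_direct, tolerance = 1e-10)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$df, 8)
  # identical groups and degenerate variance
  same <- pooled_t_test(a, a)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  deg <- pooled_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(deg$p, 0)
  expect_error(pooled_t_test(1, b), "at least two")
  # antisymmetry under group swap
  sw <- pooled_t_test(b, a)
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)
})

test_that("Cohen's D follows its definition and sign convention", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  expect_equal(cohens_d(a, a), 0)
  expect_equal(cohens_d(b, a), -cohens_d(a, b))
  # means one pooled SD apart: |D| = 1
  sp <- sqrt(((4 * stats::var(a)) + (4 * stats::var(a))) / 8)
  expect_equal(cohens_d(a + sp, a), 1, tolerance = 1e-12)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("chi-square contingency statistic matches oracles", {
  # identical column distributions: statistic 0
  expect_equal(chi_square_contingency(cbind(c(10, 20), c(10, 20)))$statistic,
               0)
  # random tables against the direct expected-count formula and chisq.test
  set.seed(13)
  for (k in 1:5) {
    tb <- matrix(stats::rpois(4, 20) + 1, 2)
    res <- chi_square_contingency(tb)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(res$statistic, sum((tb - E)^2 / E), tolerance = 1e-10)
    ref <- stats::chisq.test(tb, correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter))
  }
  expect_error(chi_square_contingency(cbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("comparison tables cover all pairs, ROIs and the full-WM row", {
  set.seed(17)
  nsub <- 18
  grp <- factor(rep(c("HC", "EM", "CM"), each = 6),
                levels = c("HC", "EM", "CM"))
  vals <- matrix(stats::rnorm(nsub * 4), nsub)
  rt <- amura:::new_roi_table(vals, roi = c(0L, 0L, 1L, 1L),
                              metric = c("FA", "MD", "FA", "MD"),
                              subject = sprintf("s%02d", 1:nsub), group = grp)
  cmp <- roi_comparison_table(rt)
  expect_setequal(unique(cmp$pair), c("EM-HC", "CM-HC", "CM-EM"))
  # single ROI + full-WM pseudo-ROI: 2 records per metric per pair
  expect_equal(nrow(cmp), 3 * 2 * 2)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_equal(unique(cmp$n_a), 6L)
  # sign of D equals sign of (mean_a - mean_b)
  j <- 1L
  a <- vals[grp == cmp$group_a[j], j]; b <- vals[grp == cmp$group_b[j], j]
  expect_equal(sign(cmp$cohens_d[j]), sign(mean(a) - mean(b)))
  expect_error(roi_comparison_table(rt, pairs = list(c("EM", "XX"))),
               "unknown group")
  cnt <- significant_counts(cmp)
  expect_identical(names(cnt), c("pair", "metric", "n_significant"))
})

test_that("ROI tables round-trip through TSV", {
  spec <- null_cohort_spec(seed = 3, n = 4L)
  rt <- cohort_roi_table(spec)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_roi_table(rt, tmp)
  back <- read_roi_table(tmp)
  expect_equal(back$values, rt$values, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$roi, rt$roi)
  expect_identical(back$metric, rt$metric)
  expect_identical(as.character(back$group), as.character(rt$group))
})

test_that("roi_table_from_maps agrees with the streamed cohort table", {
  spec <- null_cohort_spec(seed = 23, n = 3L)
  rt_stream <- cohort_roi_table(spec)
  nvox <- prod(spec$atlas$dims)
  maps <- lapply(seq_len(nrow(spec$design)), function(s)
    compute_metric_maps(amura:::subject_signal(spec, s), spec$scheme,
                        mask = as.integer(spec$atlas$labels) != 0L))
  rt_maps <- roi_table_from_maps(maps, spec$atlas, spec$design)
  key_a <- paste(rt_stream$roi, rt_stream$metric)
  key_b <- paste(rt_maps$roi, rt_maps$metric)
  expect_setequal(key_a, key_b)
  expect_equal(rt_maps$values[, match(key_a, key_b)], rt_stream$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})
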