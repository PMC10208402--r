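test_that("zeppelin and two-compartment signals follow the model", {
  dirs <- uniform_directions(20)
  mu <- c(0, 0, 1)
  expect_equal(zeppelin_signal(0, dirs, 1.7e-3, 0.3e-3, mu), rep(1, 20))
  perp <- matrix(c(1, 0, 0), 1); par <- matrix(mu, 1)
  expect_equal(zeppelin_signal(1000, perp, 1.7e-3, 0.3e-3, mu),
               exp(-1000 * 0.3e-3))
  expect_equal(zeppelin_signal(1000, par, 1.7e-3, 0.3e-3, mu),
               exp(-1000 * 1.7e-3))
  # isotropic degeneracy: independent of direction
  expect_equal(zeppelin_signal(1000, dirs, 1e-3, 1e-3, mu),
               rep(exp(-1), 20))
  # convex combination limits
  p1 <- voxel_params(f = 1)
  expect_equal(two_compartment_signal(1000, dirs, p1),
               zeppelin_signal(1000, dirs, p1$d_par, p1$d_perp, p1$mu))
  p0 <- voxel_params(f = 0.011, d_par = 1.7e-3, d_perp = 0.3e-3)
  p0$f <- 0   # free-water only
  expect_equal(two_compartment_signal(1000, dirs, p0),
               rep(exp(-1000 * 3e-3), 20))
  expect_error(voxel_params(f = 1.2), "f must lie")
  expect_error(voxel_params(d_perp = 2e-3, d_par = 1e-3), "d_perp <= d_par")
})

test_that("generated directions are deterministic, unit and well spread", {
  d1 <- uniform_directions(61)
  d2 <- uniform_directions(61)
  expect_identical(d1, d2)
  expect_equal(sqrt(rowSums(d1^2)), rep(1, 61), tolerance = 1e-12)
  # antipodally symmetrized minimum angle stays reasonable for 61 points
  ctab <- abs(tcrossprod(d1)); ctab[ctab > 1] <- 1
  ang <- acos(ctab)
  diag(ang) <- Inf
  expect_gt(min(ang), 10 * pi / 180)
})

test_that("noiseless generation inverts exactly to the mixture ADC", {
  sch <- test_scheme()
  p <- voxel_params(f = 0.7)
  sig <- matrix(amura:::params_signal(p, sch), nrow = 1)
  adc <- adc_from_signal(sig, sch)
  di <- sch$dwi_indices
  expected <- -log(two_compartment_signal(1000, sch$bvecs[di, ], p)) / 1000
  expect_equal(adc$D[1, ], expected, tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("constant-FA family holds FA and behaves like the reference case", {
  sch <- test_scheme()
  fam <- constant_fa_family(f_grid = seq(0.3, 1, by = 0.1), scheme = sch)
  expect_length(fam$infeasible, 0)
  # f = 1 solution recovers the reference d_perp
  expect_equal(fam$table$d_perp[fam$table$f == 1], 8.2e-4, tolerance = 1e-6)
  # achieved FA within 1e-4 of the target across the grid
  expect_lt(max(abs(fam$table$FA - fam$target)), 1e-4)
  # fitted MD decreases as the free-water fraction shrinks
  expect_true(all(diff(fam$table$MD) < 0))
})

test_that("constant-MD family reports infeasible fractions and holds MD", {
  sch <- test_scheme()
  expect_warning(
    fam <- constant_md_family(f_grid = seq(0.3, 1, by = 0.05), scheme = sch),
    "no MD")
  expect_true(all(fam$infeasible < min(fam$table$f)))
  expect_gt(nrow(fam$table), 2)
  expect_lt(max(abs(fam$table$MD - fam$target)), 1e-4 * fam$target)
})

test_that("Rician noise matches the requested baseline SNR", {
  set.seed(61)
  snr <- 30
  s <- add_rician_noise(rep(1, 20000), snr)
  expect_equal(mean(s) / stats::sd(s), snr, tolerance = 0.1 * snr)
  # SNR -> infinity: converges to the noiseless signal
  s2 <- add_rician_noise(rep(0.5, 5000), 1e6)
  expect_lt(max(abs(s2 - 0.5)), 1e-4)
  expect_identical(add_rician_noise(rep(0.5, 5), Inf), rep(0.5, 5))
})

test_that("cohort generation is deterministic and validates offsets", {
  spec <- null_cohort_spec(seed = 71, n = 3L)
  s1 <- amura:::subject_signal(spec, 2L)
  s2 <- amura:::subject_signal(spec, 2L)
  expect_identical(s1, s2)
  spec_b <- null_cohort_spec(seed = 72, n = 3L)
  expect_false(identical(s1, amura:::subject_signal(spec_b, 2L)))

  expect_error(cohort_spec(offsets = list(EM = list(f = c("1" = -0.9))),
                           atlas = small_atlas(), scheme = test_scheme()),
               "outside")
  expect_error(cohort_spec(offsets = list(XX = list(f = c("1" = -0.1))),
                           atlas = small_atlas(), scheme = test_scheme()),
               "not in design")
  expect_error(cohort_spec(offsets = list(EM = list(f = c("40" = -0.1))),
                           atlas = small_atlas(), scheme = test_scheme()),
               "out of range")
})

test_that("a deterministic null cohort yields identical subjects and t = 0", {
  spec <- cohort_spec(groups = c(HC = 3L, EM = 3L, CM = 3L),
                      atlas = small_atlas(), subject_sd = c(),
                      snr = Inf, scheme = test_scheme(), seed = 5)
  rt <- cohort_roi_table(spec)
  expect_lt(max(apply(rt$values, 2, function(v) diff(range(v)))), 1e-12)
  cmp <- roi_comparison_table(rt)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))
  expect_false(any(cmp$significant))
})

test_that("cohorts written to disk are byte-identical across runs", {
  tmp1 <- withr::local_tempdir(); tmp2 <- withr::local_tempdir()
  spec <- cohort_spec(groups = c(HC = 2L, EM = 2L, CM = 2L),
                      atlas = toy_atlas(c(8, 8, 4), 4L, margin = 1L),
                      scheme = synthetic_scheme(30, 1000), seed = 9)
  generate_cohort(spec, tmp1)
  generate_cohort(spec, tmp2)
  f1 <- sort(list.files(tmp1))
  expect_identical(f1, sort(list.files(tmp2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(tmp1, f))),
                     unname(tools::md5sum(file.path(tmp2, f))),
                     label = f)
  # design table maps every subject to its group
  des <- utils::read.table(file.path(tmp1, "design.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(des), 6L)
  expect_equal(as.vector(table(des$group)[c("HC", "EM", "CM")]),
               c(2L, 2L, 2L))
})

test_that("injected effects are recovered by the ROI pipeline", {
  spec <- effect_cohort_spec(seed = 81)
  rt <- cohort_roi_table(spec)
  ref <- roi_comparison_table(rt, pairs = list(c("EM", "HC")))
  hits <- ref[ref$metric == "RTOP" & ref$roi %in% 1:6, "significant"]
  expect_gte(sum(hits), 5)
})
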