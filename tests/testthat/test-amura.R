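test_that("ADC inversion reproduces the generating diffusivity profile", {
  sch <- test_scheme()
  cfg <- qspace_config()
  mu <- c(0, 0, 1)
  zep <- 0.3e-3 * diag(3) + 1.4e-3 * outer(mu, mu)
  sig <- tensor_signal(zep, sch)
  adc <- adc_from_signal(sig, sch, config = cfg)
  dtrue <- tensor_adc(adc$dirs, zep)
  expect_lt(max(abs(adc$D[1, ] - dtrue)), 1e-12)

  # no attenuation: D clips up to D_min; e-fold attenuation inverts exactly
  s2 <- matrix(1, 2, length(sch$bvals))
  s2[2, sch$dwi_indices] <- exp(-1)
  adc2 <- adc_from_signal(s2, sch, config = cfg)
  expect_true(all(adc2$D[1, ] == cfg$D_min))
  expect_equal(unname(adc2$clip[["low"]]), length(sch$dwi_indices))
  expect_equal(adc2$D[2, ], rep(1e-3, 61), tolerance = 1e-12,
               ignore_attr = TRUE)

  # S0 <= 0 flags the voxel invalid
  s3 <- rbind(s2[2, ], 0)
  adc3 <- adc_from_signal(s3, sch, config = cfg)
  expect_false(adc3$valid[2])
})

test_that("isotropic closed-form identities hold to 1e-10", {
  sch <- test_scheme()
  cfg <- qspace_config()
  D <- 1e-3; tau <- cfg$tau
  sig <- tensor_signal(diag(3) * D, sch)
  tf <- fit_dti(sig, sch)
  adc <- adc_from_signal(sig, sch, config = cfg)
  expect_equal(rtop(adc, cfg), (4 * pi * tau * D)^(-1.5),
               tolerance = 1e-10)
  expect_equal(rtpp(adc, tf$e1, cfg), (4 * pi * tau * D)^(-0.5),
               tolerance = 1e-10)
  expect_equal(rtap(adc, tf$e1, cfg), (4 * pi * tau * D)^(-1),
               tolerance = 1e-10)
  expect_equal(rtop(adc, cfg),
               rtpp(adc, tf$e1, cfg) * rtap(adc, tf$e1, cfg),
               tolerance = 1e-10)
  for (g in c(0.5, 2)) {
    expect_equal(generalized_moment(adc, g, cfg),
                 2 * pi * gamma((g + 3) / 2) *
                   (4 * pi^2 * tau * D)^(-(g + 3) / 2),
                 tolerance = 1e-10)
  }
  expect_equal(apa(adc, cfg), 0, tolerance = 1e-10)
  expect_equal(dia(adc, cfg), 0, tolerance = 1e-10)
})

test_that("the order-0 moment is exactly the return-to-origin probability", {
  sch <- test_scheme()
  cfg <- qspace_config()
  set.seed(43)
  sig <- tensor_signal(random_tensor(0.8)$tensor, sch)
  adc <- adc_from_signal(sig, sch, config = cfg)
  expect_equal(generalized_moment(adc, 0, cfg), rtop(adc, cfg),
               tolerance = 1e-12)
  expect_error(generalized_moment(adc, -3, cfg), "greater than -3")
})

test_that("metrics obey the diffusivity power-law scalings", {
  sch <- test_scheme()
  cfg <- qspace_config()
  set.seed(47)
  tn <- random_tensor(0.7)
  sig <- tensor_signal(tn$tensor, sch)
  tf <- fit_dti(sig, sch)
  adc <- adc_from_signal(sig, sch, config = cfg)
  for (cf in c(0.5, 2)) {
    sigc <- sig
    sigc[, sch$dwi_indices] <- sig[, sch$dwi_indices]^cf  # D -> cf * D
    adcc <- adc_from_signal(sigc, sch, config = cfg)
    tfc <- fit_dti(sigc, sch)
    expect_equal(rtop(adcc, cfg), cf^(-1.5) * rtop(adc, cfg),
                 tolerance = 1e-8)
    expect_equal(rtpp(adcc, tfc$e1, cfg), cf^(-0.5) * rtpp(adc, tf$e1, cfg),
                 tolerance = 1e-8)
    expect_equal(rtap(adcc, tfc$e1, cfg), cf^(-1) * rtap(adc, tf$e1, cfg),
                 tolerance = 1e-8)
    for (g in c(0.5, 2))
      expect_equal(generalized_moment(adcc, g, cfg),
                   cf^(-(g + 3) / 2) * generalized_moment(adc, g, cfg),
                   tolerance = 1e-8)
    # diffusion anisotropy is a pure shape index: unchanged by scaling D
    expect_equal(dia(adcc, cfg), dia(adc, cfg), tolerance = 1e-8)
  }
})

test_that("anisotropy indices follow the raw-index expansion and scaling map", {
  # c00 = 1, c20 = x: raw t = |x| / sqrt(1 + x^2) -> |x| as x -> 0
  idx <- sh_index_table(6)
  for (x in c(1e-4, 1e-3, 1e-2)) {
    cc <- matrix(0, nrow(idx), 1)
    cc[1, 1] <- 1
    cc[idx$l == 2 & idx$m == 0, 1] <- x
    t <- amura:::raw_anisotropy(cc)
    expect_equal(t, x, tolerance = x^2 * 2)
  }
  xs <- seq(0, 2, by = 0.1)
  ts <- vapply(xs, function(x) {
    cc <- matrix(0, nrow(idx), 1); cc[1, 1] <- 1
    cc[idx$l == 2 & idx$m == 0, 1] <- x
    amura:::raw_anisotropy(cc)
  }, numeric(1))
  expect_true(all(diff(ts) > 0))            # monotone in |x|
  expect_true(all(ts >= 0 & ts <= 1))
  # zero-power function: index defined as 0
  expect_equal(amura:::raw_anisotropy(matrix(0, nrow(idx), 1)), 0)
  # scaling map: fixes endpoints, monotone, maps [0,1] onto [0,1]
  tt <- seq(0, 1, by = 0.01)
  st <- anisotropy_scaling(tt, 0.4)
  expect_equal(st[1], 0)
  expect_equal(st[length(st)], 1)
  expect_true(all(diff(st) > 0))
  expect_true(all(st >= 0 & st <= 1))
})

test_that("the propagator anisotropy index only depends on profile shape", {
  sch <- test_scheme()
  cfg <- qspace_config(scale_anisotropy = FALSE)
  set.seed(53)
  sig <- tensor_signal(random_tensor(0.8)$tensor, sch)
  adc <- adc_from_signal(sig, sch, config = cfg)
  a0 <- apa(adc, cfg)
  # multiply the attenuation profile by a constant: index unchanged
  adc2 <- adc
  adc2$att <- adc$att * 0.37
  expect_equal(apa(adc2, cfg), a0, tolerance = 1e-12)
})

test_that("metrics are invariant under joint rotation and antipodal flips", {
  sch <- test_scheme()
  cfg <- qspace_config()
  set.seed(59)
  tn <- random_tensor(0.8)
  sig <- tensor_signal(tn$tensor, sch)
  ref <- amura_metrics(sig, sch, config = cfg)
  # flip a random half of the directions (antipodal symmetry)
  flip <- sample(c(-1, 1), 61, replace = TRUE)
  schf <- gradient_scheme(sch$bvals,
                          rbind(0, sch$bvecs[sch$dwi_indices, ] * flip))
  expect_equal(amura_metrics(sig, schf, config = cfg), ref,
               tolerance = 1e-9)
  # joint rotation of the direction set
  for (k in 1:2) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    schr <- gradient_scheme(sch$bvals, sch$bvecs %*% t(Q))
    expect_equal(amura_metrics(sig, schr, config = cfg), ref,
                 tolerance = 1e-6)
  }
})

test_that("zeppelin voxels match their directional closed forms", {
  sch <- test_scheme()
  cfg <- qspace_config()
  mu <- c(0, 1, 0)
  d_par <- 1.7e-3; d_perp <- 0.9e-3    # moderate anisotropy
  zep <- d_perp * diag(3) + (d_par - d_perp) * outer(mu, mu)
  sig <- tensor_signal(zep, sch)
  tf <- fit_dti(sig, sch)
  adc <- adc_from_signal(sig, sch, config = cfg)
  # RTPP against the parallel diffusivity, RTAP against the perpendicular
  # one; tolerances reflect the order-6 truncation plus the standard
  # Laplace-Beltrami shrinkage of the pointwise profile evaluations
  expect_equal(rtpp(adc, tf$e1, cfg), (4 * pi * cfg$tau * d_par)^(-0.5),
               tolerance = 1e-2)
  expect_equal(rtap(adc, tf$e1, cfg), (4 * pi * cfg$tau * d_perp)^(-1),
               tolerance = 3e-2)
})

test_that("the full metric set is assembled in registry order with QC", {
  sch <- test_scheme()
  sig <- rbind(tensor_signal(diag(3) * 1e-3, sch),
               tensor_signal(random_tensor(0.6)$tensor, sch))
  m <- compute_metric_maps(sig, sch)
  expect_identical(colnames(m), metric_names())
  expect_true(all(is.finite(m)))
  expect_true(all(m[, c("RTOP", "RTPP", "RTAP", "qMSD", "U12")] > 0))
  expect_false(is.null(attr(m, "clip")))
})
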