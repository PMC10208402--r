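# Brute-force oracles and fixture builders shared across the test suite.
# These are independent of the package's computation paths: dense spherical
# / radial quadrature integrators and direct model evaluations.

# Near-uniform points on the full sphere (golden-spiral construction).
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# High-order product quadrature on the sphere: Gauss-Legendre in cos(theta)
# times uniform phi.  Exact for spherical harmonics up to degree ~ 2 n_t.
sphere_quadrature <- function(n_t = 32L, n_phi = 64L) {
  gl <- pracma::gaussLegendre(n_t, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n_t)
  pts <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  list(points = pts, weights = w)   # weights sum to 4*pi
}

# Random symmetric positive tensor with FA capped; optionally axially
# symmetric (zeppelin).
random_tensor <- function(fa_max = 0.9, zeppelin = TRUE) {
  repeat {
    ev <- if (zeppelin) {
      dpar <- stats::runif(1, 1.0e-3, 2.5e-3)
      r <- stats::runif(1, 0.08, 1)
      c(dpar, r * dpar, r * dpar)
    } else {
      # eigenvalue ratios bounded below at 0.1 — the profile peakedness a
      # FA-0.9 zeppelin has; FA alone does not bound the smallest ratio
      l1 <- stats::runif(1, 1.0e-3, 2.5e-3)
      r3 <- stats::runif(1, 0.1, 1)
      r2 <- stats::runif(1, r3, 1)
      l1 * c(1, r2, r3)
    }
    md <- mean(ev)
    fa <- sqrt(1.5) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
    if (fa <= fa_max) break
  }
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  list(tensor = Q %*% diag(ev) %*% t(Q), evals = ev, e1 = Q[, 1L], fa = fa)
}

# Exact ADC of a tensor voxel along directions (mm^2/s).
tensor_adc <- function(dirs, tensor) {
  rowSums((dirs %*% tensor) * dirs)
}

# Noiseless single-voxel signal matrix for a tensor under a scheme.
tensor_signal <- function(tensor, scheme) {
  s <- numeric(length(scheme$bvals))
  s[scheme$b0_indices] <- 1
  di <- scheme$dwi_indices
  s[di] <- exp(-scheme$bvals[di] *
                 tensor_adc(scheme$bvecs[di, , drop = FALSE], tensor))
  matrix(s, nrow = 1L)
}

# Radial Gauss-Legendre integral of q^pw * exp(-a q^2) on [0, qmax(a)].
radial_weights <- function(a_min, n = 96L) {
  qmax <- sqrt(45 / a_min)
  pracma::gaussLegendre(n, 0, qmax)
}

# Brute-force generalized q-space moment for an angular diffusivity profile
# sampled on dense directions: integral over R^3 of |q|^gamma E(q).
bf_moment <- function(D_dense, gamma, tau, n_rad = 96L) {
  a <- 4 * pi^2 * tau * D_dense
  g <- radial_weights(min(a), n_rad)
  E <- exp(-outer(a, g$x^2))
  radw <- g$w * g$x^(gamma + 2)
  (4 * pi / length(D_dense)) * sum(E %*% radw)
}

# Brute-force 1D return-to-plane integral for a single diffusivity.
bf_rtpp <- function(D_axis, tau, n_rad = 200L) {
  g <- radial_weights(4 * pi^2 * tau * D_axis, n_rad)
  2 * sum(g$w * exp(-4 * pi^2 * tau * D_axis * g$x^2))
}

# Brute-force planar return-to-axis integral for a profile sampled on the
# equator ring.
bf_rtap <- function(D_ring, tau, n_rad = 96L) {
  a <- 4 * pi^2 * tau * D_ring
  g <- radial_weights(min(a), n_rad)
  E <- exp(-outer(a, g$x^2))
  (2 * pi / length(D_ring)) * sum(E %*% (g$w * g$x))
}

# Shared small fixtures --------------------------------------------------

test_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_scheme(61, 1000)
    cache
  }
})

small_atlas <- function() toy_atlas(c(8, 6, 2), 12L, margin = 0L)

null_cohort_spec <- function(seed, n = 50L) {
  cohort_spec(groups = c(HC = n, EM = n, CM = n), atlas = small_atlas(),
              scheme = test_scheme(), seed = seed)
}

effect_cohort_spec <- function(seed, n = 50L, df = -0.05, regions = 1:6) {
  cohort_spec(groups = c(HC = n, EM = n, CM = n), atlas = small_atlas(),
              offsets = list(EM = list(f = stats::setNames(
                rep(df, length(regions)), regions))),
              scheme = test_scheme(), seed = seed)
}
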