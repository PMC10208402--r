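# Apparent q-space metrics from a single shell under the mono-exponential
# model E(q u) = exp(-4 pi^2 tau q^2 D(u)), with 4 pi^2 tau q^2 = b at the
# acquired shell.  Every metric reduces to an angular average of a power of
# the apparent diffusivity D(u):
#   RTOP   = (4 pi tau)^{-3/2} <D^{-3/2}>_sphere
#   RTPP   = (4 pi tau D(e1))^{-1/2}
#   RTAP   = (4 pi tau)^{-1}   <D^{-1}>_equator perpendicular to e1
#   Ups^g  = 2 pi Gamma((g+3)/2) (4 pi^2 tau)^{-(g+3)/2} <D^{-(g+3)/2}>_sphere
# with qMSD = Ups^2, Ups^{1/2} the order-1/2 full moment, and Ups^0 = RTOP.
# The spherical harmonics are always fitted to the required *power* of D
# (transform-then-fit), so the spherical mean is exact up to the LS fit.

#' Configuration for apparent q-space metric estimation
#'
#' @param tau Effective diffusion time in seconds (default 0.070).
#' @param L Even SH order (default 6).
#' @param lambda Laplace-Beltrami penalty weight (default 0.006).
#' @param K Equator sample count for RTAP (default 64; exact for the default
#'   order-6 expansions for any K >= 16).
#' @param scale_anisotropy Apply the contrast scaling to APA/DiA
#'   (default TRUE).
#' @param epsilon Contrast exponent of the anisotropy scaling (default 0.4).
#' @param D_min,D_max Clipping window for apparent diffusivities in mm^2/s
#'   (defaults 1e-5 and 1e-2); bounds the negative powers.
#' @return A list of class `qspace_config`.
#' @export
qspace_config <- function(tau = 0.070, L = 6L, lambda = 0.006, K = 64L,
                          scale_anisotropy = TRUE, epsilon = 0.4,
                          D_min = 1e-5, D_max = 1e-2) {
  stopifnot(tau > 0, lambda >= 0, K >= 16L, epsilon > 0,
            D_min > 0, D_max > D_min)
  check_even_order(L)
  structure(list(tau = tau, L = as.integer(L), lambda = lambda,
                 K = as.integer(K), scale_anisotropy = scale_anisotropy,
                 epsilon = epsilon, D_min = D_min, D_max = D_max),
            class = "qspace_config")
}

#' Apparent diffusivity samples from a single-shell signal
#'
#' Computes \eqn{D(u) = -\log(S(u)/S_0)/b} for every diffusion direction and
#' clips to the `[D_min, D_max]` window; clip events are counted and
#' reported as a QC attribute.
#'
#' @inheritParams fit_dti
#' @param config A [qspace_config()] (supplies the clipping window).
#' @return A list of class `adc_field`: `D` (n_voxels x n_directions matrix,
#'   mm^2/s), `dirs` (n_directions x 3), `b` (shell b-value), `valid`
#'   (logical per voxel), `s0`, `att` (attenuation S/S0, for the propagator
#'   anisotropy), `clip` (counts of low/high clips).
#' @export
adc_from_signal <- function(signal, scheme = NULL, mask = NULL,
                            config = qspace_config()) {
  x <- as_signal_matrix(signal, scheme, mask)
  S <- x$signal; scheme <- x$scheme; mask <- x$mask
  validate_single_shell(scheme)
  s0 <- rowMeans(S[, scheme$b0_indices, drop = FALSE])
  valid <- mask & is.finite(s0) & s0 > 0
  di <- scheme$dwi_indices
  b <- scheme$shell_b
  D <- matrix(NA_real_, nrow(S), length(di))
  att <- matrix(NA_real_, nrow(S), length(di))
  if (any(valid)) {
    E <- S[valid, di, drop = FALSE] / s0[valid]
    E <- pmin(pmax(E, 1e-12), 1)
    Draw <- -log(E) / b
    att[valid, ] <- E
    D[valid, ] <- pmin(pmax(Draw, config$D_min), config$D_max)
  }
  nlow <- sum(D[valid, ] <= config$D_min, na.rm = TRUE)
  nhigh <- sum(D[valid, ] >= config$D_max, na.rm = TRUE)
  structure(list(D = D, dirs = scheme$bvecs[di, , drop = FALSE],
                 b = b, valid = valid, s0 = s0, att = att,
                 clip = c(low = nlow, high = nhigh,
                          total = length(di) * sum(valid))),
            class = "adc_field")
}

# Fit SH to a power of D for all valid voxels; returns coeff matrix
# (n_coeffs x n_valid) plus the valid index.
fit_adc_power <- function(adc, power, config) {
  B <- eval_sh_basis(adc$dirs, config$L)
  y <- t(adc$D[adc$valid, , drop = FALSE]^power)
  list(coeffs = sh_fit(y, B, config$lambda), valid = which(adc$valid))
}

fill_valid <- function(values, valid, n) {
  out <- rep(NA_real_, n)
  out[valid] <- values
  out
}

#' Return-to-origin probability (apparent, single shell)
#'
#' @param adc An [adc_from_signal()] field.
#' @param config A [qspace_config()].
#' @return Numeric vector per voxel, mm^-3; NA outside the valid mask.
#' @export
rtop <- function(adc, config = qspace_config()) {
  fit <- fit_adc_power(adc, -1.5, config)
  vals <- (4 * pi * config$tau)^(-1.5) * spherical_mean(fit$coeffs)
  fill_valid(vals, fit$valid, nrow(adc$D))
}

#' Generalized q-space moment of order gamma
#'
#' \eqn{\Upsilon^\gamma = 2\pi\,\Gamma((\gamma+3)/2)\,(4\pi^2\tau)^{-(\gamma+3)/2}
#' \langle D^{-(\gamma+3)/2}\rangle}; gamma = 2 is the q-space mean squared
#' displacement (qMSD) and gamma = 0 reduces exactly to RTOP.
#'
#' @inheritParams rtop
#' @param gamma Moment order, must exceed -3.
#' @export
generalized_moment <- function(adc, gamma, config = qspace_config()) {
  if (gamma <= -3) stop("moment order gamma must be greater than -3")
  ex <- (gamma + 3) / 2
  fit <- fit_adc_power(adc, -ex, config)
  vals <- 2 * pi * gamma(ex) * (4 * pi^2 * config$tau)^(-ex) *
    spherical_mean(fit$coeffs)
  fill_valid(vals, fit$valid, nrow(adc$D))
}

#' Return-to-plane probability (apparent, single shell)
#'
#' Evaluates the SH representation of D at the principal diffusion direction
#' e1 and returns \eqn{(4\pi\tau D(e_1))^{-1/2}}.
#'
#' @inheritParams rtop
#' @param e1 n x 3 matrix of principal directions (from [fit_dti()]).
#' @export
rtpp <- function(adc, e1, config = qspace_config()) {
  fit <- fit_adc_power(adc, 1, config)
  d_e1 <- point_eval_batch(fit$coeffs, e1[fit$valid, , drop = FALSE])
  d_e1 <- pmin(pmax(d_e1, config$D_min), config$D_max)
  fill_valid((4 * pi * config$tau * d_e1)^(-0.5), fit$valid, nrow(adc$D))
}

#' Return-to-axis probability (apparent, single shell)
#'
#' Averages the SH fit of D^-1 over the great circle orthogonal to e1 and
#' multiplies by \eqn{(4\pi\tau)^{-1}}.  The circle average is evaluated in
#' closed form via the Funk-Radon identity, which coincides with the sampled
#' mean of [eval_on_circle()] for any K >= 16 at the default order.
#'
#' @inheritParams rtpp
#' @export
rtap <- function(adc, e1, config = qspace_config()) {
  fit <- fit_adc_power(adc, -1, config)
  eq <- equator_mean_batch(fit$coeffs, e1[fit$valid, , drop = FALSE])
  eq <- pmax(eq, 1 / config$D_max)
  fill_valid(eq / (4 * pi * config$tau), fit$valid, nrow(adc$D))
}

#' Anisotropy contrast scaling
#'
#' Monotone map of the raw anisotropy index t in [0, 1] onto [0, 1]:
#' \eqn{\sigma_\epsilon(t) = t^{3\epsilon} / (1 - 3 t^\epsilon + 3 t^{2\epsilon})}.
#'
#' @param t Raw index values in [0, 1].
#' @param epsilon Contrast exponent (default 0.4).
#' @export
anisotropy_scaling <- function(t, epsilon = 0.4) {
  t <- pmin(1, pmax(0, t))
  te <- t^epsilon
  t^(3 * epsilon) / (1 - 3 * te + 3 * te^2)
}

# Raw anisotropy index from SH coefficients: sqrt(1 - c00^2 / total power).
raw_anisotropy <- function(coeffs) {
  pow <- colSums(coeffs^2)
  t <- sqrt(pmax(0, 1 - coeffs[1L, ]^2 / pow))
  t[pow <= 0 | !is.finite(pow)] <- 0
  pmin(1, t)
}

#' Apparent propagator anisotropy
#'
#' Fits SH to the attenuation E(u) = S(u)/S0 and measures how far it lies
#' from its closest isotropic counterpart:
#' raw index \eqn{t = \sqrt{1 - c_{00}^2 / \sum c_{lm}^2}}, optionally passed
#' through [anisotropy_scaling()].
#'
#' @inheritParams rtop
#' @export
apa <- function(adc, config = qspace_config()) {
  B <- eval_sh_basis(adc$dirs, config$L)
  C <- sh_fit(t(adc$att[adc$valid, , drop = FALSE]), B, config$lambda)
  t <- raw_anisotropy(C)
  if (config$scale_anisotropy) t <- anisotropy_scaling(t, config$epsilon)
  fill_valid(t, which(adc$valid), nrow(adc$D))
}

#' Diffusion anisotropy
#'
#' Same construction as [apa()] but applied to the apparent diffusivity
#' profile D(u) instead of the attenuation.
#'
#' @inheritParams rtop
#' @export
dia <- function(adc, config = qspace_config()) {
  fit <- fit_adc_power(adc, 1, config)
  t <- raw_anisotropy(fit$coeffs)
  if (config$scale_anisotropy) t <- anisotropy_scaling(t, config$epsilon)
  fill_valid(t, fit$valid, nrow(adc$D))
}

#' All seven apparent q-space metrics
#'
#' @inheritParams rtop
#' @param e1 Optional n x 3 principal directions; fitted with [fit_dti()]
#'   from `signal`/`scheme` when omitted.
#' @param signal,scheme,mask Used to compute `adc` (and `e1`) when `adc` is
#'   not supplied directly.
#' @return Matrix (n voxels x 7) with columns RTOP, RTPP, RTAP, APA, DiA,
#'   qMSD, U12.
#' @export
amura_metrics <- function(signal = NULL, scheme = NULL, mask = NULL,
                          adc = NULL, e1 = NULL,
                          config = qspace_config()) {
  if (is.null(adc)) {
    if (is.null(signal)) stop("either a signal or an adc_field is required")
    adc <- adc_from_signal(signal, scheme, mask, config)
  }
  if (is.null(e1)) {
    if (is.null(signal)) stop("e1 is required when no signal is given")
    e1 <- fit_dti(signal, scheme, mask)$e1
  }
  cbind(RTOP = rtop(adc, config),
        RTPP = rtpp(adc, e1, config),
        RTAP = rtap(adc, e1, config),
        APA = apa(adc, config),
        DiA = dia(adc, config),
        qMSD = generalized_moment(adc, 2, config),
        U12 = generalized_moment(adc, 0.5, config))
}

#' Metric name registry (fixed reporting order)
#' @return Character vector of the 11 metric names.
#' @export
metric_names <- function() {
  c("FA", "MD", "AD", "RD", "RTOP", "RTPP", "RTAP", "APA", "DiA",
    "qMSD", "U12")
}

#' All eleven diffusion metrics (4 DTI + 7 apparent q-space)
#'
#' The fit-stage workhorse: tensor scalars and apparent q-space metrics from
#' one single-shell acquisition, sharing a single tensor fit.
#'
#' @inheritParams fit_dti
#' @param config A [qspace_config()].
#' @return Matrix (n voxels x 11) in the fixed [metric_names()] order, with
#'   a `"clip"` attribute carrying the ADC clipping QC counts.
#' @export
compute_metric_maps <- function(signal, scheme = NULL, mask = NULL,
                                config = qspace_config()) {
  x <- as_signal_matrix(signal, scheme, mask)
  tf <- fit_dti(x$signal, x$scheme, x$mask)
  adc <- adc_from_signal(x$signal, x$scheme, x$mask, config)
  out <- cbind(dti_scalars(tf),
               amura_metrics(adc = adc, e1 = tf$e1, config = config))
  attr(out, "clip") <- adc$clip
  attr(out, "n_invalid") <- sum(x$mask & !adc$valid)
  out
}
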