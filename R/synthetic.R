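# Synthetic single-shell signals: two-compartment voxel model (zeppelin +
# free water), constant-FA / constant-MD signal families, and full
# three-group cohorts with region-wise injected effects and Rician noise.

#' Two-compartment voxel model parameters
#'
#' Signal model \eqn{S(b, u) = f\,Zp(b, d_\parallel, d_\perp) +
#' (1-f)\exp(-b D_0)} with a zeppelin (axially symmetric tensor) compartment
#' of volume fraction f and an isotropic free-water compartment.
#'
#' @param f Zeppelin volume fraction in [0, 1]; (1 - f) is the free-water
#'   fraction.
#' @param d_par,d_perp Parallel and perpendicular zeppelin diffusivities
#'   (mm^2/s), 0 < d_perp <= d_par.  Defaults 1.7e-3 / 0.3e-3, textbook
#'   healthy white-matter values.
#' @param mu Zeppelin axis (unit 3-vector).
#' @param D0 Free-water diffusivity (mm^2/s, default 3.0e-3, body
#'   temperature).
#' @return A list of class `voxel_params`.
#' @export
voxel_params <- function(f = 0.8, d_par = 1.7e-3, d_perp = 0.3e-3,
                         mu = c(0, 0, 1), D0 = 3.0e-3) {
  if (f < 0 || f > 1) stop("volume fraction f must lie in [0, 1], got ", f)
  if (d_perp <= 0 || d_perp > d_par)
    stop("need 0 < d_perp <= d_par, got d_perp = ", d_perp,
         ", d_par = ", d_par)
  if (D0 <= 0) stop("D0 must be positive")
  mu <- mu / sqrt(sum(mu^2))
  structure(list(f = f, d_par = d_par, d_perp = d_perp, mu = mu, D0 = D0),
            class = "voxel_params")
}

#' Zeppelin compartment attenuation
#'
#' \eqn{Zp(b, u) = \exp(-b\,(d_\perp + (d_\parallel - d_\perp)(u^T\mu)^2))}.
#'
#' @param b b-value (s/mm^2).
#' @param dirs Unit directions, n x 3.
#' @param d_par,d_perp Zeppelin diffusivities (mm^2/s).
#' @param mu Zeppelin axis (unit 3-vector).
#' @return Attenuation in (0, 1], one value per direction.
#' @export
zeppelin_signal <- function(b, dirs, d_par, d_perp, mu = c(0, 0, 1)) {
  dirs <- as_direction_matrix(dirs)
  mu <- mu / sqrt(sum(mu^2))
  ct2 <- (dirs %*% mu)[, 1L]^2
  exp(-b * (d_perp + (d_par - d_perp) * ct2))
}

#' Two-compartment signal attenuation
#'
#' @param b b-value (s/mm^2), scalar or one per direction.
#' @param dirs Unit directions, n x 3 (ignored for b = 0 entries).
#' @param params A [voxel_params()].
#' @return Attenuation per direction; equals 1 at b = 0.
#' @export
two_compartment_signal <- function(b, dirs, params) {
  stopifnot(inherits(params, "voxel_params"))
  zp <- zeppelin_signal(b, dirs, params$d_par, params$d_perp, params$mu)
  params$f * zp + (1 - params$f) * exp(-b * params$D0)
}

#' Deterministic well-spread diffusion directions
#'
#' Golden-spiral initialization on the hemisphere followed by a few
#' electrostatic-repulsion sweeps over antipodally symmetrized point pairs.
#' Fully deterministic for a given count.
#'
#' @param n Number of directions.
#' @param iterations Repulsion sweeps (default 80).
#' @return n x 3 matrix of unit vectors.
#' @export
uniform_directions <- function(n, iterations = 80L) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  p <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.05
  for (it in seq_len(iterations)) {
    force <- matrix(0, n, 3L)
    for (sgn in c(1, -1)) {
      d1 <- outer(p[, 1L], sgn * p[, 1L], "-")
      d2 <- outer(p[, 2L], sgn * p[, 2L], "-")
      d3 <- outer(p[, 3L], sgn * p[, 3L], "-")
      r2 <- d1^2 + d2^2 + d3^2
      diag(r2) <- Inf
      r2[r2 < 1e-12] <- Inf
      w <- 1 / (r2 * sqrt(r2))
      force <- force + cbind(rowSums(d1 * w), rowSums(d2 * w),
                             rowSums(d3 * w))
    }
    p <- p + step * force / max(1, max(abs(force)))
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

#' Single-shell synthetic acquisition scheme
#'
#' One baseline volume followed by `n_dirs` diffusion directions at a single
#' shell, mirroring a typical clinical DTI-type protocol.
#'
#' @param n_dirs Number of diffusion directions (default 61).
#' @param b Shell b-value in s/mm^2 (default 1000).
#' @return A [gradient_scheme()].
#' @export
synthetic_scheme <- function(n_dirs = 61L, b = 1000) {
  dirs <- uniform_directions(n_dirs)
  gradient_scheme(c(0, rep(b, n_dirs)), rbind(c(0, 0, 0), dirs))
}

# Noiseless single-voxel signal for a parameter set under a scheme.
params_signal <- function(params, scheme) {
  s <- numeric(length(scheme$bvals))
  s[scheme$b0_indices] <- 1
  di <- scheme$dwi_indices
  s[di] <- two_compartment_signal(scheme$shell_b,
                                  scheme$bvecs[di, , drop = FALSE], params)
  s
}

# Noiseless DTI scalars of one parameter set (FA, MD) — used by the family
# root-finders.
params_dti <- function(params, scheme) {
  s <- matrix(params_signal(params, scheme), nrow = 1L)
  sc <- dti_scalars(fit_dti(s, scheme))
  c(FA = unname(sc[1L, "FA"]), MD = unname(sc[1L, "MD"]))
}

solve_family <- function(f_grid, d_par, target, what, scheme, mu, D0) {
  # achieved-value tolerance: 1e-4 absolute for FA, 1e-4 relative for MD
  tol <- if (what == "FA") 1e-4 else 1e-4 * abs(target)
  lo <- 1e-5
  hi <- d_par * (1 - 1e-9)
  rows <- list(); params <- list(); infeasible <- numeric()
  for (f in f_grid) {
    obj <- function(dp)
      params_dti(voxel_params(f, d_par, dp, mu, D0), scheme)[[what]] - target
    olo <- obj(lo); ohi <- obj(hi)
    if (!is.finite(olo) || !is.finite(ohi) || olo * ohi > 0) {
      infeasible <- c(infeasible, f)
      next
    }
    dp <- stats::uniroot(obj, c(lo, hi), f.lower = olo, f.upper = ohi,
                         tol = 1e-13)$root
    pr <- voxel_params(f, d_par, dp, mu, D0)
    got <- params_dti(pr, scheme)
    if (abs(got[[what]] - target) > tol)
      stop("root refinement failed at f = ", f)
    params[[length(params) + 1L]] <- pr
    rows[[length(rows) + 1L]] <-
      data.frame(f = f, d_perp = dp, FA = got[["FA"]], MD = got[["MD"]])
  }
  if (length(infeasible))
    warning("no ", what, " = ", format(target), " solution for f in {",
            paste(format(infeasible), collapse = ", "),
            "}; these grid points are excluded")
  out <- list(params = params, table = do.call(rbind, rows),
              target = target, what = what, infeasible = infeasible,
              scheme = scheme)
  class(out) <- "signal_family"
  out
}

#' Constant-FA two-compartment signal family
#'
#' For each zeppelin fraction f on the grid, root-finds the perpendicular
#' diffusivity so the tensor fitted from the noiseless signal has the target
#' FA (within 1e-4).  By default the target is the FA of the f = 1 reference
#' case with `d_perp_ref`.
#'
#' @param f_grid Zeppelin fractions (default seq(0.3, 1, by = 0.05)).
#' @param d_par Fixed parallel diffusivity (mm^2/s).
#' @param d_perp_ref Perpendicular diffusivity of the f = 1 reference case;
#'   sets the default target.
#' @param target Target FA; overrides the reference case.
#' @param scheme Acquisition ([synthetic_scheme()] by default).
#' @param mu Zeppelin axis.
#' @param D0 Free-water diffusivity (mm^2/s).
#' @return A `signal_family`: solved `params` (list of [voxel_params()]),
#'   a `table` (f, d_perp, achieved FA and MD) and the infeasible grid
#'   points, if any, with a warning.
#' @export
constant_fa_family <- function(f_grid = seq(0.3, 1, by = 0.05),
                               d_par = 1.7e-3, d_perp_ref = 8.2e-4,
                               target = NULL, scheme = synthetic_scheme(),
                               mu = c(0, 0, 1), D0 = 3.0e-3) {
  if (is.null(target))
    target <- params_dti(voxel_params(1, d_par, d_perp_ref, mu, D0),
                         scheme)[["FA"]]
  solve_family(f_grid, d_par, target, "FA", scheme, mu, D0)
}

#' Constant-MD two-compartment signal family
#'
#' Analogue of [constant_fa_family()] holding the fitted MD at the target.
#' With physiological free-water diffusivity the construction only admits
#' solutions for high zeppelin fractions; infeasible grid points are
#' reported and excluded.
#'
#' @inheritParams constant_fa_family
#' @param d_perp_ref Perpendicular diffusivity of the f = 1 reference
#'   (default 0.3e-3 mm^2/s).
#' @param target Target MD (mm^2/s); overrides the reference case.
#' @export
constant_md_family <- function(f_grid = seq(0.3, 1, by = 0.05),
                               d_par = 1.7e-3, d_perp_ref = 3e-4,
                               target = NULL, scheme = synthetic_scheme(),
                               mu = c(0, 0, 1), D0 = 3.0e-3) {
  if (is.null(target))
    target <- params_dti(voxel_params(1, d_par, d_perp_ref, mu, D0),
                         scheme)[["MD"]]
  solve_family(f_grid, d_par, target, "MD", scheme, mu, D0)
}

#' Diffusion metrics along a signal family
#'
#' Computes all 11 metrics from the noiseless signal of every family member.
#'
#' @param family A `signal_family`.
#' @param config A [qspace_config()].
#' @return data.frame with f and one column per metric.
#' @export
family_metrics <- function(family, config = qspace_config()) {
  stopifnot(inherits(family, "signal_family"))
  sig <- t(vapply(family$params, params_signal,
                  numeric(length(family$scheme$bvals)), family$scheme))
  m <- compute_metric_maps(sig, family$scheme, config = config)
  data.frame(f = family$table$f, m, check.names = FALSE)
}

#' Min-max normalization of a curve
#'
#' @param x Numeric vector.
#' @return `(x - min) / (max - min)`; constant input maps to 0.
#' @export
normalize_curve <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1L]) / diff(rng)
}

#' Add Rician noise to magnitude signals
#'
#' Each sample becomes \eqn{\sqrt{(S + \sigma n_1)^2 + (\sigma n_2)^2}} with
#' independent standard normal n1, n2 and \eqn{\sigma = S_0 / SNR}.
#' Uses the current RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param S Numeric vector/matrix of noiseless signals.
#' @param snr Signal-to-noise ratio on the baseline (Inf = no noise).
#' @param s0 Baseline signal level (default 1).
#' @return Noisy signals, same shape as `S`.
#' @export
add_rician_noise <- function(S, snr, s0 = 1) {
  if (!is.finite(snr)) return(S)
  sigma <- s0 / snr
  n <- length(S)
  out <- sqrt((S + sigma * stats::rnorm(n))^2 + (sigma * stats::rnorm(n))^2)
  if (!is.null(dim(S))) dim(out) <- dim(S)
  out
}

#' Toy white-matter atlas of labeled block regions
#'
#' Cuboid regions on a 3D grid with a one-voxel background margin between
#' blocks, plus a one-voxel-thick skeleton (the central axial plane of each
#' region) standing in for a tract-skeleton sampling mask.
#'
#' @param dims Grid dimensions (default c(24, 24, 12)).
#' @param n_regions Number of regions (default 12, up to 48).
#' @param margin Background margin inside each block (default 1; use 0 for
#'   very small test grids).
#' @return A list of class `toy_atlas`: `labels` (3D integer array, 0 =
#'   background), `skeleton` (3D logical), `dims`, `n_regions`,
#'   `region_voxels` and `skeleton_voxels` (per-region linear indices).
#' @export
toy_atlas <- function(dims = c(24, 24, 12), n_regions = 12L, margin = 1L) {
  if (n_regions < 1L || n_regions > 48L)
    stop("n_regions must be between 1 and 48")
  nx <- ceiling(sqrt(n_regions))
  ny <- ceiling(n_regions / nx)
  bx <- dims[1L] %/% nx; by <- dims[2L] %/% ny; bz <- dims[3L]
  if (bx - 2 * margin < 1L || by - 2 * margin < 1L || bz - 2 * margin < 1L)
    stop("grid dims ", paste(dims, collapse = "x"), " too small for ",
         n_regions, " regions with margin ", margin)
  labels <- array(0L, dims)
  skeleton <- array(FALSE, dims)
  region_voxels <- vector("list", n_regions)
  skeleton_voxels <- vector("list", n_regions)
  r <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (r >= n_regions) break
    r <- r + 1L
    xs <- ((i - 1L) * bx + 1L + margin):(i * bx - margin)
    ys <- ((j - 1L) * by + 1L + margin):(j * by - margin)
    zs <- (1L + margin):(bz - margin)
    labels[xs, ys, zs] <- r
    zmid <- zs[ceiling(length(zs) / 2)]
    skeleton[xs, ys, zmid] <- TRUE
    idx <- which(labels == r)
    region_voxels[[r]] <- idx
    skeleton_voxels[[r]] <- which(labels == r & skeleton)
  }
  structure(list(labels = labels, skeleton = skeleton, dims = dims,
                 n_regions = n_regions, region_voxels = region_voxels,
                 skeleton_voxels = skeleton_voxels),
            class = "toy_atlas")
}

#' Specify a synthetic three-group cohort
#'
#' Each subject shares the atlas; voxel parameters per region are the region
#' baseline, plus the subject's group offset for that region, plus
#' subject-level variation (population scatter with SD `subject_sd`, and
#' Gaussian jitter with SD `offset_jitter_frac` times the group offset).
#' Signals follow [two_compartment_signal()] with magnitude Rician noise at
#' the stated baseline SNR.
#'
#' @param groups Named group sizes (default c(HC = 50, EM = 51, CM = 56),
#'   the usual healthy-control / episodic / chronic design).
#' @param atlas A [toy_atlas()].
#' @param baseline A [voxel_params()] shared by all regions.
#' @param offsets Effect injection: named list group -> parameter ->
#'   named numeric vector of offsets by region id, e.g.
#'   `list(EM = list(f = c("1" = -0.05)))`.
#' @param region_axes Optional n_regions x 3 matrix of zeppelin axes; drawn
#'   deterministically from `seed` when omitted.
#' @param subject_sd Named SDs of subject-level population variation
#'   (default c(f = 0.075), a realistic between-subject free-water scatter).
#' @param offset_jitter_frac SD of the offset jitter as a fraction of each
#'   group offset (default 0.1).
#' @param snr Baseline SNR of the Rician noise (default 30; Inf = none).
#' @param scheme Acquisition ([synthetic_scheme()] by default).
#' @param seed Integer; the whole cohort is a deterministic function of it.
#' @return A list of class `cohort_spec`, including the design table
#'   (`design`: subject_id, group).
#' @export
cohort_spec <- function(groups = c(HC = 50L, EM = 51L, CM = 56L),
                        atlas = toy_atlas(),
                        baseline = voxel_params(),
                        offsets = list(),
                        region_axes = NULL,
                        subject_sd = c(f = 0.075),
                        offset_jitter_frac = 0.1,
                        snr = 30,
                        scheme = synthetic_scheme(),
                        seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of sizes")
  if (any(groups < 1L)) stop("every group needs at least one subject")
  stopifnot(inherits(atlas, "toy_atlas"), inherits(baseline, "voxel_params"))
  for (g in names(offsets)) {
    if (!g %in% names(groups)) stop("offset group '", g, "' not in design")
    for (par in names(offsets[[g]])) {
      if (!par %in% c("f", "d_par", "d_perp", "D0"))
        stop("unknown offset parameter '", par, "'")
      off <- offsets[[g]][[par]]
      rids <- as.integer(names(off))
      if (any(is.na(rids)) || any(rids < 1L) || any(rids > atlas$n_regions))
        stop("offset region ids for ", g, "/", par, " out of range")
      trial <- unlist(baseline[par]) + off
      if (par == "f" && any(trial < 0 | trial > 1))
        stop("offsets drive f outside [0, 1] in group ", g)
      if (par %in% c("d_par", "d_perp", "D0") && any(trial <= 0))
        stop("offsets drive ", par, " non-positive in group ", g)
    }
  }
  if (is.null(region_axes)) {
    set.seed(seed %% .Machine$integer.max)
    region_axes <- matrix(stats::rnorm(3L * atlas$n_regions),
                          ncol = 3L)
    region_axes <- region_axes / sqrt(rowSums(region_axes^2))
  }
  sid <- sprintf("sub-%03d", seq_len(sum(groups)))
  design <- data.frame(
    subject_id = sid,
    group = factor(rep(names(groups), groups), levels = names(groups)))
  structure(list(groups = groups, atlas = atlas, baseline = baseline,
                 offsets = offsets, region_axes = region_axes,
                 subject_sd = subject_sd,
                 offset_jitter_frac = offset_jitter_frac,
                 snr = snr, scheme = scheme, seed = as.integer(seed),
                 design = design),
            class = "cohort_spec")
}

# Deterministic per-purpose seed schedule (all below 2^31).
seed_for <- function(base, a, b = 0L) {
  as.integer((abs(base) * 48271 + a * 97561 + b * 7919) %% 2147483629)
}

# Per-region voxel parameters of one subject (deterministic in spec$seed).
subject_region_params <- function(spec, s) {
  g <- as.character(spec$design$group[s])
  set.seed(seed_for(spec$seed, 11L, s))
  base <- spec$baseline
  out <- vector("list", spec$atlas$n_regions)
  for (r in seq_len(spec$atlas$n_regions)) {
    p <- list(f = base$f, d_par = base$d_par, d_perp = base$d_perp,
              D0 = base$D0)
    for (par in names(p)) {
      off <- 0
      goff <- spec$offsets[[g]][[par]]
      if (!is.null(goff) && as.character(r) %in% names(goff))
        off <- goff[[as.character(r)]]
      jit <- if (off != 0)
        stats::rnorm(1L, 0, abs(off) * spec$offset_jitter_frac) else 0
      pop <- if (par %in% names(spec$subject_sd))
        stats::rnorm(1L, 0, spec$subject_sd[[par]]) else 0
      p[[par]] <- p[[par]] + off + jit + pop
    }
    p$f <- min(1, max(0.01, p$f))
    p$d_par <- max(1e-5, p$d_par)
    p$d_perp <- min(max(1e-5, p$d_perp), p$d_par)
    out[[r]] <- voxel_params(p$f, p$d_par, p$d_perp,
                             spec$region_axes[r, ], p$D0)
  }
  out
}

# Full voxel grid signal of one subject (nvox x nvol), Rician noise applied.
subject_signal <- function(spec, s) {
  atlas <- spec$atlas
  nvol <- length(spec$scheme$bvals)
  nvox <- prod(atlas$dims)
  sig <- matrix(0, nvox, nvol)
  pars <- subject_region_params(spec, s)
  for (r in seq_len(atlas$n_regions)) {
    sig[atlas$region_voxels[[r]], ] <-
      matrix(params_signal(pars[[r]], spec$scheme),
             nrow = length(atlas$region_voxels[[r]]), ncol = nvol,
             byrow = TRUE)
  }
  set.seed(seed_for(spec$seed, 13L, s))
  inr <- atlas$labels != 0L
  sig[inr, ] <- add_rician_noise(sig[inr, , drop = FALSE], spec$snr)
  sig
}

#' Generate a synthetic cohort on disk
#'
#' Writes one 4D NIfTI per subject plus the shared gradient table, atlas
#' labels, skeleton mask, design table (TSV) and a YAML snapshot of the
#' generation parameters.  Byte-identical across runs for a fixed spec.
#'
#' @param spec A [cohort_spec()].
#' @param output_dir Output directory (created if missing).
#' @return Invisibly, the manifest of written files.
#' @export
generate_cohort <- function(spec, output_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- spec$atlas
  write_gradient_table(spec$scheme, file.path(output_dir, "cohort.bval"),
                       file.path(output_dir, "cohort.bvec"))
  write_scalar_map(array(as.numeric(atlas$labels), atlas$dims),
                   file.path(output_dir, "atlas.nii.gz"))
  write_scalar_map(array(as.numeric(atlas$skeleton), atlas$dims),
                   file.path(output_dir, "skeleton.nii.gz"))
  utils::write.table(spec$design, file.path(output_dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- character(nrow(spec$design))
  for (s in seq_len(nrow(spec$design))) {
    sig <- subject_signal(spec, s)
    files[s] <- file.path(output_dir,
                          paste0(spec$design$subject_id[s], "_dwi.nii.gz"))
    write_volume4d(array(sig, c(atlas$dims, ncol(sig))), files[s])
  }
  yaml::write_yaml(list(
    groups = as.list(spec$groups), seed = spec$seed, snr = spec$snr,
    n_regions = atlas$n_regions, dims = atlas$dims,
    baseline = spec$baseline[c("f", "d_par", "d_perp", "D0")],
    subject_sd = as.list(spec$subject_sd),
    offset_jitter_frac = spec$offset_jitter_frac),
    file.path(output_dir, "cohort.yaml"))
  invisible(list(dwi = files, design = file.path(output_dir, "design.tsv")))
}
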