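# Diffusion tensor estimation (OLS on log-signal) and the classical scalars.

#' Fit the diffusion tensor by ordinary least squares on log-signal
#'
#' Per voxel solves \eqn{\log(S/S_0) = -b\, g^T D g} for the six unique
#' tensor elements (plus a free log-S0 intercept).  The signal is clipped to
#' `[1e-6 * S0, S0]` before taking logs so noisy non-positive samples stay
#' finite, and eigenvalues are floored at `lambda_floor` so downstream
#' negative-power transforms remain finite.
#'
#' @param signal Either a `dwi_volume` from [read_dwi()] or a numeric matrix
#'   with one voxel per row and one column per volume.
#' @param scheme A [gradient_scheme()]; taken from the `dwi_volume` when
#'   omitted.
#' @param mask Logical vector/array selecting voxels to fit (default all).
#' @param lambda_floor Eigenvalue floor in mm^2/s (default 1e-7).
#' @return A list of class `tensor_field`: `tensor` (n x 6 matrix, columns
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `evals` (n x 3, descending), `e1`
#'   (n x 3 unit principal directions), `s0`, `valid` (logical; FALSE where
#'   S0 <= 0 or the voxel is outside the mask — scalars there are NA).
#' @export
fit_dti <- function(signal, scheme = NULL, mask = NULL, lambda_floor = 1e-7) {
  x <- as_signal_matrix(signal, scheme, mask)
  S <- x$signal; scheme <- x$scheme; mask <- x$mask
  n <- nrow(S)
  if (length(scheme$dwi_indices) < 6L)
    stop("tensor fit needs at least 6 distinct diffusion directions")
  s0 <- rowMeans(S[, scheme$b0_indices, drop = FALSE])
  valid <- mask & is.finite(s0) & s0 > 0
  di <- scheme$dwi_indices
  g <- scheme$bvecs
  b <- scheme$bvals
  # log-linear design over ALL volumes (the b = 0 rows identify the
  # intercept log-S0; on a single shell the diagonal columns alone would be
  # collinear with it)
  X <- cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3]))
  tensor <- matrix(NA_real_, n, 6L,
                   dimnames = list(NULL, c("Dxx", "Dyy", "Dzz",
                                           "Dxy", "Dxz", "Dyz")))
  if (any(valid)) {
    Sv <- S[valid, , drop = FALSE]
    s0v <- s0[valid]
    # clip diffusion-weighted samples into (0, S0] before the log
    Sv[, di] <- pmin(pmax(Sv[, di, drop = FALSE], 1e-6 * s0v), s0v)
    Sv[, scheme$b0_indices] <- pmax(Sv[, scheme$b0_indices, drop = FALSE],
                                    1e-6 * s0v)
    logS <- log(Sv)
    beta <- solve(crossprod(X), crossprod(X, t(logS)))
    tensor[valid, ] <- t(beta[-1L, , drop = FALSE])
  }
  eig <- sym3_eigen(tensor, lambda_floor)
  structure(list(tensor = tensor, evals = eig$evals, e1 = eig$e1,
                 s0 = s0, valid = valid, lambda_floor = lambda_floor),
            class = "tensor_field")
}

# Normalize signal input: returns list(signal = n x nvol matrix, scheme, mask)
as_signal_matrix <- function(signal, scheme, mask) {
  if (inherits(signal, "dwi_volume")) {
    if (is.null(scheme)) scheme <- signal$scheme
    if (is.null(mask)) mask <- signal$mask
    dm <- dim(signal$data)
    signal <- matrix(signal$data, nrow = prod(dm[1:3]), ncol = dm[4L])
  }
  if (is.null(scheme)) stop("a gradient scheme is required")
  signal <- as.matrix(signal)
  if (ncol(signal) != length(scheme$bvals))
    stop("signal has ", ncol(signal), " volumes but the scheme describes ",
         length(scheme$bvals))
  if (is.null(mask)) mask <- rep(TRUE, nrow(signal))
  mask <- as.logical(mask)
  if (length(mask) != nrow(signal))
    stop("grid mismatch: mask length ", length(mask), " vs ", nrow(signal),
         " voxels")
  list(signal = signal, scheme = scheme, mask = mask)
}

# Vectorized eigendecomposition of symmetric 3x3 tensors (n x 6 rows).
# Analytic trigonometric eigenvalues; principal eigenvector from the
# Cayley-Hamilton product (A - l2 I)(A - l3 I), whose columns span the l1
# eigenspace.  Rows with NA stay NA.  Eigenvalues floored and sorted
# descending.
sym3_eigen <- function(tensor, lambda_floor = 1e-7) {
  n <- nrow(tensor)
  evals <- matrix(NA_real_, n, 3L)
  e1 <- matrix(NA_real_, n, 3L)
  ok <- stats::complete.cases(tensor)
  if (!any(ok)) return(list(evals = evals, e1 = e1))
  Txx <- tensor[ok, 1L]; Tyy <- tensor[ok, 2L]; Tzz <- tensor[ok, 3L]
  Txy <- tensor[ok, 4L]; Txz <- tensor[ok, 5L]; Tyz <- tensor[ok, 6L]
  q <- (Txx + Tyy + Tzz) / 3
  p2 <- (Txx - q)^2 + (Tyy - q)^2 + (Tzz - q)^2 +
    2 * (Txy^2 + Txz^2 + Tyz^2)
  p <- sqrt(p2 / 6)
  iso <- p < 1e-14
  p[iso] <- 1
  bxx <- (Txx - q) / p; byy <- (Tyy - q) / p; bzz <- (Tzz - q) / p
  bxy <- Txy / p; bxz <- Txz / p; byz <- Tyz / p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  # principal eigenvector: M = (A - l2 I)(A - l3 I); pick largest column
  m11 <- (Txx - l2) * (Txx - l3) + Txy * Txy + Txz * Txz
  m21 <- Txy * (Txx - l3) + (Tyy - l2) * Txy + Tyz * Txz
  m31 <- Txz * (Txx - l3) + Tyz * Txy + (Tzz - l2) * Txz
  m12 <- (Txx - l2) * Txy + Txy * (Tyy - l3) + Txz * Tyz
  m22 <- Txy * Txy + (Tyy - l2) * (Tyy - l3) + Tyz * Tyz
  m32 <- Txz * Txy + Tyz * (Tyy - l3) + (Tzz - l2) * Tyz
  m13 <- (Txx - l2) * Txz + Txy * Tyz + Txz * (Tzz - l3)
  m23 <- Txy * Txz + (Tyy - l2) * Tyz + Tyz * (Tzz - l3)
  m33 <- Txz * Txz + Tyz * Tyz + (Tzz - l2) * (Tzz - l3)
  n1 <- m11^2 + m21^2 + m31^2
  n2 <- m12^2 + m22^2 + m32^2
  n3 <- m13^2 + m23^2 + m33^2
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  vx <- ifelse(pick == 1L, m11, ifelse(pick == 2L, m12, m13))
  vy <- ifelse(pick == 1L, m21, ifelse(pick == 2L, m22, m23))
  vz <- ifelse(pick == 1L, m31, ifelse(pick == 2L, m32, m33))
  nv <- sqrt(vx^2 + vy^2 + vz^2)
  degen <- iso | nv < 1e-30 | !is.finite(nv)
  vx[degen] <- 0; vy[degen] <- 0; vz[degen] <- 1; nv[degen] <- 1
  evals[ok, ] <- cbind(pmax(l1, lambda_floor), pmax(l2, lambda_floor),
                       pmax(l3, lambda_floor))
  e1[ok, ] <- cbind(vx / nv, vy / nv, vz / nv)
  list(evals = evals, e1 = e1)
}

#' Classical DTI scalars from a tensor field
#'
#' FA = sqrt(3/2) ||lambda - MD|| / ||lambda||, MD = mean eigenvalue,
#' AD = lambda1, RD = (lambda2 + lambda3)/2.  An all-zero tensor has FA 0.
#'
#' @param tf A `tensor_field` from [fit_dti()].
#' @return n x 4 matrix with columns FA, MD, AD, RD (FA dimensionless in
#'   [0, 1]; the rest mm^2/s).  Invalid voxels are NA.
#' @export
dti_scalars <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  ev <- tf$evals
  md <- rowMeans(ev)
  num <- sqrt((ev[, 1L] - md)^2 + (ev[, 2L] - md)^2 + (ev[, 3L] - md)^2)
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa <- pmin(1, pmax(0, fa))
  cbind(FA = fa, MD = md, AD = ev[, 1L], RD = (ev[, 2L] + ev[, 3L]) / 2)
}
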