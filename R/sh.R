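# Real symmetric spherical-harmonic engine.
#
# Basis convention (fixed, documented): real, antipodally symmetric
# (even degrees l only), orthonormal on the unit sphere.  For degree l and
# order m the basis function is
#   m = 0 : N_l0 P_l^0(cos theta)
#   m > 0 : sqrt(2) N_lm P_l^m(cos theta) cos(m phi)
#   m < 0 : sqrt(2) N_l|m| P_l^|m|(cos theta) sin(|m| phi)
# with N_lm = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!) and associated Legendre
# functions carrying the Condon-Shortley phase.  Coefficients are ordered by
# l ascending, m from -l to l; column 1 is always (0,0), the constant
# Y_00 = 1/(2 sqrt(pi)).

#' Number of coefficients of the even-degree real SH basis
#'
#' @param L Even maximum degree (non-negative integer).
#' @return Integer, \eqn{(L+1)(L+2)/2}.
#' @export
sh_basis_size <- function(L) {
  check_even_order(L)
  as.integer((L + 1L) * (L + 2L) / 2L)
}

check_even_order <- function(L) {
  if (length(L) != 1L || is.na(L) || L < 0 || L %% 2 != 0)
    stop("SH order L must be a single even non-negative integer, got: ", L)
  invisible(L)
}

#' Degree/order index table of the even-degree basis
#'
#' @param L Even maximum degree.
#' @return data.frame with columns `l` and `m`, one row per basis function,
#'   in the fixed column order of [eval_sh_basis()].
#' @export
sh_index_table <- function(L) {
  check_even_order(L)
  l <- unlist(lapply(seq(0L, L, by = 2L), function(li) rep(li, 2L * li + 1L)))
  m <- unlist(lapply(seq(0L, L, by = 2L), function(li) seq(-li, li)))
  data.frame(l = as.integer(l), m = as.integer(m))
}

# Associated Legendre functions P_l^m(x) for all l in 0..L and m in 0..l,
# vectorized over x, with Condon-Shortley phase.  Returns a list indexed by
# [l+1][m+1] of numeric vectors.  Standard stable recurrences:
#   P_m^m     = (-1)^m (2m-1)!! (1-x^2)^{m/2}
#   P_{m+1}^m = x (2m+1) P_m^m
#   (l-m) P_l^m = x (2l-1) P_{l-1}^m - (l+m-1) P_{l-2}^m
assoc_legendre_table <- function(L, x) {
  out <- vector("list", L + 1L)
  for (l in 0:L) out[[l + 1L]] <- vector("list", l + 1L)
  s <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:L) {
    pmm <- if (m == 0L) rep(1, length(x)) else
      (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * s^m
    out[[m + 1L]][[m + 1L]] <- pmm
    if (m < L) {
      pm1 <- x * (2 * m + 1) * pmm
      out[[m + 2L]][[m + 1L]] <- pm1
      if (m + 2L <= L) {
        pl2 <- pmm; pl1 <- pm1
        for (l in (m + 2L):L) {
          pl <- (x * (2 * l - 1) * pl1 - (l + m - 1) * pl2) / (l - m)
          out[[l + 1L]][[m + 1L]] <- pl
          pl2 <- pl1; pl1 <- pl
        }
      }
    }
  }
  out
}

#' Evaluate the real symmetric SH basis on a set of directions
#'
#' @param dirs Numeric matrix, one unit direction per row (n x 3).
#' @param L Even maximum degree (default 6).
#' @param check Check unit norms (default TRUE).
#' @return Design matrix `B` of size n x [sh_basis_size()]; attribute
#'   `"index"` holds the (l, m) table.
#' @export
eval_sh_basis <- function(dirs, L = 6L, check = TRUE) {
  check_even_order(L)
  dirs <- as_direction_matrix(dirs)
  if (check) {
    nn <- sqrt(rowSums(dirs^2))
    if (any(abs(nn - 1) > 1e-6))
      stop("directions must be unit vectors (max |norm - 1| = ",
           format(max(abs(nn - 1))), ")")
  }
  ct <- pmin(1, pmax(-1, dirs[, 3L]))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  plm <- assoc_legendre_table(L, ct)
  idx <- sh_index_table(L)
  B <- matrix(0, nrow = nrow(dirs), ncol = nrow(idx))
  for (j in seq_len(nrow(idx))) {
    l <- idx$l[j]; m <- idx$m[j]; am <- abs(m)
    nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    p <- plm[[l + 1L]][[am + 1L]]
    B[, j] <- if (m == 0L) nlm * p
    else if (m > 0L) sqrt(2) * nlm * p * cos(am * phi)
    else sqrt(2) * nlm * p * sin(am * phi)
  }
  attr(B, "index") <- idx
  B
}

as_direction_matrix <- function(dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3L)
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3L) stop("directions must be an n x 3 matrix")
  storage.mode(dirs) <- "double"
  dirs
}

#' Laplace-Beltrami penalty diagonal
#'
#' Diagonal entries \eqn{l^2 (l+1)^2} for each basis function; exactly 0 for
#' the constant term, so the spherical mean is never penalized directly.
#'
#' @param L Even maximum degree.
#' @return Numeric vector of length [sh_basis_size()].
#' @export
lb_penalty <- function(L) {
  idx <- sh_index_table(L)
  (idx$l * (idx$l + 1))^2
}

#' Penalized least-squares SH fit
#'
#' Solves \eqn{c = (B^T B + \lambda R)^{-1} B^T y} with the Laplace-Beltrami
#' penalty R = diag(l^2 (l+1)^2).  `y` may hold one spherical function per
#' column, so whole volumes are fitted with a single matrix product.
#'
#' @param y Numeric vector (one sample per direction) or matrix
#'   (n_dirs x n_functions).
#' @param B Design matrix from [eval_sh_basis()].
#' @param lambda Laplace-Beltrami weight (dimensionless, default 0.006).
#' @return Coefficient matrix (n_coeffs x n_functions) with the basis index
#'   attached; a vector input returns a 1-column matrix.
#' @export
sh_fit <- function(y, B, lambda = 0.006) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
  if (nrow(y) != nrow(B))
    stop("number of samples (", nrow(y), ") does not match design matrix rows (",
         nrow(B), ")")
  A <- crossprod(B) + diag(lambda * lb_penalty_from_B(B), ncol(B))
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12)
    stop("SH normal equations are ill-conditioned (condition number ~ ",
         format(1 / rc), "); use more directions or a larger penalty")
  C <- solve(A, crossprod(B, y))
  attr(C, "index") <- attr(B, "index")
  C
}

lb_penalty_from_B <- function(B) {
  idx <- attr(B, "index")
  if (is.null(idx)) stop("design matrix lacks its (l, m) index attribute")
  (idx$l * (idx$l + 1))^2
}

#' Evaluate an SH expansion on directions
#'
#' @param coeffs Coefficient matrix from [sh_fit()] (n_coeffs x n_functions).
#' @param dirs Unit directions (n x 3).
#' @return n x n_functions matrix of function values.
#' @export
sh_eval <- function(coeffs, dirs) {
  idx <- attr(coeffs, "index")
  if (is.null(idx)) stop("coefficients lack their (l, m) index attribute")
  L <- max(idx$l)
  eval_sh_basis(dirs, L) %*% coeffs
}

#' Spherical mean of an SH expansion
#'
#' The average of the represented function over the unit sphere,
#' \eqn{c_{00} / (2\sqrt{\pi})}.
#'
#' @param coeffs Coefficient matrix (n_coeffs x n_functions) or vector.
#' @return Numeric vector, one mean per function.
#' @export
spherical_mean <- function(coeffs) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, ncol = 1L)
  as.numeric(coeffs[1L, ] / (2 * sqrt(pi)))
}

#' Equally spaced points on the great circle orthogonal to an axis
#'
#' @param axis Unit 3-vector.
#' @param K Number of points (>= 16).
#' @return K x 3 matrix of unit vectors.
#' @export
circle_points <- function(axis, K = 64L) {
  if (K < 16L) stop("K must be at least 16")
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ea <- ref - sum(ref * axis) * axis
  ea <- ea / sqrt(sum(ea^2))
  eb <- c(axis[2L] * ea[3L] - axis[3L] * ea[2L],
          axis[3L] * ea[1L] - axis[1L] * ea[3L],
          axis[1L] * ea[2L] - axis[2L] * ea[1L])
  th <- 2 * pi * (seq_len(K) - 1L) / K
  cbind(cos(th) * ea[1L] + sin(th) * eb[1L],
        cos(th) * ea[2L] + sin(th) * eb[2L],
        cos(th) * ea[3L] + sin(th) * eb[3L])
}

#' Evaluate an SH expansion on the equator orthogonal to an axis
#'
#' Samples the function at `K` equally spaced points on the great circle
#' orthogonal to `axis`.  The trapezoidal mean of these samples integrates
#' trigonometric polynomials of degree < K exactly, so K >= 16 is exact for
#' the default degree-6 expansions.
#'
#' @inheritParams sh_eval
#' @param axis Unit 3-vector.
#' @param K Number of equator points (default 64).
#' @return K x n_functions matrix of samples.
#' @export
eval_on_circle <- function(coeffs, axis, K = 64L) {
  sh_eval(coeffs, circle_points(axis, K))
}

# Legendre polynomial values at zero, P_l(0), for the degrees of an index
# table (0 for odd l; (-1)^{l/2} (l-1)!! / l!! for even l).
legendre_at_zero <- function(l) {
  out <- numeric(length(l))
  for (i in seq_along(l)) {
    li <- l[i]
    out[i] <- if (li %% 2L == 1L) 0 else
      (-1)^(li / 2) * exp(lgamma(li + 1) - 2 * lgamma(li / 2 + 1)) / 2^li
  }
  out
}

# Batched equator means: one coefficient column and one axis per voxel.
# coeffs: n_coeffs x nvox; axes: nvox x 3.  Uses the Funk-Radon identity —
# the average of Y_lm over the great circle orthogonal to a is
# P_l(0) Y_lm(a) — so the mean is exact (it equals the K >= 16 sampled mean
# of eval_on_circle for degree <= 6 expansions) at the cost of one point
# evaluation per voxel.
equator_mean_batch <- function(coeffs, axes) {
  nvox <- ncol(coeffs)
  stopifnot(nrow(axes) == nvox)
  idx <- attr(coeffs, "index")
  scaled <- coeffs * legendre_at_zero(idx$l)
  attr(scaled, "index") <- idx
  point_eval_batch(scaled, axes)
}

# Batched point evaluation: value of each voxel's expansion at that voxel's
# own direction (used for D(e1)).  coeffs: n_coeffs x nvox; dirs: nvox x 3.
point_eval_batch <- function(coeffs, dirs) {
  idx <- attr(coeffs, "index")
  B <- eval_sh_basis(dirs, max(idx$l), check = FALSE)
  rowSums(B * t(coeffs))
}
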