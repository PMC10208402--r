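# Gradient tables and the single-shell acquisition contract.

#' Construct a gradient scheme
#'
#' A gradient scheme pairs one b-value (s/mm^2) and one direction per volume.
#' Volumes with b below `b0_threshold` are classified as baseline (b = 0);
#' all other directions are renormalized to exact unit norm.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs n x 3 matrix of gradient directions (image frame).
#' @param b0_threshold b-values below this are treated as b = 0
#'   (default 50 s/mm^2, robust to vendor jitter).
#' @return An object of class `gradient_scheme` with fields `bvals`, `bvecs`
#'   (unit rows for diffusion volumes, zero rows for baselines), `shell_b`
#'   (median non-zero b), `b0_indices`, `dwi_indices`, `b0_threshold`.
#' @export
gradient_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as_direction_matrix(bvecs)
  if (length(bvals) != nrow(bvecs))
    stop("gradient table mismatch: ", length(bvals), " b-values but ",
         nrow(bvecs), " directions")
  is_b0 <- bvals < b0_threshold
  if (!any(is_b0)) stop("scheme has no baseline (b = 0) volume")
  if (all(is_b0)) stop("scheme has no diffusion-weighted volume")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(!is_b0 & nrm < 1e-8))
    stop("all-zero gradient direction at non-zero b (volume ",
         paste(which(!is_b0 & nrm < 1e-8), collapse = ", "), ")")
  bvecs[is_b0, ] <- 0
  bvecs[!is_b0, ] <- bvecs[!is_b0, , drop = FALSE] / nrm[!is_b0]
  structure(list(
    bvals = bvals,
    bvecs = bvecs,
    shell_b = stats::median(bvals[!is_b0]),
    b0_indices = which(is_b0),
    dwi_indices = which(!is_b0),
    b0_threshold = b0_threshold
  ), class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", length(x$bvals), "volumes (",
      length(x$b0_indices), "baseline,", length(x$dwi_indices),
      "diffusion-weighted ), shell b ~", x$shell_b, "s/mm^2\n")
  invisible(x)
}

#' Read an FSL-dialect bval/bvec gradient table
#'
#' The bval file holds one whitespace-separated row of b-values; the bvec
#' file holds three rows (x, y, z components), one column per volume.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @inheritParams gradient_scheme
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  vecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(vecs) != 3L)
    stop("bvec file must have exactly three rows (x, y, z), found ", nrow(vecs))
  if (ncol(vecs) != length(bvals))
    stop("gradient table mismatch: ", length(bvals), " b-values but ",
         ncol(vecs), " direction columns")
  gradient_scheme(bvals, t(vecs), b0_threshold = b0_threshold)
}

#' Write an FSL-dialect bval/bvec gradient table
#'
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the scheme.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  vec_lines <- apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " "))
  writeLines(vec_lines, bvec_path)
  invisible(scheme)
}

#' Validate that a scheme is single-shell
#'
#' Passes when every non-zero b-value lies within `rel_tol` of the median
#' non-zero b-value; otherwise raises a multi-shell error naming the
#' offending values.
#'
#' @param scheme A [gradient_scheme()].
#' @param rel_tol Relative tolerance on the shell b-value (default 0.05,
#'   accepting scanner-reported per-volume jitter).
#' @return A list with `shell_b`, `n_directions`, `n_b0`.
#' @export
validate_single_shell <- function(scheme, rel_tol = 0.05) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$bvals[scheme$dwi_indices]
  med <- stats::median(b)
  off <- abs(b - med) > rel_tol * med
  if (any(off))
    stop("multi-shell acquisition detected: b-values {",
         paste(sort(unique(round(b[off]))), collapse = ", "),
         "} deviate more than ", rel_tol * 100,
         "% from the shell b = ", med, " s/mm^2")
  list(shell_b = med,
       n_directions = length(scheme$dwi_indices),
       n_b0 = length(scheme$b0_indices))
}
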