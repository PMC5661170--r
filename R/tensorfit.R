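# Per-voxel diffusion tensor estimation and derived scalar maps.
#
# Tensors are stored as 6-vectors (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s.
# Voxel coordinates are 0-based continuous voxel space throughout the
# package: voxel (i, j, k) (1-based array index) occupies the unit cube
# [i-1, i) x [j-1, j) x [k-1, k) and has its center at (i-0.5, j-0.5, k-0.5).

D6_NAMES <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")

# 6-vector -> symmetric 3x3
d6_to_mat <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

d6_from_mat <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda - mean)^2)) / sqrt(sum(lambda^2)),
#' clipped to \[0, 1\]. Slightly negative eigenvalues (noise) are clamped to
#' zero first; an all-zero tensor has FA 0 by convention.
#'
#' @param l1,l2,l3 Eigenvalue vectors (any order; recycled to common length).
#' @return Numeric vector of FA values in \[0, 1\].
#' @examples
#' compute_fa(1.7e-3, 0.3e-3, 0.3e-3)  # prolate, high FA
#' compute_fa(1, 1, 1)                 # isotropic -> 0
#' @export
compute_fa <- function(l1, l2, l3) {
  lam <- cbind(pmax(l1, 0), pmax(l2, 0), pmax(l3, 0))
  lbar <- rowMeans(lam)
  num <- rowSums((lam - lbar)^2)
  den <- rowSums(lam^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  pmin(pmax(fa, 0), 1)
}

# Eigen-decompose one 6-vector tensor; descending eigenvalues.
tensor_eigen <- function(d6) {
  e <- eigen(d6_to_mat(d6), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Principal diffusion direction of a tensor
#'
#' Unit eigenvector of the largest eigenvalue. The sign is arbitrary
#' (tensors are antipodally symmetric); tracking resolves it by continuity.
#' A near-degenerate leading pair (lambda1 - lambda2 < `tol`) is resolved
#' deterministically by the fixed-order symmetric eigensolver and flagged
#' via the `"degenerate"` attribute.
#'
#' @param d6 Length-6 tensor (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @param tol Degeneracy tolerance on the leading eigenvalue gap.
#' @return Unit 3-vector with logical attribute `degenerate`.
#' @export
principal_direction <- function(d6, tol = 1e-12) {
  e <- tensor_eigen(d6)
  v <- e$vectors[, 1]
  structure(v / sqrt(sum(v^2)),
            degenerate = (e$values[1] - e$values[2]) < tol)
}

# Rows of the diffusion design matrix: b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz)
diffusion_design <- function(gt) {
  g <- gt$bvecs
  gt$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                   2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                   2 * g[, 2] * g[, 3])
}

#' Fit diffusion tensors voxel-wise by log-linear least squares
#'
#' Ordinary least squares on log(S_i / S0) = -b_i g_i' D g_i per masked
#' voxel. Multiple b0 volumes are averaged into S0 before taking ratios;
#' nonpositive signals are clamped to `1e-6 * S0` before the log so the
#' fit stays defined on noisy data.
#'
#' @param dwi 4-D array (x, y, z, volume) of diffusion-weighted signals,
#'   volumes ordered as in `gt`.
#' @param gt A [gradient_table()].
#' @param mask Logical 3-D array of voxels to fit; default all voxels.
#' @param voxdim Voxel size in mm (length 3), default `c(1, 1, 1)`.
#' @return A `tensor_volume`: list with `D` (x, y, z, 6 array), `fa`,
#'   `e1` (x, y, z, 3 principal directions), `evals` (x, y, z, 3),
#'   `mask`, `voxdim`.
#' @export
fit_tensor <- function(dwi, gt, mask = NULL, voxdim = c(1, 1, 1)) {
  stopifnot(length(dim(dwi)) == 4)
  shape <- dim(dwi)[1:3]
  nvol <- dim(dwi)[4]
  if (nvol != length(gt$bvals))
    stop("number of volumes does not match gradient table", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, shape)
  stopifnot(all(dim(mask) == shape))

  nz <- gt$bvals > 0
  X <- diffusion_design(gt)[nz, , drop = FALSE]
  qx <- qr(X)
  if (qx$rank < 6)
    stop("gradient scheme is rank-deficient (rank ", qx$rank,
         " < 6): directions are collinear/coplanar", call. = FALSE)

  sig <- matrix(dwi, prod(shape), nvol)[as.vector(mask), , drop = FALSE]
  s0 <- rowMeans(sig[, !nz, drop = FALSE])
  if (any(s0 <= 0))
    stop("nonpositive b0 signal inside mask", call. = FALSE)
  s <- sig[, nz, drop = FALSE]
  s <- pmax(s, 1e-6 * s0)              # clamp before log
  y <- -log(s / s0)                     # n_voxel x n_dir
  # OLS for all voxels at once: D = (X'X)^{-1} X' y'
  d6 <- t(qr.coef(qx, t(y)))            # n_voxel x 6

  tensor_volume_from_d6(d6, mask, shape, voxdim)
}

# Assemble a tensor_volume from per-masked-voxel 6-vectors.
tensor_volume_from_d6 <- function(d6, mask, shape, voxdim) {
  nvox_all <- prod(shape)
  idx <- which(as.vector(mask))
  ev <- matrix(0, length(idx), 3)
  e1 <- matrix(0, length(idx), 3)
  for (r in seq_along(idx)) {
    e <- tensor_eigen(d6[r, ])
    ev[r, ] <- e$values
    e1[r, ] <- e$vectors[, 1]
  }
  fa_v <- compute_fa(ev[, 1], ev[, 2], ev[, 3])

  D <- array(0, c(shape, 6)); fa <- array(0, shape)
  evals <- array(0, c(shape, 3)); e1a <- array(0, c(shape, 3))
  for (c6 in 1:6) D[idx + (c6 - 1L) * nvox_all] <- d6[, c6]
  for (c3 in 1:3) {
    evals[idx + (c3 - 1L) * nvox_all] <- ev[, c3]
    e1a[idx + (c3 - 1L) * nvox_all] <- e1[, c3]
  }
  fa[idx] <- fa_v
  structure(list(D = D, fa = fa, e1 = e1a, evals = evals,
                 mask = mask, voxdim = voxdim),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat("<tensor_volume> ", paste(dim(x$fa), collapse = " x "),
      " voxels, ", sum(x$mask), " in mask, voxel size ",
      paste(x$voxdim, collapse = "x"), " mm\n", sep = "")
  cat("  FA in mask: median ", signif(stats::median(x$fa[x$mask]), 3),
      ", max ", signif(max(x$fa), 3), "\n", sep = "")
  invisible(x)
}
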