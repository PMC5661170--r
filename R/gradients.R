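#' Diffusion gradient table
#'
#' Bundles b-values and gradient directions for a diffusion acquisition.
#' Directions of nonzero-b volumes must be unit vectors; at least six
#' distinct nonzero-b directions and one b=0 volume are required for a
#' tensor fit to be identifiable.
#'
#' @param bvals Numeric vector of b-values in s/mm^2 (0 for b0 volumes).
#' @param bvecs Numeric matrix, one row per volume, 3 columns (x, y, z).
#'   Rows for b=0 volumes may be zero vectors.
#' @return An object of class `gradient_table`.
#' @examples
#' dirs <- rbind(diag(3), matrix(1 / sqrt(2), 3, 3) * (1 - diag(3)))
#' gt <- gradient_table(c(0, rep(1000, 6)), rbind(0, dirs))
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 || nrow(bvecs) != length(bvals))
    stop("bvecs must be an n x 3 matrix matching length(bvals)", call. = FALSE)
  if (any(bvals < 0)) stop("b-values must be nonnegative", call. = FALSE)
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("nonzero-b gradient directions must have unit norm", call. = FALSE)
  if (sum(!nz) < 1) stop("need at least one b=0 volume", call. = FALSE)
  if (sum(nz) < 6) stop("need at least six nonzero-b directions", call. = FALSE)
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_table")
}

#' Electrostatic-repulsion-style gradient scheme
#'
#' Generates a deterministic, approximately uniform set of unit gradient
#' directions on the half-sphere (golden-section spiral) plus b0 volumes —
#' a stand-in for a scanner's 32-direction single-shell scheme.
#'
#' @param n_dirs Number of diffusion-weighted directions (default 32).
#' @param bval Shell b-value in s/mm^2 (default 1000).
#' @param n_b0 Number of b=0 volumes (default 1).
#' @return A [gradient_table()].
#' @export
gradient_scheme <- function(n_dirs = 32, bval = 1000, n_b0 = 1) {
  k <- seq_len(n_dirs)
  z <- (2 * k - 1) / n_dirs - 1          # stratified in z
  z <- z * 0.99                           # keep off the poles
  phi <- k * pi * (3 - sqrt(5))           # golden angle
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  gradient_table(c(rep(0, n_b0), rep(bval, n_dirs)),
                 rbind(matrix(0, n_b0, 3), unit_rows(dirs)))
}

#' Read / write FSL-style bval and bvec text files
#'
#' `.bval` holds one row of b-values; `.bvec` holds three rows (x, y, z
#' components), one column per volume.
#'
#' @param gt A [gradient_table()].
#' @param bval_path,bvec_path File paths.
#' @return `read_bval_bvec` returns a [gradient_table()];
#'   `write_bval_bvec` returns the paths invisibly.
#' @export
write_bval_bvec <- function(gt, bval_path, bvec_path) {
  writeLines(paste(format(gt$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(gt$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  v <- as.matrix(read.table(bvec_path))
  gradient_table(bvals, t(v))
}
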