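# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Upper-triangle (i < j) index pairs of an n x n matrix, in fixed
# lexicographic order. Returned as a 2-column integer matrix.
upper_pairs <- function(n) {
  j <- rep.int(seq_len(n), pmax(seq_len(n) - 1L, 0L))
  i <- sequence(pmax(seq_len(n) - 1L, 0L))
  cbind(i = i, j = j)
}

# Flatten the upper triangle of a symmetric matrix in upper_pairs() order.
ut_values <- function(m) m[upper.tri(m)]

# Rebuild a symmetric zero-diagonal matrix from upper-triangle values.
ut_matrix <- function(values, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m + t(m)
}

stopifnot_symmetric <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop(name, " must be symmetric", call. = FALSE)
  if (any(m < 0)) stop(name, " must be nonnegative", call. = FALSE)
}

# Unit-normalize rows of a matrix of 3-vectors.
unit_rows <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v / nrm
}
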