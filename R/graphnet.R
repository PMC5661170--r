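# Sparsity-thresholded weighted graph metrics.
#
# Conventions (the Rubinov & Sporns weighted definitions, as used by the
# common connectome toolboxes): weights are first normalized by the matrix
# maximum so w-hat lies in [0, 1]; clustering is Onnela's geometric-mean
# triangle intensity; path lengths use edge lengths 1/w-hat; characteristic
# path length averages over reachable pairs only, while efficiencies count
# unreachable pairs as zero contribution (keeps everything finite on the
# sparse end of the threshold sweep).

#' Sparsity grid for the threshold sweep
#'
#' @param from,to,by Sparsity range and step; default 5% to 40% in 1% steps
#'   (36 thresholds).
#' @return Numeric vector of sparsity fractions.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.40, by = 0.01) {
  s <- seq(from, to, by)
  stopifnot(all(s > 0), all(s <= 1), all(diff(s) > 0))
  s
}

#' Threshold a weighted network at a fixed sparsity
#'
#' Keeps the `floor(S * N(N-1)/2)` largest-weight edges (weights retained,
#' not binarized) and zeroes the rest. Ties at the cutoff are broken by
#' lexicographic (i, j) order, so the result is deterministic. If the
#' network has fewer nonzero edges than requested, all are kept with a
#' warning.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @param S Sparsity fraction in (0, 1].
#' @return Thresholded weight matrix of the same shape.
#' @export
threshold_sparsity <- function(W, S) {
  stopifnot_symmetric(W, "W")
  if (S <= 0 || S > 1) stop("S must lie in (0, 1]", call. = FALSE)
  n <- nrow(W)
  w <- ut_values(W)
  k <- floor(S * n * (n - 1) / 2)
  nz <- sum(w > 0)
  if (k >= nz) {
    if (k > nz)
      warning("sparsity ", S, " requests ", k, " edges but only ", nz,
              " nonzero edges exist; keeping all", call. = FALSE)
    keep <- w > 0
  } else {
    ord <- order(-w, seq_along(w))   # weight desc, then fixed (i,j) order
    keep <- logical(length(w))
    keep[ord[seq_len(k)]] <- TRUE
  }
  out <- ut_matrix(ifelse(keep, w, 0), n)
  dimnames(out) <- dimnames(W)
  out
}

# Normalize weights by the matrix maximum; all-zero matrices pass through.
normalize_weights <- function(W) {
  mx <- max(W)
  if (mx > 0) W / mx else W
}

# igraph handle + pairwise distance matrix for a normalized weight matrix.
graph_distances <- function(Wn) {
  g <- igraph::graph_from_adjacency_matrix(Wn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(Wn), nrow(Wn))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

# Onnela weighted clustering coefficient per node, on normalized weights.
onnela_clustering <- function(Wn) {
  W13 <- Wn^(1 / 3)
  num <- diag(W13 %*% W13 %*% W13)
  k <- colSums(Wn > 0)
  ifelse(k >= 2, num / (k * (k - 1)), 0)
}

# Global efficiency of one weight matrix (already normalized scale).
eglob_of <- function(Wn) {
  n <- nrow(Wn)
  if (n < 2) return(0)
  d <- graph_distances(Wn)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global weighted network metrics
#'
#' Clustering coefficient `Cp` (mean Onnela weighted clustering), weighted
#' characteristic path length `Lp` (mean shortest path over reachable
#' pairs, edge length 1/w-hat), global efficiency `Eglob` (mean inverse
#' shortest path, unreachable pairs contribute 0) and local efficiency
#' `Eloc` (mean over nodes of the global efficiency of each node's
#' neighbor-induced subgraph). Weights are normalized by the matrix
#' maximum before anything is computed.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @return Named list with `Cp`, `Lp`, `Eglob`, `Eloc`.
#' @examples
#' W <- matrix(1, 4, 4); diag(W) <- 0   # K4 -> Cp = Lp = Eglob = 1
#' global_metrics(W)
#' @export
global_metrics <- function(W) {
  stopifnot_symmetric(W, "W")
  n <- nrow(W)
  if (max(W) == 0) {
    message("all-zero matrix: metrics defined as 0")
    return(list(Cp = 0, Lp = 0, Eglob = 0, Eloc = 0))
  }
  Wn <- normalize_weights(W)
  cp <- mean(onnela_clustering(Wn))

  d <- graph_distances(Wn)
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  lp <- if (length(fin)) mean(fin) else 0
  inv <- 1 / off
  inv[!is.finite(inv)] <- 0
  eglob <- mean(inv)

  eloc_i <- vapply(seq_len(n), function(i) {
    nb <- which(Wn[i, ] > 0)
    if (length(nb) < 2) return(0)
    eglob_of(Wn[nb, nb, drop = FALSE])
  }, numeric(1))

  list(Cp = cp, Lp = lp, Eglob = eglob, Eloc = mean(eloc_i))
}

#' Nodal efficiency
#'
#' `Enodal(i) = mean over j != i of 1 / d_ij` on max-normalized weights;
#' unreachable pairs contribute zero, so an isolated node scores 0.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @return Numeric vector, one value per node (named if `W` has dimnames).
#' @export
nodal_efficiency <- function(W) {
  stopifnot_symmetric(W, "W")
  n <- nrow(W)
  if (max(W) == 0) return(setNames(numeric(n), rownames(W)))
  d <- graph_distances(normalize_weights(W))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  setNames(rowSums(inv) / (n - 1), rownames(W))
}

#' Null-model configuration for small-world normalization
#'
#' @param n_null Number of rewired null networks (default 100).
#' @param swaps_per_edge Maslov-Sneppen double-edge-swap attempts per edge
#'   (default 10).
#' @param seed Seed for the null ensemble; `NULL` uses the current RNG
#'   stream.
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_null = 100, swaps_per_edge = 10,
                              seed = NULL) {
  stopifnot(n_null >= 1, swaps_per_edge >= 1)
  structure(list(n_null = as.integer(n_null),
                 swaps_per_edge = as.integer(swaps_per_edge), seed = seed),
            class = "null_model_config")
}

#' One degree-preserving rewired null network
#'
#' Maslov-Sneppen double-edge-swap rewiring of the graph's topology (via
#' igraph, `swaps_per_edge` swap attempts per edge) with the original
#' weight multiset randomly reassigned to the rewired edges. Preserves the
#' degree sequence exactly and the global weight multiset exactly. Uses
#' the current RNG stream.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @param swaps_per_edge Swap attempts per edge (default 10).
#' @return A weight matrix of the same size.
#' @export
rewired_null <- function(W, swaps_per_edge = 10) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  m <- igraph::ecount(g)
  if (m < 4)
    stop("graph too sparse to rewire (", m,
         " edges); use a higher sparsity threshold", call. = FALSE)
  rg <- igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * m))
  wsh <- sample(igraph::E(g)$weight)
  A <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  el <- igraph::as_edgelist(rg, names = FALSE)
  A[el] <- wsh
  A[el[, 2:1, drop = FALSE]] <- wsh
  A
}

#' Small-world parameters normalized by rewired null networks
#'
#' Generates degree-preserving Maslov-Sneppen rewired null networks with
#' the original weight multiset shuffled over the rewired topology, and
#' normalizes: `gamma = Cp / <Cp_null>`, `lambda = Lp / <Lp_null>`,
#' `sigma = gamma / lambda`. Deterministic for a fixed `cfg$seed`.
#'
#' @param W Symmetric nonnegative weight matrix (typically the output of
#'   [threshold_sparsity()]).
#' @param cfg A [null_model_config()].
#' @return Named list: `gamma`, `lambda`, `sigma`, `Cp`, `Lp`,
#'   `Cp_null`, `Lp_null` (null-ensemble means).
#' @export
normalized_smallworld <- function(W, cfg = null_model_config()) {
  stopifnot_symmetric(W, "W")
  Wn <- normalize_weights(W)
  g <- igraph::graph_from_adjacency_matrix(Wn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  m <- igraph::ecount(g)
  if (m < 4)
    stop("graph too sparse to rewire (", m,
         " edges); use a higher sparsity threshold", call. = FALSE)
  obs_cp <- mean(onnela_clustering(Wn))
  dobs <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  off <- dobs[upper.tri(dobs)]
  obs_lp <- mean(off[is.finite(off)])

  nulls <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_null), function(r) {
      A <- rewired_null(Wn, cfg$swaps_per_edge)
      cp <- mean(onnela_clustering(A))
      dn <- graph_distances(A)
      offn <- dn[upper.tri(dn)]
      lp <- mean(offn[is.finite(offn)])
      c(cp, lp)
    }, numeric(2))
  })
  cp_null <- mean(nulls[1, ]); lp_null <- mean(nulls[2, ])
  gamma <- obs_cp / cp_null
  lambda <- obs_lp / lp_null
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = obs_cp, Lp = obs_lp, Cp_null = cp_null, Lp_null = lp_null)
}

#' Area under a metric curve over the sparsity sweep
#'
#' Trapezoidal integral of one metric across the ordered sparsity grid,
#' the threshold-free summary used for group comparison.
#'
#' @param values Metric value at each threshold (no missing values).
#' @param s_values The matching sparsity grid (strictly increasing).
#' @return Scalar AUC.
#' @export
auc_over_thresholds <- function(values, s_values) {
  if (length(values) != length(s_values))
    stop("values and s_values lengths differ", call. = FALSE)
  if (length(values) < 2)
    stop("need at least two thresholds for an AUC", call. = FALSE)
  if (anyNA(values)) stop("missing metric values", call. = FALSE)
  stopifnot(all(diff(s_values) > 0))
  sum(diff(s_values) * (head(values, -1) + values[-1]) / 2)
}

#' Full metric sweep across sparsity thresholds
#'
#' Thresholds one connectome at every sparsity in the grid and computes the
#' global metrics, optionally the small-world normalization (when `nulls`
#' is given) and nodal efficiency, plus the AUC of every curve.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @param s_values Sparsity grid, default [sparsity_grid()].
#' @param nulls A [null_model_config()] to add gamma/lambda/sigma, or
#'   `NULL` to skip the null-model normalization.
#' @param nodal If `TRUE`, also compute nodal efficiency per threshold.
#' @return List: `global` (data.frame S x metric), `auc` (named vector),
#'   and when requested `nodal` (threshold x node matrix) and `nodal_auc`.
#' @export
metric_sweep <- function(W, s_values = sparsity_grid(), nulls = NULL,
                         nodal = FALSE) {
  rows <- vector("list", length(s_values))
  nodal_m <- if (nodal) matrix(0, length(s_values), nrow(W)) else NULL
  for (t in seq_along(s_values)) {
    Wt <- threshold_sparsity(W, s_values[t])
    gm <- global_metrics(Wt)
    row <- data.frame(S = s_values[t], Cp = gm$Cp, Lp = gm$Lp,
                      Eglob = gm$Eglob, Eloc = gm$Eloc)
    if (!is.null(nulls)) {
      cfg <- nulls
      if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + t   # per-threshold stream
      sw <- normalized_smallworld(Wt, cfg)
      row$gamma <- sw$gamma; row$lambda <- sw$lambda; row$sigma <- sw$sigma
    }
    rows[[t]] <- row
    if (nodal) nodal_m[t, ] <- nodal_efficiency(Wt)
  }
  global <- do.call(rbind, rows)
  metric_cols <- setdiff(names(global), "S")
  auc <- vapply(metric_cols, function(mc)
    auc_over_thresholds(global[[mc]], s_values), numeric(1))
  out <- list(global = global, auc = auc)
  if (nodal) {
    colnames(nodal_m) <- rownames(W)
    out$nodal <- nodal_m
    out$nodal_auc <- apply(nodal_m, 2, auc_over_thresholds,
                           s_values = s_values)
  }
  out
}
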