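# Network-based statistic: edge-wise two-sample t-maps, suprathreshold
# connected components, and permutation-based family-wise-error-corrected
# component p-values (component statistic: extent, i.e. edge count).

# Extract the subjects x upper-triangle-edges value matrix from a cohort
# matrix stack.
edge_value_matrix <- function(mats) {
  stopifnot(length(dim(mats)) == 3)
  n <- dim(mats)[1]
  ns <- dim(mats)[3]
  ut <- upper.tri(matrix(0, n, n))
  t(apply(mats, 3, function(m) m[ut]))[seq_len(ns), , drop = FALSE]
}

# Pooled-variance two-sample t for every column of E (subjects x edges).
# g1/g2 are row index vectors. Columns with zero pooled variance get NA.
col_tstats <- function(E, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- colMeans(E[g1, , drop = FALSE])
  m2 <- colMeans(E[g2, , drop = FALSE])
  v1 <- (colMeans(E[g1, , drop = FALSE]^2) - m1^2) * n1 / (n1 - 1)
  v2 <- (colMeans(E[g2, , drop = FALSE]^2) - m2^2) * n2 / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se <= 0 | !is.finite(t)] <- NA_real_
  t
}

#' Edge-wise two-sample t-statistics
#'
#' Pooled-variance two-sample t per region pair, testing equality of mean
#' connectivity between the two groups (zeros are ordinary values). The
#' contrast is group1 minus group2 in the order of `levels(factor(group))`
#' unless `ref` names the first group. Edges with zero pooled variance
#' (e.g. absent in every subject) are undefined (`NA`) and excluded from
#' thresholding downstream.
#'
#' @param mats n x n x n_subjects array of connectivity matrices (or a
#'   `cohort`, whose manifest supplies `group`).
#' @param group Two-level group labels, one per subject.
#' @param ref Optional label to use as group1 of the contrast.
#' @return Symmetric matrix of t values (`NA` where undefined), with
#'   attributes `df`, `groups`.
#' @export
edge_tstats <- function(mats, group = NULL, ref = NULL) {
  if (inherits(mats, "cohort")) {
    if (is.null(group)) group <- mats$manifest$group
    mats <- mats$matrices
  }
  g <- as.character(group)
  lev <- sort(unique(g))
  # patient/control cohorts default to the patient-minus-control contrast,
  # so "decrease" reads as patients below controls
  if (is.null(ref) && setequal(lev, c("control", "patient")))
    ref <- "patient"
  if (!is.null(ref)) {
    if (!ref %in% lev) stop("ref is not a group label", call. = FALSE)
    lev <- c(ref, setdiff(lev, ref))
  }
  if (length(lev) != 2)
    stop("exactly two groups required, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  g1 <- which(g == lev[1]); g2 <- which(g == lev[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least two subjects", call. = FALSE)
  n <- dim(mats)[1]
  E <- edge_value_matrix(mats)
  tvec <- col_tstats(E, g1, g2)
  tm <- ut_matrix(ifelse(is.na(tvec), 0, tvec), n)
  tm[ut_matrix(as.numeric(is.na(tvec)), n) > 0] <- NA
  dimnames(tm) <- dimnames(mats)[1:2]
  structure(tm, df = length(g) - 2L, groups = lev)
}

# Maximal connected components of a suprathreshold edge set, by union-find.
# edge_idx: indices into the upper-triangle order; pairs: upper_pairs(n).
# Returns list of integer vectors of edge indices, largest first.
edge_components <- function(edge_idx, pairs) {
  if (length(edge_idx) == 0) return(list())
  ei <- pairs[edge_idx, 1]; ej <- pairs[edge_idx, 2]
  nodes <- sort(unique(c(ei, ej)))
  parent <- seq_along(nodes)
  id <- function(v) match(v, nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ii <- id(ei); jj <- id(ej)
  for (e in seq_along(ii)) {
    ri <- find(ii[e]); rj <- find(jj[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ii, find, integer(1))
  comps <- split(edge_idx, roots)
  comps[order(-lengths(comps))]
}

#' Suprathreshold connected components of a t-matrix
#'
#' Binarizes edges whose t exceeds the threshold in the requested
#' direction (`"decrease"`: t < -threshold, i.e. group1 below group2;
#' `"increase"`: t > threshold) and returns the connected components of
#' the resulting graph, largest extent first. Undefined (`NA`) edges are
#' never suprathreshold.
#'
#' @param tmat Symmetric t matrix from [edge_tstats()].
#' @param t_threshold Positive cluster-forming threshold (default 2.1).
#' @param direction `"decrease"` or `"increase"`.
#' @return List of components, each a list with `edges` (k x 2 node
#'   indices), `nodes`, `extent`, and `codes` (when `tmat` has dimnames).
#' @export
suprathreshold_components <- function(tmat, t_threshold = 2.1,
                                      direction = c("decrease",
                                                    "increase")) {
  direction <- match.arg(direction)
  stopifnot(t_threshold > 0)
  n <- nrow(tmat)
  tv <- ut_values(tmat)
  supra <- which(!is.na(tv) &
                   if (direction == "decrease") tv < -t_threshold
                   else tv > t_threshold)
  pairs <- upper_pairs(n)
  comps <- edge_components(supra, pairs)
  lapply(comps, function(ce) {
    ed <- pairs[ce, , drop = FALSE]
    out <- list(edges = ed, nodes = sort(unique(as.vector(ed))),
                extent = nrow(ed))
    if (!is.null(rownames(tmat)))
      out$codes <- paste(rownames(tmat)[ed[, 1]],
                         rownames(tmat)[ed[, 2]], sep = "-")
    out
  })
}

#' Network-based statistic with permutation FWE correction
#'
#' Computes observed suprathreshold components, then permutes group labels
#' `n_perm` times, recording the maximal component extent of each
#' permutation's t-map thresholded the same way. The corrected p of an
#' observed component of extent k is `(1 + #permutations with max extent
#' >= k) / (n_perm + 1)`. With `direction = "both"`, the decrease and
#' increase contrasts are run as two separate one-sided analyses.
#'
#' @param mats n x n x n_subjects array (or a `cohort`).
#' @param group Two-level labels, one per subject (taken from the cohort
#'   manifest when omitted).
#' @param t_threshold Cluster-forming t threshold (default 2.1).
#' @param n_perm Number of permutations (default 5000).
#' @param direction `"decrease"`, `"increase"`, or `"both"`.
#' @param alpha Significance level for flagging components (default 0.05).
#' @param seed Seed making the permutation set reproducible.
#' @param ref Optional label for group1 of the contrast (see
#'   [edge_tstats()]).
#' @return An `nbs_result`: list with `components` (each with edges,
#'   nodes, extent, direction, `p_fwe`, `significant`), `tmat`,
#'   `null_max_extent` (per direction), and the call configuration.
#' @export
nbs_fwe <- function(mats, group = NULL, t_threshold = 2.1, n_perm = 5000,
                    direction = c("decrease", "increase", "both"),
                    alpha = 0.05, seed = NULL, ref = NULL) {
  direction <- match.arg(direction)
  if (inherits(mats, "cohort")) {
    if (is.null(group)) group <- mats$manifest$group
    mats <- mats$matrices
  }
  g <- as.character(group)
  tmat <- edge_tstats(mats, g, ref = ref)
  lev <- attr(tmat, "groups")
  g1 <- which(g == lev[1]); g2 <- which(g == lev[2])
  n1 <- length(g1)
  ns <- length(g)
  if (choose(ns, n1) < 2)
    stop("group sizes too small for label permutation", call. = FALSE)
  n <- dim(mats)[1]
  pairs <- upper_pairs(n)
  E <- edge_value_matrix(mats)

  dirs <- if (direction == "both") c("decrease", "increase") else direction
  observed <- list()
  for (d in dirs) {
    cs <- suprathreshold_components(tmat, t_threshold, d)
    for (cmp in cs) { cmp$direction <- d; observed <- c(observed, list(cmp)) }
  }

  max_extent <- function(tvec, d) {
    supra <- which(!is.na(tvec) &
                     if (d == "decrease") tvec < -t_threshold
                     else tvec > t_threshold)
    if (length(supra) == 0) return(0L)
    max(lengths(edge_components(supra, pairs)))
  }

  null_max <- with_seed(seed, {
    sapply(seq_len(n_perm), function(p) {
      pg1 <- sample(ns, n1)
      tv <- col_tstats(E, pg1, setdiff(seq_len(ns), pg1))
      vapply(dirs, function(d) max_extent(tv, d), integer(1))
    })
  })
  null_max <- matrix(null_max, nrow = length(dirs),
                     dimnames = list(dirs, NULL))

  components <- lapply(observed, function(cmp) {
    nm <- null_max[cmp$direction, ]
    cmp$p_fwe <- (1 + sum(nm >= cmp$extent)) / (n_perm + 1)
    cmp$significant <- cmp$p_fwe < alpha
    cmp
  })

  structure(list(components = components, tmat = tmat,
                 null_max_extent = null_max,
                 config = list(t_threshold = t_threshold, n_perm = n_perm,
                               direction = direction, alpha = alpha,
                               seed = seed, groups = lev)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cfg <- x$config
  cat("<nbs_result> contrast ", cfg$groups[1], " vs ", cfg$groups[2],
      ", |t| > ", cfg$t_threshold, ", ", cfg$n_perm, " permutations\n",
      sep = "")
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
    return(invisible(x))
  }
  for (cmp in x$components)
    cat(sprintf("  %s component: %d edges / %d nodes, p_fwe = %.4g%s\n",
                cmp$direction, cmp$extent, length(cmp$nodes), cmp$p_fwe,
                if (cmp$significant) " *" else ""))
  invisible(x)
}
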