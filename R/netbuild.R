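# Connectome construction: map streamlines onto an atlas parcellation and
# weight each region pair by fiber number times mean FA along the bundle,
# w_ij = FN_ij * FA_ij, zeroing edges supported by fewer than `min_fn`
# streamlines.

#' Atlas parcellation
#'
#' @param labels Integer 3-D array; 0 = background, 1..n_regions = regions.
#' @param codes Character vector of region codes (one per region index);
#'   defaults to the 90-region table of [aal90_regions()].
#' @return A `parcellation` list.
#' @export
parcellation <- function(labels, codes = aal90_regions()$code) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (min(labels) < 0 || max(labels) > length(codes))
    stop("labels must lie in 0..", length(codes), call. = FALSE)
  structure(list(labels = labels, codes = codes), class = "parcellation")
}

#' Assign a streamline to a region pair by its endpoints
#'
#' Looks up the atlas label of the voxel containing each terminal point.
#' The pair (i, j), i < j, is returned only when both endpoints fall in
#' distinct nonzero regions; background endpoints and intra-region
#' (self-connection) streamlines yield `NULL`.
#'
#' @param s A streamline (list with `points` in 0-based voxel coordinates).
#' @param parc A [parcellation()].
#' @return Integer vector `c(i, j)` with i < j, or `NULL`.
#' @export
assign_endpoints <- function(s, parc) {
  pts <- s$points
  ends <- pts[c(1, nrow(pts)), , drop = FALSE]
  vox <- floor(ends) + 1L              # to 1-based array index
  shape <- dim(parc$labels)
  # points exactly on the upper volume face belong to the last voxel
  shape_m <- matrix(shape, 2, 3, byrow = TRUE)
  on_face <- abs(ends - shape_m) < 1e-9
  vox[on_face] <- shape_m[on_face]
  if (any(vox < 1L) || any(vox[, 1] > shape[1]) ||
      any(vox[, 2] > shape[2]) || any(vox[, 3] > shape[3])) return(NULL)
  l1 <- parc$labels[vox[1, 1], vox[1, 2], vox[1, 3]]
  l2 <- parc$labels[vox[2, 1], vox[2, 2], vox[2, 3]]
  if (l1 == 0L || l2 == 0L || l1 == l2) return(NULL)
  c(min(l1, l2), max(l1, l2))
}

#' Build a weighted structural connectome from streamlines
#'
#' For each region pair, FN is the number of streamlines whose two endpoints
#' fall in the pair, and FA is the mean fractional anisotropy over all voxel
#' samples traversed by those streamlines (samples pooled across
#' streamlines, so shared voxels are counted once per streamline). The edge
#' weight is `w = FN * FA`; pairs with FN below `min_fn` are zeroed to
#' suppress spurious connections.
#'
#' @param streamlines A `streamline_set` from [fact_track()] (or a plain
#'   list of streamlines).
#' @param parc A [parcellation()].
#' @param fa_map 3-D FA array aligned with the label volume.
#' @param min_fn Minimum streamline count for an edge to survive
#'   (default 3; the filter is strict: FN < min_fn is zeroed, FN = min_fn
#'   kept).
#' @param fa_pooling `"voxel"` (default) pools per-voxel FA samples across
#'   all connecting streamlines; `"streamline"` averages each streamline's
#'   mean FA, weighting streamlines equally.
#' @return A `connectome`: list with `W` (n x n symmetric weight matrix,
#'   region codes as dimnames), `edges` (data.frame i, j, code_i, code_j,
#'   FN, meanFA, w — all pairs with FN > 0, pre-filter), `n_streamlines`,
#'   `n_unassigned` (background or intra-region).
#' @export
build_connectome <- function(streamlines, parc, fa_map, min_fn = 3,
                             fa_pooling = c("voxel", "streamline")) {
  fa_pooling <- match.arg(fa_pooling)
  stopifnot(inherits(parc, "parcellation"))
  if (!all(dim(fa_map) == dim(parc$labels)))
    stop("FA map and label volume shapes differ", call. = FALSE)
  n <- length(parc$codes)
  shape <- dim(fa_map)

  fn <- matrix(0L, n, n)
  fa_sum <- matrix(0, n, n)     # pooled FA sample sum (or per-track means)
  fa_cnt <- matrix(0, n, n)
  n_unassigned <- 0L
  for (s in streamlines) {
    pair <- assign_endpoints(s, parc)
    if (is.null(pair)) { n_unassigned <- n_unassigned + 1L; next }
    i <- pair[1]; j <- pair[2]
    vox <- streamline_voxels(s) + 1L
    ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
          vox[, 2] >= 1 & vox[, 2] <= shape[2] &
          vox[, 3] >= 1 & vox[, 3] <= shape[3]
    vox <- vox[ok, , drop = FALSE]
    fas <- fa_map[vox]
    fn[i, j] <- fn[i, j] + 1L
    if (fa_pooling == "voxel") {
      fa_sum[i, j] <- fa_sum[i, j] + sum(fas)
      fa_cnt[i, j] <- fa_cnt[i, j] + length(fas)
    } else {
      fa_sum[i, j] <- fa_sum[i, j] + mean(fas)
      fa_cnt[i, j] <- fa_cnt[i, j] + 1
    }
  }

  has <- which(fn > 0, arr.ind = TRUE)
  mean_fa <- ifelse(fa_cnt > 0, fa_sum / pmax(fa_cnt, 1), 0)
  edges <- data.frame(
    i = has[, 1], j = has[, 2],
    code_i = parc$codes[has[, 1]], code_j = parc$codes[has[, 2]],
    FN = fn[has], meanFA = mean_fa[has],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  edges$w <- edges$FN * edges$meanFA

  W <- matrix(0, n, n, dimnames = list(parc$codes, parc$codes))
  keep <- edges$FN >= min_fn
  W[cbind(edges$i[keep], edges$j[keep])] <- edges$w[keep]
  W <- W + t(W)

  structure(list(W = W, edges = edges,
                 n_streamlines = length(streamlines),
                 n_unassigned = n_unassigned, min_fn = min_fn),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$W), " nodes, ",
      sum(x$W[upper.tri(x$W)] > 0), " edges (FN >= ", x$min_fn, "), ",
      x$n_streamlines, " streamlines (", x$n_unassigned, " unassigned)\n",
      sep = "")
  invisible(x)
}
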