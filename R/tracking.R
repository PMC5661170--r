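# Deterministic FACT streamline tractography.
#
# FACT (fiber assignment by continuous tracking) propagates a trajectory
# along each voxel's principal diffusion direction until it crosses into
# the next voxel, where the direction is updated. Tracking stops on
# entering a voxel whose FA falls below `fa_threshold` or whose direction
# turns by more than `angle_threshold` degrees, or on leaving the volume.

#' Tracking configuration
#'
#' @param fa_threshold Stop (and seed-gate) FA value; voxels below it
#'   terminate tracks and never seed. Default 0.15.
#' @param angle_threshold Maximum turning angle in degrees between the
#'   directions of consecutive voxels along a track. Default 45.
#' @param min_points Minimum number of points for a streamline to be kept
#'   (default 3, about two voxel transits; suppresses single-voxel debris).
#' @param max_steps Safety cap on voxel transits per half-track.
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(fa_threshold = 0.15, angle_threshold = 45,
                            min_points = 3, max_steps = 10000) {
  stopifnot(fa_threshold >= 0, fa_threshold <= 1,
            angle_threshold > 0, angle_threshold < 90, min_points >= 2)
  structure(list(fa_threshold = fa_threshold,
                 angle_threshold = angle_threshold,
                 min_points = min_points, max_steps = max_steps),
            class = "tracking_config")
}

# Propagate one half-track from point p0 in voxel vox0 along direction d0.
# Returns the list of successive voxel-boundary exit points (excluding p0).
half_track <- function(p0, vox0, d0, fa_v, e1_m, shape, cfg, cos_thr) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  pts <- matrix(0, cfg$max_steps, 3)
  np <- 0L
  p <- p0; vox <- vox0; d <- d0
  for (step in seq_len(cfg$max_steps)) {
    # exit of the ray p + t*d from the axis-aligned unit cube of `vox`
    lo <- vox - 1L
    t_ax <- ifelse(d > 0, (lo + 1 - p) / d,
                   ifelse(d < 0, (lo - p) / d, Inf))
    t_exit <- min(t_ax)
    if (!is.finite(t_exit) || t_exit < 0) break
    pe <- p + t_exit * d
    np <- np + 1L
    pts[np, ] <- pe
    # entered voxel: nudge past the face (resolves edge/corner ties)
    pn <- p + (t_exit + 1e-6) * d
    nv <- floor(pn) + 1L
    if (any(nv < 1L) || nv[1] > nx || nv[2] > ny || nv[3] > nz) break
    lin <- nv[1] + (nv[2] - 1L) * nx + (nv[3] - 1L) * nx * ny
    if (fa_v[lin] < cfg$fa_threshold) break
    e1 <- e1_m[lin, ]
    dp <- sum(e1 * d)
    if (dp < 0) { e1 <- -e1; dp <- -dp }   # sign continuity
    if (dp < cos_thr) break                 # turning angle exceeded
    p <- pe; vox <- nv; d <- e1
  }
  pts[seq_len(np), , drop = FALSE]
}

#' Whole-volume deterministic FACT tractography
#'
#' Seeds one track at the center of every masked voxel with FA at or above
#' the stopping threshold, propagates it in both directions along the
#' principal eigenvector, and merges the two halves. The voxel that fails
#' the FA or angle test is not entered: the track ends at its entry face.
#' Output is fully deterministic (seeds are visited in array order).
#'
#' @param tensors A `tensor_volume` from [fit_tensor()] or
#'   [gen_tensor_phantom()].
#' @param cfg A [tracking_config()].
#' @return A `streamline_set`: list of streamlines, each a list with
#'   `points` (m x 3 matrix, continuous 0-based voxel coordinates) and
#'   `seed` (1-based voxel index of the seed).
#' @export
fact_track <- function(tensors, cfg = tracking_config()) {
  stopifnot(inherits(tensors, "tensor_volume"),
            inherits(cfg, "tracking_config"))
  shape <- dim(tensors$fa)
  fa_v <- as.vector(tensors$fa)
  fa_v[!as.vector(tensors$mask)] <- 0
  e1_m <- matrix(tensors$e1, prod(shape), 3)
  cos_thr <- cos(cfg$angle_threshold * pi / 180)

  seeds <- which(fa_v >= cfg$fa_threshold & fa_v > 0)
  out <- vector("list", length(seeds))
  n_kept <- 0L
  for (s in seeds) {
    k <- (s - 1L) %/% (shape[1] * shape[2])
    rem <- (s - 1L) %% (shape[1] * shape[2])
    vox <- c(rem %% shape[1], rem %/% shape[1], k) + 1L
    p0 <- vox - 0.5
    d0 <- e1_m[s, ]
    fwd <- half_track(p0, vox, d0, fa_v, e1_m, shape, cfg, cos_thr)
    bwd <- half_track(p0, vox, -d0, fa_v, e1_m, shape, cfg, cos_thr)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, 1, 3), fwd)
    # drop consecutive duplicate points (can arise when p0 sits on a face)
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) >= cfg$min_points) {
      n_kept <- n_kept + 1L
      out[[n_kept]] <- list(points = pts, seed = vox)
    }
  }
  structure(out[seq_len(n_kept)], class = "streamline_set", config = cfg)
}

#' @export
print.streamline_set <- function(x, ...) {
  npts <- vapply(x, function(s) nrow(s$points), integer(1))
  cat("<streamline_set> ", length(x), " streamlines",
      if (length(x)) paste0(", ", min(npts), "-", max(npts), " points"),
      "\n", sep = "")
  invisible(x)
}

#' Voxels traversed by a streamline
#'
#' Walks the polyline through the voxel grid and returns every grid cell it
#' passes through, in order, with consecutive duplicates removed. Uses exact
#' parametric crossings of the integer grid planes; each inter-crossing
#' midpoint identifies the occupied voxel, which is robust to points lying
#' exactly on voxel faces.
#'
#' @param s A streamline (list with `points`) or an m x 3 point matrix in
#'   continuous 0-based voxel coordinates.
#' @return Integer matrix (n x 3) of 0-based voxel indices.
#' @export
streamline_voxels <- function(s) {
  pts <- if (is.list(s)) s$points else s
  pts <- as.matrix(pts)
  vox <- matrix(integer(0), 0, 3)
  for (r in seq_len(nrow(pts) - 1)) {
    a <- pts[r, ]; b <- pts[r + 1, ]
    d <- b - a
    if (all(abs(d) < 1e-12)) next
    ts <- c(0, 1)
    for (ax in 1:3) {
      if (abs(d[ax]) < 1e-12) next
      rng <- sort(c(a[ax], b[ax]))
      planes <- seq.int(ceiling(rng[1] - 1e-9), floor(rng[2] + 1e-9))
      planes <- planes[planes > rng[1] + 1e-12 & planes < rng[2] - 1e-12]
      ts <- c(ts, (planes - a[ax]) / d[ax])
    }
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    mids <- (ts[-1] + ts[-length(ts)]) / 2
    seg_vox <- floor(rep(a, each = length(mids)) + outer(mids, d))
    vox <- rbind(vox, seg_vox)
  }
  if (nrow(pts) == 1) vox <- matrix(floor(pts[1, ]), 1, 3)
  if (nrow(vox) == 0) return(vox)
  keep <- c(TRUE, rowSums(abs(diff(vox))) > 0)
  storage.mode(vox) <- "integer"
  vox[keep, , drop = FALSE]
}
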