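# Synthetic diffusion phantoms: tensor fields with known fiber bundles and
# the single-tensor forward model that turns them into DWI signal volumes.

#' Specify a fiber-bundle phantom
#'
#' A phantom is a voxel grid holding one or more tubular fiber bundles in an
#' isotropic background. Each bundle is a tube of given radius around a
#' centerline polyline; voxels inside carry a prolate tensor whose principal
#' axis follows the local centerline tangent.
#'
#' @param shape Integer length-3 grid size in voxels.
#' @param bundles List of bundle descriptors, each a list with `centerline`
#'   (n x 3 matrix of points in continuous voxel coordinates), `radius`
#'   (voxels, > 0), and `evals` (length-3 eigenvalues in mm^2/s with
#'   lambda1 >= lambda2 = lambda3 > 0; default `c(1.7, 0.3, 0.3) * 1e-3`).
#' @param background_adc Isotropic background diffusivity in mm^2/s.
#' @param S0 Non-diffusion-weighted signal amplitude.
#' @param noise_sigma Rician noise sigma in signal units (0 = noiseless).
#' @param seed Integer seed for noise generation.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, bundles,
                         background_adc = 0.7e-3,
                         S0 = 1000, noise_sigma = 0, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (S0 <= 0) stop("S0 must be positive", call. = FALSE)
  bundles <- lapply(bundles, function(b) {
    if (is.null(b$evals)) b$evals <- c(1.7, 0.3, 0.3) * 1e-3
    ev <- b$evals
    if (!(ev[1] >= ev[2] && abs(ev[2] - ev[3]) < 1e-12 && ev[3] > 0))
      stop("bundle eigenvalues must satisfy lambda1 >= lambda2 = lambda3 > 0",
           call. = FALSE)
    if (b$radius <= 0) stop("bundle radius must be positive", call. = FALSE)
    b$centerline <- as.matrix(b$centerline)
    stopifnot(ncol(b$centerline) == 3, nrow(b$centerline) >= 2)
    b
  })
  structure(list(shape = as.integer(shape), bundles = bundles,
                 background_adc = background_adc, S0 = S0,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Distance from points to a segment, plus the segment's unit tangent.
# pts: m x 3; a, b: segment endpoints.
point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) rep(0, nrow(pts)) else
    pmin(pmax((sweep(pts, 2, a) %*% ab) / len2, 0), 1)
  proj <- outer(as.vector(t), ab) + rep(a, each = nrow(pts))
  sqrt(rowSums((pts - proj)^2))
}

#' Generate the tensor field of a phantom
#'
#' Voxels within `radius` of a bundle centerline get the bundle's prolate
#' tensor oriented along the tangent of the nearest centerline segment;
#' all other voxels get an isotropic background tensor. Where bundles
#' overlap, the first-listed bundle wins.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `tensors` (a `tensor_volume`), `bundle_mask` (integer
#'   array, 0 background, k = index of owning bundle).
#' @export
gen_tensor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  nvox <- prod(shape)
  # voxel centers in continuous voxel coords
  ctr <- as.matrix(expand.grid(x = seq_len(shape[1]) - 0.5,
                               y = seq_len(shape[2]) - 0.5,
                               z = seq_len(shape[3]) - 0.5))
  owner <- integer(nvox)
  tangent <- matrix(0, nvox, 3)
  for (k in seq_along(spec$bundles)) {
    b <- spec$bundles[[k]]
    cl <- b$centerline
    best <- rep(Inf, nvox)
    btan <- matrix(0, nvox, 3)
    for (s in seq_len(nrow(cl) - 1)) {
      d <- point_segment_dist(ctr, cl[s, ], cl[s + 1, ])
      closer <- d < best
      if (any(closer)) {
        tg <- cl[s + 1, ] - cl[s, ]
        tg <- tg / sqrt(sum(tg^2))
        best[closer] <- d[closer]
        btan[closer, ] <- matrix(tg, sum(closer), 3, byrow = TRUE)
      }
    }
    inside <- best <= b$radius & owner == 0L
    owner[inside] <- k
    tangent[inside, ] <- btan[inside, , drop = FALSE]
  }

  # D = lambda2 * I + (lambda1 - lambda2) * t t'  (lambda2 = lambda3)
  d6 <- matrix(0, nvox, 6)
  bg <- spec$background_adc
  d6[, 1:3] <- bg
  for (k in seq_along(spec$bundles)) {
    ev <- spec$bundles[[k]]$evals
    sel <- owner == k
    tg <- tangent[sel, , drop = FALSE]
    dl <- ev[1] - ev[2]
    d6[sel, ] <- cbind(ev[2] + dl * tg[, 1]^2,
                       ev[2] + dl * tg[, 2]^2,
                       ev[2] + dl * tg[, 3]^2,
                       dl * tg[, 1] * tg[, 2],
                       dl * tg[, 1] * tg[, 3],
                       dl * tg[, 2] * tg[, 3])
  }
  mask <- array(TRUE, shape)
  tv <- tensor_volume_from_d6(d6, mask, shape, c(1, 1, 1))
  list(tensors = tv, bundle_mask = array(owner, shape))
}

#' Simulate DWI signals from a tensor field
#'
#' Single-tensor forward model `S_i = S0 * exp(-b_i g_i' D g_i)` per voxel
#' and volume, with optional Rician noise (magnitude of a complex Gaussian
#' perturbation). A noiseless call is deterministic.
#'
#' @param tensors A `tensor_volume` (see [fit_tensor()]) or an
#'   (x, y, z, 6) tensor array.
#' @param gt A [gradient_table()].
#' @param S0 Non-diffusion-weighted signal (scalar, > 0).
#' @param noise_sigma Rician sigma in signal units; 0 disables noise.
#' @param seed Seed used when noise is added.
#' @return 4-D array (x, y, z, volume) of signals.
#' @export
gen_dwi_from_tensors <- function(tensors, gt, S0 = 1000, noise_sigma = 0,
                                 seed = 1L) {
  if (inherits(tensors, "tensor_volume")) tensors <- tensors$D
  stopifnot(length(dim(tensors)) == 4, dim(tensors)[4] == 6)
  if (S0 <= 0) stop("S0 must be positive", call. = FALSE)
  shape <- dim(tensors)[1:3]
  nvox <- prod(shape)
  d6 <- matrix(tensors, nvox, 6)
  X <- diffusion_design(gt)                    # n_vol x 6
  S <- S0 * exp(-(d6 %*% t(X)))                # n_vox x n_vol
  if (noise_sigma > 0) {
    S <- with_seed(seed, {
      e1 <- matrix(rnorm(length(S), sd = noise_sigma), nrow(S))
      e2 <- matrix(rnorm(length(S), sd = noise_sigma), nrow(S))
      sqrt((S + e1)^2 + e2^2)
    })
  }
  array(S, c(shape, nrow(X)))
}
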