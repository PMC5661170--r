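# Shared synthetic fixtures, all built in code at test time.

# Straight x-aligned bundle phantom: length `len` voxels, centered tube.
straight_phantom <- function(len = 40, cross = 12, radius = 2.5,
                             noise_sigma = 0, seed = 1) {
  mid <- cross / 2 + 0.5
  phantom_spec(c(len, cross, cross),
               list(list(centerline = cbind(c(0, len), mid, mid),
                         radius = radius)),
               noise_sigma = noise_sigma, seed = seed)
}

# Two parallel x-aligned bundles in one volume (for spurious-edge checks).
two_bundle_phantom <- function(len = 40, cross = 18) {
  phantom_spec(c(len, cross, 8),
               list(list(centerline = cbind(c(0, len), 4.5, 4.5),
                         radius = 2),
                    list(centerline = cbind(c(0, len), cross - 4.5, 4.5),
                         radius = 2)))
}

# Quarter-circle bundle of given radius in the x-y plane.
arc_phantom <- function(R = 20, radius = 2, pad = 6) {
  th <- seq(0, pi / 2, length.out = 60)
  cl <- cbind(pad + R * cos(th), pad + R * sin(th), 4)
  phantom_spec(c(R + 2 * pad, R + 2 * pad, 8),
               list(list(centerline = cl, radius = radius)))
}

# Labels marking the two x-extremes of a volume as regions r1 and r2.
end_labels <- function(shape, slab = 3, r1 = 1, r2 = 2) {
  lab <- array(0L, shape)
  lab[seq_len(slab), , ] <- r1
  lab[(shape[1] - slab + 1):shape[1], , ] <- r2
  lab
}

# Hand-built streamline straight along x at a given (y, z) voxel row.
x_streamline <- function(x0, x1, y, z) {
  list(points = cbind(seq(x0, x1, 0.5), y, z), seed = NA)
}

# Small fast cohort spec for unit tests.
small_cohort_spec <- function(effect_edges = cbind(c(1, 2, 3), c(2, 3, 4)),
                              ...) {
  cohort_spec(n_patients = 8, n_controls = 9, n_nodes = 30, density = 0.2,
              effect_edges = effect_edges, ...)
}
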