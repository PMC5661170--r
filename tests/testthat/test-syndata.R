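# Synthetic data generators: phantoms, DWI forward model, cohorts.

test_that("gradient table validates b-values and direction norms", {
  gt <- gradient_scheme(32)
  expect_equal(sum(gt$bvals == 0), 1)
  expect_equal(sum(gt$bvals > 0), 32)
  nrm <- sqrt(rowSums(gt$bvecs[gt$bvals > 0, ]^2))
  expect_true(all(abs(nrm - 1) < 1e-6))
  expect_error(gradient_table(rep(1000, 7), matrix(1, 7, 3)), "unit norm")
  expect_error(gradient_table(c(0, rep(1000, 5)), rbind(0, diag(3), diag(3)[1:2, ])),
               "six")
  expect_error(gradient_table(rep(1000, 6), rbind(diag(3), diag(3))),
               "b=0")
})

test_that("straight-bundle phantom has tangent-aligned tensors and isotropic background", {
  ph <- gen_tensor_phantom(straight_phantom())
  tv <- ph$tensors
  inside <- which(ph$bundle_mask > 0, arr.ind = TRUE)
  # every bundle voxel's principal eigenvector is +/- (1,0,0)
  for (r in sample(nrow(inside), 20)) {
    v <- tv$e1[inside[r, 1], inside[r, 2], inside[r, 3], ]
    expect_equal(abs(v), c(1, 0, 0), tolerance = 1e-9)
  }
  outside <- which(ph$bundle_mask == 0)
  expect_true(all(tv$fa[outside] < 1e-12))   # isotropic background: FA 0
  expect_true(all(tv$fa[ph$bundle_mask > 0] > 0.5))
})

test_that("quarter-circle bundle turns slowly relative to the angle stop", {
  ph <- gen_tensor_phantom(arc_phantom(R = 20))
  idx <- which(ph$bundle_mask > 0, arr.ind = TRUE)
  e1m <- matrix(ph$tensors$e1, prod(dim(ph$bundle_mask)), 3)
  lin <- idx[, 1] + (idx[, 2] - 1) * dim(ph$bundle_mask)[1] +
    (idx[, 3] - 1) * prod(dim(ph$bundle_mask)[1:2])
  # max angle between principal directions of x-adjacent bundle voxels
  max_ang <- 0
  for (r in seq_len(nrow(idx))) {
    nb <- which(idx[, 1] == idx[r, 1] + 1 & idx[, 2] == idx[r, 2] &
                  idx[, 3] == idx[r, 3])
    for (q in nb) {
      dp <- abs(sum(e1m[lin[r], ] * e1m[lin[q], ]))
      max_ang <- max(max_ang, acos(min(dp, 1)) * 180 / pi)
    }
  }
  expect_lt(max_ang, 45)
})

test_that("DWI forward model matches the closed form and respects b0", {
  gt <- gradient_scheme(32)
  # single-voxel isotropic tensor
  iso <- array(0, c(1, 1, 1, 6)); iso[1, 1, 1, 1:3] <- 0.7e-3
  S <- gen_dwi_from_tensors(iso, gt, S0 = 1000)
  expect_equal(S[1, 1, 1, 1], 1000)                 # b0 exactly S0
  dwis <- S[1, 1, 1, gt$bvals > 0]
  expect_equal(dwis, rep(1000 * exp(-0.7), 32), tolerance = 1e-12)
  # anisotropic along the x gradient direction: S = S0 exp(-b lambda1)
  ani <- array(0, c(1, 1, 1, 6)); ani[1, 1, 1, 1:3] <- c(1.7, 0.3, 0.3) * 1e-3
  gx <- gradient_table(c(0, rep(1000, 6)),
                       rbind(0, diag(3),
                             matrix(1 / sqrt(2), 3, 3) * (1 - diag(3))))
  Sx <- gen_dwi_from_tensors(ani, gx, S0 = 1000)
  expect_equal(Sx[1, 1, 1, 2], 1000 * exp(-1.7), tolerance = 1e-9)  # 182.68
  expect_error(gen_dwi_from_tensors(ani, gx, S0 = -5), "S0")
})

test_that("DWI generation is deterministic and Rician noise is seed-stable", {
  ph <- gen_tensor_phantom(straight_phantom(len = 10, cross = 6))
  gt <- gradient_scheme(8)
  a <- gen_dwi_from_tensors(ph$tensors, gt)
  b <- gen_dwi_from_tensors(ph$tensors, gt)
  expect_identical(a, b)
  n1 <- gen_dwi_from_tensors(ph$tensors, gt, noise_sigma = 20, seed = 5)
  n2 <- gen_dwi_from_tensors(ph$tensors, gt, noise_sigma = 20, seed = 5)
  expect_identical(n1, n2)
  expect_gt(max(abs(n1 - a)), 0)
  expect_true(all(n1 >= 0))                         # magnitude signal
})

test_that("cohort matrices are symmetric, nonnegative, zero-diagonal and seed-stable", {
  sp <- small_cohort_spec(seed = 11)
  co <- gen_cohort(sp)
  for (s in seq_len(dim(co$matrices)[3])) {
    m <- co$matrices[, , s]
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
  }
  co2 <- gen_cohort(small_cohort_spec(seed = 11))
  expect_identical(co$matrices, co2$matrices)       # bit-identical
  expect_identical(co$manifest, co2$manifest)
  co3 <- gen_cohort(small_cohort_spec(seed = 12))
  expect_false(identical(co$matrices, co3$matrices))
})

test_that("template density lands within two percentage points of the spec", {
  for (dens in c(0.10, 0.15, 0.25)) {
    sp <- cohort_spec(density = dens, seed = 3)
    W <- connectome_template(sp)
    got <- mean(W[upper.tri(W)] > 0)
    expect_lt(abs(got - dens), 0.02)
  }
})

test_that("planted effect lowers patient means on exactly the planted edges", {
  sp <- cohort_spec(effect_size = 0.4, subject_noise_sd = 0.2, seed = 21)
  co <- gen_cohort(sp)
  pat <- co$manifest$group == "patient"
  mp <- apply(co$matrices[, , pat], c(1, 2), mean)
  mc <- apply(co$matrices[, , !pat], c(1, 2), mean)
  for (r in seq_len(nrow(sp$effect_edges))) {
    i <- sp$effect_edges[r, 1]; j <- sp$effect_edges[r, 2]
    expect_lt(mp[i, j], mc[i, j])
  }
})

test_that("planted-edge group difference converges to effect_size x template weight", {
  sp <- cohort_spec(n_patients = 40, n_controls = 40, effect_size = 0.3,
                    subject_noise_sd = 1e-4, dropout = 0, seed = 5)
  co <- gen_cohort(sp)
  pat <- co$manifest$group == "patient"
  for (r in seq_len(nrow(sp$effect_edges))) {
    i <- sp$effect_edges[r, 1]; j <- sp$effect_edges[r, 2]
    diff <- mean(co$matrices[i, j, !pat]) - mean(co$matrices[i, j, pat])
    expect_equal(diff, 0.3 * co$template[i, j], tolerance = 1e-3)
  }
})

test_that("a null cohort has centered edge t-statistics", {
  sp <- cohort_spec(effect_size = 0, seed = 31)
  co <- gen_cohort(sp)
  tm <- edge_tstats(co)
  tv <- tm[upper.tri(tm)]
  expect_lt(abs(mean(tv, na.rm = TRUE)), 0.1)
})

test_that("cohort covariates respect the stated clinical ranges", {
  co <- gen_cohort(cohort_spec(seed = 41))
  mf <- co$manifest
  pat <- mf$group == "patient"
  expect_true(all(mf$HDRS[pat] >= 18 & mf$HDRS[pat] <= 34))
  expect_true(all(is.na(mf$HDRS[!pat])))
  expect_true(all(mf$age >= 18 & mf$age <= 56))
  expect_true(all(mf$duration_months[pat] >= 1 & mf$duration_months[pat] <= 10))
  expect_equal(sum(pat), 21)
  expect_equal(sum(!pat), 25)
})

test_that("planted edges absent from a custom template raise an error", {
  sp <- small_cohort_spec(seed = 2)
  tpl <- connectome_template(sp)
  tpl[1, 2] <- tpl[2, 1] <- 0                       # remove a planted edge
  expect_error(gen_cohort(sp, template = tpl), "support")
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(density = 0), "density")
  expect_error(cohort_spec(effect_size = 1), "effect_size")
  expect_error(small_cohort_spec(effect_edges = cbind(3, 3)), "off-diagonal")
  expect_error(small_cohort_spec(effect_edges = cbind(c(1, 1), c(2, 2))),
               "distinct")
})
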