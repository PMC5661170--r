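# Network-based statistic: t-maps, components, permutation FWE.

# Stack a list of matrices into the n x n x s array the NBS functions take.
stack_mats <- function(lst) {
  n <- nrow(lst[[1]])
  array(unlist(lst), c(n, n, length(lst)))
}

# Tiny cohort with one designed edge: patients {1,2,3}, controls {4,5,6}.
toy_cohort <- function() {
  base <- matrix(0, 4, 4)
  mk <- function(v) { m <- base; m[1, 2] <- m[2, 1] <- v; m[3, 4] <- m[4, 3] <- 1; m }
  list(mats = stack_mats(lapply(c(1, 2, 3, 4, 5, 6), mk)),
       group = rep(c("patient", "control"), each = 3))
}

test_that("edge t equals the hand-computed pooled-variance value", {
  tc <- toy_cohort()
  tm <- edge_tstats(tc$mats, tc$group)
  # patients {1,2,3} vs controls {4,5,6}: t = -3/sqrt(2/3) = -3.6742, df 4
  expect_equal(tm[1, 2], -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(round(tm[1, 2], 4), -3.6742)
  expect_equal(attr(tm, "df"), 4L)
  expect_identical(tm, t(tm))
  expect_true(is.na(tm[3, 4]))          # constant edge: zero pooled variance
  expect_true(is.na(tm[1, 3]))          # all-zero edge likewise undefined
})

test_that("identical groups give zero t and label exchange negates the map", {
  sp <- small_cohort_spec(seed = 3, effect_size = 0)
  co <- gen_cohort(sp)
  same <- edge_tstats(stack_mats(list(co$matrices[, , 1], co$matrices[, , 2],
                                      co$matrices[, , 1], co$matrices[, , 2])),
                      c("a", "a", "b", "b"))
  vals <- same[upper.tri(same)]
  expect_true(all(vals[!is.na(vals)] == 0))
  tm1 <- edge_tstats(co$matrices, co$manifest$group, ref = "patient")
  tm2 <- edge_tstats(co$matrices, co$manifest$group, ref = "control")
  expect_equal(unclass(tm1), -unclass(tm2), ignore_attr = TRUE)
  expect_error(edge_tstats(co$matrices, rep("a", 17)), "two groups")
})

test_that("suprathreshold components match connectivity by shared nodes", {
  tm <- matrix(0, 10, 10)
  set_t <- function(i, j, v) tm[i, j] <<- tm[j, i] <<- v
  set_t(1, 2, -3); set_t(2, 3, -2.5); set_t(7, 8, -2.2); set_t(4, 5, -1.0)
  cs <- suprathreshold_components(tm, 2.1, "decrease")
  expect_length(cs, 2)
  expect_equal(cs[[1]]$extent, 2)
  expect_equal(cs[[1]]$nodes, 1:3)
  expect_equal(cs[[2]]$extent, 1)
  expect_length(suprathreshold_components(tm, 2.1, "increase"), 0)
  expect_length(suprathreshold_components(matrix(0, 5, 5), 2.1), 0)
})

test_that("component finding matches a brute-force DFS oracle on random t-maps", {
  for (seed in 1:5) {
    set.seed(seed)
    tm <- matrix(0, 90, 90)
    tm[upper.tri(tm)] <- rnorm(4005)
    tm <- tm + t(tm)
    cs <- suprathreshold_components(tm, 2.1, "increase")
    supra <- which(upper.tri(tm) & tm > 2.1, arr.ind = TRUE)
    ref <- brute_components_nodes(supra)
    got_nodes <- lapply(cs, `[[`, "nodes")
    expect_setequal(lapply(got_nodes, paste, collapse = ","),
                    lapply(ref, paste, collapse = ","))
    # extents partition the suprathreshold edge set
    expect_equal(sum(vapply(cs, `[[`, numeric(1), "extent")), nrow(supra))
  }
})

test_that("permutation p-values are valid, monotone in extent, and order-invariant", {
  sp <- small_cohort_spec(seed = 5, effect_size = 0.5)
  co <- gen_cohort(sp)
  res <- nbs_fwe(co, n_perm = 200, seed = 9)
  P <- 200
  for (cmp in res$components) {
    expect_gte(cmp$p_fwe, 1 / (P + 1))
    expect_lte(cmp$p_fwe, 1)
  }
  ext <- vapply(res$components, `[[`, numeric(1), "extent")
  p <- vapply(res$components, `[[`, numeric(1), "p_fwe")
  expect_true(all(diff(p[order(-ext)]) >= 0))
  # permuting subject order leaves the result invariant
  set.seed(31)
  perm <- sample(seq_len(dim(co$matrices)[3]))
  res2 <- nbs_fwe(co$matrices[, , perm], co$manifest$group[perm],
                  n_perm = 200, seed = 9)
  # observed t-map and components are exactly order-invariant; the
  # permutation draw differs with subject order, so p agrees to MC error
  expect_equal(vapply(res2$components, `[[`, numeric(1), "extent"), ext)
  expect_equal(vapply(res2$components, `[[`, numeric(1), "p_fwe"), p,
               tolerance = 0.15)
})

test_that("the identity relabeling reproduces the observed maximal extent", {
  sp <- small_cohort_spec(seed = 7, effect_size = 0.5)
  co <- gen_cohort(sp)
  g <- co$manifest$group
  tm <- edge_tstats(co$matrices, g)
  obs_max <- max(c(0, vapply(suprathreshold_components(tm, 2.1, "decrease"),
                             `[[`, numeric(1), "extent")))
  # recompute through the permutation path with the identity labels
  E <- fibernet:::edge_value_matrix(co$matrices)
  tv <- fibernet:::col_tstats(E, which(g == "patient"),
                              which(g == "control"))
  supra <- which(!is.na(tv) & tv < -2.1)
  pairs <- fibernet:::upper_pairs(30)
  perm_max <- if (length(supra)) max(lengths(fibernet:::edge_components(supra, pairs))) else 0
  expect_equal(perm_max, obs_max)
})

test_that("a strongly planted decrease is recovered as a significant component", {
  sp <- small_cohort_spec(seed = 15, effect_size = 0.6,
                          subject_noise_sd = 0.15)
  co <- gen_cohort(sp)
  res <- nbs_fwe(co, n_perm = 500, seed = 2)
  expect_gt(length(res$components), 0)
  top <- res$components[[1]]
  expect_lt(top$p_fwe, 0.05)
  planted <- paste(sp$effect_edges[, 1], sp$effect_edges[, 2])
  found <- paste(top$edges[, 1], top$edges[, 2])
  expect_true(all(planted %in% found))
})

test_that("an increased effect is found only in the increase direction", {
  # planting a decrease in patients is an increase from the control side
  sp <- small_cohort_spec(seed = 25, effect_size = 0.6,
                          subject_noise_sd = 0.15)
  co <- gen_cohort(sp)
  res <- nbs_fwe(co$matrices, co$manifest$group, ref = "control",
                 n_perm = 300, direction = "both", seed = 3)
  sig <- Filter(function(cmp) cmp$significant, res$components)
  expect_gt(length(sig), 0)
  expect_true(all(vapply(sig, `[[`, character(1), "direction") == "increase"))
})
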