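# Synthetic subject cohorts: modular small-world template connectomes,
# subject-level multiplicative noise, and an optional planted group
# difference on a connected edge set.

#' Default planted subnetwork
#'
#' A 7-edge spanning tree over 8 regions of the orbitofrontal-thalamic-
#' limbic circuit (left orbital frontal regions, left thalamus, hippocampus
#' and postcentral gyrus, right rectus and orbital inferior frontal gyri).
#' The tree is a documented fixture for planted-effect experiments, chosen
#' to connect the designated nodes, not a claim about any particular
#' empirical edge list.
#'
#' @return Integer matrix (7 x 2) of atlas node indices, i < j, with the
#'   region-code pair as rownames.
#' @export
planted_subnetwork <- function() {
  pairs <- rbind(
    c("THA.L", "PoCG.L"),
    c("THA.L", "HIP.L"),
    c("THA.L", "ORBmid.L"),
    c("ORBmid.L", "ORBsup.L"),
    c("ORBsup.L", "ORBsupmed.L"),
    c("ORBsupmed.L", "REC.R"),
    c("REC.R", "ORBinf.R")
  )
  idx <- cbind(region_index(pairs[, 1]), region_index(pairs[, 2]))
  out <- t(apply(idx, 1, sort))
  rownames(out) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  colnames(out) <- c("i", "j")
  out
}

#' Specify a synthetic two-group connectome cohort
#'
#' Defaults emulate a first-episode depression case-control study: 21
#' patients vs 25 controls, 90 atlas nodes, 15% connection density,
#' patient ages ~ 37.5 +/- 11.6 vs control 31.4 +/- 11.0 years, patient
#' HDRS scores in 18-34, illness duration 1-10 months, and a planted
#' weight decrease on a 7-edge connected subnetwork in the patient group.
#'
#' @param n_patients,n_controls Group sizes (default 21 and 25).
#' @param n_nodes Number of atlas nodes (default 90).
#' @param density Fraction of node pairs carrying a template edge,
#'   in (0, 1] (default 0.15).
#' @param effect_edges Integer matrix (k x 2) of node pairs whose patient
#'   weights are reduced; default [planted_subnetwork()]. Must be distinct
#'   off-diagonal pairs.
#' @param effect_size Fractional weight reduction in patients, in \[0, 1)
#'   (default 0.4; 0 plants no effect).
#' @param subject_noise_sd Sigma of the multiplicative lognormal
#'   subject noise on nonzero edges (default 0.2).
#' @param dropout Per-subject probability that a template edge is missing
#'   (default 0.02).
#' @param age_patients,age_controls `c(mean, sd)` of the group age
#'   distributions, truncated to `age_range`.
#' @param age_range Admissible age range in years.
#' @param hdrs `c(mean, sd)` of patient HDRS scores, truncated to
#'   `hdrs_range` and rounded to integers.
#' @param hdrs_range Admissible HDRS range (default 18-34).
#' @param duration `c(mean, sd)` of patient illness duration in months,
#'   truncated to `duration_range`.
#' @param duration_range Admissible duration range in months.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   spec including this seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 21, n_controls = 25, n_nodes = 90,
                        density = 0.15,
                        effect_edges = planted_subnetwork(),
                        effect_size = 0.4,
                        subject_noise_sd = 0.2, dropout = 0.02,
                        age_patients = c(37.5, 11.6),
                        age_controls = c(31.4, 11.0),
                        age_range = c(18, 56),
                        hdrs = c(24.38, 4.08), hdrs_range = c(18, 34),
                        duration = c(3.47, 2.60), duration_range = c(1, 10),
                        seed = 1L) {
  stopifnot(n_patients >= 2, n_controls >= 2, n_nodes >= 8)
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]",
                                        call. = FALSE)
  if (effect_size < 0 || effect_size >= 1)
    stop("effect_size must lie in [0, 1)", call. = FALSE)
  if (!is.null(effect_edges)) {
    effect_edges <- as.matrix(effect_edges)
    stopifnot(ncol(effect_edges) == 2)
    effect_edges <- t(apply(effect_edges, 1, sort))
    if (any(effect_edges[, 1] == effect_edges[, 2]))
      stop("effect edges must be off-diagonal", call. = FALSE)
    if (anyDuplicated(paste(effect_edges[, 1], effect_edges[, 2])))
      stop("effect edges must be distinct", call. = FALSE)
    if (max(effect_edges) > n_nodes)
      stop("effect edge node index exceeds n_nodes", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_nodes = as.integer(n_nodes), density = density,
                 effect_edges = effect_edges, effect_size = effect_size,
                 subject_noise_sd = subject_noise_sd, dropout = dropout,
                 age_patients = age_patients, age_controls = age_controls,
                 age_range = age_range, hdrs = hdrs,
                 hdrs_range = hdrs_range, duration = duration,
                 duration_range = duration_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-normal draws by rejection (ranges here are wide; cheap).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Modular small-world template connectome
#'
#' Builds the group-level template all subjects share: nodes split into
#' `n_modules` blocks, a ring-lattice backbone inside each module (high
#' clustering), and random fill edges preferring intra-module pairs until
#' the target density is met. Weights are lognormal on a fiber-count x FA
#' scale (roughly 1-300), with intra-module edges upweighted, mimicking the
#' stronger short-range connections of real structural networks. Any
#' `ensure_edges` pairs are always present (used to host planted effects).
#' Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param n_modules Number of modules (default 6).
#' @param ring_k Within-module ring-lattice neighbors per side x 2
#'   (default 6).
#' @param intra_pref Selection weight of intra- vs inter-module fill edges
#'   (default 4).
#' @param ensure_edges Node-pair matrix of edges that must exist; default
#'   the spec's effect edges.
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
connectome_template <- function(spec, n_modules = 6, ring_k = 6,
                                intra_pref = 4,
                                ensure_edges = spec$effect_edges) {
  n <- spec$n_nodes
  module <- sort(rep_len(seq_len(n_modules), n))
  pairs <- upper_pairs(n)
  pair_id <- function(i, j) (j - 1) * (j - 2) / 2 + i  # i < j, upper order
  np <- nrow(pairs)
  target <- round(spec$density * np)

  with_seed(spec$seed, {
    present <- logical(np)
    # ring-lattice backbone within each module
    for (m in seq_len(n_modules)) {
      nodes <- which(module == m)
      sz <- length(nodes)
      for (off in seq_len(min(ring_k %/% 2, (sz - 1) %/% 2))) {
        a <- nodes
        b <- nodes[(seq_len(sz) - 1 + off) %% sz + 1]
        ij <- cbind(pmin(a, b), pmax(a, b))
        present[pair_id(ij[, 1], ij[, 2])] <- TRUE
      }
    }
    if (!is.null(ensure_edges) && nrow(ensure_edges))
      present[pair_id(ensure_edges[, 1], ensure_edges[, 2])] <- TRUE

    n_have <- sum(present)
    if (n_have < target) {
      cand <- which(!present)
      intra <- module[pairs[cand, 1]] == module[pairs[cand, 2]]
      pick <- sample(cand, target - n_have,
                     prob = ifelse(intra, intra_pref, 1))
      present[pick] <- TRUE
    } else if (n_have > target) {
      # backbone denser than requested: thin it, keeping ensured edges
      removable <- which(present)
      if (!is.null(ensure_edges) && nrow(ensure_edges))
        removable <- setdiff(removable,
                             pair_id(ensure_edges[, 1], ensure_edges[, 2]))
      drop <- sample(removable, n_have - target)
      present[drop] <- FALSE
    }

    w <- numeric(np)
    intra_all <- module[pairs[, 1]] == module[pairs[, 2]]
    w[present] <- rlnorm(sum(present), meanlog = log(20), sdlog = 0.9) *
      ifelse(intra_all[present], 3, 1)
    W <- ut_matrix(w, n)
    if (n == 90) dimnames(W) <- list(aal90_regions()$code,
                                     aal90_regions()$code)
    W
  })
}

#' Generate a synthetic two-group cohort of connectomes
#'
#' All subjects share one template (identical nonzero support up to the
#' dropout rate); each subject's nonzero weights are perturbed by
#' multiplicative lognormal noise, and patients' weights on the planted
#' effect edges are multiplied by `1 - effect_size`. Covariates (age, sex,
#' HDRS, illness duration) are drawn from the spec's distributions. The
#' whole cohort is a deterministic function of the spec (including its
#' seed).
#'
#' @param spec A [cohort_spec()].
#' @param template Optional template weight matrix; default built by
#'   [connectome_template()] (which guarantees the effect edges exist).
#'   A user-supplied template missing a planted edge is an error.
#' @return A `cohort`: list with `matrices` (n x n x n_subjects array),
#'   `manifest` (data.frame: subject_id, group, age, sex, HDRS,
#'   duration_months), `template`, and `ground_truth` (planted edges,
#'   effect size, seed).
#' @export
gen_cohort <- function(spec, template = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(template)) template <- connectome_template(spec)
  stopifnot_symmetric(template, "template")
  if (nrow(template) != spec$n_nodes)
    stop("template size does not match spec$n_nodes", call. = FALSE)
  ee <- spec$effect_edges
  if (!is.null(ee) && nrow(ee) &&
      any(template[ee] == 0))
    stop("planted effect edges must exist in the template support",
         call. = FALSE)

  np <- spec$n_patients; nc <- spec$n_controls
  ns <- np + nc
  n <- spec$n_nodes
  group <- rep(c("patient", "control"), c(np, nc))
  tw <- ut_values(template)
  nz <- which(tw > 0)
  eff <- rep(1, length(tw))
  if (!is.null(ee) && nrow(ee) && spec$effect_size > 0) {
    pid <- (ee[, 2] - 1) * (ee[, 2] - 2) / 2 + ee[, 1]
    eff[pid] <- 1 - spec$effect_size
  }

  with_seed(spec$seed + 1L, {
    mats <- array(0, c(n, n, ns), dimnames = c(dimnames(template),
                                               list(NULL)))
    for (s in seq_len(ns)) {
      w <- tw
      w[nz] <- w[nz] * exp(rnorm(length(nz), 0, spec$subject_noise_sd))
      if (spec$dropout > 0)
        w[nz][runif(length(nz)) < spec$dropout] <- 0
      if (group[s] == "patient") w <- w * eff
      mats[, , s] <- ut_matrix(w, n)
    }

    sex <- c(assign_sex(np, 8 / 21), assign_sex(nc, 8 / 25))
    age <- c(rtruncnorm(np, spec$age_patients[1], spec$age_patients[2],
                        spec$age_range[1], spec$age_range[2]),
             rtruncnorm(nc, spec$age_controls[1], spec$age_controls[2],
                        spec$age_range[1], spec$age_range[2]))
    hdrs <- c(round(rtruncnorm(np, spec$hdrs[1], spec$hdrs[2],
                               spec$hdrs_range[1], spec$hdrs_range[2])),
              rep(NA_real_, nc))
    dur <- c(round(rtruncnorm(np, spec$duration[1], spec$duration[2],
                              spec$duration_range[1],
                              spec$duration_range[2]), 1),
             rep(NA_real_, nc))
    manifest <- data.frame(
      subject_id = sprintf("sub-%s%02d", ifelse(group == "patient",
                                                "P", "C"),
                           c(seq_len(np), seq_len(nc))),
      group = group, age = round(age, 1), sex = sex,
      HDRS = hdrs, duration_months = dur,
      stringsAsFactors = FALSE
    )
    dimnames(mats)[[3]] <- manifest$subject_id

    structure(list(matrices = mats, manifest = manifest,
                   template = template,
                   ground_truth = list(effect_edges = ee,
                                       effect_size = spec$effect_size,
                                       density = spec$density,
                                       seed = spec$seed)),
              class = "cohort")
  })
}

# Deterministically shuffled sex assignment matching a female fraction.
assign_sex <- function(n, frac_female) {
  nf <- round(n * frac_female)
  sample(rep(c("F", "M"), c(nf, n - nf)))
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat("<cohort> ", dim(x$matrices)[1], " nodes, ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "; template density ",
      signif(mean(ut_values(x$template) > 0), 3), "\n", sep = "")
  if (!is.null(x$ground_truth$effect_edges))
    cat("  planted: ", nrow(x$ground_truth$effect_edges),
        " edges, effect size ", x$ground_truth$effect_size, "\n", sep = "")
  invisible(x)
}
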