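---
title: "Weighted structural connectomes from diffusion MRI: models, metrics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted structural connectomes from diffusion MRI: models, metrics and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibernet)
```

# Overview

`fibernet` implements a complete white-matter structural-network analysis
for case-control diffusion MRI studies: per-voxel diffusion tensor
estimation, deterministic FACT tractography, construction of a 90-region
weighted connectome with edge weights `w_ij = FN_ij × FA_ij`, weighted
graph-theory metrics across a sparsity sweep with small-world
normalization, the network-based statistic (NBS) for subnetwork-level
group inference, and the accompanying clinical statistics (age-adjusted
ANCOVA with FDR correction, partial correlation, power analysis,
demographic-table tests).

Because patient diffusion data cannot be shipped with a package, every
stage is exercised on synthetic inputs the package itself generates:
tensor phantoms with known fiber geometry for the voxel-level stages, and
two-group connectome cohorts with planted effects for the group-level
stages. This vignette documents the models, the conventions where the
literature leaves freedom, and what the synthetic validation does and
does not establish.

# Tensor estimation and fractional anisotropy

Per voxel, the single-tensor model relates the diffusion-weighted signal
to the symmetric tensor $D$:

$$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i).$$

`fit_tensor()` estimates the six unique elements of $D$ by ordinary least
squares on $\log(S_i/S_0)$. Weighted least squares and outlier-rejecting
schemes exist, but OLS is the minimal estimator consistent with a generic
"tensor fit" and is exactly invertible on noiseless synthetic data, which
makes the round-trip test sharp (recovery to ~1e-12 mm²/s). Numerical
conventions:

* multiple $b_0$ volumes are averaged before forming ratios;
* signals $\le 0$ (possible under noise) are clamped to $10^{-6} S_0$
  before the logarithm;
* for FA only, slightly negative eigenvalues are clamped to zero, and an
  all-zero tensor has FA 0 by definition.

Fractional anisotropy follows the standard normalized eigenvalue
dispersion, clipped to $[0,1]$:

$$\mathrm{FA} = \sqrt{\tfrac32}\;
  \frac{\sqrt{\sum_i(\lambda_i-\bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}}.$$

DWI simulation (`gen_dwi_from_tensors()`) adds Rician noise as the
magnitude of a complex Gaussian perturbation,
$\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$, the standard MR magnitude-noise
model. A Monte-Carlo test (500 repeated fits at 2% noise) checks that the
median recovered FA stays within 0.05 of truth.

# FACT tractography

`fact_track()` seeds one track at the center of every voxel whose FA
reaches the stopping threshold and propagates it in both directions along
the principal eigenvector. FACT means the direction is constant within a
voxel: the trajectory runs to the voxel's exit face (exact ray-box
intersection), then adopts the next voxel's direction. Termination rules,
with defaults FA < 0.15 and turning angle > 45°:

* the eigenvector sign is aligned with the incoming direction before the
  angle test (tensors are antipodally symmetric);
* the voxel that fails a test is *not* entered — the track ends on its
  entry face. The boundary geometry of "terminating at a voxel" is a
  convention; ours keeps every retained point inside passing voxels;
* ties at voxel edges/corners are resolved by advancing $10^{-6}$ voxels
  along the direction, making the tracker fully deterministic;
* tracks shorter than `min_points = 3` (about two voxel transits) are
  discarded as single-voxel debris.

Coordinates are continuous, 0-based voxel space with voxel centers at
integer + 0.5; `streamline_voxels()` recovers the exact ordered voxel
transit of a polyline from parametric crossings of the integer grid
planes (verified against a dense-resampling oracle).

An every-voxel seeding policy combined with the FA ≥ 0.15 gate means
seeds are effectively restricted to coherent white matter; deep-WM-only
seeding variants differ only in seed multiplicity on such data.

# Connectome construction

Nodes are the 90 cerebral regions of the standard AAL parcellation
(`aal90_regions()`), assumed already warped to the native space of the FA
map — registration is deliberately out of scope. For each streamline,
`assign_endpoints()` reads the label of the voxel containing each
terminal point (no dilation; points exactly on the upper volume face
belong to the last voxel). Streamlines with a background endpoint or both
endpoints in one region are discarded but counted, so fiber accounting is
conserved.

Edge weights multiply fiber number by mean FA: for region pair $(i,j)$,
$\mathrm{FN}_{ij}$ streamlines connect them, and $\mathrm{FA}_{ij}$ is
the mean FA over all voxel samples traversed by those streamlines. Pairs
with $\mathrm{FN}_{ij} < 3$ are zeroed (strict: FN = 3 survives) to
suppress spurious connections. The FA mean pools voxel samples across
streamlines — streamlines sharing voxels each contribute their samples —
which weights long, well-sampled paths more heavily; per-streamline
averaging is available via `fa_pooling = "streamline"` and differs only
when connecting streamlines have very unequal lengths.

# Graph metrics over the sparsity sweep

Group comparison of raw weighted networks confounds topology with
overall connectivity strength, so each subject's matrix is thresholded to
a fixed connection density: `threshold_sparsity()` keeps the top
$\lfloor S \cdot N(N-1)/2\rfloor$ edges by weight (weights retained, not
binarized; deterministic lexicographic tie-break), and all metrics are
swept over $S = 0.05, 0.06, \ldots, 0.40$ — 36 thresholds — then
summarized by the trapezoidal area under the curve on the closed interval
$[0.05, 0.40]$ (`auc_over_thresholds()`), removing the arbitrary choice
of any single threshold.

Metric definitions follow the weighted conventions of Rubinov & Sporns,
the ones implemented by the common connectome toolboxes. With weights
normalized by the matrix maximum ($\hat w \in [0,1]$) and edge lengths
$1/\hat w$:

* **Cp** — mean Onnela clustering,
  $c_i = \frac{2}{k_i(k_i-1)}\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
  0 for degree < 2;
* **Lp** — mean shortest path over *reachable* pairs (keeps Lp finite on
  sparse graphs; this choice affects λ and is therefore stated);
* **Eglob**, **Enodal** — mean inverse shortest path with unreachable
  pairs contributing 0;
* **Eloc** — mean over nodes of the global efficiency of each node's
  neighbor-induced subgraph (on the same normalized weights).

All five agree with brute-force oracles (explicit triangle enumeration,
Floyd–Warshall) to 1e-9 on every test graph up to 30 nodes.

Small-world normalization (`normalized_smallworld()`) divides Cp and Lp
by their means over $M$ degree-preserving Maslov–Sneppen rewired null
networks with the original weight multiset shuffled onto the rewired
topology: $\gamma = C_p/\langle C_p^{rand}\rangle$,
$\lambda = L_p/\langle L_p^{rand}\rangle$, $\sigma = \gamma/\lambda$,
with $\sigma > 1$ the small-world criterion. $M = 100$ nulls and 10 swap
attempts per edge are the field's customary defaults and are
configurable; the ensemble is seed-deterministic. Degree sequences and
weight multisets are preserved exactly (tested). Graphs too sparse to
admit a swap raise an error suggesting a higher threshold.

# Network-based statistic

`nbs_fwe()` implements cluster-based inference on the connectome:
pooled-variance two-sample t per edge (zeros are ordinary values; edges
with zero pooled variance are undefined and never suprathreshold),
one-sided suprathresholding at $|t| > 2.1$ in the requested direction,
connected components of the suprathreshold graph, and a permutation null
distribution of the *maximal component extent* (edge count) over random
relabelings of subjects into the original group sizes. The corrected
p-value of an observed component of extent $k$ is

$$p = \frac{1 + \#\{\text{permutations with max extent} \ge k\}}{P + 1},$$

the add-one form guaranteeing $p \in (0,1]$. Extent (not intensity) is
the component statistic because subnetwork findings are conventionally
reported as edge counts. Each direction is tested separately;
`direction = "both"` runs two one-sided analyses. No covariate adjustment
is applied inside NBS, matching the usual toolbox behavior (covariates
enter the metric-level ANCOVA instead).

Because the component extent is a small integer on sparse-support
cohorts, its permutation distribution is discrete and the test is
slightly conservative: on 200 null synthetic cohorts the empirical
familywise rate was 0.02 at a nominal 0.05 (within the 95% binomial
interval, but at its conservative edge). This is a property of max-type
discrete statistics, not an implementation artifact.

# Clinical statistics

* `ancova_group_effect()` — OLS `value ~ group + age`, group coded 0/1;
  the group coefficient's t (df = n − 3) is identical to the
  single-covariate ANCOVA F via $F = t^2$, and reduces exactly to the
  pooled t-test when the covariate is constant (tested to 1e-9).
* `fdr_bh()` — Benjamini–Hochberg step-up, delegated to
  `stats::p.adjust`; rejection at adjusted $p \le q$. The intended
  families are the global-metric AUCs and, separately, the 90 nodal
  efficiency AUCs.
* `partial_corr()` — residualize both variables on the covariate,
  Pearson r of residuals, $t = r\sqrt{(n-3)/(1-r^2)}$.
* `power_two_sample_t()` — exact noncentral-t power with
  $\mathrm{ncp} = (\Delta/\mathrm{SD})\sqrt{n_1 n_2/(n_1+n_2)}$; the
  normal approximation is avoided because at $n \approx 20$ per group it
  overstates power by a percentage point. At the design point
  Δ = 0.32, SD = 0.37, 21 vs 25, α = 0.05 it gives 0.815, confirmed by a
  Monte-Carlo oracle.
* `summary_ttest()` / `chisq_2x2()` — pooled t from summary statistics
  and Pearson chi-square *without* continuity correction, the form that
  reproduces standard clinical-table values exactly.

# The synthetic cohort generator

`gen_cohort()` emulates the study conditions end to end: 21 patients vs
25 controls by default, 90 nodes, template density 15%, patient ages
37.5 ± 11.6 vs control 31.4 ± 11.0 years (truncated to 18–56), patient
HDRS scores 24.4 ± 4.1 truncated to the 18–34 screening range, illness
duration 3.5 ± 2.6 months truncated to 1–10, and sex ratios 8F/13M vs
8F/17M.

The shared template (`connectome_template()`) is a modular small-world
graph: 6 modules of 15 nodes with a within-module ring-lattice backbone,
random fill edges preferring intra-module pairs (4:1) up to the target
density, and lognormal weights on a plausible FN × FA scale (~1–300)
with intra-module edges upweighted 3× — mimicking the sparse, heavy-
tailed, distance-dependent weight structure of real structural
connectomes, and keeping the retained graph modular under sparsity
thresholding. These parameters are fixtures chosen once for
plausibility; no distributional description of real connectomes was
available to fit.

Subjects multiply each nonzero template weight by lognormal noise
(σ = 0.2) with 2% per-subject edge dropout, preserving nonnegativity and
near-identical support. Patients' weights on the planted edge set are
multiplied by $1 -$ `effect_size` (default 0.4). The default planted
subnetwork is a 7-edge spanning tree over 8 regions of the
orbitofrontal–thalamic–limbic circuit (`planted_subnetwork()`); the tree
is a documented fixture connecting the designated nodes. Because a
random template would rarely contain 7 specific edges, the template
generator always includes the requested effect edges; supplying a custom
template that lacks one is an error. Everything is a pure function of
the spec seed (bit-identical regeneration is tested).

**What passing tests show — and don't.** Planted-effect recovery and the
type-I error study validate the inferential machinery under a known
truth with realistic sparsity and noise. They do not establish anything
about real diffusion data: the generator has identical support across
subjects (up to dropout), no registration or motion artifacts, no
distance-dependent tractography bias, and groups differing only on the
planted edges. Likewise the phantoms validate geometry and signal
modeling, not crossing-fiber behavior — FACT on the single-tensor model
cannot resolve crossings, the known limitation of deterministic DTI
tractography.

# Problem sizes and determinism

The shipped validation uses problem sizes chosen so the full suite runs
comfortably on a laptop: phantoms of a few ×10⁴ voxels with 32-direction
schemes; 90-node cohorts at the study's group sizes; 5000 permutations
for planted-effect NBS runs and 1000 for each of the 200 null
replicates; 100 rewired nulls per threshold for the small-world sweeps
(unit tests use smaller ensembles). Every stochastic component — cohort
generation, DWI noise, permutation draws, null-network rewiring — is
driven by an explicit seed, with the caller's RNG stream left
undisturbed.

A note on the sigma sweep of a density-0.15 template: thresholds above
the template density cannot add edges, so the curve is flat there and
`threshold_sparsity()` warns; the warning is informational and expected
in that design.

# Worked example

```{r, eval = FALSE}
spec   <- cohort_spec(seed = 1)
cohort <- gen_cohort(spec)

## subnetwork inference
res <- nbs_fwe(cohort, t_threshold = 2.1, n_perm = 5000,
               direction = "decrease", seed = 2)
print(res)

## small-worldness of the shared template
sw <- metric_sweep(cohort$template,
                   nulls = null_model_config(n_null = 100, seed = 3))
range(sw$global$sigma)

## clinical statistics
power_two_sample_t(0.32, 0.37, 21, 25)
chisq_2x2(matrix(c(8, 13, 8, 17), 2, byrow = TRUE))
```

# Known limitations

* Single-tensor FACT: no crossing fibers, no probabilistic variants.
* No preprocessing (eddy/motion correction, skull stripping) and no
  atlas registration — inputs are assumed aligned.
* Lp's reachable-pair convention makes λ depend on how the null networks
  fragment at sparse thresholds; both observed and null networks use the
  same convention, which contains but does not eliminate the effect.
* The weight-pooled FA mean can, for pathologically unequal streamline
  lengths, let an added streamline lower an edge weight; with
  tractography output (near-equal lengths per bundle) the weight is
  monotone in fiber count.
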