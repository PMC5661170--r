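Package: fibernet
Title: Weighted White-Matter Connectome Construction and Group Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted whole-brain structural networks from diffusion
    tensor imaging: per-voxel tensor estimation with fractional anisotropy,
    deterministic FACT streamline tractography with angle and anisotropy
    stopping rules, and 90-region connectome construction with edge weights
    given by streamline count times mean fractional anisotropy. Provides
    sparsity-thresholded weighted graph metrics (clustering, path length,
    global/local/nodal efficiency) with small-world normalization against
    degree-preserving rewired null models, the network-based statistic for
    permutation-based family-wise-error-corrected subnetwork inference, and
    group-level clinical statistics (ANCOVA with covariates, FDR, partial
    correlation, two-sample power). Includes generators for diffusion phantoms
    and synthetic subject cohorts with planted group effects, so the whole
    pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
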