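# File interchange: NIfTI volumes (via RNifti), connectome CSVs with a
# cohort manifest and ground-truth sidecar, and streamlines as plain TSV
# or TrackVis TRK.

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the package's voxel-size bookkeeping.
#'
#' @param vol Numeric array (3-D or 4-D).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxdim Voxel size in mm.
#' @return `read_nifti_volume` returns a list `vol` (array) and `voxdim`.
#' @export
write_nifti_volume <- function(vol, path, voxdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxdim, rep(1, length(dim(vol)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(vol = array(as.numeric(img), dim(img)),
       voxdim = RNifti::pixdim(img)[1:min(3, length(dim(img)))])
}

#' Write / read a connectome matrix as CSV
#'
#' Region codes form the header and are restored as dimnames on read.
#'
#' @param W Symmetric weight matrix with region-code dimnames.
#' @param path CSV path.
#' @return `read_connectome_csv` returns the matrix.
#' @export
write_connectome_csv <- function(W, path) {
  write.csv(as.data.frame(W), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  W <- as.matrix(df)
  rownames(W) <- colnames(W)
  stopifnot_symmetric(W, basename(path))
  W
}

#' Write / read a cohort as a directory of CSVs
#'
#' One `<subject_id>.csv` connectome per subject, a `manifest.csv`
#' (subject_id, group, age, sex, HDRS, duration_months) and a
#' `ground_truth.json` sidecar holding the planted edges, effect size and
#' seed.
#'
#' @param cohort A `cohort` from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `read_cohort_dir` returns a `cohort` (without the template,
#'   which is not serialized).
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- cohort$manifest
  for (s in seq_len(nrow(mf)))
    write_connectome_csv(cohort$matrices[, , s],
                         file.path(dir, paste0(mf$subject_id[s], ".csv")))
  write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  if (!is.null(gt$effect_edges)) {
    ee <- gt$effect_edges
    gt$effect_edges <- lapply(seq_len(nrow(ee)),
                              function(r) unname(ee[r, ]))
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  mf <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  mats <- NULL
  for (s in seq_len(nrow(mf))) {
    W <- read_connectome_csv(file.path(dir, paste0(mf$subject_id[s],
                                                   ".csv")))
    if (is.null(mats))
      mats <- array(0, c(dim(W), nrow(mf)),
                    dimnames = c(dimnames(W), list(mf$subject_id)))
    mats[, , s] <- W
  }
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    if (!is.null(g$effect_edges)) {
      ee <- g$effect_edges
      if (is.list(ee)) ee <- do.call(rbind, ee)
      g$effect_edges <- matrix(as.integer(as.matrix(ee)), ncol = 2,
                               dimnames = list(NULL, c("i", "j")))
    }
    g
  } else NULL
  structure(list(matrices = mats, manifest = mf, template = NULL,
                 ground_truth = gt), class = "cohort")
}

#' Write / read streamlines as TSV
#'
#' Plain-text exchange format: one row per point with columns
#' `streamline_id`, `point_index`, `x`, `y`, `z` (continuous 0-based voxel
#' coordinates).
#'
#' @param streamlines A `streamline_set` or list of streamlines.
#' @param path TSV path.
#' @return `read_streamlines_tsv` returns a `streamline_set`.
#' @export
write_streamlines_tsv <- function(streamlines, path) {
  rows <- lapply(seq_along(streamlines), function(k) {
    p <- streamlines[[k]]$points
    data.frame(streamline_id = k, point_index = seq_len(nrow(p)) - 1L,
               x = p[, 1], y = p[, 2], z = p[, 3])
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_streamlines_tsv
#' @export
read_streamlines_tsv <- function(path) {
  df <- read.delim(path)
  out <- lapply(split(df, df$streamline_id), function(d) {
    d <- d[order(d$point_index), ]
    list(points = unname(as.matrix(d[, c("x", "y", "z")])), seed = NA)
  })
  structure(unname(out), class = "streamline_set")
}

#' Write / read streamlines in TrackVis TRK format
#'
#' Binary TRK version 2 with the voxel-mm convention: point coordinates
#' are continuous voxel coordinates multiplied by the voxel size. `dim`
#' and `voxel_size` are recorded in the header; no scalars or properties
#' are stored.
#'
#' @param streamlines A `streamline_set` or list of streamlines (points in
#'   continuous 0-based voxel coordinates).
#' @param path TRK path.
#' @param dim Volume dimensions (voxels).
#' @param voxdim Voxel size in mm.
#' @return `read_trk` returns a `streamline_set` (points converted back
#'   to voxel coordinates), with `dim` and `voxdim` attributes.
#' @export
write_trk <- function(streamlines, path, dim, voxdim = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(raw(1), con)
  writeBin(as.integer(dim), con, size = 2)
  writeBin(as.numeric(voxdim), con, size = 4)
  writeBin(numeric(3), con, size = 4)                 # origin
  writeBin(0L, con, size = 2)                          # n_scalars
  writeBin(raw(200), con)                              # scalar names
  writeBin(0L, con, size = 2)                          # n_properties
  writeBin(raw(200), con)                              # property names
  m <- diag(4); m[1, 1] <- voxdim[1]; m[2, 2] <- voxdim[2]
  m[3, 3] <- voxdim[3]
  writeBin(as.numeric(t(m)), con, size = 4)            # vox_to_ras
  writeBin(raw(444), con)                              # reserved
  writeBin(c(charToRaw("LPS"), raw(1)), con)           # voxel_order
  writeBin(raw(4), con)                                # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)
  writeBin(raw(2), con)                                # pad1
  writeBin(raw(6), con)                                # invert/swap flags
  writeBin(as.integer(length(streamlines)), con, size = 4)
  writeBin(2L, con, size = 4)                          # version
  writeBin(1000L, con, size = 4)                       # hdr_size
  for (s in streamlines) {
    p <- sweep(s$points, 2, voxdim, `*`)
    writeBin(nrow(p), con, size = 4)
    writeBin(as.numeric(t(p)), con, size = 4)
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("not a TRK file", call. = FALSE)
  dim3 <- readBin(con, "integer", 3, size = 2)
  voxdim <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  readBin(con, "numeric", 16, size = 4)
  readBin(con, "raw", 444 + 4 + 4)
  readBin(con, "numeric", 6, size = 4)
  readBin(con, "raw", 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 2, size = 4)                 # version, hdr_size
  out <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4)
    if (length(np) == 0) break
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4)
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    p <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3,
                                                          drop = FALSE]
    p <- sweep(p, 2, voxdim, `/`)
    out <- c(out, list(list(points = p, seed = NA)))
  }
  if (n_count > 0 && length(out) != n_count)
    warning("TRK header count (", n_count, ") differs from tracks read (",
            length(out), ")", call. = FALSE)
  structure(out, class = "streamline_set", volume_dim = dim3,
            voxdim = voxdim)
}
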