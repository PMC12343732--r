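# Dataset input/output: FSL-dialect bval/bvec gradient tables, DWI + mask
# reading with shell detection, SH-field images, phantom export, and run
# manifests.

#' Read an FSL-format gradient table
#'
#' `bvals`: one row of per-volume b-values. `bvecs`: 3 rows x V columns of
#' unit gradient directions (a V x 3 table is accepted with a warning).
#'
#' @param bval_path,bvec_path file paths.
#' @return list with `bvals` (length V) and `bvecs` (V x 3).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) {
    bvecs <- t(bv)
  } else if (ncol(bv) == 3L && nrow(bv) != 3L) {
    warning("bvec file appears to be V x 3; transposing to the FSL 3 x V dialect")
    bvecs <- bv
  } else if (all(dim(bv) == 3L)) {
    bvecs <- t(bv)
  } else {
    stop("bvec file must have 3 rows (FSL dialect); got ",
         nrow(bv), " x ", ncol(bv))
  }
  dimnames(bvecs) <- NULL
  if (length(bvals) != nrow(bvecs))
    stop("gradient table mismatch: ", length(bvals), " bvals vs ",
         nrow(bvecs), " bvecs")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- which(bvals > 0 & abs(nrm - 1) > 1e-3)
  if (length(bad))
    stop("bvec column ", bad[1L], " is not unit-norm (|v| = ",
         format(nrm[bad[1L]], digits = 6), ")")
  list(bvals = bvals, bvecs = bvecs)
}

#' Read a multi-shell DWI dataset
#'
#' Volumes are grouped into shells by b-value (within +/- `b_tol` s/mm^2 of
#' each shell's mean, ascending); b = 0 volumes form their own group and are
#' excluded from SH fitting.
#'
#' @param dwi_path 4D NIfTI of diffusion-weighted volumes.
#' @param bval_path,bvec_path FSL gradient table.
#' @param mask_path optional binary mask NIfTI.
#' @param b_tol shell clustering tolerance in s/mm^2.
#' @return object of class `dwi_dataset`: `data` (4D array), `bvals`,
#'   `bvecs`, `mask`, `affine`, `shells` (per-shell volume indices),
#'   `shell_bvals`, `b0_idx`.
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path, mask_path = NULL,
                     b_tol = 50) {
  img <- read_nifti(dwi_path)
  if (length(img$dim) != 4L) stop("DWI image must be 4D")
  gt <- read_bvals_bvecs(bval_path, bvec_path)
  if (img$dim[4L] != length(gt$bvals))
    stop("volume count mismatch: image has ", img$dim[4L],
         " volumes, bvals has ", length(gt$bvals))
  mask <- if (is.null(mask_path)) array(TRUE, img$dim[1:3])
          else read_nifti(mask_path)$data > 0
  if (!all(dim(mask) == img$dim[1:3])) stop("mask grid does not match DWI")
  b0_idx <- which(gt$bvals <= b_tol)
  rest <- setdiff(seq_along(gt$bvals), b0_idx)
  ub <- sort(unique(gt$bvals[rest]))
  centers <- c()
  for (b in ub) if (!length(centers) || b - centers[length(centers)] > b_tol)
    centers <- c(centers, b)
  shells <- lapply(centers, function(ct)
    rest[abs(gt$bvals[rest] - ct) <= b_tol])
  if (length(unlist(shells)) != length(rest))
    stop("shell grouping at tolerance ", b_tol, " is not total and disjoint")
  structure(list(data = img$data, bvals = gt$bvals, bvecs = gt$bvecs,
                 mask = mask, affine = img$affine, shells = shells,
                 shell_bvals = centers, b0_idx = b0_idx),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat("<dwi_dataset> ", paste(dim(x$data)[1:3], collapse = " x "), " grid, ",
      dim(x$data)[4L], " volumes (", length(x$b0_idx), " b0)\n", sep = "")
  for (i in seq_along(x$shells))
    cat("  b ~ ", x$shell_bvals[i], ": ", length(x$shells[[i]]),
        " directions\n", sep = "")
  invisible(x)
}

#' Write / read an SH coefficient field as 4D NIfTI (45 volumes)
#'
#' @param field a [fod_field()].
#' @param path output path.
#' @param affine 4 x 4 transform.
#' @export
write_sh_image <- function(field, path, affine = diag(4)) {
  stopifnot(inherits(field, "fod_field"))
  if (field$K != 45L)
    stop("SH image must have 45 channels, got ", field$K)
  write_nifti(field$coef, path, affine)
  invisible(path)
}

#' @rdname write_sh_image
#' @param mask_path optional mask NIfTI to attach on read.
#' @export
read_sh_image <- function(path, mask_path = NULL) {
  img <- read_nifti(path)
  if (length(img$dim) != 4L || img$dim[4L] != 45L)
    stop("SH image must be 4D with 45 channels, got ",
         paste(img$dim, collapse = " x "))
  mask <- if (is.null(mask_path)) NULL else read_nifti(mask_path)$data > 0
  fod_field(img$data, mask = mask)
}

# pack a phantom's voxel list into a compact 3D grid
phantom_grid <- function(n) {
  nx <- ceiling(n^(1 / 3)); ny <- ceiling(sqrt(n / nx))
  nz <- ceiling(n / (nx * ny))
  c(nx, ny, nz)
}

#' Write a phantom to disk as a standard DWI dataset
#'
#' Voxels are packed into a compact 3D grid. Outputs: `dwi.nii.gz` (b0
#' volumes first, then shells ascending), FSL `bvals`/`bvecs`,
#' `mask.nii.gz`, `fod_gt.nii.gz` (45-channel ground truth), and
#' `manifest.yaml`.
#'
#' @param phantom a [generate_phantom()] object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- phantom$n_voxels
  gd <- phantom_grid(n)
  nvol <- ncol(phantom$b0) + sum(vapply(phantom$dwi, ncol, 1L))
  vols <- cbind(phantom$b0, do.call(cbind, phantom$dwi))
  full <- matrix(0, prod(gd), nvol)
  full[seq_len(n), ] <- vols
  write_nifti(array(full, c(gd, nvol)), file.path(dir, "dwi.nii.gz"))
  mask <- array(FALSE, gd); mask[seq_len(n)] <- TRUE
  write_nifti(array(as.numeric(mask), gd), file.path(dir, "mask.nii.gz"))
  gtf <- fod_field(phantom$fod_sh, dim = gd, mask = mask)
  write_sh_image(gtf, file.path(dir, "fod_gt.nii.gz"))
  bvals <- c(rep(0, ncol(phantom$b0)),
             rep(phantom$protocol$bvals, phantom$protocol$counts))
  bvecs <- cbind(matrix(0, 3L, ncol(phantom$b0)),
                 do.call(cbind, lapply(phantom$protocol$shells,
                                       function(s) t(s$dirs))))
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             file.path(dir, "bvals"))
  utils::write.table(format(bvecs, digits = 17, trim = TRUE),
                     file.path(dir, "bvecs"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    n_voxels = n, grid = as.integer(gd), snr = phantom$snr,
    sigma = phantom$sigma, seed = phantom$seed, lmax = phantom$lmax,
    d_par = phantom$d_par, d_perp = phantom$d_perp,
    shells = lapply(phantom$protocol$shells,
                    function(s) list(b = s$b, n = s$n)),
    split = lapply(phantom$split, as.integer)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Predict a 45-channel FOD field from a DWI dataset
#'
#' Intensity-normalizes the DWI (negatives zeroed, 95th-percentile clip
#' inside the mask), divides by the mean b = 0 signal, fits per-shell SH
#' inside the mask, and runs the model voxel-wise. Voxels outside the mask
#' are all-zero.
#'
#' @param model a trained [scnn_model()] or [mlp_model()].
#' @param dwi a [read_dwi()] dataset.
#' @param normalize apply [normalize_intensity()] first.
#' @param ridge per-shell SH fit ridge.
#' @param batch voxels per forward batch.
#' @return a [fod_field()] on the DWI grid.
#' @export
predict_fod <- function(model, dwi, normalize = TRUE, ridge = 1e-3,
                        batch = 4096L) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  vol <- dwi$data
  if (normalize) vol <- normalize_intensity(vol, array(dwi$mask,
                                                       dim(vol)[1:3]))
  vox <- which(as.vector(dwi$mask))
  flat <- matrix(vol, prod(dim(vol)[1:3]), dim(vol)[4L])
  s0 <- if (length(dwi$b0_idx))
    rowMeans(flat[vox, dwi$b0_idx, drop = FALSE]) else rep(1, length(vox))
  s0[s0 <= 0] <- 1
  proto <- structure(list(
    shells = lapply(seq_along(dwi$shells), function(i)
      list(b = dwi$shell_bvals[i], n = length(dwi$shells[[i]]),
           dirs = dwi$bvecs[dwi$shells[[i]], , drop = FALSE])),
    bvals = dwi$shell_bvals,
    counts = lengths(dwi$shells)), class = "dmri_protocol")
  shell_sig <- lapply(dwi$shells, function(ii)
    flat[vox, ii, drop = FALSE] / s0)
  ms <- fit_per_shell_sh(shell_sig, proto, lmax = model$config$lmax,
                         ridge = ridge)
  K <- model$config$K
  out <- matrix(0, nrow(flat), K)
  for (start in seq(1L, length(vox), by = batch)) {
    ii <- start:min(start + batch - 1L, length(vox))
    out[vox[ii], ] <- model_forward(model, unclass(ms)[ii, , , drop = FALSE])
  }
  fod_field(array(out, c(dim(vol)[1:3], K)), mask = dwi$mask)
}

#' Write a run manifest describing a CLI invocation
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param config named list of effective settings.
#' @param seed integer seed.
#' @param inputs character vector of input paths (md5-digested).
#' @param outputs character vector of output paths.
#' @return manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, config, seed, inputs = character(),
                               outputs = character()) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  path <- file.path(dir, "run_manifest.yaml")
  yaml::write_yaml(list(
    command = command,
    package_version = as.character(utils::packageVersion("sphfod")),
    seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, input_digests = digests,
    outputs = as.list(outputs)), path)
  invisible(path)
}
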