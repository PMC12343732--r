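# Evaluation metrics for FOD fields: SH-domain MSE, angular correlation
# coefficient (ACC), channel-wise 3D SSIM, PSNR, peak extraction, angular
# error of principal peaks, and peak match rate.

#' A voxel grid of SH coefficient vectors with a mask
#'
#' @param coef n_voxels x K matrix, or a 4D array [x, y, z, K].
#' @param dim grid dimensions (required when `coef` is a matrix).
#' @param mask logical array [x, y, z]; defaults to all TRUE. Metrics are
#'   computed inside the mask only.
#' @return object of class `fod_field` with elements `coef` (4D array),
#'   `mask`, `dim`, `K`.
#' @export
fod_field <- function(coef, dim = NULL, mask = NULL) {
  if (is.matrix(coef)) {
    if (is.null(dim)) {
      n <- nrow(coef)
      nx <- ceiling(n^(1 / 3))
      ny <- ceiling(sqrt(n / nx))
      nz <- ceiling(n / (nx * ny))
      dim <- c(nx, ny, nz)
    }
    K <- ncol(coef)
    full <- matrix(0, prod(dim), K)
    full[seq_len(nrow(coef)), ] <- coef
    if (is.null(mask)) {
      mask <- array(FALSE, dim)
      mask[seq_len(nrow(coef))] <- TRUE
    }
    coef <- array(full, c(dim, K))
  } else {
    stopifnot(length(base::dim(coef)) == 4L)
    dim <- base::dim(coef)[1:3]
    K <- base::dim(coef)[4L]
    if (is.null(mask)) mask <- array(TRUE, dim)
  }
  stopifnot(all(base::dim(mask) == dim))
  structure(list(coef = coef, mask = mask, dim = dim, K = K),
            class = "fod_field")
}

#' @export
print.fod_field <- function(x, ...) {
  cat("<fod_field> ", paste(x$dim, collapse = " x "), " grid, K = ", x$K,
      ", ", sum(x$mask), " voxels in mask\n", sep = "")
  invisible(x)
}

# masked n x K matrix view
field_mat <- function(f) {
  m <- matrix(f$coef, prod(f$dim), f$K)
  m[as.vector(f$mask), , drop = FALSE]
}

check_aligned <- function(pred, gt) {
  stopifnot(inherits(pred, "fod_field"), inherits(gt, "fod_field"))
  if (!all(pred$dim == gt$dim) || pred$K != gt$K)
    stop("fields are not aligned (grid or K mismatch)")
  if (!any(pred$mask & gt$mask)) stop("masks are disjoint")
}

#' SH-domain mean squared error between two FOD fields
#'
#' Mean over masked voxels of the squared Euclidean distance between SH
#' coefficient vectors: MSE = (1/N) sum_i ||S_hat_i - S_i||^2.
#'
#' @param pred,gt `fod_field` objects on the same grid.
#' @return scalar.
#' @export
sh_mse <- function(pred, gt) {
  check_aligned(pred, gt)
  d <- field_mat(pred) - field_mat(gt)
  mean(rowSums(d^2))
}

#' Angular correlation coefficient per voxel
#'
#' Cosine similarity between the two FOD amplitude profiles on a dense
#' sampling (plain cosine form, l = 0 term included; set
#' `exclude_l0 = TRUE` for the classical Anderson variant).
#'
#' @param pred_sh,gt_sh n x K matrices (or length-K vectors).
#' @param sampling a [make_sampling()] object.
#' @param exclude_l0 drop the l = 0 coefficient before comparing.
#' @return list with `per_voxel` (length n, NA where a profile has zero
#'   norm), `mean`, `sd`, `n_excluded`.
#' @export
acc <- function(pred_sh, gt_sh, sampling, exclude_l0 = FALSE) {
  if (is.null(dim(pred_sh))) pred_sh <- matrix(pred_sh, nrow = 1L)
  if (is.null(dim(gt_sh))) gt_sh <- matrix(gt_sh, nrow = 1L)
  stopifnot(all(dim(pred_sh) == dim(gt_sh)))
  if (exclude_l0) {
    pred_sh <- pred_sh[, -1L, drop = FALSE]
    gt_sh <- gt_sh[, -1L, drop = FALSE]
    U <- sampling$U[, -1L, drop = FALSE]
  } else U <- sampling$U
  Ap <- pred_sh %*% t(U)
  Ag <- gt_sh %*% t(U)
  np <- sqrt(rowSums(Ap^2)); ng <- sqrt(rowSums(Ag^2))
  ok <- np > 0 & ng > 0
  out <- rep(NA_real_, nrow(Ap))
  out[ok] <- rowSums(Ap[ok, , drop = FALSE] * Ag[ok, , drop = FALSE]) /
    (np[ok] * ng[ok])
  list(per_voxel = out, mean = mean(out[ok]), sd = stats::sd(out[ok]),
       n_excluded = sum(!ok))
}

cumsum_axis <- function(a, ax) {
  perm <- c(ax, setdiff(1:3, ax))
  b <- apply(aperm(a, perm), c(2L, 3L), cumsum)
  aperm(b, order(perm))
}

# 3D "valid"-region box-filter mean via cumulative sums.
box_mean_3d <- function(a, w) {
  d <- dim(a)
  cs <- a
  for (ax in 1:3) cs <- cumsum_axis(cs, ax)
  pad <- function(x) {
    out <- array(0, dim(x) + 1L)
    out[-1L, -1L, -1L] <- x
    out
  }
  cs <- pad(cs)
  nx <- d[1L] - w + 1L; ny <- d[2L] - w + 1L; nz <- d[3L] - w + 1L
  i0 <- seq_len(nx); j0 <- seq_len(ny); k0 <- seq_len(nz)
  s <- cs[i0 + w, j0 + w, k0 + w, drop = FALSE] -
    cs[i0, j0 + w, k0 + w, drop = FALSE] -
    cs[i0 + w, j0, k0 + w, drop = FALSE] -
    cs[i0 + w, j0 + w, k0, drop = FALSE] +
    cs[i0, j0, k0 + w, drop = FALSE] +
    cs[i0, j0 + w, k0, drop = FALSE] +
    cs[i0 + w, j0, k0, drop = FALSE] -
    cs[i0, j0, k0, drop = FALSE]
  s / w^3
}

# SSIM of two 3D arrays: uniform window, interior (fully valid) region only,
# standard constants C1 = (0.01 L)^2, C2 = (0.03 L)^2.
ssim_3d <- function(a, b, data_range, win = 7L) {
  if (any(dim(a) < win)) stop("volume smaller than SSIM window")
  if (data_range == 0) return(1.0)  # both constant
  mu_a <- box_mean_3d(a, win); mu_b <- box_mean_3d(b, win)
  va <- box_mean_3d(a^2, win) - mu_a^2
  vb <- box_mean_3d(b^2, win) - mu_b^2
  cab <- box_mean_3d(a * b, win) - mu_a * mu_b
  # unbiased (n/(n-1)) variance/covariance, as in the standard implementation
  f <- win^3 / (win^3 - 1)
  va <- va * f; vb <- vb * f; cab <- cab * f
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Channel-wise 3D SSIM between two FOD fields
#'
#' SSIM is computed independently for each SH coefficient channel as a 3D
#' volume (7^3 uniform window, means over the fully-valid interior) and
#' averaged over channels. The per-channel data range is the ground-truth
#' channel's max - min; a channel constant in both fields scores 1.
#'
#' @param pred,gt `fod_field` objects (>= 8 voxels per dimension).
#' @param win odd window width.
#' @return scalar in [-1, 1].
#' @export
ssim_per_channel <- function(pred, gt, win = 7L) {
  check_aligned(pred, gt)
  if (any(gt$dim < 8L)) stop("need >= 8 voxels per dimension for SSIM")
  vals <- vapply(seq_len(gt$K), function(k) {
    a <- pred$coef[, , , k]; b <- gt$coef[, , , k]
    ssim_3d(a, b, data_range = max(b) - min(b), win = win)
  }, numeric(1L))
  mean(vals)
}

#' Peak signal-to-noise ratio between two FOD fields
#'
#' 10 log10(data_range^2 / MSE) with data_range = max |gt| over masked SH
#' entries and MSE the per-entry mean squared error over masked voxels.
#'
#' @param pred,gt `fod_field` objects.
#' @return value in dB; +Inf for identical fields.
#' @export
psnr <- function(pred, gt) {
  check_aligned(pred, gt)
  p <- field_mat(pred); g <- field_mat(gt)
  mse <- mean((p - g)^2)
  if (mse == 0) return(Inf)
  dr <- max(abs(g))
  10 * log10(dr^2 / mse)
}

#' Extract FOD peaks on a dense icosphere sampling
#'
#' Local maxima of the reconstructed amplitude over the sampling's neighbor
#' graph, keeping peaks with amplitude >= `rel_threshold` times the global
#' maximum, antipodally deduplicated, then greedily suppressed within
#' `min_sep` degrees, sorted by descending amplitude.
#'
#' @param fod_sh length-K SH vector.
#' @param sampling an icosphere [make_sampling()] with a neighbor graph
#'   (>= 2000 points advised).
#' @param rel_threshold relative amplitude threshold (default 0.3).
#' @param min_sep minimum angular separation between peaks in degrees.
#' @param refine polish each retained peak off the grid with a few 2D
#'   Newton steps on the sphere (standard practice; makes peak directions
#'   continuum maxima, hence exactly rotation-covariant).
#' @return object of class `peak_set`: list with `dirs` (n x 3) and `amp`.
#' @export
extract_peaks <- function(fod_sh, sampling, rel_threshold = 0.3,
                          min_sep = 25, refine = TRUE) {
  if (is.null(sampling$neighbors))
    stop("peak extraction needs an icosphere sampling (neighbor graph)")
  a <- if (is.null(attr(fod_sh, "amplitudes"))) drop(sampling$U %*% fod_sh)
       else attr(fod_sh, "amplitudes")
  amax <- max(a)
  if (amax <= 0)
    return(structure(list(dirs = matrix(0, 0L, 3L), amp = numeric(0)),
                     class = "peak_set"))
  nm <- neighbor_matrix(sampling)
  nbv <- matrix(a[nm], nrow(nm))
  nb_max <- nbv[, 1L]
  for (cc in 2:ncol(nbv)) nb_max <- pmax(nb_max, nbv[, cc])
  cand <- which(a > 0 & a >= nb_max & a >= rel_threshold * amax)
  cand <- cand[order(a[cand], decreasing = TRUE)]
  dirs <- matrix(numeric(0), 0L, 3L); amp <- numeric(0)
  lmax <- sampling$lmax
  for (i in cand) {
    v <- sampling$dirs[i, ]
    if (nrow(dirs) == 0L ||
        all(acos(pmin(1, abs(dirs %*% v))) * 180 / pi >= min_sep)) {
      if (refine) {
        v <- refine_peak(fod_sh, v, lmax)
      }
      v <- if (v[3L] < 0 || (v[3L] == 0 && v[1L] < 0)) -v else v
      dirs <- rbind(dirs, v)
      amp <- c(amp, drop(build_basis(matrix(v, 1L), lmax) %*% fod_sh))
    }
  }
  structure(list(dirs = dirs, amp = amp), class = "peak_set")
}

# orthonormal tangent pair at a unit vector
tangent_basis <- function(v) {
  a <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * v) * v
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(v[2L] * t1[3L] - v[3L] * t1[2L],
          v[3L] * t1[1L] - v[1L] * t1[3L],
          v[1L] * t1[2L] - v[2L] * t1[1L])
  list(t1 = t1, t2 = t2)
}

# Newton polish of an SH-polynomial maximum on the sphere, starting from a
# grid local maximum; finite-difference 2x2 Hessian in the tangent plane.
refine_peak <- function(coeffs, v, lmax, iters = 12L, h = 1e-4) {
  fval <- function(M) {
    M <- M / sqrt(rowSums(M^2))
    drop(build_basis(M, lmax) %*% coeffs)
  }
  for (it in seq_len(iters)) {
    tb <- tangent_basis(v)
    P <- rbind(v,
               v + h * tb$t1, v - h * tb$t1,
               v + h * tb$t2, v - h * tb$t2,
               v + h * (tb$t1 + tb$t2))
    fv <- fval(P)
    g <- c((fv[2L] - fv[3L]) / (2 * h), (fv[4L] - fv[5L]) / (2 * h))
    h11 <- (fv[2L] + fv[3L] - 2 * fv[1L]) / h^2
    h22 <- (fv[4L] + fv[5L] - 2 * fv[1L]) / h^2
    h12 <- (fv[6L] - fv[2L] - fv[4L] + fv[1L]) / h^2
    H <- matrix(c(h11, h12, h12, h22), 2L)
    step <- tryCatch(-solve(H, g), error = function(e) 0.05 * g)
    if (!all(is.finite(step))) break
    # only trust Newton near a genuine maximum; otherwise take a small
    # ascent step
    if (h11 >= 0 || h11 * h22 - h12^2 <= 0) step <- 0.05 * g
    sn <- sqrt(sum(step^2))
    if (sn > 0.2) step <- step * (0.2 / sn)
    vn <- v + step[1L] * tb$t1 + step[2L] * tb$t2
    vn <- vn / sqrt(sum(vn^2))
    if (fval(matrix(vn, 1L)) < fv[1L]) break
    moved <- sqrt(sum((vn - v)^2))
    v <- vn
    if (moved < 1e-10) break
  }
  v
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", length(x$amp), " peak(s)\n", sep = "")
  invisible(x)
}

#' Antipodally symmetric angle between principal peak directions
#'
#' @param pred_peaks,gt_peaks `peak_set` objects (or unit 3-vectors).
#' @return angle in degrees in [0, 90]; NA if either set is empty.
#' @export
angular_error <- function(pred_peaks, gt_peaks) {
  dir1 <- if (inherits(pred_peaks, "peak_set")) {
    if (length(pred_peaks$amp) == 0L) return(NA_real_)
    pred_peaks$dirs[1L, ]
  } else pred_peaks
  dir2 <- if (inherits(gt_peaks, "peak_set")) {
    if (length(gt_peaks$amp) == 0L) return(NA_real_)
    gt_peaks$dirs[1L, ]
  } else gt_peaks
  acos(pmin(1, abs(sum(dir1 * dir2)))) * 180 / pi
}

# Padded neighbor index matrix for vectorized local-maximum detection
# (padded with the vertex's own index, so ties remain maxima). Cached per
# sampling size.
.nbr_cache <- new.env(parent = emptyenv())
neighbor_matrix <- function(sampling) {
  key <- paste0(sampling$scheme, "_", sampling$n)
  hit <- .nbr_cache[[key]]
  if (!is.null(hit)) return(hit)
  deg <- max(lengths(sampling$neighbors))
  nm <- matrix(rep(seq_len(sampling$n), deg), sampling$n, deg)
  for (i in seq_len(sampling$n))
    nm[i, seq_along(sampling$neighbors[[i]])] <- sampling$neighbors[[i]]
  .nbr_cache[[key]] <- nm
  nm
}

# principal-peak angular errors for aligned fields; NA marks invalid voxels
field_angular_errors <- function(pred, gt, sampling, rel_threshold = 0.3,
                                 min_sep = 25) {
  check_aligned(pred, gt)
  p <- field_mat(pred); g <- field_mat(gt)
  Ut <- t(sampling$U)
  n <- nrow(p)
  out <- numeric(n)
  for (start in seq(1L, n, by = 256L)) {
    ii <- start:min(start + 255L, n)
    Ap <- p[ii, , drop = FALSE] %*% Ut
    Ag <- g[ii, , drop = FALSE] %*% Ut
    for (j in seq_along(ii)) {
      fp <- p[ii[j], ]; attr(fp, "amplitudes") <- Ap[j, ]
      fg <- g[ii[j], ]; attr(fg, "amplitudes") <- Ag[j, ]
      out[ii[j]] <- angular_error(
        extract_peaks(fp, sampling, rel_threshold, min_sep),
        extract_peaks(fg, sampling, rel_threshold, min_sep))
    }
  }
  out
}

#' Peak match rate between two FOD fields
#'
#' Fraction of valid masked voxels whose principal-peak angular error is
#' strictly below `threshold_deg`.
#'
#' @param pred,gt `fod_field` objects.
#' @param sampling dense icosphere sampling for peak extraction.
#' @param threshold_deg angular threshold in degrees (default 20).
#' @param errors optional precomputed [field_angular_errors()] vector.
#' @return list with `rate`, `n_valid`, `n_invalid`.
#' @export
peak_match_rate <- function(pred, gt, sampling, threshold_deg = 20,
                            errors = NULL) {
  if (is.null(errors))
    errors <- field_angular_errors(pred, gt, sampling)
  ok <- !is.na(errors)
  if (!any(ok)) stop("no valid voxels (no extractable peaks)")
  list(rate = mean(errors[ok] < threshold_deg),
       n_valid = sum(ok), n_invalid = sum(!ok))
}

#' Full metric report comparing a predicted FOD field with ground truth
#'
#' Global scalars (SH-MSE, channel-wise SSIM, PSNR) and FOD-wise summaries
#' (ACC mean +/- sd, principal-peak angular error mean +/- sd, peak match
#' rate at 20 degrees).
#'
#' @param pred,gt `fod_field` objects.
#' @param sampling dense sampling for ACC (any scheme).
#' @param peak_sampling icosphere sampling for peaks (defaults to a
#'   2562-point icosphere).
#' @param ssim compute SSIM (needs >= 8 voxels per dimension).
#' @param keep_per_voxel attach per-voxel ACC and angular-error vectors
#'   (for writing metric maps).
#' @return list of class `metric_report`.
#' @export
evaluate_fields <- function(pred, gt, sampling = NULL, peak_sampling = NULL,
                            ssim = TRUE, keep_per_voxel = FALSE) {
  check_aligned(pred, gt)
  if (is.null(sampling)) sampling <- make_sampling(724L, "fibonacci",
                                                   lmax_from_k(gt$K))
  if (is.null(peak_sampling))
    peak_sampling <- make_sampling(2562L, "icosphere", lmax_from_k(gt$K))
  p <- field_mat(pred); g <- field_mat(gt)
  acc_r <- acc(p, g, sampling)
  errs <- field_angular_errors(pred, gt, peak_sampling)
  pmr <- peak_match_rate(pred, gt, peak_sampling, errors = errs)
  ok <- !is.na(errs)
  structure(list(
    global = list(mse = sh_mse(pred, gt),
                  ssim = if (ssim) ssim_per_channel(pred, gt) else NA_real_,
                  psnr = psnr(pred, gt)),
    fod_wise = list(acc_mean = acc_r$mean, acc_sd = acc_r$sd,
                    ae_mean = mean(errs[ok]), ae_sd = stats::sd(errs[ok]),
                    pmr = pmr$rate),
    n_voxels = nrow(p), n_invalid = pmr$n_invalid,
    acc_excluded = acc_r$n_excluded,
    per_voxel = if (keep_per_voxel) list(acc = acc_r$per_voxel,
                                         ae = errs) else NULL),
    class = "metric_report")
}

lmax_from_k <- function(K) {
  l <- (sqrt(8 * K + 1) - 3) / 2  # K = (l/2+1)(l+1)
  as.integer(round(l))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Global scalar:\n")
  cat(sprintf("  MSE   %.6f\n  SSIM  %.4f\n  PSNR  %.2f dB\n",
              x$global$mse, x$global$ssim, x$global$psnr))
  cat("FOD-wise:\n")
  cat(sprintf("  ACC            %.4f +/- %.4f\n", x$fod_wise$acc_mean,
              x$fod_wise$acc_sd))
  cat(sprintf("  Mean ang. err  %.2f +/- %.2f deg\n", x$fod_wise$ae_mean,
              x$fod_wise$ae_sd))
  cat(sprintf("  Peak match     %.3f (20 deg)\n", x$fod_wise$pmr))
  cat(x$n_voxels, "voxels,", x$n_invalid, "invalid,",
      x$acc_excluded, "ACC-excluded\n")
  invisible(x)
}

#' Write a metric report as JSON or CSV
#' @param report a `metric_report`.
#' @param path output path; format chosen by extension (.json or .csv).
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    df <- data.frame(
      metric = c("mse", "ssim", "psnr", "acc_mean", "acc_sd", "ae_mean",
                 "ae_sd", "pmr", "n_voxels", "n_invalid"),
      value = c(report$global$mse, report$global$ssim, report$global$psnr,
                report$fod_wise$acc_mean, report$fod_wise$acc_sd,
                report$fod_wise$ae_mean, report$fod_wise$ae_sd,
                report$fod_wise$pmr, report$n_voxels, report$n_invalid))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
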