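#' Reduced multi-shell acquisition protocol
#'
#' Builds the reduced three-shell protocol used for training: taking a
#' fraction (default 30%) of the full 64/88/128 directions at
#' b = 400/1000/2600 s/mm^2 gives 19/26/38 directions (83 total). Directions
#' are deterministic well-spread (golden-angle) sets per shell; each shell's
#' set is decorrelated from the others by a fixed rotation about z.
#'
#' @param full_counts directions per shell in the full protocol.
#' @param fraction fraction of directions to keep, in (0, 1].
#' @param bvals shell b-values in s/mm^2, ascending.
#' @return object of class `dmri_protocol`: list of shells, each with `b`,
#'   `n`, and `dirs` (n x 3 unit vectors).
#' @export
protocol_reduced <- function(full_counts = c(64L, 88L, 128L),
                             fraction = 0.30,
                             bvals = c(400, 1000, 2600)) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  stopifnot(length(full_counts) == length(bvals))
  counts <- as.integer(floor(fraction * full_counts))
  if (any(counts < 6L))
    stop("shell at b = ", bvals[which(counts < 6L)[1L]],
         " would have fewer than 6 directions")
  shells <- lapply(seq_along(bvals), function(i) {
    ang <- 2 * pi * (i - 1) / length(bvals) * (sqrt(2) - 1)
    Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3L)
    list(b = bvals[i], n = counts[i], dirs = fibonacci_sphere(counts[i]) %*% Rz)
  })
  structure(list(shells = shells, bvals = bvals, counts = counts,
                 n_total = sum(counts)),
            class = "dmri_protocol")
}

#' Full-protocol convenience wrapper (fraction = 1)
#' @inheritParams protocol_reduced
#' @export
protocol_full <- function(full_counts = c(64L, 88L, 128L),
                          bvals = c(400, 1000, 2600)) {
  protocol_reduced(full_counts, 1.0, bvals)
}

#' @export
print.dmri_protocol <- function(x, ...) {
  cat("<dmri_protocol> ", length(x$shells), " shells, ",
      x$n_total, " directions\n", sep = "")
  for (s in x$shells)
    cat("  b = ", s$b, " s/mm^2: ", s$n, " directions\n", sep = "")
  invisible(x)
}

#' Axially symmetric diffusion-tensor signal
#'
#' The simulator's single-fiber kernel:
#' S(b, g; v) = exp(-b (d_perp + (d_par - d_perp) (g . v)^2)).
#'
#' @param b b-value in s/mm^2 (>= 0).
#' @param g gradient direction(s), unit 3-vector or N x 3 matrix.
#' @param v fiber direction, unit 3-vector.
#' @param d_par,d_perp parallel / perpendicular diffusivities in mm^2/s.
#' @return signal amplitude(s) in (0, 1].
#' @export
tensor_signal <- function(b, g, v, d_par = 1.7e-3, d_perp = 0.4e-3) {
  if (b < 0) stop("`b` must be non-negative")
  if (d_perp > d_par || d_perp < 0) stop("need d_par >= d_perp >= 0")
  g <- check_unit_dirs(g, tol = 1e-6)
  v <- as.numeric(v)
  ct <- drop(g %*% v)
  exp(-b * (d_perp + (d_par - d_perp) * ct^2))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1L, ord]^2)
}

#' Zonal SH response of the tensor kernel
#'
#' Projects the axially symmetric kernel onto normalized zonal harmonics:
#' r_l = 2 pi * integral_{-1}^{1} S(t) Pbar_l(t) dt, computed by
#' Gauss-Legendre quadrature. Feeding r_l to [sh_convolve()] realizes the
#' spherical convolution of a response function with an FOD (Funk-Hecke).
#'
#' @inheritParams tensor_signal
#' @param lmax even band limit.
#' @param n_quad quadrature order (>= 64).
#' @return named vector r_l for l = 0, 2, ..., lmax.
#' @export
zonal_response <- function(b, d_par = 1.7e-3, d_perp = 0.4e-3,
                           lmax = 8L, n_quad = 64L) {
  if (b < 0) stop("`b` must be non-negative")
  lmax <- check_lmax(lmax)
  gl <- gauss_legendre(max(n_quad, 64L))
  t <- gl$nodes
  kern <- exp(-b * (d_perp + (d_par - d_perp) * t^2))
  # normalized zonal harmonic Pbar_l(t) = P_{l,m=0} fully normalized
  P <- normalized_alp(t, sqrt(pmax(0, 1 - t^2)), lmax)
  ls <- seq(0L, lmax, by = 2L)
  r <- vapply(ls, function(l) 2 * pi * sum(gl$weights * kern * P[, l + 1L, 1L]),
              numeric(1L))
  names(r) <- paste0("l", ls)
  r
}

#' Band-limited ground-truth FOD of a discrete fiber configuration
#'
#' Projects a weighted sum of Dirac deltas at the fiber directions onto the
#' even SH subspace: f = sum_i w_i Y(v_i).
#'
#' @param dirs n_fibers x 3 matrix of unit fiber directions (1-3 rows).
#' @param weights positive weights summing to 1.
#' @param lmax even band limit.
#' @return length-K SH coefficient vector.
#' @export
delta_fod_sh <- function(dirs, weights, lmax = 8L) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1L)
  if (nrow(dirs) == 0L) stop("empty fiber list")
  if (length(weights) != nrow(dirs)) stop("one weight per fiber required")
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  drop(crossprod(build_basis(dirs, lmax), weights))
}

#' Spherical convolution in the SH domain (Funk-Hecke)
#'
#' s_lm = sqrt(4 pi / (2l + 1)) * r_l * f_lm.
#'
#' @param fod_sh length-K SH vector, or M x K matrix of M FODs.
#' @param r_l zonal response from [zonal_response()] (one value per even l).
#' @param lmax even band limit (default inferred from r_l).
#' @return signal SH coefficients, same shape as `fod_sh`.
#' @export
sh_convolve <- function(fod_sh, r_l, lmax = 2L * (length(r_l) - 1L)) {
  idx <- sh_indexing(lmax)
  scale <- unname(sqrt(4 * pi / (2 * idx$l + 1)) * r_l[idx$l / 2 + 1L])
  if (is.null(dim(fod_sh))) {
    if (length(fod_sh) != nrow(idx)) stop("fod_sh length does not match lmax")
    fod_sh * scale
  } else {
    if (ncol(fod_sh) != nrow(idx)) stop("fod_sh width does not match lmax")
    sweep(fod_sh, 2L, scale, `*`)
  }
}

#' Add Rician noise to magnitude signals
#'
#' noisy = sqrt((s + n1)^2 + n2^2) with n1, n2 ~ N(0, sigma^2) independent.
#'
#' @param amplitudes numeric vector/matrix of noiseless amplitudes.
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return noisy amplitudes, same shape.
#' @export
add_rician_noise <- function(amplitudes, sigma, seed = NULL) {
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(amplitudes)
  draw <- function() {
    n <- length(amplitudes)
    n1 <- stats::rnorm(n, 0, sigma)
    n2 <- stats::rnorm(n, 0, sigma)
    out <- sqrt((amplitudes + n1)^2 + n2^2)
    attributes(out) <- attributes(amplitudes)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Uniform direction on the sphere (uses current RNG).
runif_sphere <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

# Antipodally symmetric crossing angle in degrees.
crossing_angle <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

# One fiber configuration: directions + sorted weights (principal first).
sample_fiber_config <- function(n_fibers, min_angle = 40, weight_min = 0.2,
                                max_tries = 10000L) {
  dirs <- runif_sphere(1L)
  while (nrow(dirs) < n_fibers) {
    for (i in seq_len(max_tries)) {
      cand <- runif_sphere(1L)
      if (all(apply(dirs, 1L, crossing_angle, v = cand[1L, ]) >= min_angle)) break
      if (i == max_tries) stop("could not place fibers at the requested separation")
    }
    dirs <- rbind(dirs, cand)
  }
  repeat {
    w <- stats::rexp(n_fibers)
    w <- w / sum(w)
    if (n_fibers == 1L || min(w) >= weight_min) break
  }
  ord <- order(w, decreasing = TRUE)
  list(dirs = dirs[ord, , drop = FALSE], weights = w[ord])
}

#' Generate a synthetic multi-fiber dMRI phantom
#'
#' Draws voxels with 1-3 fiber populations (random orientations uniform on
#' the sphere, pairwise crossing angles >= `min_angle`), builds band-limited
#' ground-truth FODs as weighted fiber deltas, simulates the multi-shell DWI
#' signal via SH-domain convolution with the tensor kernel's zonal response,
#' and corrupts it with Rician noise at the requested SNR (defined as
#' s0/sigma on the b = 0 amplitude). Train/val/test splits are emitted.
#'
#' @param n_voxels total number of voxels.
#' @param protocol a [protocol_reduced()] object.
#' @param n_fibers_prob probabilities of 1/2/3-fiber voxels.
#' @param min_angle minimum pairwise crossing angle in degrees (upper bound
#'   is the antipodal maximum, 90).
#' @param weight_min minimum per-fiber volume fraction for multi-fiber voxels.
#' @param d_par,d_perp kernel diffusivities in mm^2/s. The defaults are
#'   adult-like WM; `neonatal = TRUE` lowers anisotropy (d_perp = 0.7e-3)
#'   to mimic incompletely myelinated tissue.
#' @param neonatal use the neonatal-like low-anisotropy preset.
#' @param snr signal-to-noise ratio s0/sigma (Inf for noiseless).
#' @param s0 non-diffusion-weighted amplitude.
#' @param n_b0 number of simulated b = 0 volumes.
#' @param split named fractions for train/val/test (summing to 1).
#' @param lmax even band limit.
#' @param seed integer seed; same seed gives a bit-identical dataset.
#' @return object of class `fod_phantom`: list with `fod_sh` (n x K ground
#'   truth), `dwi` (list of n x n_dirs noisy shell matrices), `b0` (n x n_b0),
#'   `fibers` (per-voxel list of dirs/weights), `protocol`, `sigma`, `snr`,
#'   `split` (index vectors), `seed`, `lmax`.
#' @export
generate_phantom <- function(n_voxels,
                             protocol = protocol_reduced(),
                             n_fibers_prob = c(0.30, 0.45, 0.25),
                             min_angle = 40, weight_min = 0.2,
                             d_par = 1.7e-3, d_perp = 0.4e-3,
                             neonatal = FALSE,
                             snr = 20, s0 = 1, n_b0 = 3L,
                             split = c(train = 0.8, val = 0.1, test = 0.1),
                             lmax = 8L, seed = 1L) {
  stopifnot(n_voxels > 0)
  if (neonatal) d_perp <- 0.7e-3
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  K <- sh_basis_size(lmax)
  sigma <- if (is.finite(snr)) s0 / snr else 0
  resp <- lapply(protocol$shells, function(s)
    zonal_response(s$b, d_par, d_perp, lmax))
  shell_U <- lapply(protocol$shells, function(s) build_basis(s$dirs, lmax))
  withr::with_seed(seed, {
    nf <- sample(1:3, n_voxels, replace = TRUE, prob = n_fibers_prob)
    fibers <- lapply(nf, sample_fiber_config,
                     min_angle = min_angle, weight_min = weight_min)
    fod_sh <- t(vapply(fibers, function(f)
      delta_fod_sh(f$dirs, f$weights, lmax), numeric(K)))
    dwi <- vector("list", length(protocol$shells))
    for (i in seq_along(protocol$shells)) {
      sig_sh <- sh_convolve(fod_sh, resp[[i]], lmax)
      clean <- s0 * (sig_sh %*% t(shell_U[[i]]))
      dwi[[i]] <- add_rician_noise(clean, sigma)
    }
    names(dwi) <- paste0("b", protocol$bvals)
    b0 <- add_rician_noise(matrix(s0, n_voxels, n_b0), sigma)
    idx <- sample.int(n_voxels)
  })
  n_train <- round(split[["train"]] * n_voxels)
  n_val <- round(split[["val"]] * n_voxels)
  splits <- list(train = sort(idx[seq_len(n_train)]),
                 val = sort(idx[n_train + seq_len(n_val)]),
                 test = sort(idx[-seq_len(n_train + n_val)]))
  structure(list(fod_sh = fod_sh, dwi = dwi, b0 = b0, fibers = fibers,
                 n_fibers = nf, protocol = protocol, sigma = sigma, snr = snr,
                 s0 = s0, d_par = d_par, d_perp = d_perp,
                 split = splits, seed = seed, lmax = lmax,
                 n_voxels = n_voxels),
            class = "fod_phantom")
}

#' @export
print.fod_phantom <- function(x, ...) {
  cat("<fod_phantom> ", x$n_voxels, " voxels, snr = ", x$snr,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  fibers: ", paste0(tabulate(x$n_fibers, 3L), collapse = "/"),
      " (1/2/3), splits ",
      paste0(lengths(x$split), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Per-shell spherical-harmonic fit of DWI signals
#'
#' Fits each shell's directional signal with even SH up to lmax (45
#' coefficients per shell at lmax = 8). Reduced shells (19/26/38 directions)
#' are under-determined at lmax = 8; the fit is the ridge-stabilized
#' minimum-norm least-squares solution.
#'
#' @param dwi list of n_voxels x n_dirs matrices, one per shell (ascending b).
#' @param protocol matching [protocol_reduced()] object.
#' @param lmax even band limit.
#' @param ridge Tikhonov parameter for the per-shell fit (default 1e-3).
#' @param min_dirs fail if a shell has fewer directions (default 6).
#' @return object of class `multishell_sh`: array [n_voxels, n_shells, K]
#'   with shells ordered by ascending b-value.
#' @export
fit_per_shell_sh <- function(dwi, protocol, lmax = 8L, ridge = 1e-3,
                             min_dirs = 6L) {
  lmax <- check_lmax(lmax)
  K <- sh_basis_size(lmax)
  stopifnot(length(dwi) == length(protocol$shells))
  n <- nrow(dwi[[1L]])
  out <- array(0, dim = c(n, length(dwi), K))
  for (i in seq_along(protocol$shells)) {
    s <- protocol$shells[[i]]
    if (ncol(dwi[[i]]) != s$n)
      stop("shell b = ", s$b, ": got ", ncol(dwi[[i]]),
           " volumes, protocol says ", s$n)
    if (s$n < min_dirs)
      stop("shell b = ", s$b, " has fewer than ", min_dirs, " directions")
    U <- build_basis(s$dirs, lmax)
    G <- crossprod(U) + diag(ridge, K)
    fit <- solve(G, t(U))            # K x n_dirs
    out[, i, ] <- dwi[[i]] %*% t(fit)
  }
  structure(out, class = c("multishell_sh", "array"),
            bvals = protocol$bvals, lmax = lmax)
}
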