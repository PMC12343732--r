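#' Real symmetric spherical-harmonic indexing
#'
#' Enumerates the real, even-degree spherical-harmonic (SH) basis used
#' throughout the package: degrees l = 0, 2, ..., lmax, orders m = -l..l,
#' ordered by ascending l then ascending m (MRtrix3-compatible ordering).
#' For lmax = 8 this yields K = 45 coefficients.
#'
#' @param lmax even non-negative integer band limit (default 8).
#' @return data.frame with columns `k` (1-based flat index), `l`, `m`.
#' @export
#' @examples
#' nrow(sh_indexing(8))  # 45
sh_indexing <- function(lmax = 8L) {
  check_lmax(lmax)
  ls <- seq(0L, lmax, by = 2L)
  l <- rep(ls, times = 2L * ls + 1L)
  m <- unlist(lapply(ls, function(li) seq(-li, li)))
  data.frame(k = seq_along(l), l = l, m = m)
}

#' Number of even-degree SH coefficients for a band limit
#' @param lmax even band limit.
#' @return integer K = (lmax/2 + 1)(lmax + 1).
#' @export
sh_basis_size <- function(lmax = 8L) {
  check_lmax(lmax)
  as.integer((lmax / 2 + 1) * (lmax + 1))
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1L || lmax < 0 || lmax %% 2 != 0)
    stop("`lmax` must be a single even non-negative integer, got ", lmax)
  invisible(as.integer(lmax))
}

check_unit_dirs <- function(dirs, tol = 1e-8) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1L)
  if (ncol(dirs) != 3L) stop("directions must be an N x 3 matrix")
  nrm <- sqrt(rowSums(dirs^2))
  bad <- which(abs(nrm - 1) > tol)
  if (length(bad))
    stop("direction row ", bad[1L], " is not unit-norm (|v| = ",
         format(nrm[bad[1L]], digits = 10), ")")
  dirs
}

# Fully normalized associated Legendre functions P_l^m(x) (Condon-Shortley
# phase included), such that the complex SH Y_l^m = P_lm(cos theta) e^{i m phi}
# is orthonormal over the sphere. Stable three-term recurrence.
# Returns array [N, lmax+1, lmax+1] indexed [point, l+1, m+1].
normalized_alp <- function(x, s, lmax) {
  n <- length(x)
  P <- array(0, dim = c(n, lmax + 1L, lmax + 1L))
  P[, 1L, 1L] <- 1 / sqrt(4 * pi)
  if (lmax >= 1L) {
    for (m in seq_len(lmax)) {  # diagonal P_m^m
      P[, m + 1L, m + 1L] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[, m, m]
    }
    for (m in 0:(lmax - 1L)) {  # first off-diagonal P_{m+1}^m
      P[, m + 2L, m + 1L] <- sqrt(2 * m + 3) * x * P[, m + 1L, m + 1L]
    }
  }
  if (lmax >= 2L) {
    for (m in 0:(lmax - 2L)) {
      for (l in (m + 2L):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, l + 1L, m + 1L] <-
          a * (x * P[, l, m + 1L] - b * P[, l - 1L, m + 1L])
      }
    }
  }
  P
}

#' Evaluate the real symmetric SH basis at a set of directions
#'
#' Builds the ISFT matrix U: column k holds the real SH function (l_k, m_k)
#' evaluated at each direction, in the ordering of [sh_indexing()]. The basis
#' is orthonormal over the sphere and matches the MRtrix3 real-SH convention
#' (m < 0 -> sin terms, m > 0 -> cos terms, Condon-Shortley phase included),
#' so SH images interoperate with standard FOD tooling.
#'
#' @param dirs N x 3 matrix of unit vectors.
#' @param lmax even band limit.
#' @return N x K numeric matrix.
#' @export
build_basis <- function(dirs, lmax = 8L) {
  lmax <- check_lmax(lmax)
  dirs <- check_unit_dirs(dirs)
  idx <- sh_indexing(lmax)
  n <- nrow(dirs)
  ct <- pmin(1, pmax(-1, dirs[, 3L]))
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  P <- normalized_alp(ct, st, lmax)
  U <- matrix(0, n, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    l <- idx$l[k]; m <- idx$m[k]
    plm <- P[, l + 1L, abs(m) + 1L]
    U[, k] <- if (m == 0L) plm
      else if (m > 0L) sqrt(2) * plm * cos(m * phi)
      else sqrt(2) * plm * sin(abs(m) * phi)
  }
  U
}

#' Forward spherical Fourier transform (least-squares SH fit)
#'
#' Projects sampled amplitudes onto the even band-limited SH subspace using
#' the sampling's precomputed least-squares inverse.
#'
#' @param amplitudes length-N vector, or N x M matrix of M spherical functions.
#' @param sampling a [make_sampling()] object.
#' @return length-K vector (or K x M matrix) of SH coefficients.
#' @export
sft <- function(amplitudes, sampling) {
  stopifnot(inherits(sampling, "sphere_sampling"))
  a <- if (is.null(dim(amplitudes))) matrix(amplitudes, ncol = 1L) else amplitudes
  if (nrow(a) != sampling$n)
    stop("amplitude length ", nrow(a), " does not match sampling size ", sampling$n)
  out <- sampling$U_pinv %*% a
  if (is.null(dim(amplitudes))) drop(out) else out
}

#' Inverse spherical Fourier transform (SH synthesis)
#'
#' @param coeffs length-K vector, or K x M matrix.
#' @param sampling a [make_sampling()] object.
#' @return length-N vector (or N x M matrix) of amplitudes at `sampling$dirs`.
#' @export
isft <- function(coeffs, sampling) {
  stopifnot(inherits(sampling, "sphere_sampling"))
  cc <- if (is.null(dim(coeffs))) matrix(coeffs, ncol = 1L) else coeffs
  if (nrow(cc) != sampling$K)
    stop("coefficient length ", nrow(cc), " does not match basis size ", sampling$K)
  out <- sampling$U %*% cc
  if (is.null(dim(coeffs))) drop(out) else out
}

#' SH-domain rotation operator (block-diagonal Wigner-style matrix)
#'
#' Constructs the K x K operator D such that if f has coefficients c, the
#' rotated function f'(v) = f(R^T v) has coefficients D c. Rotations only mix
#' orders within a degree, so D is block-diagonal with one orthogonal
#' (2l+1) x (2l+1) block per even degree. Blocks are obtained by solving the
#' exact least-squares system between the basis evaluated on a dense
#' well-spread grid and on its rotated image (exact up to the band limit).
#'
#' @param R 3 x 3 rotation matrix (orthogonal, det +1).
#' @param lmax even band limit.
#' @return object of class `sh_rotation` with elements `R`, `D`, `blocks`,
#'   `lmax`.
#' @export
rotation_operator <- function(R, lmax = 8L) {
  lmax <- check_lmax(lmax)
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-10)
    stop("`R` must be a 3 x 3 orthogonal matrix (R^T R = I within 1e-10)")
  if (det(R) < 0) stop("`R` must be a proper rotation (det(R) = +1)")
  idx <- sh_indexing(lmax)
  K <- nrow(idx)
  grid <- fibonacci_sphere(max(4L * K, 400L))
  B0 <- build_basis(grid, lmax)
  B1 <- build_basis(grid %*% R, lmax)  # rows: R^T v for column-vector v
  D <- matrix(0, K, K)
  blocks <- list()
  for (l in seq(0L, lmax, by = 2L)) {
    cols <- which(idx$l == l)
    Dl <- solve(crossprod(B0[, cols]), crossprod(B0[, cols], B1[, cols]))
    D[cols, cols] <- Dl
    blocks[[paste0("l", l)]] <- Dl
  }
  structure(list(R = R, D = D, blocks = blocks, lmax = lmax, K = K),
            class = "sh_rotation")
}

#' Apply an SH rotation operator to coefficients
#' @param rot an [rotation_operator()] object.
#' @param coeffs length-K vector or K x M matrix.
#' @return rotated coefficients, same shape.
#' @export
apply_rotation <- function(rot, coeffs) {
  stopifnot(inherits(rot, "sh_rotation"))
  cc <- if (is.null(dim(coeffs))) matrix(coeffs, ncol = 1L) else coeffs
  if (nrow(cc) != rot$K) stop("coefficient length does not match operator size")
  out <- rot$D %*% cc
  if (is.null(dim(coeffs))) drop(out) else out
}

#' Random rotation matrices (Haar-uniform)
#'
#' QR-based sampling of uniformly distributed proper rotations, used by the
#' equivariance tests.
#'
#' @param n number of rotations.
#' @return a 3 x 3 matrix if n = 1, else a list of matrices.
#' @export
random_rotation <- function(n = 1L) {
  one <- function() {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  }
  if (n == 1L) one() else replicate(n, one(), simplify = FALSE)
}
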