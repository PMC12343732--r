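#' Deterministic Fibonacci (golden-angle spiral) sphere points
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors. No RNG is used.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (i - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Icosphere: subdivided icosahedron, with vertex adjacency (needed for
# peak extraction). Levels give 12, 42, 162, 642, 2562, ... vertices.
icosphere <- function(level = 4L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(6, 5, 10), c(5, 12, 3), c(3, 11, 7), c(7, 8, 9), c(9, 2, 10))
  for (lev in seq_len(level)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- vector("list", 1L); verts[[1L]] <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      midcache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(cc, ca, bc)
      nf[4L * i, ]      <- c(ab, bc, ca)
    }
    f <- nf
  }
  edges <- unique(rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)]))
  edges <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                        pmax(edges[, 1L], edges[, 2L])))
  nbr <- vector("list", nrow(v))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  list(dirs = unname(v), neighbors = lapply(nbr, sort))
}

#' Build a sphere sampling with its ISFT/SFT matrices
#'
#' The shared discretization used by the spatial-domain nonlinearity, the
#' loss, and the angular metrics: a deterministic well-spread point set with
#' the SH basis U evaluated at the points (ISFT matrix) and its least-squares
#' inverse (SFT matrix). `icosphere` rounds n_points up to the next
#' subdivision level (12, 42, 162, 642, 2562, ...) and also carries the
#' vertex neighbor graph used by peak extraction.
#'
#' @param n_points requested number of points (must be >= K; >= 2K advised).
#' @param scheme "fibonacci" or "icosphere".
#' @param lmax even band limit (default 8).
#' @param ridge optional Tikhonov ridge on the SFT normal equations
#'   (default 0, plain least squares / Moore-Penrose).
#' @return object of class `sphere_sampling`: list with `dirs` (N x 3), `U`
#'   (N x K), `U_pinv` (K x N), `quad_weights` (4*pi/N each), `lmax`, `K`,
#'   `n`, `scheme`, and `neighbors` for icosphere.
#' @export
make_sampling <- function(n_points = 724L,
                          scheme = c("fibonacci", "icosphere"),
                          lmax = 8L, ridge = 0) {
  scheme <- match.arg(scheme)
  lmax <- check_lmax(lmax)
  K <- sh_basis_size(lmax)
  if (n_points < K)
    stop("n_points = ", n_points, " < K = ", K,
         ": the spherical Fourier transform would be underdetermined")
  if (n_points < 2L * K)
    warning("n_points < 2K; least-squares SFT may be poorly conditioned")
  nbrs <- NULL
  if (scheme == "fibonacci") {
    dirs <- fibonacci_sphere(n_points)
  } else {
    level <- 0L
    while (10L * 4L^level + 2L < n_points) level <- level + 1L
    ico <- icosphere(level)
    dirs <- ico$dirs
    nbrs <- ico$neighbors
  }
  U <- build_basis(dirs, lmax)
  G <- crossprod(U)
  if (ridge > 0) G <- G + diag(ridge, K)
  U_pinv <- solve(G, t(U))
  structure(list(dirs = dirs, U = U, U_pinv = U_pinv,
                 quad_weights = rep(4 * pi / nrow(dirs), nrow(dirs)),
                 lmax = lmax, K = K, n = nrow(dirs), scheme = scheme,
                 ridge = ridge, neighbors = nbrs),
            class = "sphere_sampling")
}

#' @export
print.sphere_sampling <- function(x, ...) {
  cat("<sphere_sampling> ", x$scheme, ", n = ", x$n,
      ", lmax = ", x$lmax, " (K = ", x$K, ")\n", sep = "")
  invisible(x)
}

#' Write / read sampling directions as plain text (one "x y z" per line)
#' @param sampling a `sphere_sampling` object (write) .
#' @param path file path.
#' @export
write_sampling_dirs <- function(sampling, path) {
  utils::write.table(sampling$dirs, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_sampling_dirs
#' @export
read_sampling_dirs <- function(path) {
  as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
}
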