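test_that("reduced protocol reproduces the published shell structure", {
  p <- protocol_reduced()
  expect_equal(p$counts, c(19L, 26L, 38L))
  expect_equal(p$n_total, 83L)
  expect_equal(vapply(p$shells, function(s) nrow(s$dirs), 1L), p$counts)
  expect_equal(protocol_reduced(fraction = 1)$counts, c(64L, 88L, 128L))
  expect_error(protocol_reduced(fraction = 0.05), "fewer than 6")
  expect_error(protocol_reduced(fraction = 0), "fraction")
})

test_that("tensor kernel matches closed forms", {
  g <- c(1, 0, 0); v <- c(0, 0, 1)
  expect_equal(tensor_signal(0, g, v), 1.0)
  expect_equal(tensor_signal(1000, g, v, d_perp = 4e-4), exp(-0.4))
  expect_equal(tensor_signal(1000, v, v, d_par = 1.7e-3), exp(-1.7))
  expect_error(tensor_signal(-5, g, v), "non-negative")
  expect_error(tensor_signal(1000, g, v, d_par = 1e-4, d_perp = 2e-3),
               "d_par >= d_perp")
})

test_that("zonal response behaves as the kernel's Legendre spectrum", {
  r0 <- zonal_response(0)
  expect_equal(unname(r0[1L]), 2 * sqrt(pi), tolerance = 1e-12)
  expect_norm_lt(r0[-1L], 1e-12)
  riso <- zonal_response(1000, d_par = 1e-3, d_perp = 1e-3)
  expect_equal(unname(riso[1L]), 2 * sqrt(pi) * exp(-1), tolerance = 1e-10)
  expect_norm_lt(riso[-1L], 1e-12)
  # quadrature refinement
  expect_norm_lt(zonal_response(2600, n_quad = 64L) -
                   zonal_response(2600, n_quad = 128L), 1e-10)
})

test_that("delta FODs have the planted symmetry and peak location", {
  f <- delta_fod_sh(c(0, 0, 1), 1)
  idx <- sh_indexing(8L)
  expect_norm_lt(f[idx$m != 0L], 1e-12)
  # antipodal pair is identical to a single fiber in the even basis
  f2 <- delta_fod_sh(rbind(c(0, 0, 1), c(0, 0, -1)), c(0.5, 0.5))
  expect_norm_lt(f - f2, 1e-12)
  # dense-grid argmax within 3 degrees of the planted direction
  s <- samp_dense()
  set.seed(6)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  amp <- isft(delta_fod_sh(v, 1), s)
  vhat <- s$dirs[which.max(amp), ]
  expect_lt(acos(min(1, abs(sum(vhat * v)))) * 180 / pi, 3)
  expect_error(delta_fod_sh(matrix(0, 0L, 3L), numeric(0)), "empty")
  expect_error(delta_fod_sh(c(0, 0, 1), 0.7), "sum to 1")
})

test_that("SH convolution implements Funk-Hecke against direct evaluation", {
  r <- zonal_response(1000)
  expect_equal(sh_convolve(rep(0, 45L), r * 0), rep(0, 45L))
  # pure l=0 FOD gives an isotropic signal
  iso <- sh_convolve(c(1, rep(0, 44L)), r)
  s <- samp_small()
  expect_norm_lt(diff(range(isft(iso, s))), 1e-12)
  # direct-evaluation oracle, random configurations
  set.seed(7)
  p <- protocol_reduced()
  for (i in 1:20) {
    nf <- sample(1:3, 1L)
    cfg <- sphfod:::sample_fiber_config(nf)
    f <- delta_fod_sh(cfg$dirs, cfg$weights)
    sh <- p$shells[[sample(3L, 1L)]]
    a1 <- build_basis(sh$dirs) %*% sh_convolve(f, zonal_response(sh$b))
    a2 <- rowSums(vapply(seq_len(nf), function(j)
      cfg$weights[j] * tensor_signal(sh$b, sh$dirs, cfg$dirs[j, ]),
      numeric(nrow(sh$dirs))))
    expect_norm_lt(a1 - a2, 0.02)
  }
})

test_that("Rician noise has the right moments and is seed-stable", {
  x <- c(0.2, 0.9)
  expect_identical(add_rician_noise(x, 0), x)
  expect_error(add_rician_noise(x, -1), "non-negative")
  n <- 1e5L
  s0 <- 0.8; sig <- 0.1
  y <- add_rician_noise(rep(s0, n), sig, seed = 11L)
  # E[y^2] = s^2 + 2 sigma^2; MC standard error of the mean of y^2
  se <- stats::sd(y^2) / sqrt(n)
  expect_lt(abs(mean(y^2) - (s0^2 + 2 * sig^2)), 3 * se)
  y0 <- add_rician_noise(rep(0, n), sig, seed = 12L)
  se0 <- stats::sd(y0) / sqrt(n)
  expect_lt(abs(mean(y0) - sig * sqrt(pi / 2)), 3 * se0)
  # reproducible under seed, RNG state untouched
  expect_identical(add_rician_noise(x, 0.3, seed = 5L),
                   add_rician_noise(x, 0.3, seed = 5L))
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_rician_noise(x, 0.3, seed = 5L))
  expect_identical(rnorm(1), before)
})

test_that("phantom generation is reproducible with the requested structure", {
  ph <- generate_phantom(1000L, snr = 20, seed = 3L)
  ph2 <- generate_phantom(1000L, snr = 20, seed = 3L)
  expect_identical(ph$dwi, ph2$dwi)
  expect_identical(ph$fod_sh, ph2$fod_sh)
  expect_equal(nrow(ph$fod_sh), 1000L)
  expect_length(ph$fibers, 1000L)
  expect_equal(sort(unlist(ph$split, use.names = FALSE)), 1:1000)
  # crossing angles respect the floor
  for (f in ph$fibers[ph$n_fibers > 1L][1:50]) {
    pairs <- utils::combn(nrow(f$dirs), 2L)
    for (j in seq_len(ncol(pairs))) {
      ang <- acos(min(1, abs(sum(f$dirs[pairs[1L, j], ] *
                                   f$dirs[pairs[2L, j], ])))) * 180 / pi
      expect_gte(ang, 40)
    }
  }
})

test_that("noiseless single-fiber ground truth peaks at the planted direction", {
  ph <- generate_phantom(100L, n_fibers_prob = c(1, 0, 0), snr = Inf,
                         seed = 8L)
  s <- samp_dense()
  amp <- tcrossprod(ph$fod_sh, s$U)   # voxels x points
  hit <- vapply(1:100, function(i) {
    vhat <- s$dirs[which.max(amp[i, ]), ]
    acos(min(1, abs(sum(vhat * ph$fibers[[i]]$dirs[1L, ])))) * 180 / pi < 3
  }, logical(1L))
  expect_equal(sum(hit), 100L)
})

test_that("per-shell SH fitting satisfies its contracts", {
  # constant signal on a well-determined (full protocol) shell
  pf <- protocol_full()
  const <- lapply(pf$shells, function(s) matrix(1, 2L, s$n))
  ms <- fit_per_shell_sh(const, pf, ridge = 0)
  expect_equal(dim(ms), c(2L, 3L, 45L))
  expect_equal(ms[1L, 1L, 1L], 2 * sqrt(pi), tolerance = 1e-6)
  expect_norm_lt(ms[1L, 1L, -1L], 1e-6)
  # noiseless refit reproduces the acquisition-direction signal within 5%
  ph <- generate_phantom(20L, snr = Inf, seed = 9L)
  ms2 <- fit_per_shell_sh(ph$dwi, ph$protocol)
  for (i in seq_along(ph$protocol$shells)) {
    U <- build_basis(ph$protocol$shells[[i]]$dirs)
    refit <- ms2[, i, ] %*% t(U)
    expect_norm_lt(refit - ph$dwi[[i]], 0.05)
  }
  # shell with too few directions is named
  bad <- protocol_reduced()
  bad$shells[[2L]]$n <- 4L
  bad$shells[[2L]]$dirs <- bad$shells[[2L]]$dirs[1:4, ]
  dwi_bad <- lapply(bad$shells, function(s) matrix(1, 2L, s$n))
  expect_error(fit_per_shell_sh(dwi_bad, bad), "b = 1000")
})

test_that("noise floor: high-SNR fits converge to the noiseless fit", {
  ph_inf <- generate_phantom(50L, snr = Inf, seed = 10L)
  ph_hi <- generate_phantom(50L, snr = 1e6, seed = 10L)
  m1 <- fit_per_shell_sh(ph_inf$dwi, ph_inf$protocol)
  m2 <- fit_per_shell_sh(ph_hi$dwi, ph_hi$protocol)
  expect_norm_lt(unclass(m1) - unclass(m2), 1e-3)
})

test_that("ground-truth FOD integrates to the total fiber weight", {
  s <- samp_dense()
  ph <- generate_phantom(20L, snr = Inf, seed = 13L)
  integrals <- as.vector(tcrossprod(ph$fod_sh, s$U) %*% s$quad_weights)
  expect_norm_lt(integrals - 1, 0.01)
})
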