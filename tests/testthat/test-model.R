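test_that("equivariant_conv implements the degree-wise filter contract", {
  K <- 45L
  # identity filter: one channel, all degree weights 1, no bias
  p <- list(W = array(1, c(1L, 1L, 5L)), b = NULL, residual = FALSE)
  x <- matrix(rnorm(K), 1L)
  expect_equal(equivariant_conv(x, p), x)
  p0 <- list(W = array(0, c(3L, 2L, 5L)), b = NULL, residual = FALSE)
  expect_equal(equivariant_conv(matrix(rnorm(2L * K), 2L), p0),
               matrix(0, 3L, K))
  expect_error(equivariant_conv(matrix(rnorm(3L * K), 3L), p0), "C_in")
  expect_error(equivariant_conv(matrix(rnorm(2L * 20L), 2L), p0), "columns")
})

test_that("equivariant_conv commutes with SH rotations (with and without residual)", {
  set.seed(20)
  for (i in 1:5) {
    rot <- rotation_operator(random_rotation(), 8L)
    for (res in c(FALSE, TRUE)) {
      p <- withr::with_seed(i, conv_params(4L, 4L, residual = res))
      x <- matrix(rnorm(4L * 45L), 4L)
      xr <- t(apply_rotation(rot, t(x)))
      expect_norm_lt(equivariant_conv(xr, p) -
                       t(apply_rotation(rot, t(equivariant_conv(x, p)))),
                     1e-10)
    }
    # composition of two conv layers stays equivariant
    p1 <- withr::with_seed(i + 50L, conv_params(4L, 6L))
    p2 <- withr::with_seed(i + 90L, conv_params(6L, 3L))
    x <- matrix(rnorm(4L * 45L), 4L)
    xr <- t(apply_rotation(rot, t(x)))
    y <- function(z) equivariant_conv(equivariant_conv(z, p1), p2)
    expect_norm_lt(y(xr) - t(apply_rotation(rot, t(y(x)))), 1e-10)
  }
})

test_that("sh_nonlinearity acts as identity on positive profiles and reports its defect", {
  s <- samp_small()
  expect_equal(sh_nonlinearity(rep(0, 45L), s), rep(0, 45L))
  # strictly positive amplitudes: LeakyReLU is the identity there
  set.seed(21)
  cc <- c(4 * sqrt(pi), rnorm(44L, sd = 0.05))
  stopifnot(all(isft(cc, s) > 0))
  expect_norm_lt(sh_nonlinearity(cc, s) - cc, 1e-8)
  # the equivariance defect is finite and measured, not asserted to vanish
  rot <- rotation_operator(random_rotation(), 8L)
  x <- rnorm(45L)
  d <- sh_nonlinearity(apply_rotation(rot, x), s) -
    apply_rotation(rot, sh_nonlinearity(x, s))
  rel <- sqrt(sum(d^2)) / sqrt(sum(sh_nonlinearity(x, s)^2))
  expect_true(is.finite(rel))
  message(sprintf("sh_nonlinearity equivariance defect (relative): %.3g", rel))
})

test_that("shell attention produces simplex weights with softmax invariances", {
  set.seed(22)
  p <- attention_params()
  xs <- replicate(3L, matrix(rnorm(16L * 45L), 16L), simplify = FALSE)
  r <- shell_attention(xs[[1L]], xs[[2L]], xs[[3L]], p)
  expect_equal(sum(r$a), 1, tolerance = 1e-12)
  expect_true(all(r$a >= 0))
  expect_equal(dim(r$y), c(48L, 45L))
  # zero output layer gives uniform attention
  p0 <- p; p0$W2[] <- 0; p0$b2[] <- 0
  r0 <- shell_attention(xs[[1L]], xs[[2L]], xs[[3L]], p0)
  expect_equal(r0$a, rep(1 / 3, 3L), tolerance = 1e-12)
  # softmax shift invariance
  pc <- p; pc$b2 <- p$b2 + 7.3
  rc <- shell_attention(xs[[1L]], xs[[2L]], xs[[3L]], pc)
  expect_equal(rc$a, r$a, tolerance = 1e-12)
  expect_error(shell_attention(xs[[1L]][1:4, ], xs[[2L]][1:4, ],
                               xs[[3L]][1:4, ], p), "channels")
})

test_that("scnn_forward meets its output contract deterministically", {
  m <- scnn_model(nonlin_n = 96L, seed = 30L)
  set.seed(23)
  x <- array(rnorm(6L * 3L * 45L), c(6L, 3L, 45L))
  o1 <- scnn_forward(m, x)
  o2 <- scnn_forward(m, x)
  expect_equal(dim(o1), c(6L, 45L))
  expect_identical(o1, o2)
  expect_error(scnn_forward(m, array(0, c(2L, 2L, 45L))), "input must be")
  # single-voxel matrix input
  expect_equal(dim(scnn_forward(m, x[1L, , ])), c(1L, 45L))
})

test_that("every sCNN parameter receives a nonzero gradient (no dead branch)", {
  m <- scnn_model(nonlin_n = 96L, seed = 31L)
  set.seed(24)
  x <- array(rnorm(16L * 3L * 45L), c(16L, 3L, 45L))
  y <- matrix(rnorm(16L * 45L), 16L)
  fw <- scnn_forward(m, x, training = TRUE)
  lg <- spatial_mse_loss(fw$out, y, samp_small(), gradient = TRUE)
  gr <- sphfod:::scnn_backward(m, fw$cache, lg$grad)
  walk <- function(g, path = "") {
    if (is.numeric(g)) {
      expect_gt(max(abs(g)), 0, label = paste("gradient at", path))
    } else if (is.list(g)) {
      for (nm in seq_along(g)) {
        el <- g[[nm]]
        if (is.numeric(el) || is.list(el))
          walk(el, paste0(path, "/", names(g)[nm]))
      }
    }
  }
  walk(gr)
})

test_that("analytic gradients match finite differences (reference path)", {
  lmax <- 4L; K <- sh_basis_size(lmax)
  m <- scnn_model(lmax = lmax, shell_channels = 3L, channels = c(3L, 4L, 5L),
                  head = c(12L, 8L), attn_hidden = 4L, nonlin_n = 2L * K,
                  seed = 32L)
  set.seed(25)
  B <- 4L
  x <- array(rnorm(B * 3L * K), c(B, 3L, K))
  y <- matrix(rnorm(B * K), B, K)
  ls <- make_sampling(2L * K, lmax = lmax)
  fw <- scnn_forward(m, x, training = TRUE, fast = FALSE)
  lg <- spatial_mse_loss(fw$out, y, ls, gradient = TRUE)
  gr <- sphfod:::scnn_backward(m, fw$cache, lg$grad)
  eps <- 1e-6
  paths <- list(list("shell", 1L, "W"), list("attn", "W1"),
                list("fuse", "W"), list("enc", 2L, "W"),
                list("dec", 1L, "W"), list("head", "fc1", "W"),
                list("head", "bn1", "gamma"), list("head", "fc3", "b"))
  get <- function(tr, p) { for (el in p) tr <- tr[[el]]; tr }
  set_leaf <- function(tr, p, v) {
    if (length(p) == 1L) { tr[[p[[1L]]]] <- v; return(tr) }
    tr[[p[[1L]]]] <- set_leaf(tr[[p[[1L]]]], p[-1L], v)
    tr
  }
  loss_of <- function(mm) {
    f <- scnn_forward(mm, x, training = TRUE, fast = FALSE)
    spatial_mse_loss(f$out, y, ls)
  }
  for (pa in paths) {
    leaf <- get(m$params, pa)
    i <- sample(length(leaf), 1L)
    for (sgn in c(1, -1)) {
      l2 <- leaf; l2[i] <- l2[i] + sgn * eps
      mm <- m; mm$params <- set_leaf(m$params, pa, l2)
      if (sgn > 0) up <- loss_of(mm) else dn <- loss_of(mm)
    }
    fd <- (up - dn) / (2 * eps)
    an <- get(gr, pa)[i]
    expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("compiled and reference nonlinearity paths agree", {
  m <- scnn_model(nonlin_n = 96L, seed = 33L)
  set.seed(26)
  x <- array(rnorm(8L * 3L * 45L), c(8L, 3L, 45L))
  o_fast <- scnn_forward(m, x, fast = TRUE)
  o_ref <- scnn_forward(m, x, fast = FALSE)
  expect_norm_lt(o_fast - o_ref, 1e-4 * max(1, max(abs(o_ref))))
})

test_that("MLP meets its contract and is less rotation-consistent than the conv layer", {
  ml <- mlp_model(seed = 34L)
  set.seed(27)
  x <- matrix(rnorm(5L * 135L), 5L)
  o1 <- mlp_forward(ml, x)
  expect_equal(dim(o1), c(5L, 45L))
  expect_identical(o1, mlp_forward(ml, x))
  expect_error(mlp_forward(ml, matrix(0, 2L, 10L)), "input length")
  # rotation defect contrast on the same pairs
  rot <- rotation_operator(random_rotation(), 8L)
  cp <- conv_params(3L, 3L)
  defects_mlp <- c(); defects_conv <- c()
  for (i in 1:5) {
    xs <- matrix(rnorm(3L * 45L), 3L)       # one voxel, 3 shells
    xr <- t(apply_rotation(rot, t(xs)))
    om <- mlp_forward(ml, matrix(t(xs), 1L))
    omr <- mlp_forward(ml, matrix(t(xr), 1L))
    defects_mlp <- c(defects_mlp,
                     sqrt(sum((omr - apply_rotation(rot, drop(om)))^2)) /
                       max(1e-12, sqrt(sum(om^2))))
    yc <- equivariant_conv(xs, cp); ycr <- equivariant_conv(xr, cp)
    defects_conv <- c(defects_conv,
                      max(abs(ycr - t(apply_rotation(rot, t(yc))))))
  }
  expect_true(all(defects_mlp > defects_conv))
})

test_that("the sCNN has strictly fewer parameters than the MLP baseline", {
  expect_lt(n_parameters(scnn_model(nonlin_n = 96L)),
            n_parameters(mlp_model()))
})

test_that("checkpoints and YAML configs round-trip", {
  m <- scnn_model(nonlin_n = 96L, seed = 35L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  set.seed(28)
  x <- array(rnorm(3L * 3L * 45L), c(3L, 3L, 45L))
  expect_identical(scnn_forward(m, x), scnn_forward(m2, x))
  cfg_path <- tempfile(fileext = ".yaml")
  write_model_config(m, cfg_path)
  cfg <- read_model_config(cfg_path)
  expect_equal(cfg$kind, "scnn")
  expect_equal(cfg$lmax, m$config$lmax)
  expect_equal(cfg$nonlin_n, m$config$nonlin_n)
  expect_equal(unlist(cfg$head), unname(m$config$head))
})
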