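make_field_pair <- function(n = 40L, seed = 60L, noise = 0.1) {
  ph <- generate_phantom(n, snr = Inf, seed = seed)
  gt <- fod_field(ph$fod_sh)
  pred <- fod_field(ph$fod_sh +
                      withr::with_seed(seed + 1L,
                                       matrix(rnorm(n * 45L, sd = noise),
                                              n, 45L)))
  list(pred = pred, gt = gt, ph = ph)
}

test_that("SH-domain MSE matches hand arithmetic and the Parseval identity", {
  fp <- make_field_pair()
  expect_equal(sh_mse(fp$gt, fp$gt), 0)
  one <- matrix(0, 1L, 45L); two <- one; two[1L, 7L] <- 0.3
  expect_equal(sh_mse(fod_field(one), fod_field(two)), 0.09)
  s <- samp_dense()
  p <- sphfod:::field_mat(fp$pred); g <- sphfod:::field_mat(fp$gt)
  ratio <- sh_mse(fp$pred, fp$gt) /
    (spatial_mse_loss(p, g, s) * 4 * pi)
  expect_gte(ratio, 0.99); expect_lte(ratio, 1.01)
  bad <- fod_field(one, mask = array(FALSE, c(1L, 1L, 1L)))
  expect_error(sh_mse(bad, fod_field(one)), "disjoint")
})

test_that("ACC is a scale-invariant cosine with exact orthogonality", {
  s <- samp_default()
  set.seed(61)
  g <- matrix(rnorm(45L), 1L)
  expect_equal(acc(g, g, s)$per_voxel, 1.0)
  expect_equal(acc(2 * g, g, s)$per_voxel, 1.0, tolerance = 1e-12)
  # Gram-Schmidt in amplitude space gives an exactly orthogonal pair
  r <- matrix(rnorm(45L), 1L)
  ag <- isft(drop(g), s); ar <- isft(drop(r), s)
  o <- r - g * sum(ar * ag) / sum(ag^2)
  expect_lt(abs(acc(o, g, s)$per_voxel), 1e-8)
  # zero-norm voxels are excluded and counted
  z <- rbind(g, 0)
  res <- acc(z, rbind(g, g), s)
  expect_equal(res$n_excluded, 1L)
  expect_true(is.na(res$per_voxel[2L]))
})

test_that("channel-wise 3D SSIM matches a direct naive implementation", {
  set.seed(62)
  d <- c(10L, 9L, 8L)
  a <- array(rnorm(prod(d)), d)
  b <- a + 0.4 * array(rnorm(prod(d)), d)
  dr <- max(a) - min(a)
  got <- sphfod:::ssim_3d(b, a, data_range = dr, win = 7L)
  # independent oracle: explicit loops over fully-valid window positions
  w <- 7L; C1 <- (0.01 * dr)^2; C2 <- (0.03 * dr)^2
  vals <- c()
  for (i in seq_len(d[1L] - w + 1L)) for (j in seq_len(d[2L] - w + 1L))
    for (k in seq_len(d[3L] - w + 1L)) {
      wa <- a[i:(i + w - 1L), j:(j + w - 1L), k:(k + w - 1L)]
      wb <- b[i:(i + w - 1L), j:(j + w - 1L), k:(k + w - 1L)]
      va <- stats::var(as.vector(wa)); vb <- stats::var(as.vector(wb))
      cab <- stats::cov(as.vector(wa), as.vector(wb))
      vals <- c(vals, ((2 * mean(wa) * mean(wb) + C1) * (2 * cab + C2)) /
                  ((mean(wa)^2 + mean(wb)^2 + C1) * (va + vb + C2)))
    }
  expect_equal(got, mean(vals), tolerance = 1e-6)
})

test_that("SSIM identities hold on FOD fields", {
  set.seed(63)
  coef <- array(rnorm(10L * 10L * 10L * 45L), c(10L, 10L, 10L, 45L))
  f <- fod_field(coef)
  expect_equal(ssim_per_channel(f, f), 1.0)
  neg <- fod_field(-coef)
  expect_lt(ssim_per_channel(neg, f), 1.0)
  # degenerate constant-in-both channels score 1 by convention
  cst <- fod_field(array(2, c(8L, 8L, 8L, 45L)))
  expect_equal(ssim_per_channel(cst, cst), 1.0)
  expect_error(ssim_per_channel(fod_field(coef[1:4, , , , drop = FALSE]),
                                fod_field(coef[1:4, , , , drop = FALSE])),
               ">= 8")
})

test_that("PSNR follows its closed form", {
  g <- matrix(0, 1L, 45L); g[1L, 1L] <- 1       # data range 1
  p <- g + 1                                     # per-entry MSE 1
  expect_equal(psnr(fod_field(p), fod_field(g)), 0)
  p2 <- g + 0.5                                  # halved error: +6.02 dB
  expect_equal(psnr(fod_field(p2), fod_field(g)), 20 * log10(2),
               tolerance = 1e-9)
  expect_identical(psnr(fod_field(g), fod_field(g)), Inf)
  set.seed(64)
  gg <- matrix(rnorm(20L * 45L), 20L); pp <- gg + rnorm(20L * 45L, sd = 0.2)
  direct <- 10 * log10(max(abs(gg))^2 / mean((pp - gg)^2))
  expect_equal(psnr(fod_field(pp), fod_field(gg)), direct, tolerance = 1e-9)
})

test_that("peak extraction recovers planted fibers", {
  s <- samp_peaks()
  set.seed(65)
  v <- rnorm(3L); v <- v / sqrt(sum(v^2))
  pk <- extract_peaks(delta_fod_sh(v, 1), s)
  expect_length(pk$amp, 1L)
  expect_lt(angular_error(pk$dirs[1L, ], v), 3)
  # two orthogonal fibers, equal weights
  pk2 <- extract_peaks(delta_fod_sh(rbind(c(1, 0, 0), c(0, 0, 1)),
                                    c(0.5, 0.5)), s)
  expect_length(pk2$amp, 2L)
  errs <- apply(pk2$dirs, 1L, function(u)
    min(angular_error(u, c(1, 0, 0)), angular_error(u, c(0, 0, 1))))
  expect_true(all(errs < 5))
  # sorted by descending amplitude, separation respected
  expect_true(!is.unsorted(rev(pk2$amp)))
  expect_identical(length(extract_peaks(rep(0, 45L), s)$amp), 0L)
  expect_error(extract_peaks(rep(1, 45L), samp_default()), "icosphere")
})

test_that("angular error is the antipodal metric in degrees", {
  expect_equal(angular_error(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angular_error(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(angular_error(c(0, 0, 1), c(1, 0, 0)), 90)
  set.seed(66)
  for (i in 1:50) {
    u <- rnorm(3L); u <- u / sqrt(sum(u^2))
    v <- rnorm(3L); v <- v / sqrt(sum(v^2))
    ae <- angular_error(u, v)
    expect_gte(ae, 0); expect_lte(ae, 90)
  }
  empty <- structure(list(dirs = matrix(0, 0L, 3L), amp = numeric(0)),
                     class = "peak_set")
  expect_true(is.na(angular_error(empty, c(0, 0, 1))))
})

test_that("peak match rate matches identities and the random-direction solid angle", {
  fp <- make_field_pair(n = 30L, noise = 0)
  s <- samp_peaks()
  r <- peak_match_rate(fp$pred, fp$gt, s)
  expect_equal(r$rate, 1.0)
  expect_equal(r$n_invalid, 0L)
  # uniformly random principal peaks vs fixed gt: P(error < 20 deg) =
  # 1 - cos(20 deg), the fractional solid angle of the antipodal double cone
  n <- 1e5L
  set.seed(67)
  u <- matrix(rnorm(3L * n), n)
  u <- u / sqrt(rowSums(u^2))
  errs <- acos(pmin(1, abs(u[, 3L]))) * 180 / pi
  r2 <- peak_match_rate(fp$pred, fp$gt, s, errors = errs)
  p0 <- 1 - cos(20 * pi / 180)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(r2$rate - p0), 3 * se)
  # strict threshold: 0 degrees never matches noisy peaks
  r3 <- peak_match_rate(fp$pred, fp$gt, s, threshold_deg = 0,
                        errors = errs)
  expect_equal(r3$rate, 0)
  expect_error(peak_match_rate(fp$pred, fp$gt, s,
                               errors = rep(NA_real_, 5L)), "no valid")
})

test_that("ACC/AE/PMR are invariant under joint rotation of both fields", {
  fp <- make_field_pair(n = 40L, noise = 0.05)
  s <- samp_dense(); sp <- samp_peaks()
  rot <- rotation_operator(withr::with_seed(68L, random_rotation()), 8L)
  p <- sphfod:::field_mat(fp$pred); g <- sphfod:::field_mat(fp$gt)
  pr <- t(apply_rotation(rot, t(p))); gr <- t(apply_rotation(rot, t(g)))
  fpr <- fod_field(pr); fgr <- fod_field(gr)
  a0 <- acc(p, g, s); a1 <- acc(pr, gr, s)
  expect_norm_lt(a1$per_voxel - a0$per_voxel, 1e-6)
  # Newton-refined peaks rotate exactly with the field
  e0 <- sphfod:::field_angular_errors(fp$pred, fp$gt, sp)
  e1 <- sphfod:::field_angular_errors(fpr, fgr, sp)
  expect_norm_lt(e1 - e0, 1e-6)
  r0 <- peak_match_rate(fp$pred, fp$gt, sp, errors = e0)
  r1 <- peak_match_rate(fpr, fgr, sp, errors = e1)
  expect_lt(abs(r1$rate - r0$rate), 1e-6)
})

test_that("evaluate_fields assembles a coherent report", {
  fp <- make_field_pair(n = 512L, seed = 69L, noise = 0.05)
  rep <- evaluate_fields(fp$pred, fp$gt)
  expect_s3_class(rep, "metric_report")
  expect_gte(rep$fod_wise$acc_mean, -1); expect_lte(rep$fod_wise$acc_mean, 1)
  expect_gte(rep$fod_wise$ae_mean, 0); expect_lte(rep$fod_wise$ae_mean, 90)
  expect_gte(rep$fod_wise$pmr, 0); expect_lte(rep$fod_wise$pmr, 1)
  expect_gt(rep$global$psnr, 0)
  path <- tempfile(fileext = ".json")
  write_metric_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$global$mse, rep$global$mse, tolerance = 1e-12)
  csv <- tempfile(fileext = ".csv")
  write_metric_report(rep, csv)
  expect_equal(nrow(utils::read.csv(csv)), 10L)
})
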