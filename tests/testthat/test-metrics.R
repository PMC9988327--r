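test_that("the printed-formula NMSE matches hand arithmetic", {
  a <- suppressWarnings(signal_matrix(matrix(c(3, 4), 2, 1) + 1, c(2, 1, 1)))
  b <- signal_matrix(matrix(1, 2, 1), c(2, 1, 1))
  # difference (3, 4): Frobenius norm 5, N_Vox = 2
  expect_equal(nmse(a, b), 2.5)
  expect_equal(nmse(b, b), 0)
  # homogeneity: scaling both inputs scales nmse by |c|
  a2 <- suppressWarnings(signal_matrix(a$values * 3, c(2, 1, 1)))
  b2 <- suppressWarnings(signal_matrix(b$values * 3, c(2, 1, 1)))
  expect_equal(nmse(a2, b2), 3 * nmse(a, b))
  expect_error(nmse(a, b, mask = c(FALSE, FALSE)), "empty")
})

test_that("PSNR follows 10 log10(MAX / NMSE) with a capped zero-error
           limit", {
  # construct MAX = 1, NMSE = 0.1: 2 voxels, difference norm 0.2
  tr <- signal_matrix(matrix(c(1, 0.5), 2, 1), c(2, 1, 1))
  est <- signal_matrix(tr$values + c(0.2, 0), c(2, 1, 1))
  expect_equal(nmse(est, tr), 0.1)
  expect_equal(as.numeric(psnr(est, tr)), 10)
  capped <- psnr(tr, tr)
  expect_equal(as.numeric(capped), 300)
  expect_true(isTRUE(attr(capped, "capped")))
  # adding a constant changes MAX but not NMSE (printed-formula asymmetry)
  tr2 <- suppressWarnings(signal_matrix(tr$values + 1, c(2, 1, 1)))
  est2 <- suppressWarnings(signal_matrix(est$values + 1, c(2, 1, 1)))
  expect_equal(nmse(est2, tr2), nmse(est, tr))
  expect_gt(as.numeric(psnr(est2, tr2)), as.numeric(psnr(est, tr)))
})

test_that("PSNR decreases strictly as NMSE grows at fixed MAX", {
  tr <- random_signal(c(4, 4, 4), 3, seed = 2)
  errs <- c(0.01, 0.05, 0.2)
  ps <- vapply(errs, function(e) {
    est <- signal_matrix(tr$values + e, c(4, 4, 4))
    as.numeric(psnr(est, tr))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("SSIM is 1 for identical volumes, negative for inverted ones and
           matches the reference implementation", {
  set.seed(11)
  a <- array(runif(16^3), c(16, 16, 16))
  b <- a + array(rnorm(16^3, sd = 0.1), c(16, 16, 16))
  expect_equal(ssim_volume(a, a, data_range = 1), 1)
  # frozen scikit-image values (gaussian_weights, sigma 1.5, no sample cov)
  expect_lt(abs(ssim_volume(a, b, data_range = 1) - 0.9439563062), 1e-6)
  set.seed(12)
  a2 <- array(rnorm(12 * 14 * 16), c(12, 14, 16))
  b2 <- a2 * 0.5 + 0.3
  expect_lt(abs(ssim_volume(a2, b2, data_range = 2) - 0.0047563711), 1e-6)
  # inversion about the mean keeps luminance but anti-correlates structure
  x <- array(5 + rnorm(14^3), c(14, 14, 14))
  expect_lt(ssim_volume(x, 2 * mean(x) - x), 0)
  # volumes smaller than the window shrink it with a warning
  expect_warning(s <- ssim_volume(array(runif(6^3), c(6, 6, 6)),
                                  array(runif(6^3), c(6, 6, 6)),
                                  data_range = 1),
                 "shrunk")
  expect_true(is.finite(s))
})

test_that("signal-matrix SSIM averages the per-wavevector volumes", {
  tr <- random_signal(c(12, 12, 12), 2, seed = 4)
  est <- signal_matrix(tr$values + 0.01 * matrix(rnorm(length(tr$values)),
                                                 nrow(tr$values)),
                       tr$dims)
  per <- vapply(1:2, function(q)
    ssim_volume(dw_volume(est, q), dw_volume(tr, q), data_range = 1),
    numeric(1))
  expect_equal(ssim(est, tr, data_range = 1), mean(per))
})

test_that("relative difference handles exact, zero and masked cases", {
  expect_equal(relative_difference(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(relative_difference(1.02, 1), 0.02, tolerance = 1e-12)
  expect_equal(relative_difference(0, 2), 1)
  expect_true(is.na(relative_difference(1, 0)))
})

test_that("fiber bundle overlap matches hand counts", {
  p_truth <- c(rep(1, 10), rep(0, 5))
  expect_equal(fiber_bundle_overlap(p_truth, p_truth), 1)
  expect_equal(fiber_bundle_overlap(rep(0, 15), p_truth), 0)
  # binary maps: truth size 10, prediction size 8 inside it -> 1 - 2/10
  p <- c(rep(1, 8), rep(0, 7))
  expect_equal(fiber_bundle_overlap(p, p_truth), 0.8)
  expect_error(fiber_bundle_overlap(p, rep(0, 15)), "all zero")
  expect_error(fiber_bundle_overlap(-p, p_truth), "non-negative")
})

test_that("GFA has the closed-form delta limit and scale invariance", {
  expect_equal(gfa(rep(3, 40)), 0)
  n <- 25
  onehot <- c(1, rep(0, n - 1))
  expect_equal(gfa(onehot), sqrt(1 - 1 / n), tolerance = 1e-12)
  set.seed(5)
  psi <- matrix(abs(rnorm(30 * 4)), 30, 4)
  expect_equal(gfa(psi * 7), gfa(psi), tolerance = 1e-12)
  expect_equal(gfa(rep(0, 10)), 0)
})

test_that("metric reports assemble whole-volume and per-shell summaries", {
  spec <- tiny_phantom()
  sim <- synthesize(spec)
  est <- signal_matrix(sim$truth$values +
                         0.01 * matrix(rnorm(length(sim$truth$values)),
                                       nrow(sim$truth$values)),
                       sim$truth$dims)
  # 8-slice volumes shrink the SSIM window; expected on this fixture
  rep <- suppressWarnings(metric_report(est, sim$truth,
                                        gradients = sim$gradients))
  expect_s3_class(rep, "metric_report")
  expect_gt(rep$nmse, 0)
  expect_equal(nrow(rep$per_shell), 2L)
  expect_equal(rep$per_shell$n, c(6L, 6L))
})
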