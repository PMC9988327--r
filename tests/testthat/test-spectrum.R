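test_that("fiber response matches its closed form and limits", {
  # parallel case: exp(-b * d_l)
  expect_equal(response(c(1, 0, 0), 1000, c(1, 0, 0), 2.5e-3, 0.5e-3),
               exp(-2.5), tolerance = 1e-12)
  # b = 0 gives 1 regardless of geometry
  expect_equal(response(c(0, 1, 0), 0, c(1, 0, 0), 2e-3, 0.4e-3), 1)
  # isotropy limit: angle-independent exp(-b d)
  dirs <- unit_rows(matrix(rnorm(30), 10, 3))
  r <- response(dirs, 1000, c(0, 0, 1), 1.8e-3, 1.8e-3 / 1.0)
  expect_equal(r, rep(exp(-1.8), 10), tolerance = 1e-12)
  # non-unit fiber normalized with warning
  expect_warning(r2 <- response(c(1, 0, 0), 1000, c(2, 0, 0), 2e-3, 1e-3),
                 "renormaliz")
  expect_equal(r2, exp(-2), tolerance = 1e-12)
})

test_that("response is covariant under joint rotation of gradients and
           fiber", {
  set.seed(21)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))   # random rotation
    if (det(q) < 0) q[, 1] <- -q[, 1]
    dirs <- unit_rows(matrix(rnorm(18), 6, 3))
    fib <- dirs[1, ]
    a <- response(dirs, 1500, fib, 2e-3, 0.3e-3)
    b <- response(dirs %*% t(q), 1500, as.vector(q %*% fib), 2e-3, 0.3e-3)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("the SH basis has the right size, constant first column and
           antipodal symmetry", {
  v <- unit_rows(matrix(rnorm(45), 15, 3))
  y0 <- sh_basis(v, 0)
  expect_equal(dim(y0), c(15L, 1L))
  expect_equal(as.vector(y0), rep(1 / sqrt(4 * pi), 15))
  y8 <- sh_basis(v, 8)
  expect_equal(ncol(y8), 45L)
  expect_equal(sh_basis(-v, 8), y8, tolerance = 1e-12)
  expect_error(sh_basis(v, 3), "even")
})

test_that("the SH basis is orthonormal under exact sphere quadrature", {
  gl <- pracma::gaussLegendre(30, -1, 1)
  nphi <- 30
  phi <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
  grid <- expand.grid(ct = gl$x, phi = phi)
  w <- rep(gl$w, nphi) * (2 * pi / nphi)
  st <- sqrt(1 - grid$ct^2)
  dirs <- cbind(st * cos(grid$phi), st * sin(grid$phi), grid$ct)
  y <- sh_basis(dirs, 8)
  gram <- t(y) %*% (y * w)
  expect_equal(gram, diag(45), tolerance = 1e-10)
})

test_that("the hemisphere tessellation has 321 well-spread unit axes", {
  tess <- hemisphere_tessellation()
  expect_equal(nrow(tess), 321L)
  expect_equal(sqrt(rowSums(tess^2)), rep(1, 321), tolerance = 1e-12)
  # no two axes coincide (antipodal metric)
  d <- abs(tess %*% t(tess)); diag(d) <- 0
  expect_lt(max(d), 1 - 1e-6)
})

test_that("dictionary columns follow the response model", {
  gt <- make_gradients(list(c(b = 1000, n = 10), c(b = 2000, n = 10)),
                       seed = 6)
  grid <- new_spectrum_grid(data.frame(d_l = 2e-3, d_t = 0.5e-3),
                            iso = c(0, 1.5e-3))
  dict <- build_dictionary(gt, grid, sh_order = 4)
  expect_equal(dict$p_total, 15L + 2L)
  # D_iso = 0 column is all ones
  expect_equal(unname(dict$A[, 16]), rep(1, 20))
  # shell 2 has double b: its iso values are the square of shell 1's
  iso2 <- dict$A[, 17]
  expect_equal(unname(iso2[11:20]), unname(iso2[1:10])^2, tolerance = 1e-12)
  # b0 rows evaluate every atom to 1 before basis projection: add a b0 row
  gt0 <- gradient_table(rbind(c(0, 0, 0), gt$directions), c(0, gt$bvals))
  d0 <- build_dictionary(gt0, grid, sh_order = 0)
  # order-0 block: R (all ones in the b0 row) times constant Y
  expect_equal(unname(d0$A[1, 1]),
               nrow(d0$tessellation) / sqrt(4 * pi), tolerance = 1e-9)
})

test_that("a delta fODF synthesized through the dictionary reproduces the
           direct response within SH truncation error", {
  gt <- make_gradients(list(c(b = 1000, n = 32), c(b = 2000, n = 32)),
                       seed = 3)
  grid <- new_spectrum_grid(data.frame(d_l = 1.7e-3, d_t = 0.4e-3))
  dict <- build_dictionary(gt, grid, sh_order = 8)
  for (j in c(12, 57, 200)) {
    beta <- qr.solve(qr(dict$Y), diag(nrow(dict$Y))[, j])
    pred <- as.vector(dict$A %*% beta)
    direct <- response(gt$directions, gt$bvals, dict$tessellation[j, ],
                       1.7e-3, 0.4e-3)
    expect_lt(sqrt(sum((pred - direct)^2) / sum(direct^2)), 0.02)
  }
})

test_that("synthesized signals are exactly the dictionary-coefficient
           product", {
  gt <- make_gradients(list(c(b = 1000, n = 8)), seed = 8)
  dict <- build_dictionary(gt, spectrum_grid(n_dt = 1), sh_order = 2)
  v <- matrix(rnorm(dict$p_total * 4), dict$p_total, 4)
  expect_identical(synthesize_signal(dict, v), dict$A %*% v)
})

test_that("coefficient fitting is exact for representable data and handles
           degenerate inputs", {
  gt <- make_gradients(list(c(b = 1000, n = 12)), seed = 4)
  grid <- new_spectrum_grid(data.frame(d_l = 1.7e-3, d_t = 0.4e-3))
  dict <- build_dictionary(gt, grid, sh_order = 2)    # P_total = 6 <= N_Q
  v0 <- matrix(rnorm(6 * 5, sd = 0.2), 6, 5)
  E <- suppressWarnings(signal_matrix(t(dict$A %*% v0), c(5, 1, 1)))
  vh <- fit_coefficients(E, dict, damping = 0)
  expect_equal(unclass(vh), v0, tolerance = 1e-8, ignore_attr = TRUE)
  # zeros map to zeros
  E0 <- signal_matrix(matrix(0, 5, 12), c(5, 1, 1))
  expect_equal(max(abs(fit_coefficients(E0, dict, damping = 0))), 0)
  # rank-deficient dictionary at zero damping errors with advice
  dict_big <- build_dictionary(gt, grid, sh_order = 8)  # P_total = 45 > 12
  expect_error(fit_coefficients(E, dict_big, damping = 0), "damping")
})

test_that("the damped fit beats random candidate coefficient fields on
           noisy data", {
  set.seed(31)
  gt <- make_gradients(list(c(b = 1000, n = 12)), seed = 4)
  grid <- new_spectrum_grid(data.frame(d_l = 1.7e-3, d_t = 0.4e-3))
  dict <- build_dictionary(gt, grid, sh_order = 2)
  E <- suppressWarnings(signal_matrix(
    matrix(rnorm(3 * 12, sd = 0.5), 3, 12), c(3, 1, 1)))
  vh <- fit_coefficients(E, dict, damping = 1e-8)
  res <- sum((t(E$values) - dict$A %*% vh)^2)
  for (i in 1:100) {
    cand <- vh + matrix(rnorm(length(vh), sd = 0.05), nrow(vh))
    expect_gte(sum((t(E$values) - dict$A %*% cand)^2), res - 1e-10)
  }
})

test_that("spectrum grids enforce diffusivity constraints", {
  expect_error(new_spectrum_grid(data.frame(d_l = 1e-3, d_t = 2e-3)),
               "d_l >= d_t")
  expect_error(new_spectrum_grid(data.frame(d_l = 2e-3, d_t = 1.9e-3)),
               "1.1")
  expect_warning(new_spectrum_grid(data.frame(d_l = 3e-3, d_t = 1e-3)),
                 "range")
  expect_error(new_spectrum_grid(data.frame(d_l = numeric(0),
                                            d_t = numeric(0))),
               "at least one atom")
  g <- spectrum_grid()
  expect_true(all(g$aniso$d_l / g$aniso$d_t >= 1.1 * (1 - 1e-9)))
  expect_true(all(g$aniso$d_l >= 1.5e-3 & g$aniso$d_l <= 2.5e-3))
})
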