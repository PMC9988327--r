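small_problem <- function(r_side = 2, noise = 0, seed = NULL) {
  spec <- tiny_phantom()
  sim <- synthesize(spec)
  scheme <- plan_side(make_grouping(8, 2), 12, r_side = r_side)
  obs <- acquire(sim$truth, scheme, noise_sigma = noise, seed = seed)
  dict <- matched_dictionary(spec, sim$gradients)
  list(spec = spec, sim = sim, scheme = scheme, obs = obs, dict = dict)
}

test_that("the coefficient subproblem recovers exact solutions and zeros", {
  p <- small_problem()
  dict <- p$dict
  v0 <- matrix(rnorm(dict$p_total * 6, sd = 0.1), dict$p_total, 6)
  # project onto the dictionary's range so recovery is checked in signal
  # space (the matched dictionary has dead columns, so V itself is not
  # identifiable)
  E <- suppressWarnings(signal_matrix(t(dict$A %*% v0), c(6, 1, 1)))
  vh <- update_V(E, matrix(0, 12, 6), dict, damping = 0e0 + 1e-12)
  expect_equal(dict$A %*% vh, dict$A %*% v0, tolerance = 1e-7)
  E0 <- signal_matrix(matrix(0, 6, 12), c(6, 1, 1))
  expect_equal(max(abs(update_V(E0, matrix(0, 12, 6), dict, 1e-10))), 0)
})

test_that("the coefficient subproblem is locally optimal against random
           perturbations", {
  set.seed(13)
  p <- small_problem(noise = 0.05, seed = 3)
  E <- adjoint(p$obs)
  phi <- matrix(rnorm(12 * nrow(E$values), sd = 0.01), 12)
  vh <- update_V(E, phi, p$dict, damping = 1e-6)
  resid <- function(v) sum((t(E$values) + phi - p$dict$A %*% v)^2) +
    1e-6 * sum((v * p$dict$col_norm)^2)
  r0 <- resid(vh)
  for (i in 1:100) {
    cand <- vh + matrix(rnorm(length(vh), sd = 0.01), nrow(vh))
    expect_gte(resid(cand), r0 - 1e-9)
  }
})

test_that("the TV subproblem reduces to a shift at zero lambda and matches
           direct prox calls", {
  p <- small_problem()
  E <- adjoint(p$obs)
  psi <- matrix(rnorm(length(E$values), sd = 0.1), nrow(E$values))
  cfg0 <- recon_config(lambda_tv = 0)
  expect_identical(update_U(E, psi, cfg0), E$values - psi)
  cfg <- recon_config(lambda_tv = 0.02, rho1 = 0.5, tv_inner_iters = 40)
  u <- update_U(E, psi, cfg)
  q <- 4
  direct <- tv_prox(array(E$values[, q] - psi[, q], E$dims), cfg$weights,
                    cfg$lambda_tv / cfg$rho1, inner_iters = 40,
                    tol = cfg$tv_tol)
  expect_equal(u[, q], as.vector(direct), tolerance = 1e-12)
  # constant input stays constant
  Ec <- signal_matrix(matrix(0.5, nrow(E$values), 12), E$dims)
  expect_equal(update_U(Ec, matrix(0, nrow(E$values), 12), cfg),
               Ec$values, tolerance = 1e-8)
})

test_that("the signal subproblem zeroes the objective gradient", {
  set.seed(14)
  p <- small_problem(r_side = 2, noise = 0.05, seed = 4)
  n_vox <- prod(p$obs$dims)
  U <- matrix(rnorm(n_vox * 12, sd = 0.3), n_vox)
  Psi <- matrix(rnorm(n_vox * 12, sd = 0.1), n_vox)
  V <- matrix(rnorm(p$dict$p_total * n_vox, sd = 0.1), p$dict$p_total)
  Phi <- matrix(rnorm(12 * n_vox, sd = 0.1), 12)
  cfg <- recon_config(rho1 = 0.5, rho2 = 0.7)
  E <- update_E(p$obs, U, Psi, V, Phi, p$dict, cfg)
  m <- sidedmri:::expand_slice_mask(p$obs$slice_mask, p$obs$dims)
  objective <- function(vals) {
    av <- p$dict$A %*% V
    0.5 * sum(m * (vals - p$obs$values)^2) +
      cfg$rho1 / 2 * sum((U - vals + Psi)^2) +
      cfg$rho2 / 2 * sum((t(vals) - av + Phi)^2)
  }
  # the objective is quadratic, so central differences are exact for the
  # directional derivative at any step size; roundoff is the only error
  for (i in 1:5) {
    d <- matrix(rnorm(n_vox * 12), n_vox)
    d <- d / sqrt(sum(d^2))
    h <- 0.5
    deriv <- (objective(E$values + h * d) - objective(E$values - h * d)) /
      (2 * h)
    expect_lt(abs(deriv) / max(1, abs(objective(E$values))), 1e-10)
  }
  # analytic gradient vanishes entrywise
  av <- p$dict$A %*% V
  grad <- m * (E$values - p$obs$values) + cfg$rho1 * (E$values - U - Psi) +
    cfg$rho2 * (E$values - t(av - Phi))
  expect_lt(max(abs(grad)), 1e-10)
})

test_that("the closed-form signal update has the expected limits", {
  p <- small_problem(r_side = 2)
  n_vox <- prod(p$obs$dims)
  U <- matrix(0.3, n_vox, 12); Psi <- matrix(0.1, n_vox, 12)
  V <- matrix(0, p$dict$p_total, n_vox); Phi <- matrix(0.2, 12, n_vox)
  m <- sidedmri:::expand_slice_mask(p$obs$slice_mask, p$obs$dims)
  # rho1 = rho2 -> 0: acquired entries tend to the observations
  cfg_small <- recon_config(rho1 = 1e-10, rho2 = 1e-10)
  E <- update_E(p$obs, U, Psi, V, Phi, p$dict, cfg_small)
  expect_equal(E$values[m > 0], p$obs$values[m > 0], tolerance = 1e-8)
  # unacquired entries: weighted average of (U + Psi) and (AV - Phi)^T
  cfg <- recon_config(rho1 = 0.5, rho2 = 0.25)
  E2 <- update_E(p$obs, U, Psi, V, Phi, p$dict, cfg)
  expected <- (0.5 * (0.3 + 0.1) + 0.25 * (0 - 0.2)) / 0.75
  expect_equal(unique(round(E2$values[m == 0], 12)), expected)
})

test_that("multiplier updates accumulate the residuals additively", {
  p <- small_problem(r_side = 1)   # adjoint = truth, so E is representable
  n_vox <- prod(p$obs$dims)
  E <- adjoint(p$obs)
  V <- update_V(E, matrix(0, 12, n_vox), p$dict, 1e-8)
  # feasible point: U = E, AV = E^T -> multipliers unchanged
  up <- update_multipliers(matrix(1, n_vox, 12), matrix(2, 12, n_vox),
                           E, E$values, V, p$dict)
  expect_equal(up$Psi, matrix(1, n_vox, 12))
  expect_equal(max(abs(up$Phi - 2)), 0, tolerance = 1e-6)
  # constant residual c lands in Psi from zero
  U2 <- E$values + 0.25
  up2 <- update_multipliers(matrix(0, n_vox, 12), matrix(0, 12, n_vox),
                            E, U2, V, p$dict)
  expect_equal(max(abs(up2$Psi - 0.25)), 0, tolerance = 1e-12)
  # two successive updates compose additively
  up3 <- update_multipliers(up2$Psi, up2$Phi, E, U2, V, p$dict)
  expect_equal(up3$Psi, 2 * up2$Psi)
})

test_that("noiseless fully sampled representable data is recovered
           exactly", {
  p <- small_problem(r_side = 1)
  cfg <- recon_config(lambda_tv = 0, max_iter = 100, dict_damping = 1e-8)
  rec <- reconstruct(p$obs, p$dict, cfg)
  expect_lt(nmse_relative(rec$E, p$sim$truth), 1e-12)
  expect_lt(nmse(rec$E, p$sim$truth), 1e-6)
})

test_that("with a dominant data term the acquired entries match the
           observations", {
  p <- small_problem(r_side = 2, noise = 0.02, seed = 6)
  cfg <- recon_config(lambda_tv = 0, rho1 = 1e-6, rho2 = 1e-6, max_iter = 3)
  rec <- reconstruct(p$obs, p$dict, cfg)
  m <- sidedmri:::expand_slice_mask(p$obs$slice_mask, p$obs$dims)
  expect_equal(rec$E$values[m > 0], p$obs$values[m > 0], tolerance = 1e-4)
})

test_that("reconstruction beats the zero-filled adjoint on undersampled
           noisy data", {
  p <- small_problem(r_side = 2, noise = 1 / 30, seed = 11)
  rec <- reconstruct(p$obs, p$dict, recon_config(max_iter = 40))
  expect_lt(nmse(rec$E, p$sim$truth), nmse(adjoint(p$obs), p$sim$truth))
})

test_that("the reconstruction records history and stop reason", {
  p <- small_problem(r_side = 2)
  rec <- reconstruct(p$obs, p$dict, recon_config(max_iter = 5))
  h <- recon_history(rec)
  expect_equal(nrow(h), 5L)
  expect_true(all(c("d_psi_sq", "d_phi_sq", "data_term", "objective")
                  %in% names(h)))
  expect_true(rec$stop_reason %in% c("max_iter", "tolerance"))
  expect_equal(rec$stop_reason, "max_iter")
})
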