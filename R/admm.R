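#' Reconstruction configuration
#'
#' Parameters of the ADMM reconstruction. Defaults follow the settings the
#' method is typically run with: TV weight `lambda_tv = 0.01`, penalty
#' parameters `rho1 = rho2 = 0.5`, TV weights (0.9, 0.9, 1).
#' Stopping tolerances apply to the squared change of the multipliers
#' between iterations; when left `NULL` they are set at run time to
#' `1e-8 * (number of entries)` of the corresponding multiplier, which on
#' small volumes lets the solver run until the primal residuals plateau.
#'
#' @param lambda_tv TV regularization weight (>= 0).
#' @param rho1,rho2 ADMM penalty parameters (> 0) for the TV splitting and
#'   the dictionary constraint.
#' @param weights a [tv_weights()].
#' @param eps1,eps2 stopping tolerances on `||Psi(t) - Psi(t-1)||^2` and
#'   `||Phi(t) - Phi(t-1)||^2`.
#' @param max_iter iteration cap (>= 1).
#' @param dict_damping Tikhonov damping of the dictionary solve (>= 0).
#' @param tv_inner_iters,tv_tol inner settings forwarded to [tv_prox()].
#' @param verbose print per-iteration residuals.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda_tv = 0.01, rho1 = 0.5, rho2 = 0.5,
                         weights = tv_weights(), eps1 = NULL, eps2 = NULL,
                         max_iter = 100, dict_damping = 1e-6,
                         tv_inner_iters = 30, tv_tol = 1e-5,
                         verbose = FALSE) {
  stopifnot(lambda_tv >= 0, rho1 > 0, rho2 > 0, max_iter >= 1,
            dict_damping >= 0, inherits(weights, "tv_weights"))
  if (!is.null(eps1)) stopifnot(eps1 > 0)
  if (!is.null(eps2)) stopifnot(eps2 > 0)
  structure(list(lambda_tv = lambda_tv, rho1 = rho1, rho2 = rho2,
                 weights = weights, eps1 = eps1, eps2 = eps2,
                 max_iter = as.integer(max_iter),
                 dict_damping = dict_damping,
                 tv_inner_iters = tv_inner_iters, tv_tol = tv_tol,
                 verbose = verbose),
            class = "recon_config")
}

#' Dictionary-coefficient subproblem
#'
#' Minimizes `||E^T + Phi - A V||^2` (with damping) for the current signal
#' iterate and scaled multiplier; the Cholesky factorization of the normal
#' matrix is cached on the dictionary and reused across iterations.
#'
#' @param E a [signal_matrix()] iterate.
#' @param Phi N_Q x N_Vox multiplier (0 at initialization).
#' @param dict a [build_dictionary()] result.
#' @param damping solve damping (>= 0).
#' @return P_total x N_Vox coefficient matrix.
#' @export
update_V <- function(E, Phi, dict, damping = 0) {
  rhs <- t(E$values) + Phi
  dict_solve(dict, rhs, damping)
}

#' TV-splitting subproblem
#'
#' For every wavevector q, `U_q = tv_prox(E^(q) - Psi_q, weights,
#' lambda / rho1)`; the per-wavevector problems are independent.
#'
#' @param E a [signal_matrix()] iterate.
#' @param Psi N_Vox x N_Q scaled multiplier matrix.
#' @param cfg a [recon_config()].
#' @return N_Vox x N_Q matrix of auxiliary volumes (flattened).
#' @export
update_U <- function(E, Psi, cfg) {
  strength <- cfg$lambda_tv / cfg$rho1
  x <- E$values - Psi
  if (strength == 0) return(x)
  for (q in seq_len(ncol(x))) {
    vol <- as_volume(x[, q], E$dims)
    x[, q] <- as.vector(tv_prox(vol, cfg$weights, strength,
                                inner_iters = cfg$tv_inner_iters,
                                tol = cfg$tv_tol))
  }
  x
}

#' Signal subproblem (closed form)
#'
#' The data term, the TV splitting term and the dictionary penalty are all
#' separable per (voxel, wavevector) entry, so the minimizer is elementwise:
#' `E = (M * Y_obs + rho1 (U + Psi) + rho2 (A V - Phi)^T) / (M + rho1 +
#' rho2)` with `M` the 0/1 acquisition mask and `Y_obs` the observed values.
#'
#' @param obs the [acquire()] observation.
#' @param U,Psi N_Vox x N_Q auxiliary volumes and scaled multiplier.
#' @param V,Phi dictionary coefficients and N_Q x N_Vox multiplier.
#' @param dict a [build_dictionary()] result.
#' @param cfg a [recon_config()].
#' @return a [signal_matrix()].
#' @export
update_E <- function(obs, U, Psi, V, Phi, dict, cfg) {
  m <- expand_slice_mask(obs$slice_mask, obs$dims)
  num <- m * obs$values + cfg$rho1 * (U + Psi) +
    cfg$rho2 * t(synthesize_signal(dict, V) - Phi)
  den <- m + cfg$rho1 + cfg$rho2
  suppressWarnings(signal_matrix(num / den, obs$dims,
                                 voxel_size = obs$voxel_size))
}

#' Multiplier updates
#'
#' Scaled dual ascent: `Psi_q <- Psi_q + (U_q - E^(q))` and
#' `Phi <- Phi + (E^T - A V)`.
#'
#' @param Psi,Phi current multipliers.
#' @param E a [signal_matrix()] iterate.
#' @param U N_Vox x N_Q auxiliary volumes.
#' @param V coefficients.
#' @param dict a [build_dictionary()] result.
#' @return list with updated `Psi` and `Phi`.
#' @export
update_multipliers <- function(Psi, Phi, E, U, V, dict) {
  list(Psi = Psi + (U - E$values),
       Phi = Phi + (t(E$values) - synthesize_signal(dict, V)))
}

admm_objective <- function(E, obs, U, cfg, w) {
  tvsum <- 0
  if (cfg$lambda_tv > 0)
    for (q in seq_len(ncol(U)))
      tvsum <- tvsum + tv_seminorm(as_volume(U[, q], E$dims), w)
  data_residual(E, obs) + cfg$lambda_tv * tvsum
}

#' Reconstruct full diffusion-weighted volumes from SIDE observations
#'
#' Recovers the N_Vox x N_Q attenuation matrix E from slice-undersampled
#' observations by ADMM on the TV-regularized, dictionary-constrained
#' least-squares problem: the data term scores E against the observed
#' slices, per-volume auxiliary variables U_q carry the TV penalty, and the
#' constraint `E^T = A V` ties every voxel's signal to the
#' restriction-spectrum model. Each iteration solves the V, U and E
#' subproblems in turn and then updates the multipliers; iteration stops at
#' `max_iter` or when the squared change of both multipliers drops below
#' the tolerances.
#'
#' Initialization: multipliers at zero, E at the zero-filled adjoint of the
#' observations, U_q at the corresponding volumes of E.
#'
#' @param obs a [acquire()] or [acquire_conventional()] observation.
#' @param dict a [build_dictionary()] result with `nrow(A)` matching the
#'   observation's wavevector count.
#' @param cfg a [recon_config()].
#' @return object of class `side_recon`: the recovered `E`
#'   ([signal_matrix()]), coefficients `V`, final `U`, multipliers `Psi`
#'   and `Phi`, a per-iteration `history` data.frame (multiplier changes,
#'   primal residuals, data term, objective) and `stop_reason`
#'   (`"tolerance"` or `"max_iter"`).
#' @export
reconstruct <- function(obs, dict, cfg = recon_config()) {
  stopifnot(inherits(obs, "side_observation"),
            inherits(dict, "spectrum_dictionary"),
            inherits(cfg, "recon_config"))
  if (ncol(obs$values) != nrow(dict$A))
    stop_side("observation has ", ncol(obs$values),
              " wavevectors but the dictionary has ", nrow(dict$A),
              class = "sidedmri_dimension_error")
  n_vox <- prod(obs$dims); n_q <- ncol(obs$values)
  eps1 <- cfg$eps1 %||% (1e-8 * n_vox * n_q)
  eps2 <- cfg$eps2 %||% (1e-8 * n_vox * n_q)
  E <- adjoint(obs)
  U <- E$values
  Psi <- matrix(0, n_vox, n_q)
  Phi <- matrix(0, n_q, n_vox)
  hist <- vector("list", cfg$max_iter)
  stop_reason <- "max_iter"
  obj_min <- Inf
  V <- NULL
  for (t in seq_len(cfg$max_iter)) {
    V <- update_V(E, Phi, dict, cfg$dict_damping)
    U <- update_U(E, Psi, cfg)
    E <- update_E(obs, U, Psi, V, Phi, dict, cfg)
    av <- synthesize_signal(dict, V)
    d_psi <- sum((U - E$values)^2)          # = ||Psi(t) - Psi(t-1)||^2
    d_phi <- sum((t(E$values) - av)^2)      # = ||Phi(t) - Phi(t-1)||^2
    Psi <- Psi + (U - E$values)
    Phi <- Phi + (t(E$values) - av)
    obj <- admm_objective(E, obs, U, cfg, cfg$weights)
    hist[[t]] <- data.frame(
      iter = t, d_psi_sq = d_psi, d_phi_sq = d_phi,
      primal_tv = sqrt(d_psi), primal_dict = sqrt(d_phi),
      data_term = data_residual(E, obs), objective = obj)
    if (cfg$verbose)
      message(sprintf(
        "iter %3d | dPsi^2 %.3e dPhi^2 %.3e | data %.4e | obj %.4e",
        t, d_psi, d_phi, hist[[t]]$data_term, obj))
    obj_min <- min(obj_min, obj)
    if (is.finite(obj) && obj > 10 * obj_min && t > 5)
      stop_side("ADMM diverged: objective ", format(obj, digits = 4),
                " exceeds 10x its running minimum ",
                format(obj_min, digits = 4), " at iteration ", t)
    if (d_psi <= eps1 && d_phi <= eps2) { stop_reason <- "tolerance"; break }
  }
  structure(list(E = E, V = structure(V, class = c("coefficient_field",
                                                   class(V))),
                 U = U, Psi = Psi, Phi = Phi,
                 history = do.call(rbind, hist[!vapply(hist, is.null,
                                                       logical(1))]),
                 stop_reason = stop_reason, config = cfg, dict = dict),
            class = "side_recon")
}

#' @export
print.side_recon <- function(x, ...) {
  h <- x$history
  cat("<side_recon> ", paste(x$E$dims, collapse = " x "), " x ",
      ncol(x$E$values), ", ", nrow(h), " iterations (stop: ", x$stop_reason,
      ")\n  final data term ", format(h$data_term[nrow(h)], digits = 5),
      ", primal residuals (TV, dict) = (",
      format(h$primal_tv[nrow(h)], digits = 4), ", ",
      format(h$primal_dict[nrow(h)], digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Convergence history of a reconstruction
#'
#' @param recon a [reconstruct()] result.
#' @return data.frame with one row per ADMM iteration.
#' @export
recon_history <- function(recon) {
  stopifnot(inherits(recon, "side_recon"))
  recon$history
}

#' Plot ADMM convergence
#'
#' Primal residual and objective traces on a log scale.
#'
#' @param x a [reconstruct()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.side_recon <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$iter, cbind(h$primal_tv, h$primal_dict), type = "l",
                    lty = 1, log = "y", xlab = "iteration",
                    ylab = "primal residual", ...)
  graphics::legend("topright", legend = c("||U - E||", "||E^T - AV||"),
                   lty = 1, col = 1:2, bty = "n")
  invisible(x)
}
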