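#' Per-axis total-variation weights
#'
#' Non-negative weights (gamma_x, gamma_y, gamma_z) scaling the spatial
#' finite differences inside the TV semi-norm; the default (0.9, 0.9, 1)
#' regularizes slightly more along the slice axis, where SIDE undersampling
#' removes data.
#'
#' @param gamma_x,gamma_y,gamma_z non-negative weights.
#' @return object of class `tv_weights`.
#' @export
tv_weights <- function(gamma_x = 0.9, gamma_y = 0.9, gamma_z = 1) {
  w <- c(gamma_x, gamma_y, gamma_z)
  if (any(!is.finite(w)) || any(w < 0))
    stop_side("TV weights must be finite and non-negative")
  structure(list(gamma_x = gamma_x, gamma_y = gamma_y, gamma_z = gamma_z),
            class = "tv_weights")
}

# forward differences with Neumann boundary (difference past the last
# index is 0), each scaled by its axis weight; returns a list of 3 arrays
tv_grad <- function(u, w) {
  d <- dim(u)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 1) gx[-d[1], , ] <- w$gamma_x *
      (u[-1, , , drop = FALSE] - u[-d[1], , , drop = FALSE])
  if (d[2] > 1) gy[, -d[2], ] <- w$gamma_y *
      (u[, -1, , drop = FALSE] - u[, -d[2], , drop = FALSE])
  if (d[3] > 1) gz[, , -d[3]] <- w$gamma_z *
      (u[, , -1, drop = FALSE] - u[, , -d[3], drop = FALSE])
  list(gx, gy, gz)
}

# adjoint of tv_grad: negative weighted divergence
tv_grad_adjoint <- function(p, w) {
  d <- dim(p[[1]])
  out <- array(0, d)
  if (d[1] > 1) {
    px <- p[[1]]; px[d[1], , ] <- 0
    out[-1, , ] <- out[-1, , , drop = FALSE] + w$gamma_x * px[-d[1], , , drop = FALSE]
    out <- out - w$gamma_x * px
  }
  if (d[2] > 1) {
    py <- p[[2]]; py[, d[2], ] <- 0
    out[, -1, ] <- out[, -1, , drop = FALSE] + w$gamma_y * py[, -d[2], , drop = FALSE]
    out <- out - w$gamma_y * py
  }
  if (d[3] > 1) {
    pz <- p[[3]]; pz[, , d[3]] <- 0
    out[, , -1] <- out[, , -1, drop = FALSE] + w$gamma_z * pz[, , -d[3], drop = FALSE]
    out <- out - w$gamma_z * pz
  }
  out
}

#' Weighted isotropic 3-D total-variation semi-norm
#'
#' Sum over voxels of `sqrt(gx^2 dx^2 + gy^2 dy^2 + gz^2 dz^2)` with forward
#' differences and Neumann boundary handling, so constant volumes have TV 0.
#'
#' @param volume 3-D numeric array (a 2-D matrix is treated as one z-plane).
#' @param w a [tv_weights()].
#' @return non-negative scalar.
#' @export
tv_seminorm <- function(volume, w = tv_weights()) {
  if (length(dim(volume)) == 2L) dim(volume) <- c(dim(volume), 1L)
  stopifnot(length(dim(volume)) == 3L, all(is.finite(volume)))
  g <- tv_grad(volume, w)
  sum(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2))
}

#' Proximal operator of the weighted TV semi-norm
#'
#' Solves `argmin_U 0.5 ||U - volume||^2 + strength * TV(U)` by an
#' accelerated (FISTA) projected-gradient ascent on the dual formulation:
#' dual fields are per-voxel 3-vectors constrained to the unit ball, the
#' dual step is `1 / (4 (gx^2 + gy^2 + gz^2))` over the strength, and
#' iteration stops on the relative change of the primal iterate or after
#' `inner_iters` steps (best iterate returned with a warning on
#' non-convergence).
#'
#' @param volume 3-D numeric array.
#' @param w a [tv_weights()].
#' @param strength proximal weight (lambda / rho1 in the ADMM); 0 returns
#'   the input unchanged.
#' @param inner_iters maximum dual iterations (default 50).
#' @param tol relative-change stopping tolerance (default 1e-5).
#' @return array of the same shape.
#' @export
tv_prox <- function(volume, w = tv_weights(), strength,
                    inner_iters = 50, tol = 1e-5) {
  stopifnot(strength >= 0)
  if (strength == 0) return(volume)
  squeeze <- FALSE
  if (length(dim(volume)) == 2L) { dim(volume) <- c(dim(volume), 1L); squeeze <- TRUE }
  d <- dim(volume)
  lip <- 4 * (w$gamma_x^2 + w$gamma_y^2 + w$gamma_z^2)
  if (lip == 0) return(volume)
  step <- 1 / (lip * strength)
  zero <- array(0, d)
  p <- list(zero, zero, zero)   # dual iterate
  q <- p                        # momentum point
  t_mom <- 1
  u_prev <- volume
  converged <- FALSE
  for (it in seq_len(inner_iters)) {
    u <- volume - strength * tv_grad_adjoint(q, w)
    g <- tv_grad(u, w)
    p_new <- list(q[[1]] + step * g[[1]],
                  q[[2]] + step * g[[2]],
                  q[[3]] + step * g[[3]])
    nrm <- sqrt(p_new[[1]]^2 + p_new[[2]]^2 + p_new[[3]]^2)
    scale <- 1 / pmax(1, nrm)
    p_new <- list(p_new[[1]] * scale, p_new[[2]] * scale, p_new[[3]] * scale)
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    mom <- (t_mom - 1) / t_new
    q <- list(p_new[[1]] + mom * (p_new[[1]] - p[[1]]),
              p_new[[2]] + mom * (p_new[[2]] - p[[2]]),
              p_new[[3]] + mom * (p_new[[3]] - p[[3]]))
    p <- p_new
    t_mom <- t_new
    rel <- sqrt(sum((u - u_prev)^2)) / max(sqrt(sum(u^2)), 1e-12)
    u_prev <- u
    if (it > 1 && rel < tol) { converged <- TRUE; break }
  }
  u <- volume - strength * tv_grad_adjoint(p, w)
  if (!converged && inner_iters > 5)
    if (getOption("sidedmri.warn_tv", FALSE))
      warning("tv_prox: dual iteration hit inner_iters without meeting tol")
  if (squeeze) dim(u) <- d[1:2]
  u
}
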