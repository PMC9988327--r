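#' Axially symmetric fiber response function
#'
#' Signal attenuation of a coherent fiber population with longitudinal
#' diffusivity `d_l` and transverse diffusivity `d_t` (mm^2/s):
#' `exp(-b * ((d_l - d_t) * (q . v)^2 + d_t))`, where `q` is the unit
#' encoding direction and `v` the unit fiber axis. At b = 0 the response is
#' 1; for `d_l == d_t` it reduces to isotropic decay `exp(-b d)`.
#'
#' @param directions encoding direction(s): length-3 vector or N x 3 matrix.
#' @param bvals b-value(s) (s/mm^2), recycled against the directions.
#' @param fiber unit fiber axis (length-3).
#' @param d_l,d_t longitudinal and transverse diffusivities (mm^2/s),
#'   `d_l >= d_t >= 0`.
#' @return attenuation vector in (0, 1].
#' @export
response <- function(directions, bvals, fiber, d_l, d_t) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  stopifnot(length(fiber) == 3, all(is.finite(bvals)), all(bvals >= 0),
            is.finite(d_l), is.finite(d_t), d_l >= d_t, d_t >= 0)
  nf <- sqrt(sum(fiber^2))
  if (abs(nf - 1) > 1e-6) {
    warning("fiber axis not unit norm; renormalizing")
    fiber <- fiber / nf
  }
  nrm <- sqrt(rowSums(directions^2))
  dw <- bvals > 0
  if (any(dw & abs(nrm - 1) > 1e-6)) {
    warning("encoding direction(s) not unit norm; renormalizing")
  }
  directions <- unit_rows(directions)
  ct2 <- as.vector(directions %*% fiber)^2
  exp(-bvals * ((d_l - d_t) * ct2 + d_t))
}

#' Diffusion spectrum grid
#'
#' The set of response-function atoms spanned by the dictionary: anisotropic
#' atoms are (D_L, D_T) pairs with `D_L / D_T >= 1.1`; isotropic atoms are
#' single diffusivities. Defaults cover longitudinal diffusivities 1.5 to
#' 2.5 x 10^-3 mm^2/s with, for each, a log-spaced transverse ladder from
#' D_L/1.1 down to 0.1 x 10^-3, plus isotropic atoms at 0.5, 1.5 and
#' 3.0 x 10^-3 mm^2/s.
#'
#' @param d_l longitudinal diffusivities for the anisotropic atoms (mm^2/s).
#' @param n_dt transverse-ladder length per `d_l`.
#' @param dt_min smallest transverse diffusivity on the ladder.
#' @param d_iso isotropic diffusivities (mm^2/s); may be empty.
#' @param d_l_range,d_iso_range admissible ranges, checked with a warning
#'   when exceeded.
#' @return object of class `spectrum_grid` with `aniso` (data.frame with
#'   columns `d_l`, `d_t`) and `iso` (numeric vector).
#' @export
spectrum_grid <- function(d_l = c(1.5, 2.0, 2.5) * 1e-3,
                          n_dt = 3,
                          dt_min = 0.1e-3,
                          d_iso = c(0.5, 1.5, 3.0) * 1e-3,
                          d_l_range = c(1.5e-3, 2.5e-3),
                          d_iso_range = c(0, 3e-3)) {
  aniso <- do.call(rbind, lapply(d_l, function(dl) {
    dt <- exp(seq(log(dl / 1.1), log(dt_min), length.out = n_dt))
    data.frame(d_l = dl, d_t = dt)
  }))
  new_spectrum_grid(aniso, d_iso, d_l_range, d_iso_range)
}

#' Construct a spectrum grid from explicit atoms
#'
#' @param aniso data.frame with columns `d_l`, `d_t` (may have 0 rows).
#' @param iso numeric vector of isotropic diffusivities.
#' @inheritParams spectrum_grid
#' @return a `spectrum_grid`.
#' @export
new_spectrum_grid <- function(aniso, iso = numeric(0),
                              d_l_range = c(1.5e-3, 2.5e-3),
                              d_iso_range = c(0, 3e-3)) {
  aniso <- as.data.frame(aniso)
  if (nrow(aniso) == 0 && length(iso) == 0)
    stop_side("spectrum grid must contain at least one atom")
  if (nrow(aniso)) {
    stopifnot(all(c("d_l", "d_t") %in% names(aniso)))
    if (any(aniso$d_t < 0) || any(aniso$d_l < aniso$d_t))
      stop_side("anisotropic atoms need d_l >= d_t >= 0")
    if (any(aniso$d_l / aniso$d_t < 1.1 * (1 - 1e-9)))
      stop_side("anisotropic atoms need d_l / d_t >= 1.1")
    if (any(aniso$d_l < d_l_range[1] - 1e-12) ||
        any(aniso$d_l > d_l_range[2] + 1e-12))
      warning("d_l outside the default range [",
              d_l_range[1], ", ", d_l_range[2], "] mm^2/s")
  }
  if (length(iso) &&
      (any(iso < d_iso_range[1] - 1e-12) || any(iso > d_iso_range[2] + 1e-12)))
    warning("d_iso outside the default range [",
            d_iso_range[1], ", ", d_iso_range[2], "] mm^2/s")
  structure(list(aniso = aniso, iso = as.numeric(iso)),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat("<spectrum_grid> ", nrow(x$aniso), " anisotropic atoms, ",
      length(x$iso), " isotropic atoms\n", sep = "")
  invisible(x)
}

#' Build the restriction-spectrum dictionary
#'
#' Assembles `A = [R_1 Y_1 ... R_K Y_K | iso columns]`: for each anisotropic
#' atom k, `R_k` is the N_Q x N_F matrix of response values between every
#' gradient and every tessellation direction and `Y` the N_F x P even
#' spherical-harmonic basis on the tessellation; each isotropic atom
#' contributes the single column `exp(-b * D_iso)`. Signals synthesized from
#' a coefficient vector v are `A v`. Columns are normalized to unit
#' Euclidean norm internally for conditioning; fitted coefficients are
#' rescaled back to the raw-column convention on output.
#'
#' @param gradients a [gradient_table()] (b0 rows evaluate every atom to 1).
#' @param grid a [spectrum_grid()].
#' @param sh_order even spherical-harmonic order (default 8).
#' @param tessellation N_F x 3 unit directions covering the hemisphere
#'   (default [hemisphere_tessellation()]).
#' @return object of class `spectrum_dictionary` with the raw matrix `A`
#'   (N_Q x P_total), the per-column norms `col_norm`, the basis and grid
#'   metadata, and a solve cache.
#' @export
build_dictionary <- function(gradients, grid, sh_order = 8,
                             tessellation = hemisphere_tessellation()) {
  stopifnot(inherits(gradients, "gradient_table"),
            inherits(grid, "spectrum_grid"))
  tessellation <- unit_rows(as.matrix(tessellation))
  y <- sh_basis(tessellation, sh_order)
  p <- ncol(y)
  k <- nrow(grid$aniso)
  q <- gradients$directions
  b <- gradients$bvals
  blocks <- vector("list", k + (length(grid$iso) > 0))
  ct2 <- (q %*% t(tessellation))^2            # N_Q x N_F
  if (k > 0) {
    for (i in seq_len(k)) {
      dl <- grid$aniso$d_l[i]; dt <- grid$aniso$d_t[i]
      r_i <- exp(-b * ((dl - dt) * ct2 + dt))  # b recycles down columns
      blocks[[i]] <- r_i %*% y
    }
  }
  if (length(grid$iso))
    blocks[[k + 1L]] <- vapply(grid$iso, function(d) exp(-b * d),
                               numeric(length(b)))
  a <- do.call(cbind, blocks)
  col_norm <- sqrt(colSums(a^2))
  if (all(col_norm == 0)) stop_side("dictionary is all zero")
  col_norm[col_norm == 0] <- 1   # dead columns (e.g. tiny tessellations)
  structure(list(A = a, col_norm = col_norm, grid = grid,
                 sh_order = sh_order, P = p,
                 n_aniso = k, p_total = ncol(a),
                 tessellation = tessellation, Y = y,
                 gradients = gradients,
                 cache = new.env(parent = emptyenv())),
            class = "spectrum_dictionary")
}

#' @export
print.spectrum_dictionary <- function(x, ...) {
  cat("<spectrum_dictionary> ", nrow(x$A), " x ", x$p_total,
      " (", x$n_aniso, " anisotropic blocks of width ", x$P, ", ",
      length(x$grid$iso), " isotropic columns), SH order ", x$sh_order,
      ", N_F = ", nrow(x$tessellation), "\n", sep = "")
  invisible(x)
}

#' Synthesize signals from spectrum coefficients
#'
#' @param dict a [build_dictionary()] result.
#' @param V P_total x N_Vox coefficient matrix (raw-column convention).
#' @return N_Q x N_Vox signal matrix `A V`.
#' @export
synthesize_signal <- function(dict, V) dict$A %*% V

# damped normal-equation solve against the normalized dictionary, with the
# Cholesky factor cached per damping value (reused across ADMM iterations)
dict_solve <- function(dict, rhs, damping) {
  an <- sweep(dict$A, 2, dict$col_norm, `/`)
  key <- paste0("chol_", format(damping, digits = 17))
  ch <- dict$cache[[key]]
  if (is.null(ch)) {
    gram <- crossprod(an)
    diag(gram) <- diag(gram) + damping
    ch <- tryCatch(chol(gram), error = function(e)
      stop_side("normal matrix is singular at damping = ", damping,
                "; increase the damping parameter"))
    dict$cache[[key]] <- ch
  }
  vn <- backsolve(ch, forwardsolve(t(ch), crossprod(an, rhs)))
  vn / dict$col_norm
}

#' Fit spectrum coefficients per voxel
#'
#' Damped linear least squares `V = argmin ||E^T - A V||^2 + damping ||V||^2`
#' (damping applied in the normalized-column metric), solved with one
#' Cholesky factorization shared by all voxels.
#'
#' @param E a [signal_matrix()] (N_Vox x N_Q).
#' @param dict a [build_dictionary()] result.
#' @param damping Tikhonov damping (>= 0); with 0 the normal matrix must be
#'   nonsingular.
#' @return P_total x N_Vox coefficient matrix of class `coefficient_field`.
#' @export
fit_coefficients <- function(E, dict, damping = 0) {
  stopifnot(inherits(E, "signal_matrix"), damping >= 0)
  if (ncol(E$values) != nrow(dict$A))
    stop_side("E has ", ncol(E$values), " wavevectors but the dictionary has ",
              nrow(dict$A), class = "sidedmri_dimension_error")
  v <- dict_solve(dict, t(E$values), damping)
  structure(v, class = c("coefficient_field", class(v)))
}

#' Aggregate anisotropic fODF amplitudes
#'
#' Sums the fODF amplitudes of all anisotropic spectrum atoms on the
#' tessellation; the standard input for [gfa()].
#'
#' @param dict a [build_dictionary()] result.
#' @param V P_total x N_Vox coefficients.
#' @return N_F x N_Vox amplitude matrix.
#' @export
fodf_amplitudes <- function(dict, V) {
  if (dict$n_aniso == 0) stop_side("dictionary has no anisotropic atoms")
  amp <- matrix(0, nrow(dict$tessellation), ncol(V))
  for (k in seq_len(dict$n_aniso)) {
    idx <- (k - 1L) * dict$P + seq_len(dict$P)
    amp <- amp + dict$Y %*% V[idx, , drop = FALSE]
  }
  amp
}
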