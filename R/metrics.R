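#' Normalized mean squared error (printed-formula convention)
#'
#' `||E - E_truth||_F / N_Vox`: the Frobenius norm of the (masked)
#' difference divided by the number of voxels in the mask. Note the norm is
#' not squared and the divisor is the voxel count, not the entry count; the
#' conventional relative squared error is available as [nmse_relative()].
#'
#' @param E,E_truth [signal_matrix()] objects, numeric matrices or arrays of
#'   the same shape.
#' @param mask optional logical voxel mask (length N_Vox for signal
#'   matrices, same shape as the input otherwise).
#' @return non-negative scalar.
#' @export
nmse <- function(E, E_truth, mask = NULL) {
  d <- metric_pair(E, E_truth, mask)
  sqrt(sum(d$diff^2)) / d$n_vox
}

#' Conventional relative squared error
#'
#' `||E - E_truth||_F^2 / ||E_truth||_F^2` over the mask.
#'
#' @inheritParams nmse
#' @return non-negative scalar.
#' @export
nmse_relative <- function(E, E_truth, mask = NULL) {
  d <- metric_pair(E, E_truth, mask)
  sum(d$diff^2) / sum(d$truth^2)
}

metric_pair <- function(E, E_truth, mask) {
  get_vals <- function(x) if (inherits(x, "signal_matrix")) x$values else x
  a <- get_vals(E); b <- get_vals(E_truth)
  if (!identical(dim(a), dim(b)))
    stop_side("inputs have different shapes",
              class = "sidedmri_dimension_error")
  if (is.null(mask)) {
    n_vox <- if (inherits(E_truth, "signal_matrix")) prod(E_truth$dims)
             else length(b) / max(1, ncol(as.matrix(b)))
    return(list(diff = a - b, truth = b, n_vox = n_vox))
  }
  mask <- as.logical(mask)
  if (!any(mask)) stop_side("empty metric mask")
  if (inherits(E_truth, "signal_matrix")) {
    stopifnot(length(mask) == nrow(b))
    list(diff = a[mask, , drop = FALSE] - b[mask, , drop = FALSE],
         truth = b[mask, , drop = FALSE], n_vox = sum(mask))
  } else {
    stopifnot(length(mask) == length(b))
    list(diff = a[mask] - b[mask], truth = b[mask], n_vox = sum(mask))
  }
}

#' Peak signal-to-noise ratio (printed-formula convention)
#'
#' `10 log10(MAX / NMSE)` with `MAX` the maximum of the ground truth over
#' the mask and NMSE the printed-formula [nmse()]. Identical inputs give a
#' zero NMSE; the value is then capped at `cap` dB and flagged with
#' attribute `capped`. The conventional MAX^2/MSE variant is
#' [psnr_standard()].
#'
#' @inheritParams nmse
#' @param cap ceiling (dB) returned for a zero NMSE.
#' @return scalar dB value.
#' @export
psnr <- function(E, E_truth, mask = NULL, cap = 300) {
  d <- metric_pair(E, E_truth, mask)
  nm <- sqrt(sum(d$diff^2)) / d$n_vox
  mx <- max(d$truth)
  if (nm == 0 || 10 * log10(mx / nm) > cap)
    return(structure(cap, capped = TRUE))
  10 * log10(mx / nm)
}

#' Conventional peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / MSE)` with MSE the per-entry mean squared error.
#'
#' @inheritParams psnr
#' @return scalar dB value.
#' @export
psnr_standard <- function(E, E_truth, mask = NULL, cap = 300) {
  d <- metric_pair(E, E_truth, mask)
  mse <- mean(d$diff^2)
  mx <- max(d$truth)
  if (mse == 0 || 10 * log10(mx^2 / mse) > cap)
    return(structure(cap, capped = TRUE))
  10 * log10(mx^2 / mse)
}

# separable Gaussian filter with edge-replicating boundary
gaussian_filter3 <- function(x, sigma, radius) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  filt1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], radius), v, rep(v[n], radius))
    as.vector(stats::filter(vp, k, sides = 2))[(radius + 1):(radius + n)]
  }
  # apply() puts the filtered axis first; permute back after each pass
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(2, 3, 1))
  for (ax in 1:3)
    x <- aperm(apply(x, setdiff(1:3, ax), filt1), perms[[ax]])
  x
}

#' Structural similarity index for volumes
#'
#' Mean local SSIM over a 3-D volume with the standard constants
#' K1 = 0.01, K2 = 0.03 and a Gaussian window (sigma = 1.5, 11^3 support);
#' local statistics use Gaussian weights (no sample-covariance correction),
#' edge-replicated filtering, and the border region within the window radius
#' is excluded from the mean. Matches the widely used reference
#' implementation to numerical precision.
#'
#' @param a,b 3-D arrays of the same shape.
#' @param data_range value range L of the data; default
#'   `diff(range(c(a, b)))`, or 1 when that is zero.
#' @param sigma Gaussian window standard deviation.
#' @param radius window half-width; windows larger than the volume are
#'   shrunk with a warning.
#' @return scalar in [-1, 1].
#' @export
ssim_volume <- function(a, b, data_range = NULL, sigma = 1.5, radius = 5) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3L)
  d <- dim(a)
  if (min(d) <= 2 * radius + 1) {
    radius <- max(1L, (min(d) - 1L) %/% 2 - 1L)
    warning("volume smaller than the SSIM window; radius shrunk to ", radius)
  }
  if (is.null(data_range)) {
    data_range <- diff(range(c(a, b)))
    if (data_range == 0) data_range <- 1
  }
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  f <- function(x) gaussian_filter3(x, sigma, radius)
  ua <- f(a); ub <- f(b)
  uaa <- f(a * a); ubb <- f(b * b); uab <- f(a * b)
  va <- uaa - ua^2; vb <- ubb - ub^2; vab <- uab - ua * ub
  s <- ((2 * ua * ub + c1) * (2 * vab + c2)) /
    ((ua^2 + ub^2 + c1) * (va + vb + c2))
  core <- s[(radius + 1):(d[1] - radius),
            (radius + 1):(d[2] - radius),
            (radius + 1):(d[3] - radius), drop = FALSE]
  mean(core)
}

#' SSIM between two signal matrices
#'
#' 3-D [ssim_volume()] per wavevector volume, averaged over wavevectors.
#'
#' @param E,E_truth [signal_matrix()] objects of the same shape.
#' @param ... forwarded to [ssim_volume()].
#' @return scalar in [-1, 1].
#' @export
ssim <- function(E, E_truth, ...) {
  stopifnot(inherits(E, "signal_matrix"), inherits(E_truth, "signal_matrix"))
  if (!all(E$dims == E_truth$dims) || ncol(E$values) != ncol(E_truth$values))
    stop_side("inputs have different shapes",
              class = "sidedmri_dimension_error")
  vals <- vapply(seq_len(ncol(E$values)), function(q)
    ssim_volume(dw_volume(E, q), dw_volume(E_truth, q), ...), numeric(1))
  mean(vals)
}

#' Elementwise relative difference
#'
#' `|x - x_truth| / x_truth`, masked (NA) where the ground truth is at or
#' below `threshold`.
#'
#' @param x,x_truth numeric arrays of the same shape.
#' @param threshold truth values `<= threshold` are masked out.
#' @return array of the same shape with NA at masked positions.
#' @export
relative_difference <- function(x, x_truth, threshold = 1e-8) {
  stopifnot(identical(dim(x), dim(x_truth)) || length(x) == length(x_truth))
  out <- abs(x - x_truth) / x_truth
  out[x_truth <= threshold] <- NA_real_
  out
}

#' Fiber bundle overlap
#'
#' `1 - sum(|p - p_truth|) / sum(p_truth)` for two non-negative voxelwise
#' bundle-probability maps; 1 for identical maps, 0 for an all-zero
#' prediction, possibly negative for gross mismatch (reported as-is).
#'
#' @param p,p_truth non-negative arrays on the same grid.
#' @return scalar `<= 1`.
#' @export
fiber_bundle_overlap <- function(p, p_truth) {
  stopifnot(length(p) == length(p_truth))
  if (any(p < 0) || any(p_truth < 0))
    stop_side("probability maps must be non-negative")
  denom <- sum(p_truth)
  if (denom == 0) stop_side("ground-truth map is all zero")
  1 - sum(abs(p - p_truth)) / denom
}

#' Generalized fractional anisotropy
#'
#' Per voxel, `std(psi) / rms(psi)` over the fODF amplitudes sampled on a
#' symmetric tessellation, with the population (1/N) standard deviation;
#' 0 where the rms vanishes. Scale-invariant and 0 for an isotropic ODF.
#'
#' @param amplitudes N_F x N_Vox matrix (or a single N_F vector) of fODF
#'   amplitudes, e.g. from [fodf_amplitudes()].
#' @return numeric vector of length N_Vox in [0, 1].
#' @export
gfa <- function(amplitudes) {
  if (is.null(dim(amplitudes))) amplitudes <- matrix(amplitudes, ncol = 1)
  n <- nrow(amplitudes)
  mu <- colMeans(amplitudes)
  ms <- colMeans(amplitudes^2)
  varp <- pmax(ms - mu^2, 0)
  out <- numeric(ncol(amplitudes))
  nz <- ms > 0
  out[nz] <- sqrt(varp[nz] / ms[nz])
  out
}

#' Summary metric report
#'
#' NMSE, PSNR and SSIM between a reconstruction and ground truth, with an
#' optional per-shell breakdown when a gradient table is supplied.
#'
#' @param E,E_truth [signal_matrix()] objects.
#' @param gradients optional [gradient_table()] matching the columns.
#' @param mask optional logical voxel mask.
#' @return object of class `metric_report`: list with `nmse`, `psnr`,
#'   `ssim`, `per_shell` (data.frame) and the `mask` used.
#' @export
metric_report <- function(E, E_truth, gradients = NULL, mask = NULL) {
  rep <- list(nmse = nmse(E, E_truth, mask),
              psnr = as.numeric(psnr(E, E_truth, mask)),
              ssim = ssim(E, E_truth),
              mask = mask)
  per_shell <- NULL
  if (!is.null(gradients)) {
    sh <- shell_table(gradients)
    shell_of <- round(gradients$bvals[!gradients$b0_mask] / 25) * 25
    per_shell <- do.call(rbind, lapply(sh$b, function(b) {
      cols <- which(shell_of == b)
      es <- signal_matrix(E$values[, cols, drop = FALSE], E$dims)
      ts <- signal_matrix(E_truth$values[, cols, drop = FALSE], E_truth$dims)
      data.frame(b = b, n = length(cols), nmse = nmse(es, ts, mask),
                 psnr = as.numeric(psnr(es, ts, mask)))
    }))
  }
  rep$per_shell <- per_shell
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> NMSE ", format(x$nmse, digits = 5),
      " | PSNR ", format(x$psnr, digits = 5),
      " dB | SSIM ", format(x$ssim, digits = 5), "\n", sep = "")
  if (!is.null(x$per_shell)) {
    cat("  per shell:\n")
    print(x$per_shell, row.names = FALSE)
  }
  invisible(x)
}
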