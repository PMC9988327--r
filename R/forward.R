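#' Simulate a SIDE acquisition (forward model)
#'
#' Applies the slice/wavevector selectors of the SIDE schedule to a full
#' signal matrix: for every acquired (cycle, volume, slice group), the slices
#' of that group are copied from the wavevector column the schedule assigns,
#' with optional additive noise. Sampling is slice-level: within one
#' (slice, wavevector), either all in-plane voxels are observed or none, and
#' the acquired fraction is exactly `1 / r_side`.
#'
#' @param E a [signal_matrix()]; its z extent must equal the scheme's
#'   `n_slices`.
#' @param scheme a [plan_side()] result with `n_q == ncol(E$values)`.
#' @param noise_sigma standard deviation of the measurement noise added to
#'   observed attenuations (0 for noiseless).
#' @param seed optional integer seed making the noise reproducible.
#' @param noise `"gaussian"` (additive) or `"rician"` (magnitude of the
#'   complex Gaussian perturbation).
#' @return object of class `side_observation`: `values` (N_Vox x N_Q,
#'   zero where unobserved), `slice_mask` (N_z x N_Q logical), `dims`,
#'   `voxel_size`, and the `scheme`.
#' @export
acquire <- function(E, scheme, noise_sigma = 0, seed = NULL,
                    noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  stopifnot(inherits(E, "signal_matrix"), inherits(scheme, "side_scheme"))
  nz <- E$dims[3]
  if (nz != scheme$grouping$n_slices)
    stop_side("E has ", nz, " slices but the scheme expects ",
              scheme$grouping$n_slices, class = "sidedmri_dimension_error")
  if (ncol(E$values) != scheme$n_q)
    stop_side("E has ", ncol(E$values), " wavevectors but the scheme expects ",
              scheme$n_q, class = "sidedmri_dimension_error")
  slice_mask <- slice_sampling_mask(scheme)
  with_seed(seed, {
    vals <- E$values * expand_slice_mask(slice_mask, E$dims)
    if (noise_sigma > 0) {
      vox_mask <- expand_slice_mask(slice_mask, E$dims) > 0
      n_obs <- sum(vox_mask)
      if (noise == "gaussian") {
        vals[vox_mask] <- vals[vox_mask] + rnorm(n_obs, sd = noise_sigma)
      } else {
        vals[vox_mask] <- sqrt(
          (vals[vox_mask] + rnorm(n_obs, sd = noise_sigma))^2 +
            rnorm(n_obs, sd = noise_sigma)^2)
      }
    }
    new_side_observation(vals, slice_mask, E$dims, E$voxel_size, scheme)
  })
}

new_side_observation <- function(values, slice_mask, dims, voxel_size,
                                 scheme) {
  structure(list(values = values, slice_mask = slice_mask,
                 dims = as.integer(dims), voxel_size = voxel_size,
                 scheme = scheme),
            class = "side_observation")
}

#' @export
print.side_observation <- function(x, ...) {
  cat("<side_observation> ", paste(x$dims, collapse = " x "), " x ",
      ncol(x$values), ", acquired fraction ",
      format(mean(x$slice_mask), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Slice-level sampling mask of a SIDE scheme
#'
#' @param scheme a [plan_side()] result.
#' @return N_z x N_Q logical matrix: entry (l, q) is TRUE when slice l of
#'   wavevector q is acquired.
#' @export
slice_sampling_mask <- function(scheme) {
  g <- scheme$grouping
  m <- matrix(FALSE, g$n_slices, scheme$n_q)
  for (c0 in scheme$acquired_cycles) for (g0 in 0:(g$n_sg - 1L)) {
    qs <- scheme$assignment[c0 + 1L, , g0 + 1L]
    m[g$sg_slices[g0 + 1L, ] + 1L, qs + 1L] <- TRUE
  }
  m
}

# expand an N_z x N_Q slice mask to the N_Vox x N_Q voxel level (0/1)
expand_slice_mask <- function(slice_mask, dims) {
  per_slice <- dims[1] * dims[2]
  apply(slice_mask, 2, function(col) rep(as.numeric(col), each = per_slice))
}

#' Conventional (angular) undersampling observation
#'
#' Observation container for the comparator scheme: full volumes for the
#' selected wavevectors, nothing for the rest. Reconstructable with the same
#' solver as a SIDE observation.
#'
#' @param E a [signal_matrix()].
#' @param selected 1-based wavevector indices retained (e.g. from
#'   [plan_conventional()]).
#' @inheritParams acquire
#' @return a `side_observation` whose `scheme` field is a marker list of
#'   class `conventional_scheme`.
#' @export
acquire_conventional <- function(E, selected, noise_sigma = 0, seed = NULL,
                                 noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  stopifnot(inherits(E, "signal_matrix"))
  n_q <- ncol(E$values)
  stopifnot(all(selected >= 1), all(selected <= n_q))
  slice_mask <- matrix(FALSE, E$dims[3], n_q)
  slice_mask[, selected] <- TRUE
  with_seed(seed, {
    vals <- E$values
    vals[, -selected] <- 0
    if (noise_sigma > 0) {
      obs <- which(expand_slice_mask(slice_mask, E$dims) > 0)
      if (noise == "gaussian") {
        vals[obs] <- vals[obs] + rnorm(length(obs), sd = noise_sigma)
      } else {
        vals[obs] <- sqrt((vals[obs] + rnorm(length(obs), sd = noise_sigma))^2 +
                            rnorm(length(obs), sd = noise_sigma)^2)
      }
    }
    new_side_observation(vals, slice_mask, E$dims, E$voxel_size,
                         structure(list(type = "conventional",
                                        selected = as.integer(selected)),
                                   class = "conventional_scheme"))
  })
}

#' Adjoint of the acquisition operator (zero filling)
#'
#' Places every observed entry at its (voxel, wavevector) position and fills
#' unobserved entries with zero.
#'
#' @param obs a [acquire()] observation.
#' @return a [signal_matrix()].
#' @export
adjoint <- function(obs) {
  stopifnot(inherits(obs, "side_observation"))
  vals <- obs$values * expand_slice_mask(obs$slice_mask, obs$dims)
  suppressWarnings(signal_matrix(vals, obs$dims, voxel_size = obs$voxel_size))
}

#' Data-fidelity residual
#'
#' One half the sum of squared differences between a candidate signal matrix
#' and the observation, over acquired entries only; changes to `E` at
#' unacquired entries leave it untouched.
#'
#' @param E a [signal_matrix()].
#' @param obs a [acquire()] observation on the same grid.
#' @return scalar `0.5 * sum((E - obs)^2)` over the sampling mask.
#' @export
data_residual <- function(E, obs) {
  stopifnot(inherits(E, "signal_matrix"), inherits(obs, "side_observation"))
  if (!all(E$dims == obs$dims) || ncol(E$values) != ncol(obs$values))
    stop_side("E and observation dimensions differ",
              class = "sidedmri_dimension_error")
  m <- expand_slice_mask(obs$slice_mask, obs$dims) > 0
  0.5 * sum((E$values[m] - obs$values[m])^2)
}

#' Write / read an observation as NIfTI plus JSON sidecar
#'
#' The stack holds the acquired SIDE volumes with unacquired slices
#' zero-filled, mirroring how a scanner would emit SIDE data; the sidecar
#' records the slice mask and scheme parameters.
#'
#' @param obs a `side_observation`.
#' @param nifti_path,sidecar_path output paths.
#' @return `read_observation` returns the reconstructed `side_observation`.
#' @export
write_observation <- function(obs, nifti_path, sidecar_path) {
  arr <- array(obs$values * expand_slice_mask(obs$slice_mask, obs$dims),
               dim = c(obs$dims, ncol(obs$values)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(obs$voxel_size, 1)
  RNifti::writeNifti(img, nifti_path)
  sc <- if (inherits(obs$scheme, "side_scheme")) {
    list(type = "side", n_slices = obs$scheme$grouping$n_slices,
         r_sms = obs$scheme$grouping$r_sms, n_q = obs$scheme$n_q,
         r_side = obs$scheme$r_side)
  } else {
    list(type = "conventional", selected = obs$scheme$selected,
         n_q = ncol(obs$values))
  }
  jsonlite::write_json(list(scheme = sc, dims = obs$dims,
                            voxel_size = obs$voxel_size,
                            slice_mask = obs$slice_mask),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(obs)
}

#' @rdname write_observation
#' @export
read_observation <- function(nifti_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  img <- as.array(RNifti::readNifti(nifti_path))
  d <- dim(img)
  vals <- matrix(img, nrow = prod(d[1:3]), ncol = d[4])
  scheme <- if (identical(side$scheme$type, "side")) {
    plan_side(make_grouping(side$scheme$n_slices, side$scheme$r_sms),
              side$scheme$n_q, side$scheme$r_side)
  } else {
    structure(list(type = "conventional",
                   selected = as.integer(side$scheme$selected)),
              class = "conventional_scheme")
  }
  new_side_observation(vals, matrix(side$slice_mask, d[3], d[4]),
                       d[1:3], side$voxel_size, scheme)
}
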