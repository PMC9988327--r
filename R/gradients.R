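#' Gradient table for a multi-shell diffusion acquisition
#'
#' A gradient table holds, per wavevector, a unit encoding direction, a
#' diffusion weighting (b-value, s/mm^2) and a flag marking non-diffusion-
#' weighted (b0) measurements. Directions of non-b0 entries are renormalized
#' to unit Euclidean norm; b0 entries may carry a zero direction.
#'
#' @param directions numeric matrix with one row per wavevector and 3 columns,
#'   or a 3-column-compatible object coercible to one.
#' @param bvals numeric vector of b-values (s/mm^2), one per wavevector.
#' @param b0_threshold b-values strictly below this are treated as b0
#'   (default 10 s/mm^2).
#' @param delta_big,delta_small optional pulse timings (s): the separation of
#'   the two gradient-pulse onsets and the pulse duration.
#' @return An object of class `gradient_table` with fields `directions`,
#'   `bvals`, `b0_mask`, `b0_threshold`, `delta_big`, `delta_small`.
#' @export
gradient_table <- function(directions, bvals, b0_threshold = 10,
                           delta_big = NULL, delta_small = NULL) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop_side("directions must have 3 columns, got ", ncol(directions))
  bvals <- as.numeric(bvals)
  n <- length(bvals)
  if (n < 1L) stop_side("a gradient table needs at least one wavevector")
  if (nrow(directions) != n)
    stop_side("bvals has length ", n, " but directions has ",
              nrow(directions), " rows", class = "sidedmri_format_error")
  if (any(!is.finite(bvals)) || any(!is.finite(directions)))
    stop_side("non-finite entries in gradient table")
  if (any(bvals < 0)) stop_side("b-values must be non-negative")
  b0_mask <- bvals < b0_threshold
  nrm <- sqrt(rowSums(directions^2))
  if (any(!b0_mask & nrm < 1e-8))
    stop_side("zero-norm direction for a diffusion-weighted (b = ",
              paste(unique(bvals[!b0_mask & nrm < 1e-8]), collapse = ", "),
              ") wavevector")
  directions <- unit_rows(directions)
  structure(
    list(directions = directions, bvals = bvals, b0_mask = b0_mask,
         b0_threshold = b0_threshold,
         delta_big = delta_big, delta_small = delta_small),
    class = "gradient_table"
  )
}

#' @export
print.gradient_table <- function(x, ...) {
  sh <- shell_table(x)
  cat("<gradient_table> ", length(x$bvals), " wavevectors (",
      sum(x$b0_mask), " b0)\n", sep = "")
  if (nrow(sh))
    cat("  shells: ",
        paste0("b=", sh$b, " (n=", sh$n, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shell structure of a gradient table
#'
#' Groups non-b0 wavevectors into shells by rounded b-value.
#'
#' @param gtab a [gradient_table()].
#' @param tol b-values within `tol` of each other belong to one shell.
#' @return data.frame with columns `b` (shell b-value) and `n` (directions).
#' @export
shell_table <- function(gtab, tol = 25) {
  b <- gtab$bvals[!gtab$b0_mask]
  if (!length(b)) return(data.frame(b = numeric(0), n = integer(0)))
  shell <- round(b / tol) * tol
  tab <- table(shell)
  data.frame(b = as.numeric(names(tab)), n = as.integer(tab))
}

#' Read an FSL-dialect bvals/bvecs pair
#'
#' `bvals` is a whitespace-separated row of N numbers; `bvecs` is 3 x N
#' (FSL layout) or N x 3, disambiguated by shape. A 3 x 3 file is read as
#' 3 x N with a warning.
#'
#' @param bvals_path,bvecs_path paths to the two text files.
#' @inheritParams gradient_table
#' @return a validated [gradient_table()].
#' @export
read_gradient_table <- function(bvals_path, bvecs_path, b0_threshold = 10) {
  parse_nums <- function(path) {
    if (!file.exists(path))
      stop_side("file not found: ", path, class = "sidedmri_config_error")
    toks <- scan(path, what = character(), quiet = TRUE)
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals)))
      stop_side("non-numeric token '", toks[which(is.na(vals))[1]],
                "' in ", path, class = "sidedmri_parse_error")
    vals
  }
  bvals <- parse_nums(bvals_path)
  lines <- readLines(bvecs_path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  if (any(vapply(rows, function(r) any(is.na(r)), logical(1))))
    stop_side("non-numeric token in ", bvecs_path,
              class = "sidedmri_parse_error")
  nr <- length(rows)
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop_side("ragged rows in ", bvecs_path, class = "sidedmri_format_error")
  m <- do.call(rbind, rows)
  n <- length(bvals)
  if (nr == 3L && ncol(m) == 3L && n == 3L) {
    warning("bvecs file is 3 x 3; interpreting as FSL 3 x N layout")
    dirs <- t(m)
  } else if (nr == 3L && ncol(m) == n) {
    dirs <- t(m)                       # FSL 3 x N
  } else if (ncol(m) == 3L && nr == n) {
    dirs <- m                          # N x 3
  } else {
    stop_side("bvecs shape ", nr, " x ", ncol(m),
              " does not match ", n, " b-values",
              class = "sidedmri_format_error")
  }
  gradient_table(dirs, bvals, b0_threshold = b0_threshold)
}

#' Write a gradient table as FSL bvals/bvecs
#'
#' @param gtab a [gradient_table()].
#' @param bvals_path,bvecs_path output paths; bvecs written 3 x N.
#' @export
write_gradient_table <- function(gtab, bvals_path, bvecs_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  v <- t(gtab$directions)
  writeLines(apply(v, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvecs_path)
  invisible(gtab)
}

#' Voxel-by-wavevector signal attenuation matrix
#'
#' The reconstruction target: an N_Vox x N_Q matrix of attenuations
#' S(q)/S0 with the spatial grid attached. Column q, reshaped to
#' N_x x N_y x N_z, is the diffusion-weighted volume for wavevector q. The
#' slice axis is the third spatial axis.
#'
#' @param values numeric N_Vox x N_Q matrix.
#' @param dims integer triplet (N_x, N_y, N_z); their product must equal
#'   `nrow(values)`.
#' @param voxel_size mm triplet.
#' @param valid optional logical N_Vox vector marking voxels with usable
#'   normalization (default all TRUE).
#' @return object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, dims, voxel_size = c(1, 1, 1),
                          valid = NULL) {
  values <- as.matrix(values)
  dims <- as.integer(dims)
  if (length(dims) != 3L) stop_side("dims must be a length-3 triplet")
  if (prod(dims) != nrow(values))
    stop_side("prod(dims) = ", prod(dims), " does not match nrow(values) = ",
              nrow(values), class = "sidedmri_dimension_error")
  if (any(!is.finite(values))) stop_side("signal values must be finite")
  if (any(values > 1.5))
    warning("attenuation values above 1.5 present (max = ",
            format(max(values), digits = 4),
            "); expected S(q)/S0 in [0, 1] plus noise")
  valid <- valid %||% rep(TRUE, nrow(values))
  structure(list(values = values, dims = dims,
                 voxel_size = as.numeric(voxel_size), valid = valid),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", paste(x$dims, collapse = " x "), " voxels, ",
      ncol(x$values), " wavevectors\n", sep = "")
  invisible(x)
}

#' Extract one diffusion-weighted volume
#'
#' @param E a [signal_matrix()].
#' @param q wavevector (column) index, 1-based.
#' @return N_x x N_y x N_z array.
#' @export
dw_volume <- function(E, q) as_volume(E$values[, q], E$dims)

#' Read a 4-D diffusion-weighted NIfTI stack
#'
#' With a gradient table, the 4th dimension must equal the table length;
#' b0 volumes are averaged into S0, the remaining volumes are divided by S0
#' to give attenuations, and b0 columns are dropped from the result. Voxels
#' with S0 <= 0 are masked out (attenuation set to 0, recorded in `valid`).
#' Without a gradient table the stack is taken to already hold attenuations.
#'
#' @param nifti_path path to a 4-D NIfTI-1 file.
#' @param gradients optional [gradient_table()] covering all volumes
#'   (b0 included).
#' @return a [signal_matrix()]; when normalized, with attribute `gradients`
#'   holding the b0-free gradient table.
#' @export
read_dwi <- function(nifti_path, gradients = NULL) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop_side("expected a 4-D stack, got ", length(dim(arr)), " dimensions",
              class = "sidedmri_dimension_error")
  d <- dim(arr)
  vox <- RNifti::pixdim(img)[1:3]
  flat <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
  if (is.null(gradients))
    return(signal_matrix(flat, d[1:3], voxel_size = vox))
  if (d[4] != length(gradients$bvals))
    stop_side("4th dimension is ", d[4], " but gradient table has ",
              length(gradients$bvals), " wavevectors",
              class = "sidedmri_dimension_error")
  b0 <- gradients$b0_mask
  if (!any(b0)) stop_side("gradient table has no b0 volume to normalize by")
  s0 <- rowMeans(flat[, b0, drop = FALSE])
  valid <- s0 > 0
  e <- flat[, !b0, drop = FALSE]
  e[valid, ] <- e[valid, , drop = FALSE] / s0[valid]
  e[!valid, ] <- 0
  out <- signal_matrix(e, d[1:3], voxel_size = vox, valid = valid)
  attr(out, "gradients") <- gradient_table(
    gradients$directions[!b0, , drop = FALSE], gradients$bvals[!b0],
    b0_threshold = gradients$b0_threshold,
    delta_big = gradients$delta_big, delta_small = gradients$delta_small)
  out
}

#' Write a signal matrix as a 4-D NIfTI stack
#'
#' @param E a [signal_matrix()].
#' @param nifti_path output path (`.nii` or `.nii.gz`).
#' @export
write_dwi <- function(E, nifti_path) {
  arr <- array(E$values, dim = c(E$dims, ncol(E$values)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(E$voxel_size, 1)
  RNifti::writeNifti(img, nifti_path)
  invisible(E)
}
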