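#' Slice grouping for simultaneous multi-slice excitation
#'
#' Partitions `n_slices` slices into `n_sg = n_slices / r_sms` slice groups
#' of `r_sms` slices each. Group g (0-based) contains the evenly spaced
#' slices `{g, g + n_sg, g + 2 n_sg, ...}`, i.e. one slice from each of the
#' r_sms bands of the volume, matching how an SMS excitation spreads its
#' slices across the head.
#'
#' @param n_slices number of slices along the slice-encoding (z) axis.
#' @param r_sms SMS factor (slices excited simultaneously); must divide
#'   `n_slices`.
#' @return object of class `slice_grouping` with fields `n_slices`, `r_sms`,
#'   `n_sg` and `sg_slices`, an `n_sg` x `r_sms` integer matrix of 0-based
#'   slice indices (row g+1 lists the slices of group g).
#' @export
make_grouping <- function(n_slices, r_sms) {
  if (!is_count(n_slices) || !is_count(r_sms))
    stop_side("n_slices and r_sms must be positive integers")
  if (n_slices %% r_sms != 0)
    stop_side("r_sms = ", r_sms, " does not divide n_slices = ", n_slices,
              class = "sidedmri_scheme_error")
  n_sg <- n_slices %/% r_sms
  sg <- outer(seq_len(n_sg) - 1L, (seq_len(r_sms) - 1L) * n_sg, `+`)
  structure(list(n_slices = as.integer(n_slices), r_sms = as.integer(r_sms),
                 n_sg = as.integer(n_sg), sg_slices = sg),
            class = "slice_grouping")
}

#' @export
print.slice_grouping <- function(x, ...) {
  cat("<slice_grouping> ", x$n_slices, " slices, SMS ", x$r_sms,
      " -> ", x$n_sg, " slice groups\n", sep = "")
  invisible(x)
}

#' Plan a slice-interleaved diffusion encoding (SIDE) schedule
#'
#' In SIDE each acquired volume interleaves `n_sg` slice groups, each
#' carrying a different wavevector, so `n_q / n_sg` volumes (one *cycle*)
#' cover all wavevectors with one slice group per wavevector. From cycle to
#' cycle the wavevector-to-group assignment is shifted by one group, so that
#' `n_sg` cycles cover every (wavevector, slice group) pair exactly once.
#' Undersampling by `r_side` keeps an evenly spaced subset of
#' `n_sg / r_side` cycles, starting at cycle 0.
#'
#' The assignment rule is `q(c, m, g) = m * n_sg + ((g + c) mod n_sg)` with
#' 0-based cycle `c`, within-cycle volume `m` and slice group `g`.
#'
#' @param grouping a [make_grouping()] result.
#' @param n_q number of wavevectors; must be a multiple of `grouping$n_sg`.
#' @param r_side SIDE undersampling factor; must divide `grouping$n_sg`.
#' @return object of class `side_scheme` with the grouping, counts, the
#'   0-based `assignment` array (cycle x volume x group -> wavevector) and
#'   the 0-based `acquired_cycles`.
#' @export
plan_side <- function(grouping, n_q, r_side = 1) {
  stopifnot(inherits(grouping, "slice_grouping"))
  if (!is_count(n_q) || !is_count(r_side))
    stop_side("n_q and r_side must be positive integers")
  n_sg <- grouping$n_sg
  if (n_q %% n_sg != 0)
    stop_side("n_sg = ", n_sg, " does not divide n_q = ", n_q,
              class = "sidedmri_scheme_error")
  if (n_sg %% r_side != 0)
    stop_side("r_side = ", r_side, " does not divide n_sg = ", n_sg,
              class = "sidedmri_scheme_error")
  vpc <- n_q %/% n_sg
  assignment <- array(0L, dim = c(n_sg, vpc, n_sg))
  for (c0 in 0:(n_sg - 1L)) for (g0 in 0:(n_sg - 1L))
    assignment[c0 + 1L, , g0 + 1L] <-
      (seq_len(vpc) - 1L) * n_sg + (g0 + c0) %% n_sg
  structure(list(grouping = grouping, n_q = as.integer(n_q),
                 volumes_per_cycle = as.integer(vpc),
                 n_cycles_total = n_sg,
                 assignment = assignment,
                 acquired_cycles = as.integer(seq(0L, n_sg - 1L, by = r_side)),
                 r_side = as.integer(r_side)),
            class = "side_scheme")
}

#' @export
print.side_scheme <- function(x, ...) {
  cat("<side_scheme> N_Q = ", x$n_q, ", N_SG = ", x$grouping$n_sg,
      ", ", x$volumes_per_cycle, " volumes/cycle, R_SIDE = ", x$r_side,
      " (", length(x$acquired_cycles), "/", x$n_cycles_total,
      " cycles acquired), total acceleration ", total_acceleration(x),
      "\n", sep = "")
  invisible(x)
}

#' Long-format view of a SIDE schedule
#'
#' @param scheme a [plan_side()] result.
#' @param acquired_only keep only acquired cycles.
#' @return data.frame with 0-based columns `cycle`, `volume`, `slice_group`,
#'   `wavevector`.
#' @export
scheme_assignment <- function(scheme, acquired_only = FALSE) {
  d <- dim(scheme$assignment)
  grid <- expand.grid(cycle = 0:(d[1] - 1L), volume = 0:(d[2] - 1L),
                      slice_group = 0:(d[3] - 1L))
  grid$wavevector <- as.vector(scheme$assignment)
  if (acquired_only) grid <- grid[grid$cycle %in% scheme$acquired_cycles, ]
  grid[order(grid$cycle, grid$volume, grid$slice_group), ]
}

#' Total undersampling factor of a SIDE scheme
#'
#' The SMS and SIDE accelerations multiply: a scan accelerated by SMS factor
#' R_SMS and SIDE factor R_SIDE is R_SMS * R_SIDE-fold faster than an
#' unaccelerated single-slice acquisition.
#'
#' @param scheme a [plan_side()] result.
#' @return `r_sms * r_side`.
#' @export
total_acceleration <- function(scheme) {
  stopifnot(inherits(scheme, "side_scheme"))
  scheme$grouping$r_sms * scheme$r_side
}

#' Conventional (angular) undersampling comparator
#'
#' The conventional way to cut acquisition time by a factor `r` is to acquire
#' full volumes for only `total / r` of the wavevectors. Directions are
#' allocated per shell proportionally (largest-remainder rounding, remainder
#' ties resolved toward larger shells) and, within each shell, chosen to
#' maximize angular spread by greedy farthest-point selection when directions
#' are supplied (otherwise evenly strided).
#'
#' @param shell_sizes integer vector of per-shell direction counts.
#' @param r undersampling factor; must divide `sum(shell_sizes)`.
#' @param directions optional matrix of unit directions for all
#'   `sum(shell_sizes)` wavevectors, in shell order, used for the
#'   farthest-point selection.
#' @return sorted 1-based indices (into the concatenated shells) of the
#'   retained wavevectors, with attribute `per_shell` giving the allocation.
#' @export
plan_conventional <- function(shell_sizes, r, directions = NULL) {
  shell_sizes <- as.integer(shell_sizes)
  if (!is_count(r)) stop_side("r must be a positive integer")
  total <- sum(shell_sizes)
  if (total %% r != 0)
    stop_side("r = ", r, " does not divide the total direction count ", total,
              class = "sidedmri_scheme_error")
  keep_total <- total %/% r
  quota <- shell_sizes / r
  keep <- floor(quota)
  rem <- keep_total - sum(keep)
  if (rem > 0) {
    frac <- quota - keep
    # largest remainder first; ties toward larger shells
    ord <- order(-frac, -shell_sizes)
    keep[ord[seq_len(rem)]] <- keep[ord[seq_len(rem)]] + 1L
  }
  offs <- cumsum(c(0L, shell_sizes[-length(shell_sizes)]))
  sel <- integer(0)
  for (s in seq_along(shell_sizes)) {
    n_s <- shell_sizes[s]; k <- keep[s]
    if (k == 0L) next
    idx <- if (is.null(directions)) {
      round(seq(1, n_s, length.out = k))
    } else {
      v <- directions[offs[s] + seq_len(n_s), , drop = FALSE]
      farthest_point_subset(v, k)
    }
    sel <- c(sel, offs[s] + idx)
  }
  structure(sort(as.integer(sel)), per_shell = as.integer(keep))
}

# greedy farthest-point subset on the sphere (antipodally symmetric metric)
farthest_point_subset <- function(v, k) {
  n <- nrow(v)
  if (k >= n) return(seq_len(n))
  # angular proximity: |v_i . v_j| (directions are axes)
  d <- abs(v %*% t(v))
  picked <- 1L                            # deterministic start
  prox <- d[, 1L]
  while (length(picked) < k) {
    cand <- setdiff(seq_len(n), picked)
    nxt <- cand[which.min(prox[cand])]
    picked <- c(picked, nxt)
    prox <- pmax(prox, d[, nxt])
  }
  sort(picked)
}

#' Serialize / deserialize a SIDE scheme as JSON
#'
#' @param scheme a [plan_side()] result.
#' @param path output (input) path.
#' @return `read_scheme` returns the reconstructed `side_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(
    n_slices = scheme$grouping$n_slices, r_sms = scheme$grouping$r_sms,
    n_sg = scheme$grouping$n_sg, n_q = scheme$n_q, r_side = scheme$r_side,
    acquired_cycles = scheme$acquired_cycles,
    sg_slices = scheme$grouping$sg_slices,
    assignment = scheme_assignment(scheme)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(scheme)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grouping <- make_grouping(obj$n_slices, obj$r_sms)
  scheme <- plan_side(grouping, obj$n_q, obj$r_side)
  # sanity: the file's explicit table must match the regenerated schedule
  tab <- scheme_assignment(scheme)
  if (!isTRUE(all.equal(as.data.frame(obj$assignment)[names(tab)], tab,
                        check.attributes = FALSE)))
    stop_side("scheme file assignment table does not match its parameters",
              class = "sidedmri_format_error")
  scheme
}
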