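#' @keywords internal
"_PACKAGE"

# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_side <- function(..., class = "sidedmri_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

# rows of `m` scaled to unit Euclidean norm; zero rows left untouched
unit_rows <- function(m, tol = 1e-12) {
  nrm <- sqrt(rowSums(m^2))
  keep <- nrm > tol
  m[keep, ] <- m[keep, , drop = FALSE] / nrm[keep]
  m
}

# reshape one column of an N_Vox x N_Q matrix into an N_x x N_y x N_z array
as_volume <- function(values, dims) array(values, dim = dims)

# local RNG: run `expr` under a seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
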