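# shared fixtures, all generated in code

# small phantom for fast solver tests: 8 x 8 x 6, N_Q = 12
tiny_phantom <- function(noise_sigma = 0) {
  dims <- c(8L, 8L, 8L)
  coords <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                        z = seq_len(dims[3]))
  band <- array(coords$y >= 3 & coords$y <= 6, dims)
  fib <- data.frame(vx = 1, vy = 0, vz = 0, fraction = 0.8,
                    d_l = 1.7e-3, d_t = 0.4e-3)
  regions <- list(
    list(mask = band, fibers = fib,
         iso = list(fraction = 0.2, d_iso = 3.0e-3)),
    list(mask = !band, fibers = fib[0, ],
         iso = list(fraction = 1, d_iso = 1.5e-3)))
  phantom_spec(dims, regions,
               shells = list(c(b = 1000, n = 6), c(b = 2000, n = 6)),
               noise_sigma = noise_sigma, seed = 77L)
}

# write a bvals/bvecs pair from explicit vectors; returns the two paths
write_grad_files <- function(bvals, bvecs_rows, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  bp <- file.path(dir, "test.bval"); vp <- file.path(dir, "test.bvec")
  writeLines(paste(bvals, collapse = " "), bp)
  writeLines(vapply(bvecs_rows, function(r) paste(r, collapse = " "),
                    character(1)), vp)
  list(bvals = bp, bvecs = vp)
}

# random signal matrix on a grid
random_signal <- function(dims, n_q, seed = 1) {
  set.seed(seed)
  suppressWarnings(signal_matrix(
    matrix(runif(prod(dims) * n_q), prod(dims), n_q), dims))
}

# plain subgradient-descent oracle for the TV prox objective
tv_prox_oracle <- function(x, w, strength, iters = 1e5) {
  obj <- function(u) 0.5 * sum((u - x)^2) + strength * tv_seminorm(u, w)
  tv_subgrad <- function(u) {
    g <- sidedmri:::tv_grad(u, w)
    nrm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
    nrm[nrm < 1e-12] <- 1
    sidedmri:::tv_grad_adjoint(
      list(g[[1]] / nrm, g[[2]] / nrm, g[[3]] / nrm), w)
  }
  u <- x
  best <- obj(u)
  # the 0.5||u - x||^2 term makes the objective strongly convex, so a
  # geometrically decaying step converges far better than the classic
  # 1/sqrt(k) schedule while remaining a plain subgradient iteration
  for (k in seq_len(iters)) {
    u <- u - (0.1 * 0.99985^k) * ((u - x) + strength * tv_subgrad(u))
    ok <- obj(u)
    if (ok < best) best <- ok
  }
  best
}

# row-normalize to unit vectors (test-local copy)
unit_rows <- function(m) m / sqrt(rowSums(m^2))
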