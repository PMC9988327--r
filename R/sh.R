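#' Real even-order spherical-harmonic basis
#'
#' Evaluates the real, antipodally symmetric spherical harmonics of all even
#' orders up to `sh_order` at a set of unit directions. The basis is
#' orthonormal on the sphere; ordering is l ascending and, within l, m from
#' -l to l. Sine harmonics carry m < 0, cosine harmonics m > 0, and the
#' first column (l = 0) is the constant 1/sqrt(4 pi).
#'
#' @param tessellation N_F x 3 matrix of unit vectors.
#' @param sh_order even maximum order (>= 0).
#' @return N_F x P matrix, P = (sh_order+1)(sh_order+2)/2.
#' @export
sh_basis <- function(tessellation, sh_order) {
  if (!is.numeric(sh_order) || length(sh_order) != 1L || sh_order < 0 ||
      sh_order %% 2 != 0)
    stop_side("sh_order must be an even non-negative integer")
  v <- as.matrix(tessellation)
  if (ncol(v) != 3L) stop_side("tessellation must be N x 3")
  v <- unit_rows(v)
  n <- nrow(v)
  theta_cos <- pmin(pmax(v[, 3], -1), 1)      # cos(theta) = z
  phi <- atan2(v[, 2], v[, 1])
  p_count <- (sh_order + 1) * (sh_order + 2) / 2
  out <- matrix(0, n, p_count)
  col <- 1L
  for (l in seq(0, sh_order, by = 2)) {
    # associated Legendre P_l^m(cos theta), m = 0..l (Condon-Shortley phase)
    plm <- pracma::legendre(l, theta_cos)     # (l+1) x n
    if (l == 0) plm <- matrix(plm, 1, n)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrm * plm[am + 1L, ]
      out[, col] <- if (m < 0) sqrt(2) * base * sin(am * phi)
                    else if (m == 0) base
                    else sqrt(2) * base * cos(am * phi)
      col <- col + 1L
    }
  }
  out
}

#' Hemisphere tessellation from a subdivided icosahedron
#'
#' Vertices of an icosahedron subdivided `subdiv` times by edge midpoints and
#' projected to the unit sphere, reduced to one representative per antipodal
#' pair. The default (3 subdivisions) yields 321 directions, which samples
#' order-8 spherical harmonics comfortably.
#'
#' @param subdiv number of binary subdivisions (default 3).
#' @return N_F x 3 matrix of unit vectors with non-negative z (ties broken
#'   toward positive x, then positive y).
#' @export
hemisphere_tessellation <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- unit_rows(verts)
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdiv)) {
    key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mid_cache <- new.env()
    vlist <- lapply(seq_len(nrow(verts)), function(j) verts[j, ])
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      m <- vlist[[a]] + vlist[[b]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      mid_cache[[k]] <- length(vlist)
      length(vlist)
    }
    newf <- matrix(0L, 4 * nrow(faces), 3)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c3 <- faces[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[4 * f - 3, ] <- c(a, ab, ca)
      newf[4 * f - 2, ] <- c(b, bc, ab)
      newf[4 * f - 1, ] <- c(c3, ca, bc)
      newf[4 * f, ]     <- c(ab, bc, ca)
    }
    verts <- do.call(rbind, vlist)
    faces <- newf
  }
  eps <- 1e-9
  upper <- verts[, 3] > eps |
    (abs(verts[, 3]) <= eps & (verts[, 1] > eps |
       (abs(verts[, 1]) <= eps & verts[, 2] > eps)))
  v <- verts[upper, , drop = FALSE]
  v[order(v[, 3], v[, 2], v[, 1]), ]
}
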