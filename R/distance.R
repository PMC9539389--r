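# Exact Euclidean distance transform, computed by the separable
# lower-envelope-of-parabolas algorithm on squared distances.

# 1D squared-distance transform at sample positions x (strictly increasing).
dt1d <- function(f, x) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- fin[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  if (length(fin) > 1L) {
    for (q in fin[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
        if (k > 1L && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

# Apply dt1d along one margin of a 3D array of squared distances.
dt_pass <- function(sq, margin, spacing) {
  d <- dim(sq)
  perm <- switch(margin, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  a <- aperm(sq, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1L])
  x <- seq_len(da[1L]) * spacing
  for (j in seq_len(ncol(m))) m[, j] <- dt1d(m[, j], x)
  a <- array(m, dim = da)
  aperm(a, order(perm))
}

#' Euclidean distance transform from a voxel source set
#'
#' Exact centre-to-centre Euclidean distance from every voxel to the
#' nearest source voxel, honouring anisotropic voxel spacing.
#'
#' @param source logical 3D array marking source voxels (distance 0).
#' @param pixdim numeric length-3 voxel spacing (default 1 mm isotropic).
#' @return Numeric 3D array of distances; `Inf` if `source` is empty.
#' @export
distance_transform <- function(source, pixdim = c(1, 1, 1)) {
  assert_volume(source)
  sq <- array(ifelse(source, 0, Inf), dim = dim(source))
  for (margin in 1:3) sq <- dt_pass(sq, margin, pixdim[margin])
  sqrt(sq)
}
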