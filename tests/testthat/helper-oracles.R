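# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use direct per-voxel neighbourhood scans and naive
# formulas, not the package's shift-based / separable algorithms.

options(lesionmtr.verbose = FALSE)

oracle_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
          c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# Neighbour linear indices for every voxel: n x k matrix, NA outside grid.
# Memoised per (grid, connectivity) since oracle loops reuse it heavily.
.oracle_nb_cache <- new.env(parent = emptyenv())
oracle_neighbour_matrix <- function(d, connectivity) {
  key <- paste(c(d, connectivity), collapse = "_")
  if (!is.null(.oracle_nb_cache[[key]])) return(.oracle_nb_cache[[key]])
  out <- oracle_neighbour_matrix_build(d, connectivity)
  .oracle_nb_cache[[key]] <- out
  out
}

oracle_neighbour_matrix_build <- function(d, connectivity) {
  off <- oracle_offsets(connectivity)
  co <- arrayInd(seq_len(prod(d)), d)
  out <- matrix(NA_integer_, nrow = prod(d), ncol = nrow(off))
  for (j in seq_len(nrow(off))) {
    n1 <- co[, 1] + off[j, 1]; n2 <- co[, 2] + off[j, 2]; n3 <- co[, 3] + off[j, 3]
    ok <- n1 >= 1 & n1 <= d[1] & n2 >= 1 & n2 <= d[2] & n3 >= 1 & n3 <= d[3]
    out[ok, j] <- n1[ok] + (n2[ok] - 1) * d[1] + (n3[ok] - 1) * d[1] * d[2]
  }
  out
}

# Erosion: voxel survives iff in mask and every structuring-element
# neighbour is inside the grid and in the mask.
oracle_erode <- function(mask, connectivity) {
  d <- dim(mask)
  nb <- oracle_neighbour_matrix(d, connectivity)
  out <- array(FALSE, dim = d)
  for (v in which(mask)) {
    n <- nb[v, ]
    out[v] <- !anyNA(n) && all(mask[n])
  }
  out
}

oracle_dilate <- function(mask, connectivity) {
  d <- dim(mask)
  nb <- oracle_neighbour_matrix(d, connectivity)
  out <- mask
  for (v in which(mask)) {
    n <- nb[v, ]
    out[n[!is.na(n)]] <- TRUE
  }
  out
}

# Stack-based flood fill, one seed at a time, seeds in linear-index order.
oracle_components <- function(mask, connectivity) {
  d <- dim(mask)
  nb <- oracle_neighbour_matrix(d, connectivity)
  lab <- array(0L, dim = d)
  nid <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    nid <- nid + 1L
    stack <- seed
    lab[seed] <- nid
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (n in nb[v, ]) {
        if (!is.na(n) && mask[n] && lab[n] == 0L) {
          lab[n] <- nid
          stack <- c(stack, n)
        }
      }
    }
  }
  attr(lab, "n") <- nid
  lab
}

# Cuffs by repeated oracle dilation with the stated exclusion rule.
oracle_cuffs <- function(labels, atlas, connectivity) {
  d <- dim(labels)
  n <- max(labels)
  lesion_any <- labels > 0
  eligible <- !lesion_any & !(array(atlas %in% c(1L, 2L), dim = d))
  claims <- array(0L, dim = d)
  per <- vector("list", n)
  for (id in seq_len(n)) {
    m0 <- labels == id
    d1 <- oracle_dilate(m0, connectivity)
    d2 <- oracle_dilate(d1, connectivity)
    d3 <- oracle_dilate(d2, connectivity)
    rings <- list(which(d1 & !m0 & eligible),
                  which(d2 & !d1 & eligible),
                  which(d3 & !d2 & eligible))
    for (r in 1:3) claims[rings[[r]]] <- claims[rings[[r]]] + 1L
    per[[id]] <- rings
  }
  owner <- array(0L, dim = d)
  ring <- array(0L, dim = d)
  for (id in seq_len(n)) {
    for (r in 1:3) {
      keep <- per[[id]][[r]][claims[per[[id]][[r]]] < 2L]
      owner[keep] <- id
      ring[keep] <- r
    }
  }
  list(owner = owner, ring = ring, excluded = claims >= 2L)
}

# All-pairs minimum Euclidean distance to the source set.
oracle_edt <- function(source, pixdim = c(1, 1, 1)) {
  d <- dim(source)
  src <- arrayInd(which(source), d)
  out <- array(Inf, dim = d)
  if (nrow(src) == 0) return(out)
  co <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(prod(d))) {
    dx <- (co[v, 1] - src[, 1]) * pixdim[1]
    dy <- (co[v, 2] - src[, 2]) * pixdim[2]
    dz <- (co[v, 3] - src[, 3]) * pixdim[3]
    out[v] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  out
}

# Sort-based type-7 quantile, written from the order-statistic definition.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, 1.0)
}

# OLS via the normal equations, independent of lm().
oracle_ols <- function(y, X) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# Random sparse 3D mask.
random_mask <- function(d, density = 0.1) {
  array(stats::runif(prod(d)) < density, dim = d)
}
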