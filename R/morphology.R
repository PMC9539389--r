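# 3D binary-mask morphology: erosion, dilation and connected-component
# labelling under 6- (face) or 26- (face/edge/corner) connectivity.
# Voxels outside the grid count as background for both operators.

conn_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    matrix(c(-1L, 0L, 0L, 1L, 0L, 0L,
             0L, -1L, 0L, 0L, 1L, 0L,
             0L, 0L, -1L, 0L, 0L, 1L),
           ncol = 3L, byrow = TRUE)
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    dimnames(g) <- NULL
    g[rowSums(abs(g)) > 0L, , drop = FALSE]
  } else {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
}

# out[v] = mask[v + off], with FALSE outside the grid
shift_mask <- function(mask, off) {
  d <- dim(mask)
  if (any(d - abs(off) <= 0L)) return(array(FALSE, dim = d))
  dst <- src <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0L) {
      dst[[k]] <- seq_len(d[k] - o)
      src[[k]] <- seq_len(d[k] - o) + o
    } else {
      dst[[k]] <- seq_len(d[k] + o) - o
      src[[k]] <- seq_len(d[k] + o)
    }
  }
  out <- array(FALSE, dim = d)
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- mask[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Morphological erosion and dilation of a 3D binary mask
#'
#' One-voxel-layer operations with the structuring element implied by the
#' connectivity: the 6-connected cross (faces only, the default) or the full
#' 26-connected 3x3x3 cube. Voxels outside the grid are background, so
#' erosion removes mask voxels touching the grid boundary.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return Logical 3D array of the same shape.
#' @export
erode_mask <- function(mask, connectivity = 6L) {
  assert_volume(mask)
  out <- mask
  off <- conn_offsets(connectivity)
  for (j in seq_len(nrow(off))) {
    out <- out & shift_mask(mask, off[j, ])
    if (!any(out)) break
  }
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, connectivity = 6L) {
  assert_volume(mask)
  out <- mask
  off <- conn_offsets(connectivity)
  for (j in seq_len(nrow(off))) out <- out | shift_mask(mask, off[j, ])
  out
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first labelling of maximal connected components. Component ids
#' are assigned in order of each component's first voxel in raster
#' (column-major linear index) order, so labelling is deterministic.
#'
#' @inheritParams erode_mask
#' @return Integer 3D array: 0 outside the mask, component id inside.
#'   Attribute `n` holds the number of components.
#' @export
label_components <- function(mask, connectivity = 6L) {
  assert_volume(mask)
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) {
    attr(labels, "n") <- 0L
    return(labels)
  }
  off <- conn_offsets(connectivity)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  next_id <- 0L
  for (s in idx) {
    if (labels[s] != 0L) next
    next_id <- next_id + 1L
    labels[s] <- next_id
    frontier <- s
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      nb <- integer(0)
      for (j in seq_len(nrow(off))) {
        nc1 <- fc[, 1L] + off[j, 1L]
        nc2 <- fc[, 2L] + off[j, 2L]
        nc3 <- fc[, 3L] + off[j, 3L]
        ok <- nc1 >= 1L & nc1 <= d[1L] & nc2 >= 1L & nc2 <= d[2L] &
          nc3 >= 1L & nc3 <= d[3L]
        if (any(ok)) {
          nb <- c(nb, nc1[ok] + (nc2[ok] - 1L) * strides[2L] +
                    (nc3[ok] - 1L) * strides[3L])
        }
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) labels[nb] <- next_id
      frontier <- nb
    }
  }
  attr(labels, "n") <- next_id
  labels
}

n_components <- function(labels) {
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(0L, labels)
  n
}
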