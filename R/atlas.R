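# Schematic tissue atlas: nested ellipsoidal shells. The analysis only
# needs tissue labels, two topologically separate CSF surfaces and
# distances, so no anatomical realism is attempted.

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.atlas_cache <- new.env(parent = emptyenv())

#' Generate a schematic brain tissue atlas
#'
#' Builds a concentric-shell atlas on an isotropic voxel grid: a central
#' ellipsoidal ventricular-CSF cavity, a deep-grey-matter shell around it,
#' the white-matter bulk, a cortical grey-matter ribbon (thick enough to
#' define two depth bands) and an outer-CSF rind filling the rest of the
#' grid, plus a small cerebellar grey-matter blob embedded in the white
#' matter. Every voxel receives exactly one label from [TISSUE_LABELS];
#' the two CSF compartments are separated by tissue. The seed perturbs the
#' per-axis shell radii slightly so atlases differ across seeds.
#'
#' @param grid_shape integer length-3 (or scalar, recycled); each axis must
#'   be at least 32 voxels so all shells fit.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return Integer 3D array of tissue labels.
#' @export
generate_atlas <- function(grid_shape, seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(!is.finite(grid_shape))) {
    stop("grid_shape must be 3 integer extents", call. = FALSE)
  }
  if (any(grid_shape < 32L)) {
    stop(sprintf("grid too small to fit the atlas shells: need >= 32 per axis, got %s",
                 paste(grid_shape, collapse = "x")), call. = FALSE)
  }
  key <- paste(c(grid_shape, seed), collapse = "_")
  if (!is.null(.atlas_cache[[key]])) return(.atlas_cache[[key]])

  scale <- with_seed(seed, stats::runif(3L, 0.93, 1.0))
  centre <- (grid_shape + 1) / 2
  semi <- (grid_shape - 1) / 2 * scale

  # normalised elliptical radius per voxel
  ax <- lapply(1:3, function(k) ((seq_len(grid_shape[k]) - centre[k]) / semi[k])^2)
  u2 <- outer(outer(ax[[1L]], ax[[2L]], `+`), ax[[3L]], `+`)
  u <- sqrt(u2)

  atlas <- array(TISSUE_LABELS[["ocsf"]], dim = grid_shape)
  atlas[u < 0.94] <- TISSUE_LABELS[["cgm"]]
  atlas[u < 0.68] <- TISSUE_LABELS[["wm"]]
  atlas[u < 0.30] <- TISSUE_LABELS[["dgm"]]
  atlas[u < 0.18] <- TISSUE_LABELS[["vcsf"]]

  # cerebellar GM: small ellipsoid inside the WM shell
  cb_centre <- centre + c(0.49 * semi[1L], 0, 0)
  cb_semi <- pmax(0.09 * semi, 1.2)
  axc <- lapply(1:3, function(k)
    ((seq_len(grid_shape[k]) - cb_centre[k]) / cb_semi[k])^2)
  ucb <- outer(outer(axc[[1L]], axc[[2L]], `+`), axc[[3L]], `+`)
  cb <- ucb < 1 & atlas == TISSUE_LABELS[["wm"]]
  atlas[cb] <- TISSUE_LABELS[["cbgm"]]

  missing <- setdiff(TISSUE_LABELS, unique(as.vector(atlas)))
  if (length(missing)) {
    stop(sprintf("atlas construction failed: empty compartment(s) %s",
                 paste(tissue_name(missing), collapse = ", ")), call. = FALSE)
  }
  .atlas_cache[[key]] <- atlas
  atlas
}
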