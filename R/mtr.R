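# Magnetisation transfer ratio maps and longitudinal change maps.

#' Compute a magnetisation transfer ratio (MTR) map
#'
#' MTR is computed voxelwise as `100 * (MToff - MTon) / MToff`, in
#' percentage units (pu). Voxels where `MToff <= 0` cannot yield a defined
#' ratio; they are removed from the validity mask and counted in a log
#' message rather than propagating NaN.
#'
#' @param mt_off,mt_on numeric 3D arrays: signal without / with the
#'   magnetisation-transfer saturation pulse.
#' @param mask logical 3D array of voxels to evaluate; default all voxels.
#' @return An object of class `mtr_volume`: list with `values` (pu, `NA`
#'   outside the validity mask), `mask` (logical validity mask) and `dim`.
#' @export
compute_mtr <- function(mt_off, mt_on, mask = NULL) {
  assert_volume(mt_off)
  assert_volume(mt_on)
  assert_same_shape(mt_off, mt_on, "MT volumes")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(mt_off))
  assert_same_shape(mt_off, mask, "volume and mask")
  bad <- mask & !(is.finite(mt_off) & mt_off > 0 & is.finite(mt_on))
  if (any(bad)) {
    lmtr_log("mtr", "%d voxel(s) with MToff <= 0 or non-finite input removed from mask",
             sum(bad))
    mask <- mask & !bad
  }
  values <- array(NA_real_, dim = dim(mt_off))
  values[mask] <- 100 * (mt_off[mask] - mt_on[mask]) / mt_off[mask]
  mtr_volume(values, mask)
}

#' Construct an MTR volume container
#'
#' @param values numeric 3D array in percentage units; `NA` allowed only
#'   outside `mask`.
#' @param mask logical validity mask (default: finite voxels).
#' @return `mtr_volume` object.
#' @export
mtr_volume <- function(values, mask = NULL) {
  assert_volume(values)
  if (is.null(mask)) mask <- array(is.finite(values), dim = dim(values))
  assert_same_shape(values, mask, "values and mask")
  if (any(!is.finite(values[mask]))) {
    stop("non-finite MTR values inside the validity mask", call. = FALSE)
  }
  structure(list(values = values, mask = mask, dim = dim(values)),
            class = "mtr_volume")
}

#' @export
print.mtr_volume <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("MTR volume %s: %d valid voxels, range [%.2f, %.2f] pu\n",
              paste(x$dim, collapse = "x"), sum(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Voxelwise MTR change map (follow-up minus baseline)
#'
#' @param baseline,followup `mtr_volume` objects (or bare numeric arrays)
#'   on the same grid.
#' @return `mtr_volume` of `followup - baseline` in pu; the validity mask
#'   is the intersection of the input masks.
#' @export
change_map <- function(baseline, followup) {
  if (!inherits(baseline, "mtr_volume")) baseline <- mtr_volume(baseline)
  if (!inherits(followup, "mtr_volume")) followup <- mtr_volume(followup)
  assert_same_shape(baseline$values, followup$values, "MTR volumes")
  mask <- baseline$mask & followup$mask
  values <- array(NA_real_, dim = baseline$dim)
  values[mask] <- followup$values[mask] - baseline$values[mask]
  mtr_volume(values, mask)
}
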