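# Concentric CSF-distance bands. White matter and deep grey matter are
# banded together by distance from the ventricular CSF surface: the
# per-subject distance range is divided into 10 bins, the innermost and
# outermost bins are excluded to mitigate partial volume effects, and the
# surviving bins are renumbered 1-8 (1 nearest the ventricles). The
# cortical ribbon gets 2 depth bands by distance from the outer CSF:
# band 2 (outer) is the nearer-to-CSF half, band 1 (inner) the deeper half.

#' Build CSF-distance band maps from a tissue atlas
#'
#' @param atlas integer 3D tissue-label array (see [TISSUE_LABELS]).
#' @param pixdim voxel spacing, default 1 mm isotropic.
#' @param scheme `"equal-width"` (default): 10 equal-width distance bins
#'   between 0 and the subject's maximum; `"equal-count"`: decile bins.
#' @return Object of class `band_map`: list with `wmdgm_band` (integer
#'   array, 1-8 in WM/DGM voxels, `NA` in excluded bins and other tissue),
#'   `wmdgm_raw` (pre-exclusion bin 1-10), `cgm_band` (1 inner / 2 outer in
#'   cortical voxels), and the two distance volumes for audit.
#' @export
build_bands <- function(atlas, pixdim = c(1, 1, 1),
                        scheme = c("equal-width", "equal-count")) {
  assert_volume(atlas)
  scheme <- match.arg(scheme)
  vcsf <- atlas == TISSUE_LABELS[["vcsf"]]
  ocsf <- atlas == TISSUE_LABELS[["ocsf"]]
  wmdgm <- atlas == TISSUE_LABELS[["wm"]] | atlas == TISSUE_LABELS[["dgm"]]
  cgm <- atlas == TISSUE_LABELS[["cgm"]]
  if (!any(vcsf)) stop("atlas has no ventricular CSF", call. = FALSE)
  if (!any(ocsf)) stop("atlas has no outer CSF", call. = FALSE)
  if (!any(wmdgm)) stop("atlas has no WM/DGM tissue", call. = FALSE)
  if (!any(cgm)) stop("atlas has no cortical grey matter", call. = FALSE)

  dist_v <- distance_transform(vcsf, pixdim)
  dist_o <- distance_transform(ocsf, pixdim)

  d <- dist_v[wmdgm]
  raw <- array(NA_integer_, dim = dim(atlas))
  if (scheme == "equal-width") {
    width <- max(d) / 10
    raw[wmdgm] <- pmin(10L, pmax(1L, as.integer(ceiling(d / width))))
  } else {
    cuts <- stats::quantile(d, probs = seq(0.1, 0.9, by = 0.1), type = 7)
    raw[wmdgm] <- 1L + as.integer(rowSums(outer(d, cuts, `>`)))
  }
  band <- raw
  band[raw == 1L | raw == 10L] <- NA_integer_
  keep <- !is.na(band)
  band[keep] <- band[keep] - 1L

  dc <- dist_o[cgm]
  med <- stats::median(dc)
  cgm_band <- array(NA_integer_, dim = dim(atlas))
  cgm_band[cgm] <- ifelse(dc <= med, 2L, 1L)

  structure(list(wmdgm_band = band, wmdgm_raw = raw, cgm_band = cgm_band,
                 dist_ventricular = dist_v, dist_outer = dist_o,
                 scheme = scheme),
            class = "band_map")
}

#' @export
print.band_map <- function(x, ...) {
  cat(sprintf("band_map (%s): WMDGM bands 1-8 (%d voxels banded, %d excluded), CGM bands 1-2 (%d voxels)\n",
              x$scheme, sum(!is.na(x$wmdgm_band)),
              sum(!is.na(x$wmdgm_raw)) - sum(!is.na(x$wmdgm_band)),
              sum(!is.na(x$cgm_band))))
  invisible(x)
}

#' Assign a lesion to its predominant distance band
#'
#' The lesion gets the band holding the plurality of its banded voxels;
#' ties break toward the lower (nearer-CSF) band. Lesions with no banded
#' voxels (e.g. wholly inside the excluded bins) return `NA` and are
#' logged.
#'
#' @param voxels integer vector of linear voxel indices of the lesion.
#' @param band_map a [build_bands()] result.
#' @param type `"wmdgm"` or `"cgm"`: which band volume to use.
#' @return Integer band id, or `NA` if unassignable.
#' @export
assign_lesion_band <- function(voxels, band_map, type = c("wmdgm", "cgm")) {
  type <- match.arg(type)
  vol <- if (type == "wmdgm") band_map$wmdgm_band else band_map$cgm_band
  b <- vol[voxels]
  b <- b[!is.na(b)]
  if (length(b) == 0L) {
    lmtr_log("bands", "lesion with no banded voxels left unassigned")
    return(NA_integer_)
  }
  tab <- table(b)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}
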