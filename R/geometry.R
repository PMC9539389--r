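# Lesion decomposition: tissue classification, core/rim split by
# one-voxel-layer erosion, and three concentric perilesional cuffs by
# successive one-voxel-layer dilations with the multi-lesion exclusion
# rule applied per voxel across all three rings jointly.

#' Classify a lesion's tissue composition
#'
#' A lesion is pure if every member voxel carries the same atlas label
#' (`"wm"`, `"cgm"`, `"dgm"` or `"cbgm"`); otherwise `"mixed"`. Lesions may
#' not contain CSF voxels.
#'
#' @param voxels integer linear indices of the lesion's voxels.
#' @param atlas integer tissue-label array.
#' @return Character scalar: `"wm"`, `"cgm"`, `"dgm"`, `"cbgm"` or `"mixed"`.
#' @export
classify_tissue <- function(voxels, atlas) {
  if (length(voxels) == 0L) stop("empty lesion component", call. = FALSE)
  labs <- unique(atlas[voxels])
  if (any(labs %in% CSF_LABELS)) {
    stop("lesion contains CSF voxels: invalid lesion mask", call. = FALSE)
  }
  if (length(labs) == 1L) tissue_name(labs) else "mixed"
}

#' Split a lesion into core and rim
#'
#' The core is the morphological erosion of the lesion by one voxel layer;
#' the rim is the remainder. Thin lesions can have an empty core, which is
#' permitted (such lesions are skipped by core-level analyses).
#'
#' @param mask logical 3D array of one lesion (or of non-adjacent lesions,
#'   whose erosions are independent).
#' @param connectivity structuring-element connectivity, 6 or 26.
#' @return List with logical arrays `core` and `rim` (disjoint; their
#'   union is `mask`).
#' @export
split_core_rim <- function(mask, connectivity = 6L) {
  core <- erode_mask(mask, connectivity)
  list(core = core, rim = mask & !core)
}

#' Interior voxels after stripping the outermost layer
#'
#' Identical to the core from [split_core_rim()]; used to mitigate partial
#' volume effects in pure-WM voxel- and segment-level analyses (stripping
#' is not applied to CGM/DGM lesions, which it would leave too small).
#'
#' @inheritParams split_core_rim
#' @return Logical 3D array of interior voxels (possibly empty).
#' @export
strip_outer_layer <- function(mask, connectivity = 6L) {
  erode_mask(mask, connectivity)
}

# Bounding box of linear indices, padded and clipped to the grid.
bbox_of <- function(idx, d, pad) {
  co <- arrayInd(idx, d)
  lapply(1:3, function(k) {
    max(1L, min(co[, k]) - pad):min(d[k], max(co[, k]) + pad)
  })
}

#' Build the three perilesional cuffs for every lesion
#'
#' Each lesion's first cuff is its one-voxel-layer dilation minus the
#' lesion; the second and third cuffs are the next two dilation shells.
#' Cuffs are restricted to normal-appearing tissue: non-lesional, non-CSF
#' voxels (optionally only the lesion's own tissue class). Any voxel
#' claimed by the cuffs of two or more lesions is excluded from all of
#' them; exclusions are counted in the result.
#'
#' @param labels integer component-label array from [label_components()].
#' @param atlas integer tissue-label array.
#' @param connectivity 6 or 26.
#' @param restrict_to_tissue if `TRUE`, a lesion's cuffs are additionally
#'   restricted to its own (majority) tissue class.
#' @return List with `owner` (integer array: lesion id owning each cuff
#'   voxel, 0 if none), `ring` (integer array 1-3), `excluded` (logical
#'   array of voxels dropped by the multi-lesion rule) and `n_excluded`.
#' @export
make_cuffs <- function(labels, atlas, connectivity = 6L,
                       restrict_to_tissue = FALSE) {
  assert_same_shape(labels, atlas, "labels and atlas")
  d <- dim(labels)
  n <- n_components(labels)
  lesion_any <- labels > 0L
  eligible <- !lesion_any & !is_csf(atlas)
  owner <- array(0L, dim = d)
  ring <- array(0L, dim = d)
  claims <- array(0L, dim = d)
  per_lesion <- vector("list", n)
  for (id in seq_len(n)) {
    idx <- which(labels == id)
    if (length(idx) == 0L) next
    bb <- bbox_of(idx, d, pad = 3L)
    sub_dim <- lengths(bb)
    sub <- array(FALSE, dim = sub_dim)
    sub[arrayInd(idx, d) -
          matrix(vapply(bb, min, 1L) - 1L, nrow = length(idx), ncol = 3L,
                 byrow = TRUE)] <- TRUE
    d1 <- dilate_mask(sub, connectivity)
    d2 <- dilate_mask(d1, connectivity)
    d3 <- dilate_mask(d2, connectivity)
    rings <- list(d1 & !sub, d2 & !d1, d3 & !d2)
    ok <- eligible[bb[[1L]], bb[[2L]], bb[[3L]]]
    if (restrict_to_tissue) {
      maj <- as.integer(names(which.max(table(atlas[idx]))))
      ok <- ok & (atlas[bb[[1L]], bb[[2L]], bb[[3L]]] == maj)
    }
    offs <- c(min(bb[[1L]]) - 1L, min(bb[[2L]]) - 1L, min(bb[[3L]]) - 1L)
    per <- vector("list", 3L)
    for (r in 1:3) {
      ridx <- which(rings[[r]] & ok)
      if (length(ridx)) {
        co <- arrayInd(ridx, sub_dim)
        glin <- (co[, 1L] + offs[1L]) +
          (co[, 2L] + offs[2L] - 1L) * d[1L] +
          (co[, 3L] + offs[3L] - 1L) * d[1L] * d[2L]
        per[[r]] <- glin
        claims[glin] <- claims[glin] + 1L
      } else {
        per[[r]] <- integer(0)
      }
    }
    per_lesion[[id]] <- per
  }
  excluded <- claims >= 2L
  n_excl <- sum(excluded)
  if (n_excl > 0L) {
    lmtr_log("decompose", "%d cuff voxel(s) claimed by >1 lesion excluded", n_excl)
  }
  for (id in seq_len(n)) {
    per <- per_lesion[[id]]
    if (is.null(per)) next
    for (r in 1:3) {
      keep <- per[[r]][!excluded[per[[r]]]]
      owner[keep] <- id
      ring[keep] <- r
    }
  }
  list(owner = owner, ring = ring, excluded = excluded, n_excluded = n_excl)
}

#' Decompose all lesions into core, rim and perilesional cuffs
#'
#' Runs [split_core_rim()] and [make_cuffs()] over a labelled lesion map
#' and tabulates per-lesion tissue class and region sizes.
#'
#' @param labels integer component-label array from [label_components()]
#'   (labelling connectivity should match `connectivity`).
#' @inheritParams make_cuffs
#' @return Object of class `lesion_decomposition`: list with integer
#'   arrays `core`, `rim` (lesion id per voxel, 0 outside), `cuff_owner`,
#'   `cuff_ring`, logical `cuff_excluded`, and `table`, a data frame with
#'   one row per lesion (`lesion_id`, `tissue_class`, `size`, `core_size`,
#'   `rim_size`, `cuff1_size`, `cuff2_size`, `cuff3_size`).
#' @export
decompose_lesions <- function(labels, atlas, connectivity = 6L,
                              restrict_to_tissue = FALSE) {
  assert_same_shape(labels, atlas, "labels and atlas")
  n <- n_components(labels)
  mask <- labels > 0L
  core_mask <- erode_mask(mask, connectivity)
  core <- labels
  core[!core_mask] <- 0L
  rim <- labels
  rim[core_mask] <- 0L
  cuffs <- make_cuffs(labels, atlas, connectivity, restrict_to_tissue)
  tab <- data.frame(lesion_id = seq_len(max(n, 0L)),
                    tissue_class = character(max(n, 0L)),
                    size = integer(max(n, 0L)), core_size = integer(max(n, 0L)),
                    rim_size = integer(max(n, 0L)), cuff1_size = integer(max(n, 0L)),
                    cuff2_size = integer(max(n, 0L)), cuff3_size = integer(max(n, 0L)),
                    stringsAsFactors = FALSE)
  if (n > 0L) {
    tab$size <- tabulate(labels[mask], nbins = n)
    tab$core_size <- tabulate(core[core > 0L], nbins = n)
    tab$rim_size <- tab$size - tab$core_size
    for (r in 1:3) {
      ow <- cuffs$owner[cuffs$ring == r]
      tab[[paste0("cuff", r, "_size")]] <- tabulate(ow, nbins = n)
    }
    tab$tissue_class <- vapply(seq_len(n), function(id)
      classify_tissue(which(labels == id), atlas), character(1))
  }
  n_empty <- sum(tab$core_size == 0L)
  if (n_empty > 0L) {
    lmtr_log("decompose", "%d lesion(s) with empty core (skipped by core-level analyses)",
             n_empty)
  }
  structure(list(core = core, rim = rim, cuff_owner = cuffs$owner,
                 cuff_ring = cuffs$ring, cuff_excluded = cuffs$excluded,
                 n_cuff_excluded = cuffs$n_excluded,
                 connectivity = connectivity, table = tab),
            class = "lesion_decomposition")
}

#' @export
print.lesion_decomposition <- function(x, ...) {
  cat(sprintf("lesion_decomposition: %d lesion(s), connectivity %d, %d cuff voxel(s) excluded\n",
              nrow(x$table), x$connectivity, x$n_cuff_excluded))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}
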