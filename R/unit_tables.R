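# Long-format analysis unit tables: one row per lesion, component,
# segment or voxel, with baseline and follow-up values, arm and the four
# binary minimisation covariates. These are the inputs to the
# baseline-adjusted mixed models.

unit_covariates <- c("age_band", "gender", "centre", "edss_band")

subject_rows <- function(s) {
  p <- s$patient
  data.frame(patient_id = p$patient_id, arm = p$arm,
             age_band = p$age_band, gender = p$gender,
             centre = p$centre, edss_band = p$edss_band,
             stringsAsFactors = FALSE)
}

#' Whole-lesion analysis units
#'
#' One row per lesion with the lesion-mean baseline and follow-up MTR
#' (and T1-weighted intensity), lesion tissue class and size. Optionally
#' the outermost voxel layer of pure-WM lesions is stripped first, and a
#' predominant distance band is attached.
#'
#' @param trial an [simulate_trial()] result (or any object with the same
#'   structure built from real data).
#' @param strip_wm strip the outermost layer of pure-WM lesions before
#'   averaging (lesions whose interior is empty are dropped).
#' @param band_map optional [build_bands()] result; adds a `band` column
#'   (WMDGM band for WM lesions, cortical band for CGM lesions).
#' @return Data frame with columns `unit_id`, `patient_id`, `lesion_id`,
#'   `level`, `tissue`, `size`, `baseline`, `followup`, `t1_baseline`,
#'   `arm`, the four covariates and (optionally) `band`.
#' @export
lesion_unit_table <- function(trial, strip_wm = FALSE, band_map = NULL) {
  out <- lapply(trial$subjects, function(s) {
    tab <- s$lesion_table
    if (nrow(tab) == 0L) return(NULL)
    cov <- subject_rows(s)
    rows <- lapply(seq_len(nrow(tab)), function(j) {
      id <- tab$lesion_id[j]
      vox <- which(s$lesion_labels == id)
      if (strip_wm && tab$tissue_class[j] == "wm") {
        vox <- vox[s$depth[vox] >= 2L]
        if (length(vox) == 0L) return(NULL)
      }
      band <- NA_integer_
      if (!is.null(band_map)) {
        band <- switch(tab$tissue_class[j],
                       wm = assign_lesion_band(vox, band_map, "wmdgm"),
                       cgm = assign_lesion_band(vox, band_map, "cgm"),
                       NA_integer_)
      }
      data.frame(cov,
                 lesion_id = paste0(cov$patient_id, "_L", id),
                 level = "lesion",
                 tissue = tab$tissue_class[j],
                 size = tab$size[j],
                 baseline = mean(s$mtr_baseline[vox]),
                 followup = mean(s$mtr_followup[vox]),
                 t1_baseline = mean(s$t1w[vox]),
                 band = band,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out$unit_id <- out$lesion_id
  rownames(out) <- NULL
  out
}

#' Component-level analysis units (core, rim, three cuffs)
#'
#' One row per lesion per non-empty region from [decompose_lesions()],
#' with region-mean baseline and follow-up MTR. Empty cores (thin
#' lesions) simply contribute no core row.
#'
#' @inheritParams lesion_unit_table
#' @param decomps optional list of per-subject [decompose_lesions()]
#'   results (computed on the fly if `NULL`).
#' @return Data frame as in [lesion_unit_table()] plus a `component`
#'   column (`core`, `rim`, `cuff1`, `cuff2`, `cuff3`).
#' @export
component_unit_table <- function(trial, decomps = NULL) {
  conn <- trial$config$connectivity
  out <- lapply(seq_along(trial$subjects), function(i) {
    s <- trial$subjects[[i]]
    tab <- s$lesion_table
    if (nrow(tab) == 0L) return(NULL)
    dec <- if (is.null(decomps)) {
      decompose_lesions(s$lesion_labels, trial$atlas, conn)
    } else {
      decomps[[i]]
    }
    cov <- subject_rows(s)
    rows <- list()
    for (j in seq_len(nrow(tab))) {
      id <- tab$lesion_id[j]
      regions <- list(core = which(dec$core == id),
                      rim = which(dec$rim == id),
                      cuff1 = which(dec$cuff_owner == id & dec$cuff_ring == 1L),
                      cuff2 = which(dec$cuff_owner == id & dec$cuff_ring == 2L),
                      cuff3 = which(dec$cuff_owner == id & dec$cuff_ring == 3L))
      for (rg in names(regions)) {
        vox <- regions[[rg]]
        if (length(vox) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          cov,
          lesion_id = paste0(cov$patient_id, "_L", id),
          level = "component",
          tissue = tab$tissue_class[j],
          component = rg,
          n_vox = length(vox),
          baseline = mean(s$mtr_baseline[vox]),
          followup = mean(s$mtr_followup[vox]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out$unit_id <- paste0(out$lesion_id, "_", out$component)
  rownames(out) <- NULL
  out
}

# Eligible voxels of one pure lesion for voxel/segment analyses:
# outer-layer-stripped for WM, full lesion for CGM/DGM.
eligible_voxels <- function(s, id, tissue, strip_wm = TRUE) {
  vox <- which(s$lesion_labels == id)
  if (strip_wm && tissue == "wm") vox <- vox[s$depth[vox] >= 2L]
  vox
}

#' Voxel-level analysis units for pure lesions of one tissue
#'
#' One row per eligible lesional voxel. Pure-WM lesions are
#' outer-layer-stripped to mitigate partial volume effects; CGM/DGM
#' lesions are not. When the table exceeds `cap` rows a deterministic
#' subsample (seeded from the trial config) is taken: voxel-level model
#' fits are the contract, not exhaustive enumeration.
#'
#' @inheritParams lesion_unit_table
#' @param tissue `"wm"`, `"cgm"` or `"dgm"`.
#' @param strip_wm strip pure-WM outer layers (default `TRUE`).
#' @param cap maximum number of voxel rows.
#' @return Data frame with one row per voxel: `baseline`, `followup`,
#'   `t1_baseline`, `band`, covariates, ids.
#' @export
voxel_unit_table <- function(trial, tissue, strip_wm = TRUE, cap = 20000L,
                             band_map = NULL) {
  out <- lapply(trial$subjects, function(s) {
    tab <- s$lesion_table
    keep <- which(tab$tissue_class == tissue)
    if (length(keep) == 0L) return(NULL)
    cov <- subject_rows(s)
    rows <- lapply(keep, function(j) {
      id <- tab$lesion_id[j]
      vox <- eligible_voxels(s, id, tissue, strip_wm)
      if (length(vox) == 0L) return(NULL)
      band <- rep(NA_integer_, length(vox))
      if (!is.null(band_map)) {
        band <- if (tissue == "cgm") band_map$cgm_band[vox] else
          band_map$wmdgm_band[vox]
      }
      data.frame(cov,
                 lesion_id = paste0(cov$patient_id, "_L", id),
                 level = "voxel",
                 tissue = tissue,
                 voxel = vox,
                 baseline = s$mtr_baseline[vox],
                 followup = s$mtr_followup[vox],
                 t1_baseline = s$t1w[vox],
                 band = band,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out$unit_id <- paste0(out$lesion_id, "_V", out$voxel)
  rownames(out) <- NULL
  if (nrow(out) > cap) {
    lmtr_log("tables", "voxel table for %s capped at %d of %d rows",
             tissue, cap, nrow(out))
    keep <- with_seed(trial$config$seed + 7919L,
                      sort(sample.int(nrow(out), cap)))
    out <- out[keep, ]
    rownames(out) <- NULL
  }
  out
}

#' Segment-level analysis units for pure lesions of one tissue
#'
#' Voxels within each lesion are grouped into regions by the cohort-level
#' tissue-specific baseline quartile of the chosen variable (baseline MTR
#' or baseline T1-weighted intensity); each non-empty segment contributes
#' one row with segment-mean baseline and follow-up MTR.
#'
#' @inheritParams voxel_unit_table
#' @param variable `"mtr"` or `"t1"`: the stratifying baseline variable.
#' @return Data frame with a `stratum` column (baseline quartile of the
#'   stratifying variable) plus the usual unit columns, and the fitted
#'   [fit_cutpoints()] object as attribute `strata`.
#' @export
segment_unit_table <- function(trial, tissue, variable = c("mtr", "t1"),
                               strip_wm = TRUE) {
  variable <- match.arg(variable)
  vox_df <- voxel_unit_table(trial, tissue, strip_wm = strip_wm, cap = .Machine$integer.max)
  if (is.null(vox_df) || nrow(vox_df) < 4L) return(NULL)
  strat_vals <- if (variable == "mtr") vox_df$baseline else vox_df$t1_baseline
  strata <- fit_cutpoints(strat_vals, "quartiles")
  vox_df$stratum <- assign_stratum(strat_vals, strata)
  sp <- split(vox_df, list(vox_df$lesion_id, vox_df$stratum), drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(g[1L, c("patient_id", "arm", unit_covariates, "lesion_id", "tissue")],
               level = "segment",
               stratum = g$stratum[1L],
               n_vox = nrow(g),
               baseline = mean(g$baseline),
               followup = mean(g$followup),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$unit_id <- paste0(out$lesion_id, "_S", out$stratum)
  rownames(out) <- NULL
  attr(out, "strata") <- strata
  out
}
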