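# NIfTI and CSV I/O for the pipeline: per-subject volumes (atlas, lesion
# mask, MTR at both timepoints, T1-weighted, ground truth) plus patient
# and lesion CSVs. Voxel coordinates are 0-based array indices; world
# coordinates only via the NIfTI affine (unit spacing by default).

subject_volume_names <- c("atlas", "lesion_mask", "mtr_m0", "mtr_m6",
                          "t1w_m0", "truth")

#' Write one synthetic subject's volumes to a directory
#'
#' Writes `atlas.nii.gz`, `lesion_mask.nii.gz`, `mtr_m0.nii.gz`,
#' `mtr_m6.nii.gz`, `t1w_m0.nii.gz`, `truth.nii.gz` under
#' `dir/<patient_id>/`.
#'
#' @param subject one element of an `mtr_trial`'s `subjects` list.
#' @param atlas the trial atlas volume.
#' @param dir output directory.
#' @param pixdim voxel spacing recorded in the headers.
#' @return The subject directory path, invisibly.
#' @export
write_subject <- function(subject, atlas, dir, pixdim = c(1, 1, 1)) {
  sdir <- file.path(dir, subject$patient$patient_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  vols <- list(atlas = atlas,
               lesion_mask = array(as.integer(subject$lesion_labels > 0L),
                                   dim = dim(subject$lesion_labels)),
               mtr_m0 = subject$mtr_baseline,
               mtr_m6 = subject$mtr_followup,
               t1w_m0 = subject$t1w,
               truth = subject$truth)
  for (nm in names(vols)) {
    img <- RNifti::asNifti(vols[[nm]])
    RNifti::pixdim(img) <- pixdim
    RNifti::writeNifti(img, file.path(sdir, paste0(nm, ".nii.gz")))
  }
  utils::write.csv(subject$lesion_table,
                   file.path(sdir, "lesions.csv"), row.names = FALSE)
  invisible(sdir)
}

#' Read a subject directory back into volume form
#'
#' Loads the per-subject NIfTI volumes written by [write_subject()],
#' checking that every volume shares the first one's shape and affine; a
#' mismatch raises an error naming the offending file.
#'
#' @param dir subject directory.
#' @param names volume names to load (default all present of the standard
#'   set).
#' @return Named list of 3D arrays plus `pixdim`.
#' @export
read_subject <- function(dir, names = NULL) {
  if (is.null(names)) {
    names <- subject_volume_names[file.exists(
      file.path(dir, paste0(subject_volume_names, ".nii.gz")))]
  }
  if (length(names) == 0L) stop("no subject volumes found in ", dir, call. = FALSE)
  out <- list()
  ref <- NULL
  ref_name <- NULL
  for (nm in names) {
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    if (!file.exists(path)) stop("missing volume file: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    if (is.null(ref)) {
      ref <- img
      ref_name <- nm
    } else {
      if (!identical(dim(img), dim(ref))) {
        stop(sprintf("volume '%s' shape %s does not match '%s' shape %s",
                     nm, paste(dim(img), collapse = "x"),
                     ref_name, paste(dim(ref), collapse = "x")), call. = FALSE)
      }
      if (max(abs(RNifti::xform(img) - RNifti::xform(ref))) > 1e-4) {
        stop(sprintf("volume '%s' is not voxel-aligned with '%s' (affine mismatch)",
                     nm, ref_name), call. = FALSE)
      }
    }
    a <- array(as.vector(img), dim = dim(img))
    if (any(!is.finite(a))) stop("non-finite values in volume: ", path, call. = FALSE)
    out[[nm]] <- a
  }
  out$pixdim <- RNifti::pixdim(ref)[1:3]
  out
}

#' Write a full trial to disk
#'
#' Per-subject volume directories plus `patients.csv` (arm and the four
#' minimisation covariates) and a pooled ground-truth `lesions.csv`.
#'
#' @param trial an [simulate_trial()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  les <- do.call(rbind, lapply(trial$subjects, function(s) {
    if (nrow(s$lesion_table) == 0L) return(NULL)
    cbind(patient_id = s$patient$patient_id, s$lesion_table)
  }))
  utils::write.csv(les, file.path(dir, "lesions.csv"), row.names = FALSE)
  for (s in trial$subjects) write_subject(s, trial$atlas, dir)
  invisible(dir)
}
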