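# Synthetic two-arm trial generator. Emulates the statistical structure
# the downstream analysis assumes: lesions of mixed tissue types with
# reduced MTR relative to surrounding tissue, patient- and lesion-level
# random intercepts shared between timepoints, independent voxel noise at
# each timepoint (so the placebo baseline/follow-up correlation follows a
# closed form), a T1-weighted volume linearly coupled to baseline MTR,
# and treatment effects plantable by tissue, baseline quartile, distance
# band and lesion component via the same operators the analysis uses.

#' Specify planted treatment effects
#'
#' The planted per-voxel treatment effect (added to active-arm follow-up
#' MTR at lesional voxels) is the tissue-level effect multiplied by the
#' voxel's baseline-MTR-quartile, distance-band and core/rim multipliers.
#' All-ones multipliers reduce to a uniform per-tissue effect.
#'
#' @param tau_by_tissue named numeric (pu): effect per tissue class
#'   (`wm`, `cgm`, `dgm`, `cbgm`).
#' @param quartile_multipliers length-4 numeric, by baseline-MTR voxel
#'   quartile (1 = lowest).
#' @param wmdgm_band_multipliers length-8 numeric, by WM/DGM distance band.
#' @param cgm_band_multipliers length-2 numeric, by cortical depth band.
#' @param component_multipliers named numeric for `core` and `rim`.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(tau_by_tissue = c(wm = 0.2, cgm = 1.4, dgm = 1.4, cbgm = 0),
                        quartile_multipliers = rep(1, 4),
                        wmdgm_band_multipliers = rep(1, 8),
                        cgm_band_multipliers = rep(1, 2),
                        component_multipliers = c(core = 1, rim = 1)) {
  tau <- c(wm = 0, cgm = 0, dgm = 0, cbgm = 0)
  tau[names(tau_by_tissue)] <- tau_by_tissue
  stopifnot(length(quartile_multipliers) == 4L,
            length(wmdgm_band_multipliers) == 8L,
            length(cgm_band_multipliers) == 2L,
            all(c("core", "rim") %in% names(component_multipliers)))
  vals <- c(tau, quartile_multipliers, wmdgm_band_multipliers,
            cgm_band_multipliers, component_multipliers)
  if (any(!is.finite(vals))) stop("effect_spec values must be finite", call. = FALSE)
  structure(list(tau_by_tissue = tau,
                 quartile_multipliers = as.numeric(quartile_multipliers),
                 wmdgm_band_multipliers = as.numeric(wmdgm_band_multipliers),
                 cgm_band_multipliers = as.numeric(cgm_band_multipliers),
                 component_multipliers = component_multipliers[c("core", "rim")]),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
null_effect_spec <- function() {
  effect_spec(tau_by_tissue = c(wm = 0, cgm = 0, dgm = 0, cbgm = 0))
}

#' Synthetic trial configuration
#'
#' Defaults describe a 49-patient two-arm trial on a 48^3 schematic atlas
#' with a WM-dominated lesion mix, an 8 pu MTR deficit at lesion centres
#' shading outward, and noise components chosen so the placebo lesional
#' baseline/follow-up correlation lands mid-range of what longitudinal
#' MTR studies observe (tune precisely with [calibrate_sigma_voxel()]).
#'
#' @param n_patients number of patients (two arms).
#' @param grid_shape voxel grid extent (scalar or length 3, >= 32).
#' @param lesions_per_patient named means (Poisson counts) per lesion
#'   class: `wm`, `cgm`, `dgm`, `cbgm`, `mixed`. Cerebellar lesions
#'   default off.
#' @param lesion_radius_range ellipsoid semi-axis range in voxels.
#' @param tissue_mtr_means named pu means per tissue label.
#' @param lesion_mtr_deficit pu reduction at the lesion centre.
#' @param within_lesion_gradient pu recovered per voxel moving outward
#'   from the centre depth toward the rim.
#' @param effect_spec an [effect_spec()].
#' @param sigma_patient,sigma_lesion,sigma_voxel SDs (pu) of the patient
#'   intercept, lesion intercept and per-timepoint voxel noise.
#' @param t1_coupling list `intercept`, `slope`, `sigma`: T1-weighted
#'   intensity = intercept + slope * baseline MTR + N(0, sigma).
#' @param connectivity structuring-element connectivity used for lesion
#'   depth and component labels, 6 or 26.
#' @param seed integer seed controlling all randomness.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_patients = 49L,
                         grid_shape = 48L,
                         lesions_per_patient = c(wm = 8, cgm = 2, dgm = 1,
                                                 cbgm = 0, mixed = 5),
                         lesion_radius_range = c(1.5, 3.5),
                         tissue_mtr_means = c(vcsf = 5, ocsf = 5, wm = 38,
                                              cgm = 32, dgm = 34, cbgm = 33),
                         lesion_mtr_deficit = 8,
                         within_lesion_gradient = 1.5,
                         effect_spec = lesionmtr::effect_spec(),
                         sigma_patient = 0.5,
                         sigma_lesion = 0.75,
                         sigma_voxel = 1.1,
                         t1_coupling = list(intercept = 200, slope = 15, sigma = 25),
                         connectivity = 6L,
                         seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  les <- c(wm = 0, cgm = 0, dgm = 0, cbgm = 0, mixed = 0)
  les[names(lesions_per_patient)] <- lesions_per_patient
  stopifnot(n_patients >= 4L, all(grid_shape >= 32L),
            all(les >= 0), length(lesion_radius_range) == 2L,
            lesion_radius_range[1] > 0,
            diff(lesion_radius_range) >= 0,
            all(tissue_mtr_means > 0),
            lesion_mtr_deficit >= 0, within_lesion_gradient >= 0,
            sigma_patient >= 0, sigma_lesion >= 0, sigma_voxel >= 0,
            t1_coupling$sigma >= 0,
            connectivity %in% c(6L, 26L))
  if (!inherits(effect_spec, "effect_spec")) stop("effect_spec must be an effect_spec()", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 grid_shape = as.integer(grid_shape),
                 lesions_per_patient = les,
                 lesion_radius_range = lesion_radius_range,
                 tissue_mtr_means = tissue_mtr_means,
                 lesion_mtr_deficit = lesion_mtr_deficit,
                 within_lesion_gradient = within_lesion_gradient,
                 effect_spec = effect_spec,
                 sigma_patient = sigma_patient,
                 sigma_lesion = sigma_lesion,
                 sigma_voxel = sigma_voxel,
                 t1_coupling = t1_coupling,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Reduced-size trial configuration
#'
#' A 12-patient 32^3 profile used for simulation studies where many
#' replicate trials are fitted: large enough that every analysis level is
#' non-degenerate (a few dozen pure-GM lesions per cohort, on the order of
#' a thousand stripped WM lesional voxels), small enough that hundreds of
#' replicates are cheap.
#'
#' @param ... overrides passed to [trial_config()].
#' @export
scaled_trial_config <- function(...) {
  args <- list(n_patients = 12L, grid_shape = 32L,
               lesions_per_patient = c(wm = 6, cgm = 2, dgm = 1,
                                       cbgm = 0, mixed = 2))
  over <- list(...)
  args[names(over)] <- over
  do.call(trial_config, args)
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("trial_config: %d patients, grid %s, lesions/patient %s, seed %d\n",
              x$n_patients, paste(x$grid_shape, collapse = "x"),
              paste(sprintf("%s=%g", names(x$lesions_per_patient),
                            x$lesions_per_patient), collapse = " "),
              x$seed))
  invisible(x)
}

# ---- patients and arms ------------------------------------------------

make_patients <- function(n) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age_band = stats::rbinom(n, 1, 0.5),
             gender = stats::rbinom(n, 1, 0.5),
             centre = stats::rbinom(n, 1, 0.5),
             edss_band = stats::rbinom(n, 1, 0.5),
             stringsAsFactors = FALSE)
}

# Stratified alternation within minimisation strata: patients are grouped
# by the 4 binary covariates and assigned along a single alternating
# sequence with a random start, giving balance within +/-1 per stratum
# and +/-1 overall.
assign_arms <- function(patients) {
  stratum <- interaction(patients$age_band, patients$gender,
                         patients$centre, patients$edss_band, drop = TRUE)
  ord <- order(stratum, seq_len(nrow(patients)))
  start <- stats::rbinom(1, 1, 0.5)
  seqarm <- rep(if (start == 1L) c("active", "placebo") else c("placebo", "active"),
                length.out = nrow(patients))
  arm <- character(nrow(patients))
  arm[ord] <- seqarm[seq_along(ord)]
  patients$arm <- factor(arm, levels = c("placebo", "active"))
  patients
}

# ---- lesion planting --------------------------------------------------

.candidate_cache <- new.env(parent = emptyenv())

lesion_candidates <- function(atlas) {
  key <- paste(c(dim(atlas), sum(atlas)), collapse = "_")
  if (!is.null(.candidate_cache[[key]])) return(.candidate_cache[[key]])
  gm <- atlas == TISSUE_LABELS[["cgm"]] | atlas == TISSUE_LABELS[["dgm"]]
  near_gm <- dilate_mask(dilate_mask(gm, 26L), 26L)
  out <- list(
    wm = which(atlas == TISSUE_LABELS[["wm"]] & !near_gm),
    cgm = which(atlas == TISSUE_LABELS[["cgm"]]),
    dgm = which(atlas == TISSUE_LABELS[["dgm"]]),
    cbgm = which(atlas == TISSUE_LABELS[["cbgm"]]),
    mixed = which(atlas == TISSUE_LABELS[["wm"]] & near_gm))
  .candidate_cache[[key]] <- out
  out
}

# Voxels of a random ellipsoid around a centre, as linear indices.
ellipsoid_voxels <- function(centre, semi, d) {
  bb <- lapply(1:3, function(k) {
    max(1L, floor(centre[k] - semi[k])):min(d[k], ceiling(centre[k] + semi[k]))
  })
  nb <- lengths(bb)
  x <- rep(bb[[1L]], times = nb[2L] * nb[3L])
  y <- rep(rep(bb[[2L]], each = nb[1L]), times = nb[3L])
  z <- rep(bb[[3L]], each = nb[1L] * nb[2L])
  u2 <- ((x - centre[1L]) / semi[1L])^2 + ((y - centre[2L]) / semi[2L])^2 +
    ((z - centre[3L]) / semi[3L])^2
  keep <- u2 <= 1
  x[keep] + (y[keep] - 1L) * d[1L] + (z[keep] - 1L) * d[1L] * d[2L]
}

# 26-neighbourhood closure of a voxel index set (for separation checks).
neighbourhood26 <- function(idx, d) {
  co <- arrayInd(idx, d)
  off <- conn_offsets(26L)
  out <- idx
  for (j in seq_len(nrow(off))) {
    nc1 <- co[, 1L] + off[j, 1L]
    nc2 <- co[, 2L] + off[j, 2L]
    nc3 <- co[, 3L] + off[j, 3L]
    ok <- nc1 >= 1L & nc1 <= d[1L] & nc2 >= 1L & nc2 <= d[2L] &
      nc3 >= 1L & nc3 <= d[3L]
    out <- c(out, nc1[ok] + (nc2[ok] - 1L) * d[1L] + (nc3[ok] - 1L) * d[1L] * d[2L])
  }
  unique(out)
}

#' Plant non-overlapping ellipsoidal lesions in a tissue atlas
#'
#' Lesion counts per class are Poisson draws around the configured means
#' (forcing at least one cohort-wide lesion of any class with a positive
#' mean happens at the cohort level in [simulate_trial()]). Each lesion is
#' a random ellipsoid clipped to its target tissue (pure classes) or to
#' any non-CSF tissue (mixed), reduced to the connected component holding
#' its centre, and separated from previously planted lesions by at least
#' one voxel in the 26-neighbourhood sense so components never merge.
#' Placement failures after bounded retries are skipped with a log entry.
#'
#' @param atlas integer tissue atlas.
#' @param config a [trial_config()].
#' @param counts optional named integer vector overriding the Poisson
#'   draw (`wm`, `cgm`, `dgm`, `cbgm`, `mixed`).
#' @return List: `labels` (integer lesion-id array, ids in planting
#'   order), `table` (lesion_id, target_class, tissue_class, size).
#' @export
plant_lesions <- function(atlas, config, counts = NULL) {
  d <- dim(atlas)
  cand <- lesion_candidates(atlas)
  if (is.null(counts)) {
    counts <- vapply(config$lesions_per_patient, function(m)
      stats::rpois(1L, m), 1L)
  }
  labels <- array(0L, dim = d)
  blocked <- array(FALSE, dim = d)   # lesions plus their 26-neighbourhoods
  rows <- list()
  id <- 0L
  classes <- names(config$lesions_per_patient)
  for (cl in classes) {
    n_cl <- counts[[cl]]
    if (n_cl == 0L || length(cand[[cl]]) == 0L) next
    for (i in seq_len(n_cl)) {
      placed <- FALSE
      for (attempt in 1:30) {
        centre_idx <- cand[[cl]][sample.int(length(cand[[cl]]), 1L)]
        centre <- as.vector(arrayInd(centre_idx, d))
        semi <- stats::runif(3L, config$lesion_radius_range[1L],
                             config$lesion_radius_range[2L])
        vox <- ellipsoid_voxels(centre, semi, d)
        if (cl == "mixed") {
          vox <- vox[!(atlas[vox] %in% CSF_LABELS)]
        } else {
          vox <- vox[atlas[vox] == TISSUE_LABELS[[cl]]]
        }
        if (length(vox) == 0L || any(blocked[vox])) next
        # keep the connected component containing the centre
        if (length(vox) > 1L) {
          bb <- bbox_of(vox, d, pad = 1L)
          sub_dim <- lengths(bb)
          sub <- array(FALSE, dim = sub_dim)
          offs <- vapply(bb, min, 1L) - 1L
          co <- arrayInd(vox, d)
          co[, 1L] <- co[, 1L] - offs[1L]
          co[, 2L] <- co[, 2L] - offs[2L]
          co[, 3L] <- co[, 3L] - offs[3L]
          sub[co] <- TRUE
          lab <- label_components(sub, config$connectivity)
          cc <- centre - offs
          cid <- lab[cc[1L], cc[2L], cc[3L]]
          if (cid == 0L) next
          keep <- which(lab == cid)
          kco <- arrayInd(keep, sub_dim)
          vox <- (kco[, 1L] + offs[1L]) +
            (kco[, 2L] + offs[2L] - 1L) * d[1L] +
            (kco[, 3L] + offs[3L] - 1L) * d[1L] * d[2L]
        }
        if (cl == "mixed" && length(unique(atlas[vox])) < 2L) next
        id <- id + 1L
        labels[vox] <- id
        blocked[neighbourhood26(vox, d)] <- TRUE
        rows[[id]] <- data.frame(lesion_id = id, target_class = cl,
                                 tissue_class = classify_tissue(vox, atlas),
                                 size = length(vox),
                                 stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        lmtr_log("simulate", "could not place a %s lesion after 30 attempts; skipped", cl)
      }
    }
  }
  attr(labels, "n") <- id
  tab <- if (id > 0L) do.call(rbind, rows) else
    data.frame(lesion_id = integer(0), target_class = character(0),
               tissue_class = character(0), size = integer(0))
  list(labels = labels, table = tab)
}

# Depth layers by successive erosion: rim voxels have depth 1; depth
# increases by 1 per surviving erosion. 0 outside lesions. Computed on
# the lesions' bounding box for speed; erosion treats voxels outside the
# box as background, which is exact because the box is padded by 1.
lesion_depth <- function(mask, connectivity) {
  d <- dim(mask)
  depth <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) return(depth)
  bb <- bbox_of(idx, d, pad = 1L)
  m <- mask[bb[[1L]], bb[[2L]], bb[[3L]]]
  sub_depth <- array(0L, dim = dim(m))
  i <- 0L
  while (any(m)) {
    i <- i + 1L
    sub_depth[m] <- i
    m <- erode_mask(m, connectivity)
  }
  depth[bb[[1L]], bb[[2L]], bb[[3L]]] <- sub_depth
  depth
}

# ---- simulation -------------------------------------------------------

# Noiseless systematic baseline + shared random intercepts for one subject.
subject_signal <- function(atlas, labels, depth, config, b_patient, b_lesion) {
  tm <- config$tissue_mtr_means
  sig <- array(tm[tissue_name(atlas)], dim = dim(atlas))
  idx <- which(labels > 0L)
  if (length(idx)) {
    ids <- labels[idx]
    dmax <- tapply(depth[idx], ids, max)
    reduction <- pmax(0, config$lesion_mtr_deficit -
                        config$within_lesion_gradient *
                        (dmax[as.character(ids)] - depth[idx]))
    sig[idx] <- sig[idx] - reduction + b_lesion[ids]
  }
  sig + b_patient
}

# Per-voxel planted effect for one subject's lesional voxels.
planted_tau <- function(idx, atlas, depth, baseline, spec, band_map, cuts_by_tissue) {
  if (length(idx) == 0L) return(numeric(0))
  tis <- tissue_name(atlas[idx])
  tau <- unname(spec$tau_by_tissue[tis])
  cm <- spec$component_multipliers
  if (any(cm != 1)) {
    tau <- tau * ifelse(depth[idx] >= 2L, cm[["core"]], cm[["rim"]])
  }
  if (any(spec$quartile_multipliers != 1) && length(cuts_by_tissue)) {
    for (tt in unique(tis)) {
      st <- cuts_by_tissue[[tt]]
      if (is.null(st)) next
      sel <- tis == tt
      q <- assign_stratum(baseline[idx[sel]], st)
      tau[sel] <- tau[sel] * spec$quartile_multipliers[q]
    }
  }
  if (!is.null(band_map)) {
    if (any(spec$wmdgm_band_multipliers != 1)) {
      b <- band_map$wmdgm_band[idx]
      sel <- !is.na(b) & tis %in% c("wm", "dgm")
      tau[sel] <- tau[sel] * spec$wmdgm_band_multipliers[b[sel]]
    }
    if (any(spec$cgm_band_multipliers != 1)) {
      b <- band_map$cgm_band[idx]
      sel <- !is.na(b) & tis == "cgm"
      tau[sel] <- tau[sel] * spec$cgm_band_multipliers[b[sel]]
    }
  }
  tau
}

#' Simulate a complete synthetic two-arm trial
#'
#' Generates the shared schematic atlas, a patient table with the four
#' binary minimisation covariates and stratified-alternation arm
#' assignment, per-patient lesion masks, and baseline / follow-up MTR and
#' baseline T1-weighted volumes. The voxel model is
#' `baseline = tissue mean - deficit(depth) + b_patient + b_lesion + e0`
#' and `followup = systematic part + arm * tau(voxel) + e1`, with the
#' random intercepts shared between timepoints and the voxel noise drawn
#' independently per timepoint. Planted effects use the same quartile,
#' band and component operators as the analysis, so ground truth and
#' analysis labels agree by construction. Placebo subjects have an
#' identically-zero truth volume.
#'
#' @param config a [trial_config()].
#' @return Object of class `mtr_trial`: list with `config`, `atlas`,
#'   `patients` (with `arm`), `band_map` (`NULL` unless band-dependent
#'   effects were planted), and `subjects` — one list per patient holding
#'   `lesion_labels`, `lesion_table`, `depth`, `mtr_baseline`,
#'   `mtr_followup`, `t1w`, `truth`.
#' @export
simulate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  spec <- config$effect_spec
  with_seed(config$seed, {
    atlas <- generate_atlas(config$grid_shape, seed = config$seed)
    patients <- assign_arms(make_patients(config$n_patients))

    # force at least one cohort-wide lesion of each requested class
    counts <- t(vapply(seq_len(config$n_patients), function(i)
      vapply(config$lesions_per_patient, function(m) stats::rpois(1L, m), 1L),
      integer(length(config$lesions_per_patient))))
    colnames(counts) <- names(config$lesions_per_patient)
    for (cl in colnames(counts)) {
      if (config$lesions_per_patient[[cl]] > 0 && sum(counts[, cl]) == 0L) {
        counts[1L, cl] <- 1L
      }
    }

    nv <- prod(config$grid_shape)
    subjects <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      pl <- plant_lesions(atlas, config, counts = counts[i, ])
      depth <- lesion_depth(pl$labels > 0L, config$connectivity)
      n_les <- nrow(pl$table)
      b_patient <- stats::rnorm(1L, 0, config$sigma_patient)
      b_lesion <- if (n_les) stats::rnorm(n_les, 0, config$sigma_lesion) else numeric(0)
      sig <- subject_signal(atlas, pl$labels, depth, config, b_patient, b_lesion)
      baseline <- sig + stats::rnorm(nv, 0, config$sigma_voxel)
      t1w <- config$t1_coupling$intercept +
        config$t1_coupling$slope * baseline +
        stats::rnorm(nv, 0, config$t1_coupling$sigma)
      dim(baseline) <- dim(t1w) <- config$grid_shape
      subjects[[i]] <- list(patient = patients[i, ],
                            lesion_labels = pl$labels,
                            lesion_table = pl$table,
                            depth = depth,
                            signal = sig,
                            mtr_baseline = baseline,
                            t1w = t1w)
    }

    # cohort-level voxel quartile cutpoints, only if quartile effects planted
    cuts_by_tissue <- list()
    if (any(spec$quartile_multipliers != 1)) {
      pool <- lapply(subjects, function(s) {
        idx <- which(s$lesion_labels > 0L)
        data.frame(tis = tissue_name(atlas[idx]), val = s$mtr_baseline[idx])
      })
      pool <- do.call(rbind, pool)
      for (tt in unique(pool$tis)) {
        v <- pool$val[pool$tis == tt]
        if (length(v) >= 4L) cuts_by_tissue[[tt]] <- fit_cutpoints(v, "quartiles")
      }
    }
    band_map <- NULL
    if (any(spec$wmdgm_band_multipliers != 1) ||
        any(spec$cgm_band_multipliers != 1)) {
      band_map <- build_bands(atlas)
    }

    for (i in seq_len(config$n_patients)) {
      s <- subjects[[i]]
      idx <- which(s$lesion_labels > 0L)
      truth <- array(0, dim = config$grid_shape)
      if (s$patient$arm == "active" && length(idx)) {
        truth[idx] <- planted_tau(idx, atlas, s$depth, s$mtr_baseline,
                                  spec, band_map, cuts_by_tissue)
      }
      followup <- s$signal + truth + stats::rnorm(nv, 0, config$sigma_voxel)
      dim(followup) <- config$grid_shape
      subjects[[i]]$mtr_followup <- followup
      subjects[[i]]$truth <- truth
      subjects[[i]]$signal <- NULL
    }
    structure(list(config = config, atlas = atlas, patients = patients,
                   band_map = band_map, subjects = subjects),
              class = "mtr_trial")
  })
}

#' @export
print.mtr_trial <- function(x, ...) {
  n_les <- sum(vapply(x$subjects, function(s) nrow(s$lesion_table), 1L))
  cat(sprintf("mtr_trial: %d patients (%d active / %d placebo), %d lesions, grid %s\n",
              nrow(x$patients), sum(x$patients$arm == "active"),
              sum(x$patients$arm == "placebo"), n_les,
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

# ---- correlation calibration -----------------------------------------

# Pooled variance of the noiseless lesional signal (systematic profile
# plus shared random intercepts), estimated from a noise-free run.
signal_variance <- function(config, n_subjects = 8L) {
  cfg <- config
  cfg$sigma_voxel <- 0
  cfg$n_patients <- as.integer(max(4L, n_subjects))
  cfg$effect_spec <- null_effect_spec()
  tr <- simulate_trial(cfg)
  vals <- unlist(lapply(tr$subjects, function(s)
    s$mtr_baseline[s$lesion_labels > 0L]))
  stats::var(vals)
}

#' Closed-form placebo baseline/follow-up voxel correlation
#'
#' Both timepoints share the same signal S (systematic profile plus
#' patient and lesion intercepts) and differ by independent voxel noise,
#' so the pooled lesional-voxel Pearson correlation is
#' `r = var(S) / (var(S) + sigma_voxel^2)`.
#'
#' @param config a [trial_config()].
#' @param var_signal optional known signal variance; estimated from a
#'   noise-free simulation when `NULL`.
#' @param n_subjects subjects used for the signal-variance estimate.
#' @return Predicted Pearson correlation.
#' @export
predicted_voxel_correlation <- function(config, var_signal = NULL, n_subjects = 8L) {
  if (is.null(var_signal)) var_signal <- signal_variance(config, n_subjects)
  var_signal / (var_signal + config$sigma_voxel^2)
}

#' Calibrate voxel noise to a target correlation
#'
#' Inverts the closed-form correlation identity: given a target placebo
#' baseline/follow-up lesional-voxel correlation r, sets
#' `sigma_voxel = sqrt(var(S) * (1/r - 1))`.
#'
#' @param config a [trial_config()].
#' @param target_r target Pearson correlation in (0, 1).
#' @param n_subjects subjects used for the signal-variance estimate.
#' @return The config with `sigma_voxel` replaced.
#' @export
calibrate_sigma_voxel <- function(config, target_r = 0.85, n_subjects = 8L) {
  stopifnot(target_r > 0, target_r < 1)
  vs <- signal_variance(config, n_subjects)
  config$sigma_voxel <- sqrt(vs * (1 / target_r - 1))
  config
}

#' Measured placebo lesional-voxel baseline/follow-up correlation
#'
#' @param trial an [simulate_trial()] result.
#' @return Pearson correlation over all placebo subjects' lesional voxels.
#' @export
placebo_voxel_correlation <- function(trial) {
  pl <- trial$subjects[vapply(trial$subjects, function(s)
    s$patient$arm == "placebo", TRUE)]
  b <- unlist(lapply(pl, function(s) s$mtr_baseline[s$lesion_labels > 0L]))
  f <- unlist(lapply(pl, function(s) s$mtr_followup[s$lesion_labels > 0L]))
  if (length(b) < 3L) stop("too few placebo lesional voxels", call. = FALSE)
  stats::cor(b, f)
}
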