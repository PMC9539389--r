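test_that("simulation is deterministic under a fixed seed", {
  cfg <- scaled_trial_config(seed = 101)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$patients, t2$patients)
  expect_identical(t1$subjects[[1]]$mtr_baseline, t2$subjects[[1]]$mtr_baseline)
  expect_identical(t1$subjects[[5]]$lesion_labels, t2$subjects[[5]]$lesion_labels)
  t3 <- simulate_trial(scaled_trial_config(seed = 102))
  expect_false(identical(t1$subjects[[1]]$mtr_baseline,
                         t3$subjects[[1]]$mtr_baseline))
})

test_that("arm assignment is balanced within each minimisation stratum", {
  for (seed in c(1, 2, 3)) {
    tr <- simulate_trial(scaled_trial_config(seed = seed, n_patients = 20))
    p <- tr$patients
    strata <- interaction(p$age_band, p$gender, p$centre, p$edss_band, drop = TRUE)
    for (s in levels(strata)) {
      tab <- table(p$arm[strata == s])
      expect_lte(abs(tab[["active"]] - tab[["placebo"]]), 1)
    }
    expect_lte(abs(sum(p$arm == "active") - sum(p$arm == "placebo")), 1)
  }
})

test_that("lesions avoid CSF, stay disjoint, and record their tissue class", {
  tr <- simulate_trial(scaled_trial_config(seed = 103))
  for (s in tr$subjects) {
    idx <- which(s$lesion_labels > 0)
    expect_false(any(tr$atlas[idx] %in% CSF_LABELS))
    # labels equal recomputed connected components (lesions never merge)
    lab <- label_components(s$lesion_labels > 0, tr$config$connectivity)
    expect_equal(attr(lab, "n"), nrow(s$lesion_table))
    for (j in seq_len(nrow(s$lesion_table))) {
      vox <- which(s$lesion_labels == s$lesion_table$lesion_id[j])
      expect_equal(classify_tissue(vox, tr$atlas), s$lesion_table$tissue_class[j])
    }
  }
  classes <- unlist(lapply(tr$subjects, function(s) s$lesion_table$tissue_class))
  expect_true(any(classes == "wm"))
  expect_true(any(classes %in% c("cgm", "dgm")))
  expect_true(any(classes == "mixed"))
})

test_that("a zero-lesion configuration yields empty masks and still runs", {
  cfg <- scaled_trial_config(seed = 104,
                             lesions_per_patient = c(wm = 0, cgm = 0, dgm = 0,
                                                     cbgm = 0, mixed = 0))
  tr <- simulate_trial(cfg)
  expect_true(all(vapply(tr$subjects, function(s) sum(s$lesion_labels), 0) == 0))
  expect_true(all(vapply(tr$subjects, function(s) nrow(s$lesion_table), 0L) == 0L))
})

test_that("noiseless null trial has identical baseline and follow-up", {
  cfg <- scaled_trial_config(seed = 105, effect_spec = null_effect_spec(),
                             sigma_patient = 0, sigma_lesion = 0, sigma_voxel = 0)
  tr <- simulate_trial(cfg)
  for (s in tr$subjects) {
    expect_equal(s$mtr_followup, s$mtr_baseline, tolerance = 1e-12)
    expect_true(all(s$truth == 0))
  }
})

test_that("noiseless uniform effect appears exactly in active lesional voxels", {
  es <- effect_spec(tau_by_tissue = c(wm = 1.5, cgm = 1.5, dgm = 1.5, cbgm = 1.5))
  cfg <- scaled_trial_config(seed = 106, effect_spec = es,
                             sigma_patient = 0, sigma_lesion = 0, sigma_voxel = 0)
  tr <- simulate_trial(cfg)
  for (s in tr$subjects) {
    diff <- s$mtr_followup - s$mtr_baseline
    lesional <- s$lesion_labels > 0
    if (s$patient$arm == "active") {
      expect_equal(unique(round(diff[lesional], 10)), 1.5)
      expect_equal(unique(round(s$truth[lesional], 10)), 1.5)
    } else {
      expect_true(all(s$truth == 0))
      expect_equal(max(abs(diff)), 0)
    }
    expect_equal(max(abs(diff[!lesional])), 0)
  }
})

test_that("T1-weighted volume is a linear transform of baseline MTR plus noise", {
  cfg <- scaled_trial_config(seed = 107,
                             t1_coupling = list(intercept = 200, slope = 15, sigma = 0))
  tr <- simulate_trial(cfg)
  s <- tr$subjects[[1]]
  expect_equal(s$t1w, 200 + 15 * s$mtr_baseline, tolerance = 1e-10)
})

test_that("placebo voxel correlation follows the closed-form oracle", {
  # spec'd reference point: sigma_voxel = 2 pu with an 8 pu central deficit
  cfg <- scaled_trial_config(seed = 108, n_patients = 26,
                             lesions_per_patient = c(wm = 9, cgm = 2, dgm = 1,
                                                     cbgm = 0, mixed = 2),
                             lesion_radius_range = c(2, 4),
                             sigma_voxel = 2.0, lesion_mtr_deficit = 8)
  tr <- simulate_trial(cfg)
  n_vox <- sum(vapply(tr$subjects, function(s)
    if (s$patient$arm == "placebo") sum(s$lesion_labels > 0) else 0L, 0L))
  expect_gte(n_vox, 1e4)
  r_measured <- placebo_voxel_correlation(tr)
  # the interval width covers Monte-Carlo error in both the measured r and
  # the signal-variance estimate (lesion draws differ between cohorts)
  r_predicted <- predicted_voxel_correlation(cfg, n_subjects = 16)
  expect_lt(abs(r_measured - r_predicted), 0.05)
})

test_that("global RNG state is untouched by simulation", {
  set.seed(999)
  before <- .Random.seed
  invisible(simulate_trial(scaled_trial_config(seed = 109)))
  expect_identical(.Random.seed, before)
})
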