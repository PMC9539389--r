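trial_fixture <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) tr <<- simulate_trial(scaled_trial_config(seed = 120))
    tr
  }
})

test_that("lesion unit table matches direct per-lesion averaging", {
  tr <- trial_fixture()
  lt <- lesion_unit_table(tr)
  expect_equal(nrow(lt), sum(vapply(tr$subjects, function(s) nrow(s$lesion_table), 1L)))
  s <- tr$subjects[[3]]
  for (j in seq_len(min(3, nrow(s$lesion_table)))) {
    id <- s$lesion_table$lesion_id[j]
    vox <- which(s$lesion_labels == id)
    row <- lt[lt$lesion_id == paste0(s$patient$patient_id, "_L", id), ]
    expect_equal(row$baseline, mean(s$mtr_baseline[vox]))
    expect_equal(row$followup, mean(s$mtr_followup[vox]))
    expect_equal(row$size, length(vox))
  }
})

test_that("stripping WM outer layers drops lesions with empty interiors", {
  tr <- trial_fixture()
  full <- lesion_unit_table(tr)
  stripped <- lesion_unit_table(tr, strip_wm = TRUE)
  expect_lte(nrow(stripped), nrow(full))
  expect_identical(stripped[stripped$tissue != "wm", c("lesion_id", "baseline")],
                   full[full$tissue != "wm" & full$lesion_id %in% stripped$lesion_id,
                        c("lesion_id", "baseline")])
})

test_that("component table regions are consistent with the decomposition", {
  tr <- trial_fixture()
  ct <- component_unit_table(tr)
  expect_true(all(ct$component %in% c("core", "rim", "cuff1", "cuff2", "cuff3")))
  # every lesion has a rim row; cores only where the interior is nonempty
  lt <- lesion_unit_table(tr)
  rims <- ct[ct$component == "rim", ]
  expect_setequal(rims$lesion_id, lt$lesion_id)
  s <- tr$subjects[[1]]
  dec <- decompose_lesions(s$lesion_labels, tr$atlas, tr$config$connectivity)
  id <- s$lesion_table$lesion_id[1]
  gl <- paste0(s$patient$patient_id, "_L", id)
  core_vox <- which(dec$core == id)
  if (length(core_vox)) {
    expect_equal(ct$baseline[ct$lesion_id == gl & ct$component == "core"],
                 mean(s$mtr_baseline[core_vox]))
  }
})

test_that("voxel tables honour tissue purity, stripping and the cap", {
  tr <- trial_fixture()
  vt <- voxel_unit_table(tr, "wm")
  expect_true(all(tr$atlas[vt$voxel] == TISSUE_LABELS[["wm"]]))
  # stripped: no rim (depth 1) voxels remain
  s_ids <- split(vt, vt$patient_id)
  one <- s_ids[[1]]
  s <- tr$subjects[[which(vapply(tr$subjects, function(s)
    s$patient$patient_id == one$patient_id[1], TRUE))]]
  expect_true(all(s$depth[one$voxel] >= 2))
  # unstripped contains the stripped set
  vt_all <- voxel_unit_table(tr, "wm", strip_wm = FALSE)
  expect_gt(nrow(vt_all), nrow(vt))
  # cap subsamples deterministically
  c1 <- voxel_unit_table(tr, "wm", cap = 200L)
  c2 <- voxel_unit_table(tr, "wm", cap = 200L)
  expect_equal(nrow(c1), 200)
  expect_identical(c1, c2)
})

test_that("segment tables partition eligible voxels into quartile regions", {
  tr <- trial_fixture()
  st <- segment_unit_table(tr, "wm", "mtr")
  vt <- voxel_unit_table(tr, "wm", cap = .Machine$integer.max)
  expect_equal(sum(st$n_vox), nrow(vt))
  expect_true(all(st$stratum %in% 1:4))
  expect_lte(max(table(st$lesion_id)), 4)
  # T1-defined segments use the T1 variable for grouping
  st_t1 <- segment_unit_table(tr, "wm", "t1")
  expect_equal(sum(st_t1$n_vox), nrow(vt))
  expect_false(identical(st$n_vox, st_t1$n_vox))
})

test_that("the analysis suite emits coherent report rows on a small trial", {
  tr <- trial_fixture()
  rep <- run_analysis_suite(tr, voxel_cap = 3000L)
  r <- rep$results
  expect_true(all(c("lesion", "component", "segment", "voxel") %in% r$level))
  expect_true(all(r$lo <= r$estimate & r$estimate <= r$hi, na.rm = TRUE))
  expect_true(all(r$p > 0 & r$p <= 1, na.rm = TRUE))
  expect_true(all(r$p_interaction > 0 & r$p_interaction <= 1, na.rm = TRUE))
  # one row per non-skipped level x tissue x factor x subgroup combination
  expect_false(any(duplicated(r[, c("level", "tissue", "factor", "subgroup")])))
  txt <- render_report(rep)
  expect_gt(length(txt), nrow(r))
})
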