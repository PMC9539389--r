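wm_atlas <- function(d) array(TISSUE_LABELS[["wm"]], d)

test_that("tissue classification distinguishes pure and mixed lesions", {
  d <- c(6, 6, 6)
  atlas <- wm_atlas(d)
  atlas[4, , ] <- TISSUE_LABELS[["cgm"]]
  atlas[5, , ] <- TISSUE_LABELS[["dgm"]]

  expect_equal(classify_tissue(which(array(seq_len(prod(d)), d) %in% 1:3), atlas), "wm")
  vox_wm <- c(1L, 2L, 3L)
  vox_mix <- c(vox_wm, which(atlas == TISSUE_LABELS[["cgm"]])[1])
  expect_equal(classify_tissue(vox_mix, atlas), "mixed")
  expect_equal(classify_tissue(which(atlas == TISSUE_LABELS[["dgm"]])[1:4], atlas), "dgm")

  atlas[1, 1, 1] <- TISSUE_LABELS[["vcsf"]]
  expect_error(classify_tissue(c(1L, 2L), atlas), "CSF")
  expect_error(classify_tissue(integer(0), atlas), "empty")
})

test_that("core/rim partition the lesion and a point lesion has empty core", {
  d <- c(7, 7, 7)
  m <- array(FALSE, d)
  m[3:5, 3:5, 3:5] <- TRUE
  cr <- split_core_rim(m, 6)
  expect_equal(cr$core | cr$rim, m)
  expect_false(any(cr$core & cr$rim))

  pt <- array(FALSE, d); pt[4, 4, 4] <- TRUE
  cr <- split_core_rim(pt, 6)
  expect_equal(sum(cr$core), 0)
  expect_equal(which(cr$rim), which(pt))
  expect_equal(strip_outer_layer(pt, 6), erode_mask(pt, 6))
})

test_that("strip_outer_layer equals the core for random components", {
  set.seed(41)
  for (conn in c(6, 26)) {
    m <- random_mask(c(9, 9, 9), 0.3)
    expect_equal(strip_outer_layer(m, conn), split_core_rim(m, conn)$core)
  }
})

test_that("isolated point lesion has octahedral cuff shells 6/18/38", {
  d <- c(9, 9, 9)
  m <- array(FALSE, d); m[5, 5, 5] <- TRUE
  lab <- label_components(m, 6)
  cf <- make_cuffs(lab, wm_atlas(d), 6)
  expect_equal(sum(cf$ring == 1), 6)
  expect_equal(sum(cf$ring == 2), 18)
  expect_equal(sum(cf$ring == 3), 38)
  expect_equal(cf$n_excluded, 0)
})

test_that("voxels claimed by two lesions' cuffs are excluded from both", {
  d <- c(11, 7, 7)
  m <- array(FALSE, d)
  m[3, 4, 4] <- TRUE
  m[7, 4, 4] <- TRUE   # 3 voxels apart along x; midline voxel (5,4,4)
  lab <- label_components(m, 6)
  cf <- make_cuffs(lab, wm_atlas(d), 6)
  mid <- which(array(FALSE, d) | (slice.index(m, 1) == 5 &
                                    slice.index(m, 2) == 4 &
                                    slice.index(m, 3) == 4))
  expect_true(cf$excluded[mid])
  expect_equal(cf$owner[mid], 0L)
  expect_gte(cf$n_excluded, 1)
})

test_that("cuffs avoid CSF and lesional tissue", {
  d <- c(9, 9, 9)
  atlas <- wm_atlas(d)
  atlas[1:3, , ] <- TISSUE_LABELS[["vcsf"]]
  m <- array(FALSE, d)
  m[4, 4:5, 4:5] <- TRUE  # lesion hugging the CSF boundary
  lab <- label_components(m, 6)
  cf <- make_cuffs(lab, atlas, 6)
  cuff_vox <- which(cf$ring > 0)
  expect_false(any(atlas[cuff_vox] %in% CSF_LABELS))
  expect_false(any(m[cuff_vox]))
})

test_that("decomposition table is internally consistent", {
  set.seed(51)
  d <- c(12, 12, 12)
  atlas <- wm_atlas(d)
  m <- array(FALSE, d)
  m[3:5, 3:5, 3:5] <- TRUE
  m[8:9, 8:9, 8:9] <- TRUE
  lab <- label_components(m, 6)
  dec <- decompose_lesions(lab, atlas, 6)
  tab <- dec$table
  expect_equal(nrow(tab), 2)
  expect_equal(tab$core_size + tab$rim_size, tab$size)
  expect_equal(tab$size, c(27L, 8L))
  expect_equal(tab$core_size, c(1L, 0L))  # 2x2x2 lesion has empty core
  # cuff regions never intersect lesions
  expect_false(any(m[dec$cuff_owner > 0]))
})

test_that("restricting cuffs to the lesion tissue class drops other-tissue voxels", {
  d <- c(9, 9, 9)
  atlas <- wm_atlas(d)
  atlas[6:9, , ] <- TISSUE_LABELS[["cgm"]]
  m <- array(FALSE, d)
  m[5, 4:5, 4:5] <- TRUE  # WM lesion at the WM/CGM border
  lab <- label_components(m, 6)
  free <- make_cuffs(lab, atlas, 6)
  restricted <- make_cuffs(lab, atlas, 6, restrict_to_tissue = TRUE)
  expect_true(any(atlas[free$ring > 0] == TISSUE_LABELS[["cgm"]]))
  expect_true(all(atlas[restricted$ring > 0] == TISSUE_LABELS[["wm"]]))
})
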