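test_that("distance transform agrees with all-pairs brute force", {
  set.seed(61)
  for (i in 1:4) {
    d <- c(10, 10, 10)
    src <- random_mask(d, 0.05)
    if (!any(src)) src[1, 1, 1] <- TRUE
    expect_equal(distance_transform(src), oracle_edt(src), tolerance = 1e-9)
  }
  # anisotropic spacing honoured
  src <- array(FALSE, c(8, 8, 8)); src[1, , ] <- TRUE
  dt <- distance_transform(src, pixdim = c(2, 1, 1))
  expect_equal(dt[5, 4, 4], 8)  # 4 voxels * 2 mm
})

test_that("slab phantom band boundaries sit at analytic positions", {
  # 1-D geometry: ventricular CSF plane at x = 1..2, WM slab x = 3..42,
  # outer CSF and CGM arranged so build_bands runs.
  d <- c(46, 8, 8)
  atlas <- array(TISSUE_LABELS[["wm"]], d)
  atlas[1:2, , ] <- TISSUE_LABELS[["vcsf"]]
  atlas[43:44, , ] <- TISSUE_LABELS[["cgm"]]
  atlas[45:46, , ] <- TISSUE_LABELS[["ocsf"]]
  bm <- build_bands(atlas)
  wm_x <- 3:42
  dist_along_x <- wm_x - 2          # distance to the x = 2 CSF face
  width <- max(dist_along_x) / 10   # 4 voxels per raw band
  raw_expected <- ceiling(dist_along_x / width)
  got_raw <- bm$wmdgm_raw[cbind(wm_x, 4, 4)]
  expect_equal(got_raw, raw_expected)
  # bands 1 and 10 excluded, survivors renumbered 1..8
  expect_true(all(is.na(bm$wmdgm_band[cbind(3:6, 4, 4)])))
  expect_true(all(is.na(bm$wmdgm_band[cbind(39:42, 4, 4)])))
  expect_equal(bm$wmdgm_band[cbind(7:38, 4, 4)], rep(1:8, each = 4))
})

test_that("band index is non-decreasing along a ray from the ventricles", {
  a <- generate_atlas(36, seed = 2)
  bm <- build_bands(a)
  centre <- 18
  ray <- bm$wmdgm_raw[centre:36, centre, centre]
  ray <- ray[!is.na(ray)]
  expect_true(all(diff(ray) >= 0))
})

test_that("every WM/DGM voxel is banded or excluded; counts partition", {
  a <- generate_atlas(32, seed = 1)
  bm <- build_bands(a)
  wmdgm <- a == TISSUE_LABELS[["wm"]] | a == TISSUE_LABELS[["dgm"]]
  expect_true(all(!is.na(bm$wmdgm_raw[wmdgm])))
  expect_true(all(is.na(bm$wmdgm_raw[!wmdgm])))
  n_banded <- sum(!is.na(bm$wmdgm_band))
  n_excluded <- sum(wmdgm) - n_banded
  expect_equal(n_banded + n_excluded, sum(wmdgm))
  expect_true(all(bm$wmdgm_band[!is.na(bm$wmdgm_band)] %in% 1:8))
  # CGM split: outer band nearer the outer CSF than inner band
  cgm <- !is.na(bm$cgm_band)
  expect_lt(mean(bm$dist_outer[cgm & bm$cgm_band == 2]),
            mean(bm$dist_outer[cgm & bm$cgm_band == 1]))
})

test_that("lesion band assignment uses plurality with low tie-break", {
  a <- generate_atlas(32, seed = 1)
  bm <- build_bands(a)
  pick <- function(band, n) which(!is.na(bm$wmdgm_band) & bm$wmdgm_band == band)[1:n]
  expect_equal(assign_lesion_band(pick(3, 8), bm, "wmdgm"), 3L)
  expect_equal(assign_lesion_band(c(pick(4, 10), pick(5, 3)), bm, "wmdgm"), 4L)
  expect_equal(assign_lesion_band(c(pick(2, 5), pick(3, 5)), bm, "wmdgm"), 2L)
  # no banded voxels -> NA
  unbanded <- which(is.na(bm$wmdgm_band) & !is.na(bm$wmdgm_raw))[1:3]
  expect_true(is.na(assign_lesion_band(unbanded, bm, "wmdgm")))
})

test_that("degenerate atlases raise compartment errors", {
  d <- c(32, 32, 32)
  atlas <- array(TISSUE_LABELS[["wm"]], d)
  expect_error(build_bands(atlas), "CSF")
})
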