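# Flattening, ROI construction, standardization, I/O and visit tables.

flat_surfaces <- function(W, D, ilm_um, bm_um) {
  layer_surfaces(matrix(ilm_um, W, D), matrix(bm_um, W, D))
}

test_that("flattening leaves a planar BM untouched and is idempotent", {
  set.seed(11)
  v <- oct_volume(array(rnorm(16 * 8 * 4), c(16, 8, 4)),
                  spacing = c(10, 100, 300))
  target <- 10L
  s <- flat_surfaces(8, 4, 20, 100)  # BM at row 10 everywhere
  out <- flatten_volume(v, s, target_row = target)
  expect_equal(out$voxels, v$voxels)
  # idempotence on a non-planar BM
  s2 <- layer_surfaces(matrix(20, 8, 4),
                       matrix(100 + 10 * (seq_len(8) - 4), 8, 4))
  f1 <- flatten_volume(v, s2, target_row = target)
  s2_flat <- flatten_surfaces(s2, v, target_row = target)
  f2 <- flatten_volume(f1, s2_flat, target_row = target)
  expect_equal(f2$voxels, f1$voxels)
  # BM row variance is zero after flattening (recomputed from surfaces)
  bm_rows <- round(s2_flat$bm / v$spacing[1])
  expect_equal(stats::var(as.numeric(bm_rows)), 0)
})

test_that("tilted BM flattening matches a direct index-shift oracle", {
  set.seed(12)
  H <- 12L; W <- 8L; D <- 2L
  v <- oct_volume(array(rnorm(H * W * D), c(H, W, D)),
                  spacing = c(10, 100, 300))
  # BM slope: one voxel per column, reference column 4
  bm_um <- matrix(10 * (4 + (seq_len(W) - 4)), W, D)
  s <- layer_surfaces(matrix(10, W, D), bm_um)
  target <- 4L
  out <- flatten_volume(v, s, target_row = target, fill = -1)
  for (w in seq_len(W)) {
    shift <- target - (4 + (w - 4))  # = -(w - 4)
    for (h in seq_len(H)) {
      src <- h - shift
      expected <- if (src >= 1 && src <= H) v$voxels[src, w, 1] else -1
      expect_equal(out$voxels[h, w, 1], expected)
    }
  }
})

test_that("flattening validates surface grids", {
  v <- oct_volume(array(0, c(8, 4, 2)))
  bad <- layer_surfaces(matrix(5, 3, 2), matrix(50, 3, 2))
  expect_error(flatten_volume(v, bad), "en-face grid")
  expect_error(layer_surfaces(matrix(NaN, 4, 2), matrix(1, 4, 2)), "finite")
  expect_error(layer_surfaces(matrix(10, 4, 2), matrix(5, 4, 2)), "bm")
})

test_that("ROI mask reproduces the margin arithmetic", {
  # ILM row 50, BM row 100 at 3.4 um spacing -> rows 42..150
  sp <- 3.4
  H <- 200L
  v <- oct_volume(array(0, c(H, 2, 1)), spacing = c(sp, 100, 300))
  s <- flat_surfaces(2, 1, 50 * sp, 100 * sp)
  m <- build_roi_mask(s, v)
  on_rows <- which(m$mask[, 1, 1] == 1) - 1L  # 0-based
  expect_equal(range(on_rows), c(42L, 150L))
  # single contiguous run
  expect_equal(on_rows, seq(42L, 150L))
})

test_that("degenerate and clamped ROI bands behave per contract", {
  sp <- 5
  v <- oct_volume(array(0, c(80, 2, 1)), spacing = c(sp, 100, 300))
  # ILM == BM: band width round(26/sp) + round(169/sp) + 1
  s <- flat_surfaces(2, 1, 100, 100)
  m <- build_roi_mask(s, v)
  expect_equal(sum(m$mask[, 1, 1]),
               round(26 / sp) + round(169 / sp) + 1)
  # BM + 169 um beyond the bottom: clamped, no error
  s2 <- flat_surfaces(2, 1, 330, 390)  # bm row 78; +169 um extends past 79
  m2 <- build_roi_mask(s2, v)
  expect_equal(max(which(m2$mask[, 1, 1] == 1)), 80L)  # last row (1-based)
})

test_that("ROI mask is monotone in its margins", {
  set.seed(13)
  v <- oct_volume(array(0, c(60, 6, 3)), spacing = c(5, 100, 300))
  s <- layer_surfaces(matrix(runif(18, 80, 120), 6, 3),
                      matrix(runif(18, 150, 200), 6, 3))
  m1 <- build_roi_mask(s, v, margin_above = 26, margin_below = 169)
  m2 <- build_roi_mask(s, v, margin_above = 60, margin_below = 250)
  expect_true(all(m2$mask[m1$mask == 1] == 1))
})

test_that("standardization rescales, crops and preserves the mask fraction", {
  set.seed(14)
  # already 3x3 mm and target-shaped: pure rescale
  shp <- c(32L, 24L, 8L)
  v <- oct_volume(array(runif(prod(shp), 0, 255), shp),
                  spacing = c(10, 3000 / 24, 3000 / 8))
  roi <- structure(list(mask = array(1, shp)), class = "roi_mask")
  out <- standardize_volume(v, roi, target_shape = shp)
  expect_equal(min(out$volume$voxels), -1)
  expect_equal(max(out$volume$voxels), 1)
  expect_equal(dim(out$volume$voxels), shp)
  # ordering of intensities is preserved (monotone rescale)
  o <- order(v$voxels[, 1, 1])
  expect_equal(order(out$volume$voxels[, 1, 1]), o)

  # 6x6 mm field: center voxel kept, corner removed
  v2 <- oct_volume(array(0, c(16, 24, 8)), spacing = c(10, 6000 / 24, 6000 / 8))
  v2$voxels[8, 12, 4] <- 100   # en-face center
  v2$voxels[8, 1, 1] <- 100    # en-face corner
  roi2 <- structure(list(mask = array(0, dim(v2$voxels))), class = "roi_mask")
  out2 <- standardize_volume(v2, roi2, target_shape = c(16L, 12L, 4L))
  expect_gt(max(out2$volume$voxels), 0.9)      # bright center retained
  expect_equal(sum(out2$volume$voxels > 0.9), sum(out2$volume$voxels == 1))
  corner_region <- out2$volume$voxels[, 1:2, 1]
  expect_true(all(corner_region < 0.5))        # corner cropped away

  # mask volume fraction preserved within 2% through the resize
  set.seed(15)
  shp3 <- c(64L, 48L, 16L)
  v3 <- oct_volume(array(runif(prod(shp3)), shp3),
                   spacing = c(10, 3000 / 48, 3000 / 16))
  mask3 <- array(0, shp3)
  mask3[20:45, , ] <- 1
  roi3 <- structure(list(mask = mask3), class = "roi_mask")
  out3 <- standardize_volume(v3, roi3, target_shape = c(32L, 24L, 8L))
  expect_lt(abs(mean(out3$roi$mask) - mean(mask3)), 0.02)
  expect_true(all(out3$roi$mask %in% c(0, 1)))
})

test_that("standardization rejects small fields of view and flags constants", {
  v <- oct_volume(array(0, c(16, 8, 4)), spacing = c(10, 100, 100))
  roi <- structure(list(mask = array(1, c(16, 8, 4))), class = "roi_mask")
  expect_error(standardize_volume(v, roi, target_shape = c(16L, 8L, 4L)),
               "field of view")
  v2 <- oct_volume(array(5, c(16, 8, 4)), spacing = c(10, 3000 / 8, 3000 / 4))
  expect_warning(out <- standardize_volume(v2, roi,
                                           target_shape = c(16L, 8L, 4L)),
                 "constant")
  expect_true(all(out$volume$voxels == -1))
})

test_that("volume I/O round-trips voxels and metadata", {
  set.seed(16)
  dir <- withr_local_tempdir()
  v <- oct_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
                  spacing = c(3.4, 11.7, 60.2), eye_id = "eyeA",
                  visit_time = 7.5)
  p <- file.path(dir, "vol.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(v2$voxels, v$voxels)           # bit-exact
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$eye_id, "eyeA")
  expect_equal(v2$visit_time, 7.5)
  # missing file and missing parent errors
  expect_error(read_volume(file.path(dir, "nope.nii")), "no such file")
  expect_error(write_volume(v, file.path(dir, "nodir", "x.nii")),
               "parent directory")
  # wrong dimensionality
  img2d <- RNifti::asNifti(matrix(1:4, 2))
  p2 <- file.path(dir, "flat.nii")
  RNifti::writeNifti(img2d, p2)
  expect_error(read_volume(p2), "3D")
  # missing sidecar: defaults applied and flagged
  file.remove(sub("\\.nii\\.gz$", ".json", p))
  v3 <- read_volume(p)
  expect_equal(v3$spacing, v$spacing, tolerance = 1e-4)  # pixdim fallback
})

test_that("visit tables validate and round-trip with censoring blanks", {
  dir <- withr_local_tempdir()
  df <- tibble::tibble(eye_id = c("e1", "e1", "e2"),
                       visit_time_months = c(0, 3.5, 0),
                       path = c("a.nii", "b.nii", "c.nii"),
                       t_minus_months = c(2, NA, 1),
                       t_plus_months = c(5, NA, 4))
  p <- file.path(dir, "visits.csv")
  write_visit_table(df, p)
  df2 <- read_visit_table(p)
  expect_equal(df2$t_minus_months, df$t_minus_months)
  expect_true(is.na(df2$t_plus_months[2]))
  bad <- df; bad$t_minus_months[1] <- 9
  expect_error(write_visit_table(bad, p), "strictly below")
  bad2 <- df; bad2$visit_time_months[1] <- -1
  expect_error(write_visit_table(bad2, p), "non-negative")
})
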