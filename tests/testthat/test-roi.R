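test_that("a constant map interpolates to a constant heatmap over the CSI footprint", {
  m <- stub_ratio_map(matrix(0.42, 16, 16))
  hm <- interpolate_heatmap(m, target_shape = c(256, 256))
  inside <- !is.na(hm)
  expect_true(any(inside))
  expect_true(all(abs(hm[inside] - 0.42) < 1e-12))
  # pixels outside the 24 mm CSI FOV (within the 30 mm anatomical FOV) are NA
  expect_true(all(is.na(hm[1:20, ])))
  expect_true(all(is.na(hm[, 1:20])))
})

test_that("midway anatomical pixels take the mean of flanking CSI voxels", {
  vals <- matrix(1, 4, 4)
  vals[2, ] <- 2; vals[3, ] <- 4
  m <- stub_ratio_map(vals, fov_mm = 24)
  # 8x8 target over 24 mm: rows interleave the source rows exactly halfway
  hm <- interpolate_heatmap(m, target_shape = c(8, 8), target_fov_mm = 24)
  # source row centers sit at -9, -3, +3, +9 mm; target row 4 center is at
  # -1.5 mm, a quarter of the way from row 2 to row 3
  expect_equal(hm[4, 4], 0.75 * 2 + 0.25 * 4)
  # target row 3 center (-4.5 mm) is 3/4 of the way from row 1 to row 2
  expect_equal(hm[3, 4], 0.25 * 1 + 0.75 * 2)
})

test_that("masked source voxels propagate as missing, never interpolated", {
  vals <- matrix(1, 4, 4)
  vals[2, 2] <- NA
  m <- stub_ratio_map(vals)
  hm <- interpolate_heatmap(m, target_shape = c(64, 64))
  expect_true(any(is.na(hm[20:40, 20:40])))
  # far corner inside the footprint is untouched
  expect_false(is.na(hm[48, 48]))
  expect_equal(hm[48, 48], 1)
})

test_that("bilinear interpolation is exact for planar maps at interior points", {
  n <- 8
  vals <- outer(seq_len(n), seq_len(n), function(i, j) 0.2 + 0.03 * i - 0.01 * j)
  m <- stub_ratio_map(vals, fov_mm = 24)
  hm <- interpolate_heatmap(m, target_shape = c(128, 128), target_fov_mm = 24)
  # interior pixels (inside the outer voxel centers) must be exact
  pix <- 24 / 128
  mm <- (seq_len(128) - 64.5) * pix
  vox_mm <- 24 / n
  interior <- abs(mm) < (n / 2 - 1) * vox_mm
  ii <- which(interior); jj <- which(interior)
  truth <- outer(mm[ii], mm[jj], function(y, x)
    0.2 + 0.03 * (y / vox_mm + (n + 1) / 2) - 0.01 * (x / vox_mm + (n + 1) / 2))
  expect_lt(max(abs(hm[ii, jj] - truth)), 1e-10)
})

test_that("heatmap geometry validation rejects inconsistent FOVs", {
  m <- stub_ratio_map(matrix(1, 4, 4))
  expect_error(interpolate_heatmap(m, target_shape = c(2, 2)), "target shape")
  expect_error(interpolate_heatmap(m, target_fov_mm = 10), "FOV")
  expect_error(interpolate_heatmap(matrix(1, 4, 4)), "source_fov_mm")
})

test_that("anatomical masks transfer to the CSI grid by majority vote", {
  anat <- matrix(FALSE, 256, 256)
  anat[, 1:128] <- TRUE # left half in mm space
  m <- downsample_mask(anat, c(16, 16))
  expect_true(all(m[, 1:8]))
  expect_false(any(m[, 9:16]))
})

test_that("ROI means follow the quality mask and the stated conventions", {
  ratio <- matrix(NA_real_, 4, 4)
  ratio[1, 1] <- 0.3; ratio[1, 2] <- 0.5; ratio[2, 2] <- 9
  mask <- !is.na(ratio); mask[2, 2] <- FALSE # 9 is a non-quality voxel
  m <- stub_ratio_map(ratio, mask = mask)
  roi <- matrix(TRUE, 4, 4)
  r <- roi_mean(m, roi, "hemisphere")
  expect_equal(r$mean_ratio, 0.4) # mean of {0.3, 0.5}
  expect_equal(r$voxel_count, 2L)
  # adding fully masked voxels to the ROI changes nothing
  roi2 <- roi; roi2[3:4, ] <- TRUE
  expect_equal(roi_mean(m, roi2, "hemisphere")$mean_ratio, 0.4)
  # uniform ROI
  u <- stub_ratio_map(matrix(0.4, 3, 3))
  expect_equal(roi_mean(u, matrix(TRUE, 3, 3), "u")$mean_ratio, 0.4)
  expect_error(roi_mean(m, matrix(c(rep(FALSE, 15), TRUE), 4, 4), "empty1"),
               "empty1")
})

test_that("percent-of-contralateral arithmetic and guards", {
  expect_equal(percent_of_contralateral(0.548, 0.400), 37, tolerance = 1e-12)
  expect_equal(percent_of_contralateral(0.4, 0.4), 0)
  expect_equal(percent_of_contralateral(0.3, 0.4), -25)
  expect_error(percent_of_contralateral(0.5, 0), "contralateral")
  a <- stub_ratio_map(matrix(0.548, 2, 2))
  b <- stub_ratio_map(matrix(0.400, 2, 2))
  ra <- roi_mean(a, matrix(TRUE, 2, 2), "inj")
  rb <- roi_mean(b, matrix(TRUE, 2, 2), "con")
  expect_equal(percent_of_contralateral(ra, rb), 37, tolerance = 1e-9)
})

test_that("hemisphere means recover phantom ground truth on noiseless data", {
  cfg <- csi_config(n_frames = 8L)
  ph <- make_phantom(seed = 4)
  rmap <- csi_pipeline(synthesize_kspace(ph, cfg, noise_sd = 0, seed = 1))
  hm <- phantom_hemisphere_masks(ph)
  truth <- phantom_ratio_truth(ph, cfg)
  for (side in names(hm)) {
    m16 <- downsample_mask(hm[[side]], dim(rmap$ratio))
    m8 <- downsample_mask(hm[[side]], dim(truth))
    est <- roi_mean(rmap, m16, side)$mean_ratio
    tru <- mean(truth[m8 & !is.na(truth)])
    expect_lt(abs(est - tru) / tru, 0.05)
  }
})
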