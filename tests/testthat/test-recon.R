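test_that("zero-filling doubles the matrix and only adds exact zeros", {
  k <- array(complex(real = stats::rnorm(8 * 8 * 16),
                     imaginary = stats::rnorm(8 * 8 * 16)),
             dim = c(8, 8, 16))
  z <- zero_fill(k)
  expect_identical(dim(z), c(16L, 16L, 16L))
  # 192 of 256 spatial positions are zero for every FID point
  zero_per_point <- apply(z, 3, function(m) sum(m == 0))
  expect_true(all(zero_per_point >= 192))
  expect_identical(z[5:12, 5:12, ], k)
  expect_equal(sum(Mod(z)^2), sum(Mod(k)^2))
  expect_identical(zero_fill(array(0i, c(4, 4, 2))),
                   array(0i, c(8, 8, 2)))
  expect_error(zero_fill(array(0i, c(4, 6, 2))), "square")
})

test_that("a single-voxel phantom reconstructs at its location and offset", {
  cfg <- tiny_config()
  lab <- matrix(0L, 4, 4); lab[2, 3] <- 1L
  ph <- manual_phantom(lab, list(`1` = kinetic_params()))
  dat <- synthesize_kspace(ph, cfg, noise_sd = 0, seed = 1)
  summed <- sum_over_time(reconstruct(dat, zerofill = TRUE))
  pow <- apply(Mod(summed$spectra)^2, c(1, 2), sum)
  peak <- which(pow == max(pow), arr.ind = TRUE)
  # acquired voxel (2,3) maps to the 2x2 block rows 3:4, cols 5:6
  expect_true(peak[1] %in% 3:4 && peak[2] %in% 5:6)
  sp <- Mod(summed$spectra[peak[1], peak[2], ])
  f_at_max <- summed$frequency_axis[which.max(sp)]
  bin <- cfg$spectral_width_hz / cfg$n_fid_points
  expect_lt(abs(f_at_max - cfg$offsets_hz[["pyruvate"]]), bin + 1e-9)
})

test_that("reconstruction without zero-fill matches direct voxel spectra", {
  cfg <- tiny_config()
  ph <- make_phantom(grid_side = 4L, lesion_center = c(2, 3),
                     lesion_radius = 1, seed = 1)
  dat <- synthesize_kspace(ph, cfg, noise_sd = 0, seed = 1)
  frames <- reconstruct(dat, zerofill = FALSE)
  ref_fids <- synthesize_voxel_fids(ph, cfg)
  scale <- max(Mod(ref_fids))
  for (f in seq_len(cfg$n_frames)) {
    ref <- direct_voxel_spectra(array(ref_fids[f, , , ],
                                      dim = dim(ref_fids)[-1]))
    err <- max(Mod(frames[[f]]$spectra - ref)) / scale
    expect_lt(err, 1e-8)
  }
})

test_that("zero k-space reconstructs to zero spectra", {
  cfg <- tiny_config()
  dat <- structure(list(kspace = array(0i, c(cfg$n_frames, 4, 4,
                                             cfg$n_fid_points)),
                        config = cfg), class = "dynamic_csi")
  frames <- reconstruct(dat)
  expect_true(all(Mod(frames[[1]]$spectra) == 0))
})

test_that("spatial transform satisfies Parseval's identity per frame", {
  cfg <- tiny_config()
  ph <- make_phantom(grid_side = 4L, lesion_center = c(2, 3),
                     lesion_radius = 1, seed = 2)
  dat <- synthesize_kspace(ph, cfg, noise_sd = 0.3, seed = 3)
  frames <- reconstruct(dat, zerofill = FALSE)
  for (f in seq_len(cfg$n_frames)) {
    e_k <- sum(Mod(dat$kspace[f, , , ])^2)
    # spectra are a plain (non-unitary) FFT of the voxel FIDs along the
    # spectral dimension, so divide by n_fid_points
    e_img <- sum(Mod(frames[[f]]$spectra)^2) / cfg$n_fid_points
    expect_lt(abs(e_img - e_k) / e_k, 1e-10)
  }
})

test_that("translating the phantom translates the reconstruction circularly", {
  cfg <- tiny_config()
  lab <- matrix(0L, 4, 4); lab[2, 2] <- 1L; lab[3, 2] <- 2L
  prm <- list(`1` = kinetic_params(),
              `2` = kinetic_params(kpl_per_s = 0.3))
  sh <- function(m, by) m[c((nrow(m) - by + 1):nrow(m), 1:(nrow(m) - by)), ]
  ph1 <- manual_phantom(lab, prm)
  ph2 <- manual_phantom(sh(lab, 1L), prm) # one acquired-voxel pitch down
  s1 <- sum_over_time(reconstruct(synthesize_kspace(ph1, cfg, 0, 1)))
  s2 <- sum_over_time(reconstruct(synthesize_kspace(ph2, cfg, 0, 1)))
  # one acquired voxel = two zero-filled voxels
  shifted <- s1$spectra[c(7:8, 1:6), , ]
  expect_lt(max(Mod(s2$spectra - shifted)) / max(Mod(s1$spectra)), 1e-8)
})

test_that("zero-filling interpolates a smooth phantom without distortion", {
  cfg <- csi_config(n_frames = 4L)
  n <- cfg$n_phase_encodes
  # Gaussian blob: one class per voxel, amplitude graded via the bolus
  ctr <- (n + 1) / 2
  lab <- matrix(seq_len(n * n), n, n)
  prm <- lapply(seq_len(n * n), function(v) {
    i <- (v - 1) %% n + 1; j <- (v - 1) %/% n + 1
    a <- exp(-((i - ctr)^2 + (j - ctr)^2) / (2 * 2.5^2))
    kinetic_params(bolus_amplitude = a)
  })
  names(prm) <- as.character(seq_len(n * n))
  ph <- manual_phantom(lab, prm)
  dat <- synthesize_kspace(ph, cfg, noise_sd = 0, seed = 1)
  s_lo <- sum_over_time(reconstruct(dat, zerofill = FALSE))
  s_hi <- sum_over_time(reconstruct(dat, zerofill = TRUE))
  p_lo <- apply(Mod(s_lo$spectra), c(1, 2), max)
  p_hi <- apply(Mod(s_hi$spectra), c(1, 2), max) * 2 # unitary scaling
  # k-space zero-padding is a pure interpolation: fine-grid samples at the
  # original sample positions (odd indices) reproduce the coarse image
  odd <- seq(1, 2 * n - 1, by = 2)
  expect_lt(max(abs(p_hi[odd, odd] - p_lo)) / max(p_lo), 1e-10)
  # and interpolated (even-index) samples stay near the mean of their
  # flanking original samples for a smooth phantom (band-limited
  # interpolation is not linear, so this is a loose bracket)
  for (i in 4:5) for (j in 4:5) {
    mid <- p_hi[2 * i, 2 * j - 1]
    flank <- mean(c(p_lo[i, j], p_lo[i + 1, j]))
    expect_lt(abs(mid - flank) / flank, 0.05)
  }
})

test_that("summing over time is an exact element-wise sum", {
  cfg <- tiny_config()
  ph <- make_phantom(grid_side = 4L, lesion_center = c(2, 3),
                     lesion_radius = 1, seed = 1)
  frames <- reconstruct(synthesize_kspace(ph, cfg, 0, 1))
  one <- sum_over_time(frames[1])
  expect_equal(one$spectra, frames[[1]]$spectra)
  twice <- sum_over_time(frames[c(1, 1)])
  expect_equal(twice$spectra, 2 * frames[[1]]$spectra)
  bad <- frames[[2]]
  bad$spectra <- bad$spectra[, , 1:32, drop = FALSE]
  expect_error(sum_over_time(list(frames[[1]], bad)), "geometry")
})

test_that("per-frame AUCs sum to the AUC of the summed spectrum", {
  # noiseless common-lineshape signal: every frame is a scaled copy of the
  # same two-Lorentzian spectrum, so peak AUCs must be additive over frames
  cfg <- csi_config()
  f <- frequency_axis(cfg)
  w <- default_fit_windows(cfg)
  frame_amp <- cbind(p = c(1, 0.7, 0.4, 0.2), l = c(0.3, 0.35, 0.2, 0.1))
  spectra <- lapply(seq_len(nrow(frame_amp)), function(k)
    lorentzian(f, frame_amp[k, "p"], -920, 40) +
      lorentzian(f, frame_amp[k, "l"], 920, 40))
  aucs <- vapply(spectra, function(s) {
    fit <- fit_lorentzian_pair(s, f, w)
    c(fit$pyruvate$auc, fit$lactate$auc)
  }, numeric(2))
  fit_sum <- fit_lorentzian_pair(Reduce(`+`, spectra), f, w)
  total <- c(fit_sum$pyruvate$auc, fit_sum$lactate$auc)
  expect_lt(max(abs(rowSums(aucs) - total) / total), 1e-6)
})
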