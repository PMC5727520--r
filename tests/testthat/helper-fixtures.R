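# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no binary fixtures.

# A small, fast acquisition used where the full 8x8 / 16-frame protocol
# would be overkill.
tiny_config <- function(...) {
  csi_config(n_phase_encodes = 4L, n_fid_points = 64L, n_frames = 4L, ...)
}

# Hand-built phantom with an arbitrary label grid and per-class params,
# bypassing make_phantom's geometry (for uniform grids, single voxels,
# smooth blobs and shift tests).
manual_phantom <- function(label_grid, params_by_class,
                           csi_fov_mm = 24) {
  structure(list(label_grid = label_grid,
                 params_by_class = params_by_class,
                 anatomical_labels = matrix(0L, 16, 16),
                 grid_side = nrow(label_grid),
                 lesion_center = c(NA, NA), lesion_radius = 0,
                 brain_radius = NA, csi_fov_mm = csi_fov_mm,
                 anat_fov_mm = 30, anat_matrix = 16L, seed = 0L),
            class = "tissue_phantom")
}

uniform_phantom <- function(grid_side, params = kinetic_params()) {
  manual_phantom(matrix(1L, grid_side, grid_side), list(`1` = params))
}

# Independent matrix-exponential oracle for the two-site exchange system:
# augmented 3x3 generator propagated with Matrix::expm between sample
# times, splitting at the bolus edges.
expm_exchange_oracle <- function(params, times) {
  stopifnot(params$bolus_shape == "rect")
  u <- params$bolus_amplitude / params$bolus_duration_s
  edges <- c(params$bolus_start_s,
             params$bolus_start_s + params$bolus_duration_s)
  gen <- function(rate) {
    matrix(c(-(params$kpl_per_s + params$r1p_per_s), 0, rate,
             params$kpl_per_s, -params$r1l_per_s, 0,
             0, 0, 0), nrow = 3, byrow = TRUE)
  }
  state <- c(0, 0, 1)
  t_cur <- 0
  out <- matrix(NA_real_, length(times), 2)
  for (k in seq_along(times)) {
    t_next <- times[k]
    cuts <- sort(c(edges[edges > t_cur & edges < t_next], t_next))
    for (tc in cuts) {
      rate <- if (t_cur >= edges[1] && t_cur < edges[2]) u else 0
      state <- as.numeric(Matrix::expm(gen(rate) * (tc - t_cur)) %*% state)
      t_cur <- tc
    }
    out[k, ] <- state[1:2]
  }
  colnames(out) <- c("pyruvate", "lactate")
  out
}

# Brute-force count of grid cells whose centers fall inside a disk.
disk_count_oracle <- function(n, center, radius) {
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) cnt <- cnt + 1L
  cnt
}

# Independent spectral transform for round-trip oracles: plain fft along
# the last dim of an (ny, nx, npts) FID array, fftshifted.
direct_voxel_spectra <- function(fids) {
  d <- dim(fids)
  shift <- c((d[3] / 2 + 1):d[3], 1:(d[3] / 2))
  out <- array(0 + 0i, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    out[i, j, ] <- stats::fft(fids[i, j, ])[shift]
  out
}

# Minimal ratio-map stub for ROI arithmetic tests.
stub_ratio_map <- function(ratio, mask = !is.na(ratio), fov_mm = 24) {
  structure(list(ratio = ratio, quality_mask = mask,
                 fov_mm = fov_mm, voxel_mm = fov_mm / nrow(ratio)),
            class = "ratio_map")
}

# Null long-format table: i.i.d. standard Gaussian responses.
null_table_2x2 <- function(n_per_cell = 10) {
  g <- expand.grid(hemisphere_label = c("contralateral", "injured"),
                   timepoint_label = c("t1", "t2"),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  g$animal_id <- sprintf("a%03d", seq_len(nrow(g)))
  g$value <- stats::rnorm(nrow(g))
  g
}
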