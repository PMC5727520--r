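# CSI reconstruction: spatial zero-filling, centered inverse 2D DFT per FID
# point, spectral FFT per voxel, and summation of the dynamic frames.

#' Zero-fill a CSI k-space frame by a factor of two
#'
#' Embeds the acquired, DC-centered spatial k-space block in the center of a
#' doubled grid (an 8 x 8 acquisition becomes a 16 x 16 matrix); every added
#' coefficient is exactly zero and the spectral dimension is untouched. With
#' even matrix sizes the DC coefficient stays at index `n/2 + 1`, which
#' places the extra zero row/column on the high-frequency side.
#'
#' @param kspace_frame Complex array `(ky, kx, n_fid_points)` with ky = kx.
#' @return Complex array `(2 ky, 2 kx, n_fid_points)`.
#' @export
zero_fill <- function(kspace_frame) {
  d <- dim(kspace_frame)
  if (length(d) != 3L || d[1L] != d[2L])
    stop("zero_fill: expected a square (ky, kx, points) array")
  n <- d[1L]
  out <- array(0 + 0i, dim = c(2L * n, 2L * n, d[3L]))
  idx <- (n %/% 2L + 1L):(n %/% 2L + n)
  out[idx, idx, ] <- kspace_frame
  out
}

new_voxel_spectrum_grid <- function(spectra, frequency_axis, fov_mm) {
  structure(list(spectra = spectra, frequency_axis = frequency_axis,
                 fov_mm = fov_mm,
                 voxel_mm = fov_mm / dim(spectra)[1L]),
            class = "voxel_spectrum_grid")
}

#' @export
print.voxel_spectrum_grid <- function(x, ...) {
  d <- dim(x$spectra)
  cat(sprintf("<voxel_spectrum_grid> %dx%d voxels (%.3g mm), %d bins over %+.4g..%+.4g Hz\n",
              d[1], d[2], x$voxel_mm, d[3],
              min(x$frequency_axis), max(x$frequency_axis)))
  invisible(x)
}

# spectral FFT along the FID dimension of an (ny, nx, npts) array, with
# fftshift so the frequency axis is monotone
spectral_fft <- function(fids) {
  d <- dim(fids)
  m <- matrix(fids, d[1L] * d[2L], d[3L])
  sp <- t(stats::mvfft(t(m)))[, fftshift_idx(d[3L]), drop = FALSE]
  array(sp, dim = d)
}

#' Reconstruct dynamic CSI k-space into per-frame voxel spectra
#'
#' Standard CSI reconstruction: optional spatial zero-filling by two, a
#' centered unitary inverse 2D DFT per FID point, then an FFT along the FID
#' dimension (fftshifted to a monotone frequency axis) per voxel.
#'
#' @param data A [synthesize_kspace()] `dynamic_csi` object (or any list
#'   with a conforming `kspace` array and `config`).
#' @param zerofill Logical; apply the factor-of-two spatial zero-fill
#'   (default `TRUE`, giving the 16 x 16 analysis grid for an 8 x 8
#'   acquisition).
#' @return A list of `voxel_spectrum_grid` objects, one per dynamic frame.
#' @export
reconstruct <- function(data, zerofill = TRUE) {
  cfg <- data$config
  validate_csi_config(cfg)
  d <- dim(data$kspace)
  if (length(d) != 4L || d[2L] != cfg$n_phase_encodes ||
      d[3L] != cfg$n_phase_encodes || d[4L] != cfg$n_fid_points ||
      d[1L] != cfg$n_frames)
    stop("reconstruct: k-space dims ", paste(d, collapse = "x"),
         " do not match the acquisition config")
  freq <- frequency_axis(cfg)
  lapply(seq_len(d[1L]), function(f) {
    kf <- array(data$kspace[f, , , ], dim = d[-1L])
    if (zerofill) kf <- zero_fill(kf)
    ns <- dim(kf)[1L]
    img <- array(0 + 0i, dim = dim(kf))
    for (p in seq_len(dim(kf)[3L]))
      img[, , p] <- ifft2_centered(kf[, , p])
    new_voxel_spectrum_grid(spectral_fft(img), freq, cfg$fov_mm)
  })
}

#' Sum reconstructed spectra over dynamic frames
#'
#' Element-wise summation of the per-frame voxel spectra, the step that
#' collapses the dynamic acquisition into the single spectrum per voxel on
#' which peak fitting is performed. Complex summation is the default; set
#' `magnitude = TRUE` to sum magnitude spectra instead.
#'
#' @param frames A list of `voxel_spectrum_grid` objects with identical
#'   geometry (as returned by [reconstruct()]).
#' @param magnitude Logical; sum `Mod(spectra)` instead of complex values.
#' @return A single `voxel_spectrum_grid`.
#' @export
sum_over_time <- function(frames, magnitude = FALSE) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("sum_over_time: need at least one frame")
  ref <- frames[[1L]]
  for (fr in frames[-1L]) {
    if (!identical(dim(fr$spectra), dim(ref$spectra)) ||
        !isTRUE(all.equal(fr$frequency_axis, ref$frequency_axis)) ||
        !isTRUE(all.equal(fr$fov_mm, ref$fov_mm)))
      stop("sum_over_time: frames have mismatched geometry")
  }
  acc <- if (magnitude) Mod(ref$spectra) else ref$spectra
  for (fr in frames[-1L])
    acc <- acc + if (magnitude) Mod(fr$spectra) else fr$spectra
  new_voxel_spectrum_grid(acc, ref$frequency_axis, ref$fov_mm)
}
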