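# Spatial Fourier encoding of the phantom's voxel FIDs into CSI k-space.
# Conventions (used consistently by the reconstruction module):
#   * k-space is DC-centered: the zero spatial frequency sits at index
#     n/2 + 1 along each spatial dimension,
#   * the spatial transform is unitary (scaled by 1/sqrt(N)), so Parseval's
#     identity holds exactly between image and k-space.

fftshift_idx <- function(n) c((n %/% 2L + 1L):n, seq_len(n %/% 2L))
ifftshift_idx <- function(n) fftshift_idx(n) # identical for even n

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m))]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m))]

# unitary, DC-centered 2D spatial transforms
fft2_centered <- function(img) fftshift2(stats::fft(img)) / sqrt(length(img))
ifft2_centered <- function(k)
  stats::fft(ifftshift2(k), inverse = TRUE) / sqrt(length(k))

#' Directly synthesized voxel FIDs of a phantom
#'
#' Computes, for every dynamic frame and voxel, the complex free induction
#' decay \eqn{\sum_m A_m \sin(\alpha) \exp(2\pi i f_m t - t / T_{2m}^*)}
#' summed over metabolites, where \eqn{A_m} is the class's longitudinal
#' magnetization at frame start (from [simulate_dynamics()]) and \eqn{f_m}
#' the configured resonance offset. This is the spatial-domain ground truth
#' that [synthesize_kspace()] Fourier-encodes.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param config A [csi_config()]; its `n_phase_encodes` must equal the
#'   phantom grid side.
#' @return Complex array of dims `(n_frames, ny, nx, n_fid_points)`.
#' @export
synthesize_voxel_fids <- function(phantom, config) {
  validate_csi_config(config)
  n <- phantom$grid_side
  if (n != config$n_phase_encodes)
    stop("synthesize_voxel_fids: phantom grid side (", n,
         ") must match config n_phase_encodes (", config$n_phase_encodes, ")")
  npts <- config$n_fid_points
  tt <- (seq_len(npts) - 1L) / config$spectral_width_hz
  sinfa <- sin(config$flip_angle_deg * pi / 180)
  mets <- names(config$offsets_hz)

  out <- array(0 + 0i, dim = c(config$n_frames, n, n, npts))
  for (k in names(phantom$params_by_class)) {
    prm <- phantom$params_by_class[[k]]
    if (!all(mets %in% names(prm$t2star_s)))
      stop("synthesize_voxel_fids: t2star_s must name every configured metabolite")
    traj <- simulate_dynamics(prm, config, at = "frame")
    amp <- cbind(pyruvate = traj$pyruvate, lactate = traj$lactate)
    vox <- which(phantom$label_grid == as.integer(k), arr.ind = TRUE)
    if (nrow(vox) == 0L) next
    # per-frame FID of this class (frames x points)
    fid <- matrix(0 + 0i, config$n_frames, npts)
    for (m in mets) {
      shape <- exp((2i * pi * config$offsets_hz[[m]] - 1 / prm$t2star_s[[m]]) * tt)
      fid <- fid + sinfa * outer(amp[, m], shape)
    }
    for (v in seq_len(nrow(vox)))
      out[, vox[v, 1L], vox[v, 2L], ] <- fid
  }
  out
}

#' Synthesize raw dynamic CSI k-space from a phantom
#'
#' Fourier-encodes the phantom's voxel FIDs into DC-centered k-space, frame
#' by frame and FID point by FID point, using a unitary 2D discrete Fourier
#' transform, then adds i.i.d. complex Gaussian noise (standard deviation
#' `noise_sd` per real and imaginary component) to every sample. A single
#' seed governs the whole dataset, so the output is bit-reproducible.
#'
#' @inheritParams synthesize_voxel_fids
#' @param noise_sd Standard deviation of the complex Gaussian noise added to
#'   each k-space sample (per component); must be >= 0.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `dynamic_csi`: a list with `kspace` (complex
#'   array, dims `(n_frames, ky, kx, n_fid_points)`), `config`, and
#'   `ground_truth` (the phantom).
#' @examples
#' ph <- make_phantom()
#' dat <- synthesize_kspace(ph, csi_config(), noise_sd = 0, seed = 1)
#' dim(dat$kspace)
#' @export
synthesize_kspace <- function(phantom, config, noise_sd = 0, seed = 1L) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("synthesize_kspace: noise_sd must be a single number >= 0")
  fids <- synthesize_voxel_fids(phantom, config)
  dm <- dim(fids)
  ks <- array(0 + 0i, dim = dm)
  for (f in seq_len(dm[1L]))
    for (p in seq_len(dm[4L]))
      ks[f, , , p] <- fft2_centered(fids[f, , , p])
  if (noise_sd > 0) {
    ks <- ks + with_preserved_seed(seed, {
      complex(real = rnorm(length(ks), sd = noise_sd),
              imaginary = rnorm(length(ks), sd = noise_sd))
    })
  }
  if (any(!is.finite(Re(ks)) | !is.finite(Im(ks))))
    stop("synthesize_kspace: non-finite k-space values")
  structure(list(kspace = ks, config = config, ground_truth = phantom),
            class = "dynamic_csi")
}

#' @export
print.dynamic_csi <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("<dynamic_csi> %d frames, %dx%d k-space, %d FID points\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Noise level matching a target spectral signal-to-noise ratio
#'
#' In vivo CSI noise is characterized by the signal-to-noise ratio of the
#' spectra actually fitted, so the noise level is parameterized the same
#' way: `snr` is defined as the pyruvate peak height of a normal-tissue
#' voxel in the time-summed magnitude spectrum divided by the noise
#' standard deviation at that stage. k-space noise of standard deviation
#' `sd` per component propagates unchanged through the unitary spatial
#' transform, gains `sqrt(n_fid_points)` through the spectral FFT and
#' `sqrt(n_frames)` through time summation, so
#' `sd = peak / (snr * sqrt(n_fid_points * n_frames))`, with the peak
#' height computed from the phantom's noiseless signal. Zero-filling leaves
#' this ratio unchanged: under the unitary convention it halves the voxel
#' amplitude and, because only a quarter of the padded k-space samples
#' carry noise, halves the voxel noise as well.
#'
#' @inheritParams synthesize_voxel_fids
#' @param snr Target peak signal-to-noise ratio (> 0).
#' @return k-space noise standard deviation per component.
#' @export
noise_sd_for_snr <- function(phantom, config, snr) {
  if (snr <= 0) stop("noise_sd_for_snr: snr must be > 0")
  prm <- phantom$params_by_class[["1"]]
  if (is.null(prm)) prm <- phantom$params_by_class[[1L]]
  traj <- simulate_dynamics(prm, config, at = "frame")
  tt <- (seq_len(config$n_fid_points) - 1L) / config$spectral_width_hz
  shape <- exp((2i * pi * config$offsets_hz[["pyruvate"]] -
                  1 / prm$t2star_s[["pyruvate"]]) * tt)
  sinfa <- sin(config$flip_angle_deg * pi / 180)
  fid <- sinfa * sum(traj$pyruvate) * shape # time-summed voxel FID
  peak <- max(Mod(stats::fft(fid)))
  peak / (snr * sqrt(config$n_fid_points * config$n_frames))
}
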