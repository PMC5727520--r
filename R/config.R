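#' Acquisition configuration for a dynamic 2D CSI experiment
#'
#' Bundles every sequence and geometry parameter needed to simulate or
#' reconstruct one dynamic chemical shift imaging (CSI) acquisition. The
#' defaults describe a 14.1 T mouse-brain protocol: TE/TR = 1.2/60 ms,
#' 2500 Hz spectral width sampled with 128 FID points, 10 degree excitations,
#' a 24 x 24 mm2 field of view encoded on an 8 x 8 phase-encode matrix,
#' 5 mm slice, one full CSI frame every 4 s for 16 frames (about one minute
#' of dynamic acquisition after bolus arrival).
#'
#' @param te_s Echo time in seconds.
#' @param tr_s Repetition time between phase-encode excitations, seconds.
#' @param spectral_width_hz Receiver bandwidth in Hz; the reconstructed
#'   frequency axis spans `+/- spectral_width_hz / 2`.
#' @param n_fid_points Number of complex FID samples per excitation (even).
#' @param flip_angle_deg Excitation flip angle in degrees, in `(0, 90]`.
#' @param fov_mm Square field of view in mm.
#' @param n_phase_encodes Acquired matrix side (ky = kx), even.
#' @param slice_thickness_mm Slice thickness in mm.
#' @param frame_period_s Temporal resolution of the dynamic frames, seconds.
#'   One full `n_phase_encodes^2` encode must fit inside a frame period.
#' @param n_frames Number of dynamic frames.
#' @param offsets_hz Named numeric vector of metabolite resonance offsets
#'   relative to the carrier, Hz. Each offset must lie inside the sampled
#'   bandwidth. Defaults place pyruvate at -920 Hz and lactate at +920 Hz
#'   (about 12.2 ppm apart for carbon-13 at 14.1 T).
#'
#' @return An object of class `csi_config` (a validated named list).
#' @examples
#' cfg <- csi_config()
#' cfg$n_phase_encodes^2 * cfg$tr_s # encode duration fits in a 4 s frame
#' @export
csi_config <- function(te_s = 1.2e-3,
                       tr_s = 60e-3,
                       spectral_width_hz = 2500,
                       n_fid_points = 128L,
                       flip_angle_deg = 10,
                       fov_mm = 24,
                       n_phase_encodes = 8L,
                       slice_thickness_mm = 5,
                       frame_period_s = 4,
                       n_frames = 16L,
                       offsets_hz = c(pyruvate = -920, lactate = 920)) {
  cfg <- list(
    te_s = te_s, tr_s = tr_s,
    spectral_width_hz = spectral_width_hz,
    n_fid_points = as.integer(n_fid_points),
    flip_angle_deg = flip_angle_deg,
    fov_mm = fov_mm,
    n_phase_encodes = as.integer(n_phase_encodes),
    slice_thickness_mm = slice_thickness_mm,
    frame_period_s = frame_period_s,
    n_frames = as.integer(n_frames),
    offsets_hz = offsets_hz
  )
  class(cfg) <- "csi_config"
  validate_csi_config(cfg)
  cfg
}

validate_csi_config <- function(cfg) {
  num <- c("te_s", "tr_s", "spectral_width_hz", "n_fid_points",
           "flip_angle_deg", "fov_mm", "n_phase_encodes",
           "slice_thickness_mm", "frame_period_s", "n_frames")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("csi_config: `", nm, "` must be a single positive number")
  }
  if (cfg$flip_angle_deg > 90)
    stop("csi_config: flip_angle_deg must lie in (0, 90]")
  if (cfg$n_fid_points %% 2L != 0L || cfg$n_phase_encodes %% 2L != 0L)
    stop("csi_config: n_fid_points and n_phase_encodes must be even")
  if (cfg$n_phase_encodes^2 * cfg$tr_s > cfg$frame_period_s + 1e-12)
    stop("csi_config: a full CSI encode (n_phase_encodes^2 * tr_s = ",
         signif(cfg$n_phase_encodes^2 * cfg$tr_s, 4),
         " s) does not fit in frame_period_s = ", cfg$frame_period_s, " s")
  off <- cfg$offsets_hz
  if (is.null(names(off)) || any(!nzchar(names(off))))
    stop("csi_config: offsets_hz must be a named vector")
  if (any(abs(off) > cfg$spectral_width_hz / 2))
    stop("csi_config: metabolite offsets must lie within +/- spectral_width_hz/2")
  invisible(cfg)
}

#' @export
print.csi_config <- function(x, ...) {
  cat("<csi_config>\n")
  cat(sprintf("  TE/TR = %.3g/%.3g ms, flip %.3g deg\n",
              x$te_s * 1e3, x$tr_s * 1e3, x$flip_angle_deg))
  cat(sprintf("  spectral width %.4g Hz, %d FID points\n",
              x$spectral_width_hz, x$n_fid_points))
  cat(sprintf("  FOV %.3g mm, %dx%d encodes, slice %.3g mm\n",
              x$fov_mm, x$n_phase_encodes, x$n_phase_encodes,
              x$slice_thickness_mm))
  cat(sprintf("  %d frames every %.3g s\n", x$n_frames, x$frame_period_s))
  cat(sprintf("  offsets: %s\n",
              paste(sprintf("%s %+g Hz", names(x$offsets_hz), x$offsets_hz),
                    collapse = ", ")))
  invisible(x)
}

#' Frequency axis of a reconstructed spectrum
#'
#' Returns the monotone frequency axis (Hz) obtained when an `n`-point FID
#' sampled at `sw` Hz is Fourier transformed and fftshifted, i.e.
#' `(-n/2, ..., n/2 - 1) * sw / n`.
#'
#' @param config A [csi_config()].
#' @return Numeric vector of length `config$n_fid_points`.
#' @export
frequency_axis <- function(config) {
  n <- config$n_fid_points
  (seq_len(n) - 1L - n %/% 2L) * config$spectral_width_hz / n
}
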