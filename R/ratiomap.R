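# Voxel-wise lactate-to-pyruvate AUC ratio maps from time-summed spectra.

#' Lactate-to-pyruvate AUC ratio map
#'
#' Fits the two-Lorentzian model of [fit_lorentzian_pair()] to the phased
#' absorption spectrum of every voxel of a time-summed [voxel spectrum
#' grid][sum_over_time] and forms the ratio of the analytic lactate and
#' pyruvate AUCs. Voxels whose fit fails to converge or whose pyruvate AUC
#' falls below `pyruvate_auc_floor` are masked out and carry `NA` in the
#' ratio map — never a silent zero.
#'
#' When `pyruvate_auc_floor` is `NULL` it defaults to five times the median
#' background AUC, where the background AUC is the area a Lorentzian of the
#' median fitted pyruvate linewidth would have at the spectrum's typical
#' off-resonance magnitude (median absolute value outside both fit windows,
#' across all voxels).
#'
#' @param grid A `voxel_spectrum_grid` (reconstructed and time-summed).
#' @param windows List of two `(lo, hi)` frequency windows (pyruvate,
#'   lactate); see [default_fit_windows()].
#' @param pyruvate_auc_floor Minimum pyruvate AUC for a voxel to enter the
#'   map, or `NULL` for the data-driven default.
#' @param lineshape Passed to [fit_lorentzian_pair()]; defaults to
#'   `"periodic"` because reconstructed CSI spectra come from sampled FIDs,
#'   whose lineshape is the bandwidth-periodic summation of Lorentzians.
#' @return An object of class `ratio_map`: `ratio` and `quality_mask`
#'   matrices (`ny x nx`), per-voxel `fits`, the AUC matrices
#'   `pyruvate_auc` / `lactate_auc`, and the floor used.
#' @export
ratio_map <- function(grid, windows, pyruvate_auc_floor = NULL,
                      lineshape = "periodic") {
  if (!inherits(grid, "voxel_spectrum_grid"))
    stop("ratio_map: expected a voxel_spectrum_grid")
  d <- dim(grid$spectra)
  freq <- grid$frequency_axis
  windows <- check_windows(freq, windows)
  in_win <- (freq >= windows[[1L]][1L] & freq <= windows[[1L]][2L]) |
            (freq >= windows[[2L]][1L] & freq <= windows[[2L]][2L])

  fits <- vector("list", d[1L] * d[2L])
  dim(fits) <- d[1:2]
  p_auc <- l_auc <- matrix(NA_real_, d[1L], d[2L])
  conv <- matrix(FALSE, d[1L], d[2L])
  bg_vals <- numeric(0)
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      s <- grid$spectra[i, j, ]
      fit <- fit_lorentzian_pair(s, freq, windows, lineshape = lineshape)
      fits[[i, j]] <- fit
      conv[i, j] <- fit$pyruvate$converged && fit$lactate$converged
      if (conv[i, j]) {
        p_auc[i, j] <- fit$pyruvate$auc
        l_auc[i, j] <- fit$lactate$auc
      }
      bg_vals <- c(bg_vals, stats::median(Mod(s)[!in_win]))
    }
  }

  if (is.null(pyruvate_auc_floor)) {
    fw <- vapply(fits[conv], function(f) f$pyruvate$fwhm_hz, numeric(1))
    fw_med <- if (length(fw)) stats::median(fw) else 40
    pyruvate_auc_floor <- 5 * stats::median(bg_vals) * pi * fw_med / 2
  }

  mask <- conv & !is.na(p_auc) & p_auc > pyruvate_auc_floor
  ratio <- matrix(NA_real_, d[1L], d[2L])
  ratio[mask] <- l_auc[mask] / p_auc[mask]

  structure(list(ratio = ratio, quality_mask = mask, fits = fits,
                 pyruvate_auc = p_auc, lactate_auc = l_auc,
                 pyruvate_auc_floor = pyruvate_auc_floor,
                 fov_mm = grid$fov_mm, voxel_mm = grid$voxel_mm),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf("<ratio_map> %dx%d voxels, %d in quality mask (floor %.3g)\n",
              nrow(x$ratio), ncol(x$ratio), sum(x$quality_mask),
              x$pyruvate_auc_floor))
  if (any(x$quality_mask))
    cat(sprintf("  ratio range %.3g .. %.3g\n",
                min(x$ratio, na.rm = TRUE), max(x$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Run the full quantification pipeline on one acquisition
#'
#' Convenience wrapper: [reconstruct()] every frame (with zero-filling),
#' [sum_over_time()], then [ratio_map()] with the default windows around the
#' configured metabolite offsets.
#'
#' @param data A `dynamic_csi` acquisition.
#' @param zerofill Passed to [reconstruct()].
#' @param windows Fit windows; default [default_fit_windows()] of the
#'   acquisition config.
#' @param pyruvate_auc_floor Passed to [ratio_map()].
#' @param magnitude_sum Passed to [sum_over_time()] as `magnitude`.
#' @return A `ratio_map`.
#' @export
csi_pipeline <- function(data, zerofill = TRUE, windows = NULL,
                         pyruvate_auc_floor = NULL, magnitude_sum = FALSE) {
  if (is.null(windows)) windows <- default_fit_windows(data$config)
  summed <- sum_over_time(reconstruct(data, zerofill = zerofill),
                          magnitude = magnitude_sum)
  ratio_map(summed, windows, pyruvate_auc_floor)
}
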