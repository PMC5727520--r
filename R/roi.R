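# Anatomical-resolution heatmaps and hemisphere ROI summaries.
# The CSI field of view (24 mm) and the anatomical field of view (30 mm)
# are assumed concentric (shared gradient isocenter); mm coordinates are
# measured from the common center.

as_value_matrix <- function(map) {
  if (inherits(map, "ratio_map")) {
    v <- map$ratio
    attr(v, "fov_mm") <- map$fov_mm
    v
  } else if (is.matrix(map)) {
    map
  } else stop("expected a ratio_map or a numeric matrix")
}

#' Interpolate a CSI-resolution map to anatomical resolution
#'
#' Bilinear interpolation of a voxel-grid map (a [ratio_map()] or any
#' numeric matrix with `NA` marking masked voxels) onto the anatomical image
#' grid, with physical voxel-center alignment: the CSI grid is embedded at
#' its true position inside the larger anatomical field of view. Anatomical
#' pixels outside the CSI field of view are `NA`, and masked source voxels
#' are never interpolated across — any output pixel that would draw on a
#' masked voxel is itself `NA`. Pixels between the FOV edge and the outer
#' voxel centers take the nearest-edge value.
#'
#' @param map A `ratio_map` (its `NA`-masked `ratio` is used) or a numeric
#'   source matrix.
#' @param target_shape Integer `(rows, cols)` of the anatomical grid,
#'   default `c(256, 256)`.
#' @param source_fov_mm Field of view of the source grid; taken from the
#'   `ratio_map` when available.
#' @param target_fov_mm Field of view of the anatomical grid (default 30).
#' @return Numeric matrix of shape `target_shape` with `NA` outside the CSI
#'   footprint and across masked voxels.
#' @export
interpolate_heatmap <- function(map, target_shape = c(256L, 256L),
                                source_fov_mm = NULL, target_fov_mm = 30) {
  vals <- as_value_matrix(map)
  if (is.null(source_fov_mm)) source_fov_mm <- attr(vals, "fov_mm")
  if (is.null(source_fov_mm))
    stop("interpolate_heatmap: source_fov_mm required for a plain matrix")
  n <- nrow(vals)
  if (ncol(vals) != n) stop("interpolate_heatmap: source must be square")
  if (any(target_shape < dim(vals)))
    stop("interpolate_heatmap: target shape must be >= source shape")
  if (target_fov_mm < source_fov_mm)
    stop("interpolate_heatmap: anatomical FOV (", target_fov_mm,
         " mm) smaller than CSI FOV (", source_fov_mm, " mm)")
  vs <- source_fov_mm / n
  eps <- 1e-12

  axis_map <- function(N, pt) {
    mm <- (seq_len(N) - (N + 1) / 2) * pt
    inside <- abs(mm) <= source_fov_mm / 2
    u <- mm / vs + (n + 1) / 2
    u <- pmin(pmax(u, 1), n)
    i0 <- pmin(floor(u), n - 1)
    list(i0 = as.integer(i0), frac = u - i0, inside = inside)
  }
  ry <- axis_map(target_shape[1L], target_fov_mm / target_shape[1L])
  rx <- axis_map(target_shape[2L], target_fov_mm / target_shape[2L])

  Ny <- target_shape[1L]; Nx <- target_shape[2L]
  I0 <- matrix(ry$i0, Ny, Nx); A <- matrix(ry$frac, Ny, Nx)
  J0 <- matrix(rx$i0, Ny, Nx, byrow = TRUE)
  B <- matrix(rx$frac, Ny, Nx, byrow = TRUE)

  gather <- function(di, dj) vals[cbind(as.vector(I0) + di, as.vector(J0) + dj)]
  w <- list((1 - A) * (1 - B), A * (1 - B), (1 - A) * B, A * B)
  v <- list(gather(0L, 0L), gather(1L, 0L), gather(0L, 1L), gather(1L, 1L))
  out <- matrix(0, Ny, Nx)
  bad <- matrix(FALSE, Ny, Nx)
  for (k in 1:4) {
    wk <- as.vector(w[[k]])
    active <- wk > eps
    term <- numeric(length(wk))
    term[active] <- wk[active] * v[[k]][active]
    bad <- bad | matrix(active & is.na(v[[k]]), Ny, Nx)
    term[is.na(term)] <- 0
    out <- out + matrix(term, Ny, Nx)
  }
  out[bad] <- NA_real_
  outside <- outer(!ry$inside, rep(TRUE, Nx), "&") |
             outer(rep(TRUE, Ny), !rx$inside, "&")
  out[outside] <- NA_real_
  out
}

#' Transfer an anatomical-resolution mask to the CSI grid
#'
#' Each CSI voxel receives the majority vote of the anatomical pixels whose
#' centers fall inside it; pixels outside the CSI field of view are ignored.
#'
#' @param anat_mask Logical (or 0/1) matrix on the anatomical grid.
#' @param csi_shape Integer `(rows, cols)` of the CSI analysis grid.
#' @param anat_fov_mm,csi_fov_mm Fields of view (concentric), mm.
#' @return Logical matrix of shape `csi_shape`.
#' @export
downsample_mask <- function(anat_mask, csi_shape,
                            anat_fov_mm = 30, csi_fov_mm = 24) {
  anat_mask <- anat_mask > 0
  n <- csi_shape[1L]
  if (length(csi_shape) != 2L || csi_shape[2L] != n)
    stop("downsample_mask: csi_shape must be square")
  vs <- csi_fov_mm / n
  idx_of <- function(N, pt) {
    mm <- (seq_len(N) - (N + 1) / 2) * pt
    i <- floor((mm + csi_fov_mm / 2) / vs) + 1
    i[mm < -csi_fov_mm / 2 | mm >= csi_fov_mm / 2] <- NA
    pmin(pmax(i, 1), n)
  }
  ri <- idx_of(nrow(anat_mask), anat_fov_mm / nrow(anat_mask))
  ci <- idx_of(ncol(anat_mask), anat_fov_mm / ncol(anat_mask))
  ok_r <- which(!is.na(ri)); ok_c <- which(!is.na(ci))
  cell <- as.vector(outer(ri[ok_r], ci[ok_c],
                          function(r, c) (c - 1L) * n + r))
  val <- as.vector(anat_mask[ok_r, ok_c])
  total <- tabulate(cell, nbins = n * n)
  votes <- tabulate(cell[val], nbins = n * n)
  matrix(total > 0 & votes / pmax(total, 1) > 0.5, n, n)
}

#' Mean ratio over a region of interest
#'
#' Arithmetic mean of the ratio over the voxels in `roi_mask` that also pass
#' the map's quality mask, following the convention of reporting each
#' hemisphere as the mean of its voxels.
#'
#' @param map A [ratio_map()].
#' @param roi_mask Logical matrix on the map's grid.
#' @param roi_name Region name carried into the result (and error messages).
#' @param animal_id,timepoint_label Optional identifiers for group tables.
#' @return An object of class `roi_result` with `roi_name`, `mean_ratio`,
#'   `voxel_count`, `animal_id`, `timepoint_label`.
#' @export
roi_mean <- function(map, roi_mask, roi_name,
                     animal_id = NA_character_,
                     timepoint_label = NA_character_) {
  if (!inherits(map, "ratio_map")) stop("roi_mean: expected a ratio_map")
  if (!identical(dim(roi_mask), dim(map$ratio)))
    stop("roi_mean: ROI mask dims do not match the map")
  eff <- (roi_mask > 0) & map$quality_mask
  if (!any(eff))
    stop("roi_mean: ROI '", roi_name,
         "' contains no quality-masked voxels")
  structure(list(roi_name = roi_name,
                 mean_ratio = mean(map$ratio[eff]),
                 voxel_count = sum(eff),
                 animal_id = animal_id,
                 timepoint_label = timepoint_label),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result> %s: mean ratio %.4g over %d voxels\n",
              x$roi_name, x$mean_ratio, x$voxel_count))
  invisible(x)
}

#' Percent change of the injured hemisphere relative to the contralateral
#'
#' `100 * (injured - contralateral) / contralateral`, the normalization used
#' to express each animal's lactate-to-pyruvate elevation as a percent of
#' its own uninjured hemisphere.
#'
#' @param injured,contralateral `roi_result` objects (or single numbers).
#' @return A single number (percent; positive = elevated on injured side).
#' @export
percent_of_contralateral <- function(injured, contralateral) {
  gv <- function(x) if (inherits(x, "roi_result")) x$mean_ratio else x
  inj <- gv(injured); con <- gv(contralateral)
  if (!is.finite(con) || con <= 0)
    stop("percent_of_contralateral: contralateral mean must be > 0")
  100 * (inj - con) / con
}
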