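# File interchange: NIfTI for image-like outputs (ratio maps, heatmaps,
# label masks), CSV for tabular summaries, and R's native serialization for
# whole acquisition objects.

#' Write a ratio map (and its quality mask) as NIfTI
#'
#' Writes the ratio values (masked voxels as `NaN`) to `path` and the
#' quality mask (0/1) alongside it with a `_mask` suffix, with in-plane
#' pixel dimensions taken from the map geometry.
#'
#' @param map A [ratio_map()].
#' @param path Output file name (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths written.
#' @export
write_ratio_map_nifti <- function(map, path) {
  if (!inherits(map, "ratio_map")) stop("expected a ratio_map")
  img <- RNifti::asNifti(map$ratio, pixdim = rep(map$voxel_mm, 2L))
  RNifti::writeNifti(img, path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  if (identical(mask_path, path)) mask_path <- paste0(path, "_mask")
  RNifti::writeNifti(
    RNifti::asNifti(map$quality_mask + 0, pixdim = rep(map$voxel_mm, 2L)),
    mask_path)
  invisible(c(path, mask_path))
}

#' Write an integer label image (or stack) as NIfTI
#'
#' @param labels Integer matrix or `(slices, rows, cols)` array.
#' @param path Output file name.
#' @param pixel_mm In-plane pixel size, mm.
#' @param slice_thickness_mm Slice thickness, mm.
#' @return Invisibly, `path`.
#' @export
write_label_nifti <- function(labels, path, pixel_mm = 30 / 256,
                              slice_thickness_mm = 0.5) {
  if (length(dim(labels)) == 3L) labels <- aperm(labels, c(2L, 3L, 1L))
  img <- RNifti::asNifti(labels * 1,
                         pixdim = c(pixel_mm, pixel_mm, slice_thickness_mm))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer label image from NIfTI
#'
#' @param path NIfTI file; a 3D volume is returned as a
#'   `(slices, rows, cols)` array matching [label_volume()].
#' @return Integer matrix or array.
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- round(as.array(img))
  storage.mode(arr) <- "integer"
  if (length(dim(arr)) == 3L) arr <- aperm(arr, c(3L, 1L, 2L))
  arr
}

#' Collect ROI summaries into a long-format table
#'
#' @param results A list of [roi_mean()] `roi_result` objects.
#' @return A data.frame with columns `animal_id`, `timepoint_label`,
#'   `roi_name`, `mean_ratio`, `voxel_count`.
#' @export
roi_results_table <- function(results) {
  if (inherits(results, "roi_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(animal_id = r$animal_id,
               timepoint_label = r$timepoint_label,
               roi_name = r$roi_name,
               mean_ratio = r$mean_ratio,
               voxel_count = r$voxel_count)))
}

#' Save / load a dynamic CSI acquisition
#'
#' Whole-object serialization of a `dynamic_csi` acquisition (complex
#' k-space, configuration and ground-truth phantom) using R's native
#' serialization format.
#'
#' @param data A `dynamic_csi` object.
#' @param path File path (conventionally `.rds`).
#' @return `write_csi` invisibly returns `path`; `read_csi` returns the
#'   `dynamic_csi` object.
#' @export
write_csi <- function(data, path) {
  if (!inherits(data, "dynamic_csi")) stop("expected a dynamic_csi object")
  saveRDS(data, path)
  invisible(path)
}

#' @rdname write_csi
#' @export
read_csi <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "dynamic_csi"))
    stop("read_csi: file does not contain a dynamic_csi object")
  obj
}
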