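# Region volumetry from multi-slice anatomical label masks: exact voxel
# counting times the voxel volume, replacing interactive segmentation
# software in the longitudinal lesion / cavity / ventricle measurements.

#' Per-label volumes of an anatomical label stack
#'
#' Counts voxels of each declared label across all slices and converts the
#' counts to mm3 as `count * (fov_mm / matrix)^2 * slice_thickness_mm`
#' (exact integer counting; binary labels, no partial-volume weighting).
#'
#' @param label_stack Integer array `(slices, rows, cols)` or a single-slice
#'   matrix.
#' @param fov_mm In-plane field of view of the anatomical images (default
#'   30 mm at a 256 matrix, i.e. 0.1172 mm pixels).
#' @param slice_thickness_mm Slice thickness (default 0.5 mm).
#' @param labels Named integer vector declaring the allowed label values;
#'   any undeclared value in the stack is an error that names the
#'   offenders.
#' @param animal_id,timepoint_label Optional identifiers.
#' @return A `label_volume_report`: a data.frame with one row per declared
#'   non-background label (`label`, `name`, `voxel_count`, `volume_mm3`)
#'   plus geometry attributes.
#' @examples
#' m <- matrix(0L, 256, 256); m[1:40, 1:25] <- 1L
#' label_volume(m)
#' @export
label_volume <- function(label_stack,
                         fov_mm = 30,
                         slice_thickness_mm = 0.5,
                         labels = c(background = 0L, lesion = 1L,
                                    cavity = 2L, ventricle = 3L),
                         animal_id = NA_character_,
                         timepoint_label = NA_character_) {
  if (fov_mm <= 0 || slice_thickness_mm <= 0)
    stop("label_volume: geometry must be positive")
  if (is.matrix(label_stack))
    label_stack <- array(label_stack, dim = c(1L, dim(label_stack)))
  d <- dim(label_stack)
  if (length(d) != 3L || any(d < 1L))
    stop("label_volume: expected a non-empty (slices, rows, cols) array")
  if (d[2L] != d[3L])
    stop("label_volume: in-plane matrix must be square")
  present <- sort(unique(as.vector(label_stack)))
  unknown <- setdiff(present, labels)
  if (length(unknown))
    stop("label_volume: unknown labels present: ",
         paste(unknown, collapse = ", "))
  pixel_mm <- fov_mm / d[2L]
  vox_mm3 <- pixel_mm^2 * slice_thickness_mm
  fg <- labels[labels != 0L]
  counts <- vapply(fg, function(l) sum(label_stack == l), integer(1))
  rep_df <- data.frame(label = unname(fg), name = names(fg),
                       voxel_count = unname(counts),
                       volume_mm3 = unname(counts) * vox_mm3,
                       animal_id = animal_id,
                       timepoint_label = timepoint_label,
                       row.names = NULL)
  attr(rep_df, "pixel_mm") <- pixel_mm
  attr(rep_df, "slice_thickness_mm") <- slice_thickness_mm
  class(rep_df) <- c("label_volume_report", "data.frame")
  rep_df
}

#' Percent volume decrease between two timepoints
#'
#' `100 * (v_earlier - v_later) / v_earlier`: positive values mean
#' shrinkage relative to the earlier timepoint (e.g. a lesion that halves in
#' volume is a +50 percent decrease), negative values mean growth.
#'
#' @param v_later,v_earlier Volumes in mm3; `v_earlier` must be > 0.
#' @return Percent decrease (single number).
#' @export
percent_volume_change <- function(v_later, v_earlier) {
  if (!is.finite(v_earlier) || v_earlier <= 0)
    stop("percent_volume_change: earlier volume must be > 0")
  100 * (v_earlier - v_later) / v_earlier
}
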