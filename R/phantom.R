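# Digital tissue phantom emulating a focal cortical contusion: a circular
# "brain" on the CSI voxel grid, split into left (contralateral) and right
# (injured) hemispheres, with a disk-shaped lesion of elevated exchange rate
# in the right hemisphere, plus a 256 x 256 anatomical label map (lesion,
# cavity, ventricles) for volumetry.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# distance of every grid cell center from a point (row, col), in voxel units
grid_dist <- function(n, center) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2)
}

#' Build a tissue phantom with a focal lesion
#'
#' Generates the voxel-grid tissue labels, per-class kinetic parameters and
#' an anatomical-resolution label map for one synthetic animal. The brain is
#' a centered disk of radius `0.45 * grid_side` voxels; the left half of the
#' grid is the contralateral hemisphere and the right half the injured one.
#' Injured tissue occupies a disk of `lesion_radius` voxels around
#' `lesion_center`, optionally with a smaller lesion core. Between-animal
#' variability is modeled as one shared lognormal multiplier (coefficient of
#' variation `kpl_cv`) applied to every class's exchange rate.
#'
#' Labels on the voxel grid: 0 background, 1 tissue, 2 injured tissue,
#' 3 lesion core. Labels on the anatomical grid: 0 other, 1 lesion,
#' 2 cavity, 3 ventricle.
#'
#' @param grid_side Acquired CSI matrix side (voxels).
#' @param lesion_center Numeric `(row, col)` of the lesion center in voxel
#'   coordinates, defaulting to the upper right cortex.
#' @param lesion_radius Lesion radius in voxels; 0 gives an uninjured
#'   (sham-like) phantom with perfectly mirrored hemispheres.
#' @param tissue_params,lesion_params,core_params [kinetic_params()] for
#'   normal tissue, injured tissue and lesion core. `lesion_params` defaults
#'   to `tissue_params` with the exchange rate doubled; `core_params`
#'   defaults to `lesion_params`.
#' @param core_radius Radius of the lesion core in voxels (0 = none).
#' @param kpl_cv Coefficient of variation of the shared animal-level
#'   multiplier on `kpl_per_s` (0 = no variability).
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @param csi_fov_mm,anat_fov_mm,anat_matrix Geometry used to draw the
#'   anatomical label map concentric with the CSI field of view.
#'
#' @return An object of class `tissue_phantom` with fields `label_grid`,
#'   `params_by_class` (named by label), `anatomical_labels`, and geometry
#'   metadata.
#' @examples
#' ph <- make_phantom(seed = 7)
#' table(ph$label_grid)
#' @export
make_phantom <- function(grid_side = 8L,
                         lesion_center = NULL,
                         lesion_radius = 1.6,
                         tissue_params = kinetic_params(),
                         lesion_params = NULL,
                         core_radius = 0,
                         core_params = NULL,
                         kpl_cv = 0,
                         seed = 1L,
                         csi_fov_mm = 24,
                         anat_fov_mm = 30,
                         anat_matrix = 256L) {
  grid_side <- as.integer(grid_side)
  if (grid_side < 4L || grid_side %% 2L != 0L)
    stop("make_phantom: grid_side must be an even integer >= 4")
  ctr <- (grid_side + 1) / 2
  if (is.null(lesion_center))
    lesion_center <- c(ctr - 1, ctr + 1.5)
  if (lesion_radius < 0 || core_radius < 0 || core_radius > lesion_radius)
    stop("make_phantom: radii must satisfy 0 <= core_radius <= lesion_radius")
  if (lesion_radius > 0 &&
      (any(lesion_center - lesion_radius < 0.5) ||
       any(lesion_center + lesion_radius > grid_side + 0.5)))
    stop("make_phantom: lesion (center ",
         paste(signif(lesion_center, 3), collapse = ", "),
         ", radius ", lesion_radius, ") lies outside the ",
         grid_side, "x", grid_side, " grid")
  if (is.null(lesion_params)) {
    lesion_params <- tissue_params
    lesion_params$kpl_per_s <- 2 * tissue_params$kpl_per_s
  }
  if (is.null(core_params)) core_params <- lesion_params

  brain_r <- 0.45 * grid_side
  labels <- matrix(0L, grid_side, grid_side)
  labels[grid_dist(grid_side, c(ctr, ctr)) <= brain_r] <- 1L
  if (lesion_radius > 0) {
    d <- grid_dist(grid_side, lesion_center)
    labels[d <= lesion_radius & labels > 0L] <- 2L
    if (core_radius > 0) labels[d <= core_radius & labels > 0L] <- 3L
  }
  half <- grid_side %/% 2L
  if (!any(labels[, seq_len(half)] > 0L) ||
      !any(labels[, half + seq_len(half)] > 0L))
    stop("make_phantom: both hemispheres must contain tissue voxels")

  params_by_class <- list(`1` = tissue_params, `2` = lesion_params,
                          `3` = core_params)
  params_by_class <- params_by_class[as.character(
    sort(unique(labels[labels > 0L])))]

  # shared animal-level variability of the exchange rate
  if (kpl_cv > 0) {
    mult <- with_preserved_seed(seed, {
      sdlog <- sqrt(log(1 + kpl_cv^2))
      exp(rnorm(1L, mean = -sdlog^2 / 2, sd = sdlog))
    })
    for (k in names(params_by_class))
      params_by_class[[k]]$kpl_per_s <- params_by_class[[k]]$kpl_per_s * mult
  }

  anat <- make_anatomical_labels(grid_side, lesion_center, lesion_radius,
                                 csi_fov_mm, anat_fov_mm, anat_matrix)

  ph <- list(label_grid = labels,
             params_by_class = params_by_class,
             anatomical_labels = anat,
             grid_side = grid_side,
             lesion_center = lesion_center,
             lesion_radius = lesion_radius,
             brain_radius = brain_r,
             csi_fov_mm = csi_fov_mm,
             anat_fov_mm = anat_fov_mm,
             anat_matrix = as.integer(anat_matrix),
             seed = as.integer(seed))
  class(ph) <- "tissue_phantom"
  ph
}

# Anatomical-resolution labels: lesion disk at the lesion's physical
# position, a cavity (40% of the lesion radius) at its center, and two
# small para-midline ventricles. mm coordinates are concentric with the
# CSI field of view.
make_anatomical_labels <- function(grid_side, lesion_center, lesion_radius,
                                   csi_fov_mm, anat_fov_mm, anat_matrix) {
  vox_mm <- csi_fov_mm / grid_side
  pix_mm <- anat_fov_mm / anat_matrix
  ctr <- (grid_side + 1) / 2
  xy <- (seq_len(anat_matrix) - (anat_matrix + 1) / 2) * pix_mm
  X <- matrix(xy, anat_matrix, anat_matrix, byrow = TRUE) # col -> x
  Y <- matrix(xy, anat_matrix, anat_matrix)               # row -> y
  lab <- matrix(0L, anat_matrix, anat_matrix)
  if (lesion_radius > 0) {
    cx <- (lesion_center[2] - ctr) * vox_mm
    cy <- (lesion_center[1] - ctr) * vox_mm
    r_mm <- lesion_radius * vox_mm
    d <- sqrt((X - cx)^2 + (Y - cy)^2)
    lab[d <= r_mm] <- 1L
    lab[d <= 0.4 * r_mm] <- 2L
  }
  for (sgn in c(-1, 1)) {
    d <- sqrt((X - sgn * 1.2)^2 + (Y - 1.5)^2)
    lab[d <= 0.8 & lab == 0L] <- 3L
  }
  lab
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", x$grid_side, "x", x$grid_side,
      " grid, lesion radius ", x$lesion_radius, " voxels\n", sep = "")
  tab <- table(factor(x$label_grid, levels = 0:3))
  cat("  voxels: background ", tab["0"], ", tissue ", tab["1"],
      ", injured ", tab["2"], ", core ", tab["3"], "\n", sep = "")
  invisible(x)
}

#' Calibrate the lesion exchange rate for a target AUC-ratio elevation
#'
#' Finds the `kpl_per_s` for injured tissue such that its ground-truth
#' lactate-to-pyruvate AUC ratio is elevated by `elevation_pct` percent over
#' the reference tissue. The ratio is strictly increasing in the exchange
#' rate, so the calibration is a one-dimensional root find.
#'
#' @param tissue_params Reference (contralateral) [kinetic_params()].
#' @param config A [csi_config()].
#' @param elevation_pct Target percent elevation of the AUC ratio (> -100).
#' @return A `kinetic_params` object identical to `tissue_params` except for
#'   the calibrated `kpl_per_s`.
#' @export
calibrate_lesion_kpl <- function(tissue_params, config, elevation_pct) {
  base <- ground_truth_ratio(tissue_params, config)
  target <- base * (1 + elevation_pct / 100)
  if (target <= 0) stop("calibrate_lesion_kpl: target ratio must be positive")
  f <- function(k) {
    p <- tissue_params; p$kpl_per_s <- k
    ground_truth_ratio(p, config) - target
  }
  lo <- 0
  hi <- max(tissue_params$kpl_per_s, 1e-3)
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e3) stop("calibrate_lesion_kpl: no exchange rate reaches the target")
  }
  k <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  out <- tissue_params
  out$kpl_per_s <- k
  out
}

#' Ground-truth AUC-ratio map of a phantom
#'
#' @param phantom A [make_phantom()] phantom.
#' @param config A [csi_config()].
#' @return A `grid_side x grid_side` matrix with each tissue voxel's
#'   noiseless lactate-to-pyruvate AUC ratio (by class) and `NA` background.
#' @export
phantom_ratio_truth <- function(phantom, config) {
  out <- matrix(NA_real_, phantom$grid_side, phantom$grid_side)
  for (k in names(phantom$params_by_class)) {
    r <- ground_truth_ratio(phantom$params_by_class[[k]], config)
    out[phantom$label_grid == as.integer(k)] <- r
  }
  out
}

#' Hemisphere region-of-interest masks on the anatomical grid
#'
#' Returns logical masks for the injured (right) and contralateral (left)
#' hemispheres of the phantom brain, drawn at anatomical resolution: the
#' brain disk (radius `0.45 * csi_fov_mm`) split at the midline, excluding a
#' one-pixel midline band.
#'
#' @param phantom A [make_phantom()] phantom.
#' @return A list of two logical `anat_matrix x anat_matrix` matrices,
#'   `injured` and `contralateral`.
#' @export
phantom_hemisphere_masks <- function(phantom) {
  n <- phantom$anat_matrix
  pix_mm <- phantom$anat_fov_mm / n
  xy <- (seq_len(n) - (n + 1) / 2) * pix_mm
  X <- matrix(xy, n, n, byrow = TRUE)
  Y <- matrix(xy, n, n)
  brain <- sqrt(X^2 + Y^2) <= 0.45 * phantom$csi_fov_mm
  list(injured = brain & X > 0, contralateral = brain & X < 0)
}
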