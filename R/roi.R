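#' Spherical region of interest
#'
#' An ROI is a sphere of fixed physical diameter placed at a mm coordinate.
#' `exclusion = "exclude_cortical"` removes voxels the structure volume
#' labels as cortical bone from every sample drawn through the ROI.
#'
#' @param center Numeric length-3 mm world coordinate of the sphere center.
#' @param diameter Sphere diameter in mm.
#' @param exclusion `"exclude_cortical"` or `"none"`.
#' @return An object of class `spherical_roi`.
#' @export
spherical_roi <- function(center, diameter,
                          exclusion = c("exclude_cortical", "none")) {
  exclusion <- match.arg(exclusion)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be a finite length-3 mm coordinate", call. = FALSE)
  if (!is.finite(diameter) || diameter <= 0)
    stop("`diameter` must be positive", call. = FALSE)
  structure(list(center = center, diameter = diameter, exclusion = exclusion),
            class = "spherical_roi")
}

# Closed-ball membership tolerance: voxel centers landing exactly on the
# ROI boundary are included; the epsilon only absorbs floating-point error
# in the squared-distance comparison.
.radius_eps <- 1e-9

roi_intersects_volume <- function(roi, shape, spacing) {
  r <- roi$diameter / 2
  ext <- volume_extent(shape, spacing)
  all(roi$center + r >= -.radius_eps) && all(roi$center - r <= ext + .radius_eps)
}

check_roi_placement <- function(roi, vol) {
  if (!roi_intersects_volume(roi, vol$shape, vol$spacing))
    stop("ROI sphere lies entirely outside the volume", call. = FALSE)
}

#' Place the femoral-head ROI
#'
#' A 3-cm (30 mm) diameter spherical ROI centered on the femoral head,
#' sampling as much cancellous bone as possible; voxels labeled cortical are
#' excluded from every sample. ROIs that extend past the volume edge are
#' clipped to the in-bounds voxels.
#'
#' @param volume A `voxel_volume`.
#' @param structure The paired `structure_volume`.
#' @param head_center mm coordinate of the femoral head center.
#' @param diameter ROI diameter in mm (30 by default).
#' @return A `spherical_roi` with cortical exclusion.
#' @export
make_head_roi <- function(volume, structure, head_center, diameter = 30) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(structure, "structure_volume"))
  if (!all(volume$shape == structure$shape))
    stop("volume and structure shapes differ", call. = FALSE)
  roi <- spherical_roi(head_center, diameter, "exclude_cortical")
  check_roi_placement(roi, volume)
  roi
}

#' Place the acetabular-dome ROI
#'
#' A 1-cm (10 mm) diameter spherical ROI at the superior acetabular dome,
#' the fallback reference site when the contralateral hip is incomparable.
#' The dome is aspherical and hemmed in by pelvic cortex, so a warning is
#' issued when the sphere overlaps cortical-labeled voxels (they are still
#' excluded from all samples).
#'
#' @inheritParams make_head_roi
#' @param dome_center mm coordinate of the acetabular dome.
#' @param diameter ROI diameter in mm (10 by default).
#' @return A `spherical_roi` with cortical exclusion.
#' @export
make_acetabular_roi <- function(volume, structure, dome_center, diameter = 10) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(structure, "structure_volume"))
  if (!all(volume$shape == structure$shape))
    stop("volume and structure shapes differ", call. = FALSE)
  roi <- spherical_roi(dome_center, diameter, "exclude_cortical")
  check_roi_placement(roi, volume)
  d2 <- voxel_dist2(structure$shape, structure$spacing, roi$center)
  in_ball <- d2 <= (diameter / 2)^2 + .radius_eps
  if (any(structure$labels[in_ball] == tissue_codes()[["cortical"]]))
    warning("acetabular ROI exceeds the available cancellous space; ",
            "cortical voxels are excluded from the samples", call. = FALSE)
  roi
}

plane_axes <- function() c(sagittal = 1L, coronal = 2L, axial = 3L)

# Logical mask (2-D in-plane index pairs) plus slice index for the ROI's
# central cross-section in `plane`. The slice is the voxel layer whose
# center is nearest the ROI center along the plane's fixed axis; disc
# membership is closed-ball on the in-plane distance to the ROI center.
central_disc <- function(roi, shape, spacing, plane) {
  ax <- plane_axes()[[plane]]
  in_plane <- setdiff(1:3, ax)
  slice <- which.min(abs(axis_centers(shape[ax], spacing[ax]) - roi$center[ax]))
  u2 <- (axis_centers(shape[in_plane[1]], spacing[in_plane[1]]) -
           roi$center[in_plane[1]])^2
  v2 <- (axis_centers(shape[in_plane[2]], spacing[in_plane[2]]) -
           roi$center[in_plane[2]])^2
  disc <- outer(u2, v2, "+") <= (roi$diameter / 2)^2 + .radius_eps
  list(axis = ax, slice = slice, disc = disc, in_plane = in_plane)
}

extract_slice <- function(arr, axis, slice) {
  switch(axis,
         arr[slice, , , drop = TRUE],
         arr[, slice, , drop = TRUE],
         arr[, , slice, drop = TRUE])
}

#' Mean uptake over an ROI's central cross-section in one plane
#'
#' Takes the ROI's central cross-sectional disc in the coronal, axial or
#' sagittal plane (the single voxel slice nearest the ROI center along that
#' plane's axis) and averages the photon counts of the non-excluded voxels
#' whose centers fall within the disc. Off-volume parts of the disc are
#' clipped.
#'
#' @param volume A `voxel_volume`.
#' @param roi A `spherical_roi`.
#' @param plane `"coronal"`, `"axial"` or `"sagittal"`.
#' @param structure Optional paired `structure_volume`; required when the
#'   ROI excludes cortical voxels.
#' @return A single mean count, with attribute `n_voxels` (eligible voxel
#'   count).
#' @export
plane_mean_uptake <- function(volume, roi,
                              plane = c("coronal", "axial", "sagittal"),
                              structure = NULL) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(roi, "spherical_roi"))
  plane <- match.arg(plane)
  check_roi_placement(roi, volume)
  cd <- central_disc(roi, volume$shape, volume$spacing, plane)
  eligible <- cd$disc
  if (roi$exclusion == "exclude_cortical") {
    if (is.null(structure))
      stop("`structure` is required for cortical exclusion", call. = FALSE)
    lab <- extract_slice(structure$labels, cd$axis, cd$slice)
    eligible <- eligible & lab != tissue_codes()[["cortical"]]
  }
  n <- sum(eligible)
  if (n == 0L)
    stop(sprintf("no eligible voxels in the %s-plane ROI cross-section; ",
                 plane), "check ROI placement", call. = FALSE)
  vals <- extract_slice(volume$counts, cd$axis, cd$slice)[eligible]
  structure(mean(vals), n_voxels = n)
}

#' Mean uptake of a spherical ROI
#'
#' The default `"planes"` mode follows the three-orthogonal-plane protocol:
#' the mean count is measured independently on the ROI's central coronal,
#' axial and sagittal cross-sections, and the three plane means are averaged
#' into the combined value. `"sphere"` mode instead averages over every
#' non-excluded voxel of the full 3-D ball; the mode used is recorded in the
#' result so the two can never be confused downstream.
#'
#' @inheritParams plane_mean_uptake
#' @param mode `"planes"` (three-plane average) or `"sphere"` (full ball).
#' @return An object of class `uptake_measurement` with fields
#'   `plane_means` (named, `"planes"` mode only), `combined_mean`,
#'   `n_voxels`, and `mode`.
#' @export
#' @examples
#' vol <- voxel_volume(array(7, c(9, 9, 9)), 1)
#' roi <- spherical_roi(c(4, 4, 4), 6, exclusion = "none")
#' roi_mean_uptake(vol, roi)$combined_mean  # 7: constant field
roi_mean_uptake <- function(volume, roi, structure = NULL,
                            mode = c("planes", "sphere")) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(roi, "spherical_roi"))
  mode <- match.arg(mode)
  check_roi_placement(roi, volume)
  if (mode == "planes") {
    planes <- c("coronal", "axial", "sagittal")
    pm <- lapply(planes, function(p) plane_mean_uptake(volume, roi, p, structure))
    means <- vapply(pm, as.numeric, numeric(1))
    ns <- vapply(pm, attr, integer(1), which = "n_voxels")
    names(means) <- names(ns) <- planes
    out <- list(plane_means = means, combined_mean = mean(means),
                n_voxels = ns, mode = "planes")
  } else {
    d2 <- voxel_dist2(volume$shape, volume$spacing, roi$center)
    eligible <- d2 <= (roi$diameter / 2)^2 + .radius_eps
    if (roi$exclusion == "exclude_cortical") {
      if (is.null(structure))
        stop("`structure` is required for cortical exclusion", call. = FALSE)
      eligible <- eligible &
        structure$labels != tissue_codes()[["cortical"]]
    }
    n <- sum(eligible)
    if (n == 0L)
      stop("no eligible voxels in the spherical ROI", call. = FALSE)
    out <- list(plane_means = NULL,
                combined_mean = mean(volume$counts[eligible]),
                n_voxels = c(sphere = n), mode = "sphere")
  }
  structure(out, class = "uptake_measurement")
}

#' @export
print.uptake_measurement <- function(x, ...) {
  cat(sprintf("<uptake_measurement> mode=%s combined_mean=%.4g\n",
              x$mode, x$combined_mean))
  if (x$mode == "planes") {
    for (p in names(x$plane_means))
      cat(sprintf("  %-8s mean %.4g  (n=%d)\n", p, x$plane_means[[p]],
                  x$n_voxels[[p]]))
  } else {
    cat(sprintf("  n=%d voxels in ball\n", x$n_voxels[["sphere"]]))
  }
  invisible(x)
}
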