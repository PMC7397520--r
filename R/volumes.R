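#' Tissue class codes used in structure volumes
#'
#' Integer label codes for the four tissue classes a structure volume can
#' contain. The structure volume plays the role of the CT channel: it tells
#' the ROI machinery where cortical bone is so it can be excluded.
#'
#' @return Named integer vector mapping class name to label code.
#' @export
#' @examples
#' tissue_codes()
tissue_codes <- function() {
  c(background = 0L, cancellous = 1L, cortical = 2L, acetabular_dome = 3L)
}

#' Construct a photon-count voxel volume
#'
#' A voxel volume is a 3-D array of nonnegative photon counts together with
#' its physical voxel spacing in mm. Axis order is (x = left-right,
#' y = anterior-posterior, z = inferior-superior); the world coordinate of
#' voxel `(i, j, k)` (1-based R indices) is `(i - 1, j - 1, k - 1) * spacing`
#' mm, i.e. voxel centers start at the origin.
#'
#' @param counts 3-D numeric array of nonnegative counts.
#' @param spacing Numeric length-3 vector, mm per voxel along each axis
#'   (or a scalar for isotropic spacing).
#' @return An object of class `voxel_volume` with elements `counts`,
#'   `spacing` and `shape`.
#' @export
voxel_volume <- function(counts, spacing) {
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3-D array", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE))
    stop("photon counts must be nonnegative", call. = FALSE)
  spacing <- expand_spacing(spacing)
  structure(
    list(counts = counts, spacing = spacing, shape = dim(counts)),
    class = "voxel_volume"
  )
}

#' Construct a tissue-label structure volume
#'
#' @param labels 3-D integer array of tissue codes (see [tissue_codes()]).
#' @param spacing mm per voxel per axis, as in [voxel_volume()].
#' @return An object of class `structure_volume`.
#' @export
structure_volume <- function(labels, spacing) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  if (!all(labels %in% tissue_codes()))
    stop("unknown tissue label code in structure volume", call. = FALSE)
  spacing <- expand_spacing(spacing)
  structure(
    list(labels = labels, spacing = spacing, shape = dim(labels)),
    class = "structure_volume"
  )
}

expand_spacing <- function(spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  as.numeric(spacing)
}

# World-coordinate (mm) centers of the voxels along one axis.
axis_centers <- function(n, spacing) (seq_len(n) - 1) * spacing

# mm extent of the voxel-center lattice along each axis.
volume_extent <- function(shape, spacing) (shape - 1) * spacing

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "<voxel_volume> %s voxels @ %s mm, counts in [%g, %g]\n",
    paste(x$shape, collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    min(x$counts), max(x$counts)
  ))
  invisible(x)
}

#' @export
print.structure_volume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = tissue_codes(),
                      labels = names(tissue_codes())))
  cat(sprintf("<structure_volume> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  print(tab)
  invisible(x)
}

#' Write a volume to a NIfTI-1 file
#'
#' Photon-count volumes are written as floating point, structure volumes as
#' integer labels; voxel spacing is stored in the NIfTI pixdim field.
#'
#' @param vol A `voxel_volume` or `structure_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  arr <- if (inherits(vol, "voxel_volume")) vol$counts
         else if (inherits(vol, "structure_volume")) vol$labels
         else stop("`vol` must be a voxel_volume or structure_volume",
                   call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param what `"counts"` to return a `voxel_volume`, `"labels"` for a
#'   `structure_volume`.
#' @return A `voxel_volume` or `structure_volume`.
#' @export
read_volume_nifti <- function(path, what = c("counts", "labels")) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.vector(img), dim = dim(img))
  if (what == "counts") voxel_volume(arr, spacing)
  else structure_volume(array(as.integer(round(arr)), dim = dim(arr)), spacing)
}
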