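#' 3D scalar volume with physical voxel spacing
#'
#' A `voxel_grid` is the container used for both PET SUV maps and
#' contrast-enhanced T1 MRI intensity maps: a 3D numeric array plus the
#' physical size of a voxel along each axis (millimetres) and the world
#' coordinate of the centre of voxel `(0,0,0)` (0-based indexing; the centre
#' of array element `[1,1,1]` in R). All downstream geometry (centroids,
#' peak-to-centroid distances, surfaces) is computed in this world frame, so
#' anisotropic voxels are handled correctly.
#'
#' @param values 3D numeric array of intensities (SUV for PET, arbitrary
#'   units for MRI). Must be finite throughout.
#' @param spacing Numeric length-3, physical voxel size per axis in mm;
#'   strictly positive.
#' @param origin Numeric length-3, world position (mm) of the centre of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @param modality `"PET"` or `"MRI"`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume(g) # 8 mm^3
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       modality = c("PET", "MRI")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array, got ",
         if (is.array(values)) paste0(length(dim(values)), "D") else class(values)[1],
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive finite values (mm)",
         call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` contains non-finite entries (NaN/Inf); clean the volume first",
         call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid %s> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              x$modality, d[1], d[2], d[3],
              paste(format(x$spacing, trim = TRUE), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param grid A [voxel_grid].
#' @return Voxel volume in cubic millimetres (product of the spacings).
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

# World coordinates (mm) of voxel centres given 1-based array indices
# (n x 3 matrix). Voxel-centre convention: index (1,1,1) sits at `origin`.
world_coords <- function(ijk, spacing, origin) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3L)
  sweep(sweep(ijk - 1, 2L, spacing, `*`), 2L, origin, `+`)
}

#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI (`.nii`/`.nii.gz`) volume into a [voxel_grid], taking the
#' voxel spacing from the header. Axis order is kept as stored (x, y, z);
#' the world origin is set to `c(0,0,0)` — all geometry in this package is
#' translation-invariant, so only spacing matters.
#'
#' @param path Path to the NIfTI file.
#' @param modality `"PET"` or `"MRI"`.
#' @return A [voxel_grid].
#' @export
read_volume <- function(path, modality = c("PET", "MRI")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-positive voxel spacing in header of ", path, call. = FALSE)
  }
  voxel_grid(array(as.numeric(arr), dim(arr)), spacing = spacing,
             modality = modality)
}

#' Write a voxel grid as NIfTI
#'
#' @param grid A [voxel_grid].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
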