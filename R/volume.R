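#' CT image volume
#'
#' A 3D scalar grid of Hounsfield-unit values with voxel spacing and origin
#' metadata. This is the raster input to the whole pipeline; all physical
#' quantities (diameters, surface areas, smoothing lengths) are derived from
#' `spacing_mm`.
#'
#' @param grid Numeric 3D array of HU values (finite).
#' @param spacing_mm Positive length-3 voxel spacing in mm.
#' @param origin Length-3 physical coordinate of the first voxel center.
#' @return An `image_volume` object.
#' @export
image_volume <- function(grid, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3) abort("`grid` must be a 3D array.")
  if (!all(is.finite(grid))) abort("`grid` must be finite-valued.")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be a positive length-3 vector.")
  }
  structure(
    list(grid = grid, spacing_mm = spacing_mm, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Binary tumor mask
#'
#' A binary region-of-interest grid paired with an [image_volume()]: same
#' shape, spacing and origin.
#'
#' @param grid Logical or 0/1 3D array.
#' @param spacing_mm,origin As in [image_volume()].
#' @return A `tumor_mask` object.
#' @export
tumor_mask <- function(grid, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3) abort("`grid` must be a 3D array.")
  g <- grid != 0
  storage.mode(g) <- "logical"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be a positive length-3 vector.")
  }
  structure(
    list(grid = g, spacing_mm = spacing_mm, origin = as.numeric(origin)),
    class = "tumor_mask"
  )
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$grid), dim(mask$grid))) {
    abort("volume and mask shapes differ.")
  }
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > 1e-9) {
    abort("volume and mask spacings differ.")
  }
  invisible(TRUE)
}

mask_count <- function(mask) sum(mask$grid)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
    paste(dim(x$grid), collapse = "x"),
    paste(format(x$spacing_mm), collapse = "x"),
    min(x$grid), max(x$grid)
  ))
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf(
    "<tumor_mask> %s voxels, %d foreground (%.2f cm3)\n",
    paste(dim(x$grid), collapse = "x"), sum(x$grid),
    sum(x$grid) * prod(x$spacing_mm) / 1000
  ))
  invisible(x)
}

#' Read / write NIfTI volumes and masks
#'
#' Thin wrappers over RNifti keeping spacing metadata in sync with the
#' package's containers.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti_volume()` an [image_volume()]; `read_nifti_mask()` a
#'   [tumor_mask()].
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
    spacing_mm = RNifti::pixdim(img)[1:3]
  )
}

#' @rdname read_nifti_volume
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  tumor_mask(array(as.numeric(img) != 0, dim(img)[1:3]),
    spacing_mm = RNifti::pixdim(img)[1:3]
  )
}

#' @rdname read_nifti_volume
#' @param x An [image_volume()], [tumor_mask()] or `habitat_map`.
#' @export
write_nifti <- function(x, path) {
  grid <- x$grid
  if (is.logical(grid)) storage.mode(grid) <- "integer"
  img <- RNifti::asNifti(grid, pixdim = x$spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
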