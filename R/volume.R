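#' 3D volume on a regular grid
#'
#' A `volume_grid` is the package's basic container: a 3D scalar array with
#' physical voxel spacing (mm) and an origin. The axis convention is
#' x: left-right, y: anterior-posterior, z: inferior-superior, so axis 3 is
#' the craniocaudal axis used as the rotation axis for projections.
#'
#' @param values numeric 3D array.
#' @param spacing_mm positive voxel spacing per axis, mm. Defaults to the
#'   2.04 x 2.04 x 3.00 mm grid common in whole-body FDG-PET/CT.
#' @param origin_mm physical coordinate of the first voxel, mm.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing_mm = c(2.04, 2.04, 3.00),
                        origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("'origin_mm' must have length 3")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  rng <- range(x$values)
  cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Coerce to a volume_grid
#'
#' Arrays are wrapped with the supplied (or default) spacing; existing
#' `volume_grid` objects are returned unchanged.
#' @inheritParams volume_grid
#' @param x array or `volume_grid`.
#' @return A `volume_grid`.
#' @export
as_volume_grid <- function(x, spacing_mm = c(2.04, 2.04, 3.00),
                           origin_mm = c(0, 0, 0)) {
  if (is_volume_grid(x)) return(x)
  volume_grid(x, spacing_mm, origin_mm)
}

## new volume on the same grid as `vol`
vg_like <- function(vol, values) {
  volume_grid(values, vol$spacing_mm, vol$origin_mm)
}

## error unless two volumes share shape and spacing
stop_unless_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s must share the same shape (%s vs %s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6)
    stop(sprintf("%s must share the same voxel spacing", what))
  invisible(TRUE)
}

## voxel volume in ml (1 ml = 1000 mm^3)
voxel_volume_ml <- function(spacing_mm) prod(spacing_mm) / 1000

is_binary <- function(x) {
  v <- if (is_volume_grid(x)) x$values else x
  all(v %in% c(0, 1))
}

#' Read a NIfTI volume
#'
#' Thin wrapper over [RNifti::readNifti()] returning a [volume_grid] with
#' spacing taken from the image pixdim.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  vals <- array(as.numeric(img), dim = dim(img))
  volume_grid(vals, spacing_mm = as.numeric(pd[seq_len(3)]))
}

#' Write a volume as NIfTI
#'
#' @param vol a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume_grid(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
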