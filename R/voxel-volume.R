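#' Voxel volumes
#'
#' A `voxel_volume` is a 3D scalar grid in `(z, y, x)` axis order together
#' with its voxel spacing `(dz, dy, dx)` in micrometres and a dimensionless
#' axial calibration factor `kappa` applied to `dz` (correcting confocal
#' z-spacing for shrinkage / refractive-index mismatch). Voxel indices are
#' 0-based; the physical position of voxel `(iz, iy, ix)` is its centre,
#' `((ix + 0.5) dx, (iy + 0.5) dy, (iz + 0.5) kappa dz)` in `(x, y, z)` um.
#'
#' @param data numeric or integer 3D array, dim `(nz, ny, nx)`.
#' @param spacing numeric length-3, `(dz, dy, dx)` in um, all `> 0`.
#' @param axial_calibration positive scalar `kappa`; calibrated z-spacing is
#'   `kappa * dz`. Default 1 (no correction).
#' @param is_binary logical; if `NA` (default) it is detected from the data
#'   (all values in `{0, 1}`).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, axial_calibration = 1, is_binary = NA) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values (dz, dy, dx)")
  if (!is.numeric(axial_calibration) || length(axial_calibration) != 1L ||
      !is.finite(axial_calibration) || axial_calibration <= 0)
    stop("`axial_calibration` must be a single positive finite number")
  if (is.na(is_binary))
    is_binary <- all(data %in% c(0, 1))
  structure(list(data = data, spacing = spacing,
                 axial_calibration = as.numeric(axial_calibration),
                 is_binary = isTRUE(is_binary)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels (z,y,x), %s\n",
              d[1], d[2], d[3], if (x$is_binary) "binary" else "grayscale"))
  cat(sprintf("  calibrated spacing (dz,dy,dx): %.4g x %.4g x %.4g um (kappa = %g)\n",
              sp[1], sp[2], sp[3], x$axial_calibration))
  cat(sprintf("  physical extent (z,y,x): %.4g x %.4g x %.4g um, volume %.6g um^3\n",
              d[1] * sp[1], d[2] * sp[2], d[3] * sp[3], physical_volume(x)))
  invisible(x)
}

#' Calibrated voxel spacing
#'
#' @param vol a [voxel_volume()].
#' @return `(kappa * dz, dy, dx)` in um.
#' @export
voxel_spacing <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  c(vol$spacing[1] * vol$axial_calibration, vol$spacing[2], vol$spacing[3])
}

#' Physical volume of a stack
#'
#' `Nz * Ny * Nx * (kappa dz) * dy * dx`, recomputable from metadata alone.
#'
#' @param vol a [voxel_volume()].
#' @return volume in um^3.
#' @export
physical_volume <- function(vol) {
  sp <- voxel_spacing(vol)
  prod(dim(vol$data)) * prod(sp)
}

#' Read a multi-page TIFF stack
#'
#' Pages become z-slices of a `(z, y, x)` array; grayscale values are
#' preserved bit-exactly (8/16-bit integers).
#'
#' @param path path to a multi-page TIFF.
#' @param spacing `(dz, dy, dx)` voxel spacing in um.
#' @param axial_calibration axial calibration factor `kappa`, default 1.
#' @return A [voxel_volume()].
#' @export
read_stack <- function(path, spacing, axial_calibration = 1) {
  if (!file.exists(path)) stop("cannot read TIFF stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("non-uniform page sizes in ", path)
  nz <- length(pages); ny <- dims[1, 1]; nx <- dims[2, 1]
  arr <- array(0L, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  voxel_volume(arr, spacing, axial_calibration)
}

#' Write a stack as multi-page TIFF
#'
#' @param vol a [voxel_volume()]; values must be non-negative integers.
#' @param path output path.
#' @param bits bits per sample (8 or 16); default picks 8 unless values
#'   exceed 255.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, bits = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  mx <- max(vol$data)
  if (is.null(bits)) bits <- if (mx > 255) 16L else 8L
  scale <- 2^bits - 1
  if (mx > scale) stop("data values exceed ", bits, "-bit range")
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(vol$data[z, , ], d[2], d[3]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Apply axial calibration
#'
#' Rescales the z-spacing by `kappa`; voxel data are untouched, all
#' downstream lengths along z scale accordingly.
#'
#' @param vol a [voxel_volume()].
#' @param kappa positive finite scalar.
#' @return The calibrated volume.
#' @export
apply_axial_calibration <- function(vol, kappa) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("`kappa` must be a single positive finite number")
  vol$axial_calibration <- as.numeric(kappa)
  vol
}

#' Global threshold binarization
#'
#' Voxels with intensity `>= threshold` become 1, all others 0 (inclusive
#' global threshold).
#'
#' @param vol a grayscale [voxel_volume()].
#' @param threshold intensity cutoff.
#' @return A binary [voxel_volume()].
#' @export
binarize <- function(vol, threshold) {
  stopifnot(inherits(vol, "voxel_volume"))
  out <- vol
  out$data <- array(as.integer(vol$data >= threshold), dim = dim(vol$data))
  out$is_binary <- TRUE
  out
}
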