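#' Voxel dimensions in nanometres
#'
#' Array tomography volumes are strongly anisotropic: the in-plane pixel
#' pitch is set by the camera/objective (typically 100 nm after
#' deconvolution) while the axial sampling equals the ultramicrotome
#' section thickness (typically 70 nm).
#'
#' @param vx,vy Nanometres per voxel in x and y.
#' @param vz Nanometres per voxel in z (section thickness).
#' @return An object of class `voxel_size`.
#' @examples
#' voxel_size()          # the standard 100 x 100 x 70 nm grid
#' voxel_size(200, 200, 70)
#' @export
voxel_size <- function(vx = 100, vy = 100, vz = 70) {
  v <- c(vx = as.numeric(vx), vy = as.numeric(vy), vz = as.numeric(vz))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("invalid geometry: voxel dimensions must be strictly positive",
         call. = FALSE)
  }
  structure(as.list(v), class = "voxel_size")
}

#' @export
print.voxel_size <- function(x, ...) {
  cat(sprintf("voxel size: %g x %g x %g nm\n", x$vx, x$vy, x$vz))
  invisible(x)
}

# round to nearest integer, halves away from zero (printed-table convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Physical volume of a voxel grid
#'
#' Converts voxel counts and a voxel size into cubic micrometres, plus the
#' nearest-integer value conventionally printed in data-volume tables.
#'
#' @param nx,ny,nz Voxel counts per axis (>= 1).
#' @param voxel A [voxel_size()].
#' @return A list with elements `um3` (real) and `um3_rounded` (nearest
#'   integer, halves rounded away from zero).
#' @examples
#' physical_volume(2176, 3328, 43)$um3_rounded  # 217976
#' @export
physical_volume <- function(nx, ny, nz, voxel = voxel_size()) {
  stopifnot(inherits(voxel, "voxel_size"))
  n <- c(nx, ny, nz)
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    stop("invalid geometry: voxel counts must be positive integers",
         call. = FALSE)
  }
  um3 <- nx * ny * nz * voxel$vx * voxel$vy * voxel$vz / 1e9
  list(um3 = um3, um3_rounded = round_half_away(um3))
}
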