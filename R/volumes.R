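#' Volumetric map
#'
#' A 3-D value lattice together with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in mm (RAS orientation), and a logical
#' in-brain mask of the same dimensions.
#'
#' @param values numeric 3-D array.
#' @param affine numeric 4x4 matrix; must be invertible. Column 4 is the
#'   world position of voxel index (0, 0, 0).
#' @param mask logical 3-D array matching \code{dim(values)}; defaults to
#'   all \code{TRUE}.
#' @return An object of class \code{volumetric_map}.
#' @export
volumetric_map <- function(values, affine, mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine matrix must be invertible")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  if (any(!is.finite(values[mask])))
    stop("values must be finite within the mask")
  structure(list(values = values, affine = affine, mask = mask),
            class = "volumetric_map")
}

#' @export
print.volumetric_map <- function(x, ...) {
  d <- dim(x$values)
  vs <- voxel_size(x$affine)
  cat(sprintf("<volumetric_map> %d x %d x %d voxels (%.2f x %.2f x %.2f mm), %d in mask\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], sum(x$mask)))
  invisible(x)
}

# Per-axis voxel edge length in mm from the affine.
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Default centered RAS affine
#'
#' Builds a diagonal affine for an isotropic grid whose world origin lies at
#' the grid center, so the mid-sagittal plane sits at x = 0 and left
#' hemisphere voxels have negative x.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @return 4x4 affine matrix.
#' @export
centered_affine <- function(grid_shape, voxel_size_mm) {
  a <- diag(c(rep(voxel_size_mm, 3), 1))
  a[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  a
}

# World mm coordinates of 1-based voxel indices (n x 3 matrix).
vox_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1)            # affine acts on 0-based indices
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

# Continuous 0-based voxel coordinates of world mm positions.
world_to_vox <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1)
  t(solve(affine) %*% t(h))[, 1:3, drop = FALSE]
}

# Frequency-domain Gaussian kernel for circular (FFT) smoothing of fields on
# a periodic lattice.  Returns the FFT of the normalized kernel, reusable
# across volumes sharing grid + FWHM.
gaussian_kernel_fft <- function(grid_shape, fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))   # mm
  k1 <- function(n, h) {
    d <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] * h
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  kx <- k1(grid_shape[1], voxel_size_mm)
  ky <- k1(grid_shape[2], voxel_size_mm)
  kz <- k1(grid_shape[3], voxel_size_mm)
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- grid_shape
  fft(kern)
}

# Smooth a 3-D array by circular convolution with a precomputed kernel FFT.
smooth_field <- function(arr, kern_fft) {
  Re(fft(fft(arr) * kern_fft, inverse = TRUE)) / length(arr)
}

#' Gaussian smoothing of a 3-D field
#'
#' Circular (periodic-boundary) convolution with an isotropic Gaussian
#' kernel of the given full width at half maximum.
#'
#' @param arr numeric 3-D array.
#' @param fwhm_mm kernel FWHM in mm.
#' @param voxel_size_mm voxel edge length in mm.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxel_size_mm) {
  stopifnot(fwhm_mm > 0, voxel_size_mm > 0)
  smooth_field(arr, gaussian_kernel_fft(dim(arr), fwhm_mm, voxel_size_mm))
}

#' Write a volumetric map to NIfTI
#'
#' @param map \code{volumetric_map}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(map, path) {
  stopifnot(inherits(map, "volumetric_map"))
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a volumetric map
#'
#' @param path NIfTI file.
#' @param mask optional logical array; defaults to finite, nonzero voxels
#'   being unmasked only if \code{mask_zero} is \code{TRUE}.
#' @param mask_zero treat exact zeros as outside the mask.
#' @return \code{volumetric_map}.
#' @export
read_volume <- function(path, mask = NULL, mask_zero = FALSE) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  aff <- unclass(RNifti::xform(img))
  if (is.null(mask) && mask_zero) mask <- vals != 0
  volumetric_map(vals, aff, mask)
}
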