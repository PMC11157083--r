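#' 2D grayscale image container
#'
#' Thin S3 wrapper around a numeric matrix in row = y (down), column = x
#' (right) order, carrying the physical pixel size. TEM micrographs acquired
#' at 5000x magnification have 287.5 pixels per micrometre, which is the
#' default.
#'
#' @param pixels Numeric matrix of intensities; rows index y, columns x.
#' @param pixel_size Edge length of one pixel in micrometres.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size = 1 / 287.5) {
  if (!is.null(dim(pixels)) && length(dim(pixels)) != 2L)
    stop("multi-channel or non-2D input rejected; supply a single-channel matrix")
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (length(dim(pixels)) != 2L)
    stop("multi-channel or non-2D input rejected; supply a single-channel matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.5f um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

as_gray_image <- function(img, pixel_size = 1 / 287.5) {
  if (inherits(img, "gray_image")) return(img)
  gray_image(img, pixel_size)
}

#' 3D fluorescence image stack container
#'
#' Holds a 3D array in (z, y, x) order plus the anisotropic voxel size in
#' micrometres. Default voxel size mirrors a 20x air-objective z-stack with
#' 0.323 um lateral sampling and 1 um axial steps.
#'
#' @param voxels Numeric 3D array, dimensions (z, y, x).
#' @param voxel_size Numeric length-3 vector (z, y, x) in micrometres.
#' @param channel Optional channel label, e.g. "S-opsin".
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = c(1, 0.323, 0.323),
                        channel = "S-opsin") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (z, y, x)")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (z, y, x)")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s: %d x %d x %d (z,y,x), voxel %.3f x %.3f x %.3f um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

as_image_stack <- function(x, voxel_size = c(1, 0.323, 0.323)) {
  if (inherits(x, "image_stack")) return(x)
  image_stack(x, voxel_size)
}
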