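# Preprocessing of 3D fluorescence stacks before classifier training,
# prediction and quantification: top-hat background subtraction followed by
# per-stack max normalization to 4096.

#' Top-hat background subtraction
#'
#' Subtracts the grayscale morphological opening with a box structuring
#' element of half-width `radius` in z, y and x (a true 3D top-hat, default
#' 7x7x7 support). Removes smooth background while preserving bright
#' structures smaller than the box; the result is pointwise >= 0 and <= the
#' input.
#'
#' @param stack An [image_stack()] or 3D array.
#' @param radius Box half-width in voxels (>= 1, default 3).
#' @return An [image_stack()].
#' @export
tophat_background <- function(stack, radius = 3L) {
  stack <- as_image_stack(stack)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  if (any(dim(stack$voxels) < 2L * radius + 1L))
    stop("stack smaller than the structuring element")
  opening <- dilate_box3(erode_box3(stack$voxels, radius), radius)
  out <- stack$voxels - opening
  out[out < 0] <- 0   # guard fp; opening <= input holds exactly
  image_stack(out, stack$voxel_size, stack$channel)
}

#' Per-stack maximum normalization
#'
#' Rescales every voxel by `4096 / max(stack)` so the new maximum is exactly
#' 4096. Values stay floating point (no re-quantization). Applied after
#' [tophat_background()] in the standard pipeline.
#'
#' @param stack An [image_stack()] or 3D array with positive maximum.
#' @return An [image_stack()].
#' @export
normalize_max <- function(stack) {
  stack <- as_image_stack(stack)
  mx <- max(stack$voxels)
  if (mx <= 0) stop("degenerate input: all-zero (or non-positive) stack")
  image_stack(stack$voxels * (4096 / mx), stack$voxel_size, stack$channel)
}

#' Standard LM preprocessing pipeline
#'
#' Top-hat background subtraction (radius 3) then max normalization to 4096,
#' in that order.
#'
#' @inheritParams tophat_background
#' @return An [image_stack()] with maximum 4096.
#' @export
preprocess_stack <- function(stack, radius = 3L) {
  normalize_max(tophat_background(stack, radius))
}
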