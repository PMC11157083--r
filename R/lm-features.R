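# Convolutional feature bank for the pixel classifier. Filter vocabulary:
# original, gaussian, difference_of_gaussian, laplace_of_gaussian_box,
# sobel_of_gaussian, median_box, mean_box, tophat_box, each at sigma 1 or 2.
# "Box" filters use half-width = sigma.

FILTER_VOCABULARY <- c("original", "gaussian", "difference_of_gaussian",
                       "laplace_of_gaussian_box", "sobel_of_gaussian",
                       "median_box", "mean_box", "tophat_box")

#' Feature bank specification
#'
#' An ordered list of (filter, sigma) pairs drawn from the fixed vocabulary
#' `original`, `gaussian`, `difference_of_gaussian`,
#' `laplace_of_gaussian_box`, `sobel_of_gaussian`, `median_box`, `mean_box`,
#' `tophat_box` with sigma 1 or 2. The production default is the most
#' efficient combination found for S-opsin stacks: the original image plus
#' Gaussian blur, difference of Gaussian and Laplace box of Gaussian, all at
#' sigma 1.
#'
#' @param filters Character vector of filter names.
#' @param sigmas Numeric vector of sigmas, recycled to `length(filters)`.
#' @return Data.frame of class `feature_bank` with columns `filter`, `sigma`.
#' @export
feature_bank <- function(filters = c("original", "gaussian",
                                     "difference_of_gaussian",
                                     "laplace_of_gaussian_box"),
                         sigmas = c(0, 1, 1, 1)) {
  if (length(filters) == 0L) stop("feature bank must be non-empty")
  bad <- setdiff(filters, FILTER_VOCABULARY)
  if (length(bad)) stop("unknown filter name(s): ", paste(bad, collapse = ", "))
  sigmas <- rep_len(sigmas, length(filters))
  structure(data.frame(filter = filters, sigma = sigmas,
                       stringsAsFactors = FALSE),
            class = c("feature_bank", "data.frame"))
}

gaussian_blur3 <- function(a, sigma) {
  k <- gaussian_kernel1(sigma)
  for (ax in 1:3) a <- conv_axis3(a, k, ax)
  a
}

laplace_box3 <- function(a) {
  # 6-neighbour discrete Laplacian, replicate edges
  out <- -6 * a
  for (ax in 1:3) {
    n <- dim(a)[ax]
    out <- out + slice_axis3(a, pmin(seq_len(n) + 1L, n), ax) +
      slice_axis3(a, pmax(seq_len(n) - 1L, 1L), ax)
  }
  out
}

sobel_magnitude3 <- function(a) {
  d <- c(-1, 0, 1); s <- c(1, 2, 1) / 4
  g2 <- array(0, dim(a))
  for (ax in 1:3) {
    g <- a
    for (ax2 in 1:3) g <- conv_axis3(g, if (ax2 == ax) d else s, ax2)
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

mean_box3 <- function(a, r) {
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  for (ax in 1:3) a <- conv_axis3(a, k, ax)
  a
}

median_box3 <- function(a, r) {
  # gather all (2r+1)^3 shifted copies (replicate edges) and take row medians
  d <- dim(a)
  offs <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  n <- nrow(offs)
  m <- matrix(0, length(a), n)
  for (i in seq_len(n)) {
    iz <- pmin(pmax(seq_len(d[1]) + offs$dz[i], 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + offs$dy[i], 1L), d[2])
    ix <- pmin(pmax(seq_len(d[3]) + offs$dx[i], 1L), d[3])
    m[, i] <- a[iz, iy, ix]
  }
  # odd n: median is the middle order statistic; partial sort per row is
  # still O(n log n) via apply, acceptable at test scales
  med <- apply(m, 1L, stats::median.default)
  array(med, d)
}

apply_filter3 <- function(a, filter, sigma) {
  r <- max(1L, as.integer(round(sigma)))
  switch(filter,
         original = a,
         gaussian = gaussian_blur3(a, sigma),
         difference_of_gaussian = gaussian_blur3(a, sigma) -
           gaussian_blur3(a, 2 * sigma),
         laplace_of_gaussian_box = laplace_box3(gaussian_blur3(a, sigma)),
         sobel_of_gaussian = sobel_magnitude3(gaussian_blur3(a, sigma)),
         median_box = median_box3(a, r),
         mean_box = mean_box3(a, r),
         tophat_box = a - dilate_box3(erode_box3(a, r), r),
         stop("unknown filter name: ", filter))
}

#' Per-voxel feature vectors for a stack
#'
#' Applies every (filter, sigma) entry of the bank to the (preprocessed)
#' stack and returns one feature column per entry, voxels in array order.
#' Deterministic.
#'
#' @param stack An [image_stack()] or 3D array.
#' @param bank A [feature_bank()].
#' @return Numeric matrix, `n_voxels x nrow(bank)`, with named columns
#'   `filter_sigma`.
#' @export
compute_features <- function(stack, bank = feature_bank()) {
  stack <- as_image_stack(stack)
  stopifnot(inherits(bank, "feature_bank"))
  a <- stack$voxels
  out <- matrix(0, length(a), nrow(bank))
  colnames(out) <- ifelse(bank$filter == "original", "original",
                          paste0(bank$filter, "_s", bank$sigma))
  for (i in seq_len(nrow(bank)))
    out[, i] <- as.vector(apply_filter3(a, bank$filter[i], bank$sigma[i]))
  out
}
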