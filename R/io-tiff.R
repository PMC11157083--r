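# Minimal baseline TIFF 6.0 I/O (uncompressed, single-channel grayscale,
# strip-based, 8/16-bit unsigned integer or 32-bit float, little- or
# big-endian on read). No imaging package exists in the target R
# environment, so this implements exactly the subset the pipelines need;
# multi-sample (color) files are rejected by design.

#' Read a grayscale TIFF
#'
#' Reads an uncompressed single-channel TIFF. A single page is returned as a
#' [gray_image()]; a multi-page file as an [image_stack()] with pages along
#' z. Multi-sample (color) files are rejected rather than silently
#' converted.
#'
#' @param path File path.
#' @param pixel_size Pixel size (um) stored on a 2D result.
#' @param voxel_size Voxel size (z, y, x) stored on a 3D result.
#' @return A [gray_image()] or [image_stack()].
#' @export
read_tiff <- function(path, pixel_size = 1 / 287.5,
                      voxel_size = c(1, 0.323, 0.323)) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(as.integer(magic), c(0x49L, 0x49L))) "little"
  else if (identical(as.integer(magic), c(0x4dL, 0x4dL))) "big"
  else stop("not a TIFF file")
  r16 <- function() readBin(con, "integer", 1, 2, signed = FALSE,
                            endian = endian)
  r32 <- function() {
    v <- readBin(con, "integer", 1, 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (r16() != 42L) stop("bad TIFF magic number")
  ifd_offset <- r32()
  pages <- list()
  while (ifd_offset != 0) {
    seek(con, ifd_offset)
    n_entries <- r16()
    tags <- list()
    for (e in seq_len(n_entries)) {
      tag <- r16(); type <- r16(); count <- r32()
      value_pos <- seek(con)   # current position = value field
      elt_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      nbytes <- elt_size * count
      if (nbytes > 4) { off <- r32(); seek(con, off) }
      vals <- switch(as.character(type),
                     "3" = readBin(con, "integer", count, 2, signed = FALSE,
                                   endian = endian),
                     "4" = vapply(seq_len(count), function(i) {
                       v <- readBin(con, "integer", 1, 4, endian = endian)
                       if (v < 0) v + 2^32 else v
                     }, numeric(1)),
                     "1" = as.integer(readBin(con, "raw", count)),
                     NULL)
      seek(con, value_pos + 4)
      tags[[as.character(tag)]] <- vals
    }
    ifd_offset <- r32()
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop("TIFF missing dimensions")
    if (!identical(as.integer(g(259, 1L)), 1L))
      stop("compressed TIFF not supported")
    spp <- g(277, 1L)
    if (spp != 1L)
      stop("multi-channel input rejected; supply a single-channel image")
    bits <- g(258, 1L)
    fmt <- g(339, 1L)
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF missing strip offsets")
    if (is.null(counts)) counts <- rep(width * height * bits / 8 /
                                         length(offsets), length(offsets))
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n_elt <- counts[s] / (bits / 8)
      v <- if (fmt == 3L) {
        if (bits != 32L) stop("only 32-bit float TIFF supported")
        readBin(con, "double", n_elt, 4, endian = endian)
      } else if (bits == 8L) {
        as.numeric(readBin(con, "integer", n_elt, 1, signed = (fmt == 2L),
                           endian = endian))
      } else if (bits == 16L) {
        as.numeric(readBin(con, "integer", n_elt, 2, signed = (fmt == 2L),
                           endian = endian))
      } else if (bits == 32L) {
        vv <- readBin(con, "integer", n_elt, 4, endian = endian)
        if (fmt != 2L) vv[vv < 0] <- vv[vv < 0] + 2^32
        as.numeric(vv)
      } else stop("unsupported bit depth: ", bits)
      vals <- c(vals, v)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height,
                                          ncol = width, byrow = TRUE)
  }
  if (length(pages) == 0L) stop("TIFF contains no images")
  if (length(pages) == 1L) return(gray_image(pages[[1]], pixel_size))
  a <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
  image_stack(a, voxel_size)
}

#' Write a grayscale TIFF
#'
#' Writes an uncompressed little-endian baseline TIFF; a matrix or
#' [gray_image()] becomes one page, an [image_stack()] one page per z slice.
#'
#' @param x Matrix, [gray_image()], or [image_stack()].
#' @param path Output path.
#' @param format `"float32"` (default), `"uint16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, format = c("float32", "uint16", "uint8")) {
  format <- match.arg(format)
  pages <- if (inherits(x, "image_stack")) {
    lapply(seq_len(dim(x$voxels)[1]), function(z) x$voxels[z, , ])
  } else if (inherits(x, "gray_image")) list(x$pixels) else list(as.matrix(x))
  bits <- switch(format, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (format == "float32") 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L)
  # layout: header(8) | page data ... | IFDs
  sizes <- vapply(pages, function(p) length(p) * bits / 8, numeric(1))
  data_offsets <- 8 + cumsum(c(0, sizes[-length(sizes)]))
  ifd_size <- 2 + 10 * 12 + 4
  ifd_offsets <- 8 + sum(sizes) + (seq_along(pages) - 1L) * ifd_size
  w32(ifd_offsets[1])
  for (p in pages) {
    v <- as.vector(t(p))   # row-major
    if (format == "float32") writeBin(v, con, 4, endian = "little")
    else {
      iv <- as.integer(round(v))
      if (any(iv < 0 | iv > 2^bits - 1))
        stop("values out of range for ", format)
      writeBin(iv, con, bits / 8, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    w16(10L)
    entry(256L, 4L, 1L, ncol(p))            # ImageWidth
    entry(257L, 4L, 1L, nrow(p))            # ImageLength
    entry(258L, 3L, 1L, bits)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression = none
    entry(262L, 3L, 1L, 1L)                 # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_offsets[i])    # StripOffsets
    entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, 1L, nrow(p))            # RowsPerStrip
    entry(279L, 4L, 1L, sizes[i])           # StripByteCounts
    entry(339L, 3L, 1L, fmt)                # SampleFormat
    w32(if (i < length(pages)) ifd_offsets[i + 1L] else 0L)
  }
  invisible(path)
}
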