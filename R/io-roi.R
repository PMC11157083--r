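# ImageJ ROI file dialect: single .roi files and .zip archives of ROIs, as
# saved by ImageJ's ROI manager / selection tools. Big-endian binary layout;
# supported types are polygon (0), freehand (7), traced (8) and rectangle
# (1). Reading .zip uses base unzip; writing uses a minimal STORED-entry
# zip writer (no external zip binary required).

ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
               polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L)

#' Read an ImageJ .roi file
#'
#' @param path Path to a `.roi` file, or a raw vector of its bytes.
#' @return List of class `imagej_roi` with `name`, `type`, and vertex
#'   vectors `x`, `y` in ImageJ pixel coordinates (0-based, vertex (0,0) is
#'   the top-left corner of the first pixel).
#' @export
read_imagej_roi <- function(path) {
  bytes <- if (is.raw(path)) path else readBin(path, "raw",
                                               file.size(path))
  u8 <- function(i) as.integer(bytes[i])
  u16 <- function(i) u8(i) * 256L + u8(i + 1L)
  s16 <- function(i) { v <- u16(i); if (v >= 32768L) v - 65536L else v }
  u32 <- function(i) ((u8(i) * 256 + u8(i + 1)) * 256 + u8(i + 2)) * 256 +
    u8(i + 3)
  if (rawToChar(bytes[1:4]) != "Iout") stop("not an ImageJ ROI file")
  type <- u8(7L)
  top <- s16(9L); left <- s16(11L); bottom <- s16(13L); right <- s16(15L)
  n <- u16(17L)
  name <- NA_character_
  h2 <- u32(61L)
  if (h2 > 0 && h2 + 24 <= length(bytes)) {
    name_off <- u32(h2 + 17L); name_len <- u32(h2 + 21L)
    if (name_len > 0 && name_off + 2 * name_len <= length(bytes)) {
      chars <- vapply(seq_len(name_len),
                      function(i) u16(name_off + 2L * (i - 1L) + 1L),
                      integer(1))
      name <- intToUtf8(chars)
    }
  }
  tname <- names(ROI_TYPES)[match(type, ROI_TYPES)]
  if (is.na(tname)) stop("unsupported ROI type code: ", type)
  if (tname %in% c("polygon", "freehand", "traced")) {
    if (n < 3L) stop("polygon ROI with fewer than 3 vertices")
    xs <- vapply(seq_len(n), function(i) s16(64L + 2L * (i - 1L) + 1L),
                 integer(1)) + left
    ys <- vapply(seq_len(n), function(i) s16(64L + 2L * (n + i - 1L) + 1L),
                 integer(1)) + top
  } else if (tname %in% c("rect", "oval")) {
    xs <- c(left, right, right, left)
    ys <- c(top, top, bottom, bottom)
    if (tname == "oval") tname <- "rect"   # treated as bounding rectangle
  } else {
    stop("ROI type '", tname, "' is not supported")
  }
  structure(list(name = name, type = tname, x = xs, y = ys),
            class = "imagej_roi")
}

#' Write an ImageJ .roi file
#'
#' Writes a polygon ROI in the ImageJ dialect (version 228, big-endian)
#' readable by ImageJ and by [read_imagej_roi()].
#'
#' @param roi An `imagej_roi` (or list with `x`, `y`, optional `name`).
#' @param path Output path, or `NULL` to return the raw bytes.
#' @return `path` (or the raw vector), invisibly.
#' @export
write_imagej_roi <- function(roi, path = NULL) {
  x <- as.integer(round(roi$x)); y <- as.integer(round(roi$y))
  stopifnot(length(x) == length(y), length(x) >= 3L)
  name <- if (is.null(roi$name) || is.na(roi$name)) "roi" else roi$name
  n <- length(x)
  left <- min(x); top <- min(y)
  b16 <- function(v) as.raw(c(v %/% 256, v %% 256) %% 256)
  b32 <- function(v) as.raw(c(v %/% 16777216, v %/% 65536, v %/% 256, v) %% 256)
  h2_off <- 64L + 4L * n
  name_off <- h2_off + 64L
  out <- c(charToRaw("Iout"), b16(228L),                # magic, version
           as.raw(c(0L, 0L)),                           # type polygon, pad
           b16(top), b16(left), b16(max(y)), b16(max(x)),
           b16(n), raw(42),                             # bytes 18..59
           b32(h2_off))
  out <- c(out, unlist(lapply(x - left, b16)), unlist(lapply(y - top, b16)))
  h2 <- raw(64)
  h2[17:20] <- b32(name_off)
  h2[21:24] <- b32(nchar(name))
  out <- c(out, h2, unlist(lapply(utf8ToInt(name), b16)))
  if (is.null(path)) return(invisible(out))
  writeBin(out, path)
  invisible(path)
}

#' Read all ROIs from an ImageJ ROI zip archive
#'
#' @param path Path to a `.zip` of `.roi` files.
#' @return Named list of `imagej_roi` objects (names from entry names).
#' @export
read_roi_zip <- function(path) {
  exdir <- tempfile("roizip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
  rois <- lapply(files, read_imagej_roi)
  names(rois) <- sub("\\.roi$", "", basename(files), ignore.case = TRUE)
  rois
}

#' Write ROIs to an ImageJ-compatible zip archive
#'
#' Stores each ROI as `<name>.roi` in an uncompressed (STORED) zip, the
#' archive layout ImageJ's ROI manager produces.
#'
#' @param rois List of `imagej_roi` objects (named, or carrying `name`s).
#' @param path Output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_roi_zip <- function(rois, path) {
  nms <- names(rois)
  if (is.null(nms)) nms <- vapply(seq_along(rois), function(i) {
    nm <- rois[[i]]$name
    if (is.null(nm) || is.na(nm)) paste0("roi", i) else nm
  }, character(1))
  entries <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]; r$name <- nms[i]
    list(name = paste0(nms[i], ".roi"), data = write_imagej_roi(r, NULL))
  })
  write_stored_zip(entries, path)
  invisible(path)
}

# ---- minimal STORED zip writer with CRC-32 --------------------------------

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320 as signed
          else bitwShiftR(c, 1L)
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8L) , tab[idx + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else crc
}

le16 <- function(v) as.raw(c(v %% 256, v %/% 256) %% 256)
le32 <- function(v) as.raw(c(v, v %/% 256, v %/% 65536, v %/% 16777216) %% 256)

write_stored_zip <- function(entries, path) {
  locals <- raw(0); central <- raw(0); offset <- 0
  for (e in entries) {
    data <- e$data
    nm <- charToRaw(e$name)
    crc <- crc32(data)
    lh <- c(le32(0x04034b50), le16(20), le16(0), le16(0), le16(0), le16(0),
            le32(crc), le32(length(data)), le32(length(data)),
            le16(length(nm)), le16(0), nm, data)
    cd <- c(le32(0x02014b50), le16(20), le16(20), le16(0), le16(0), le16(0),
            le16(0), le32(crc), le32(length(data)), le32(length(data)),
            le16(length(nm)), le16(0), le16(0), le16(0), le16(0), le32(0),
            le32(offset), nm)
    locals <- c(locals, lh)
    central <- c(central, cd)
    offset <- offset + length(lh)
  }
  eocd <- c(le32(0x06054b50), le16(0), le16(0), le16(length(entries)),
            le16(length(entries)), le32(length(central)), le32(offset),
            le16(0))
  writeBin(c(locals, central, eocd), path)
  invisible(path)
}

# bitwShiftR on negative ints: emulate logical shift via masking
bitwShiftR <- function(x, n) {
  if (x >= 0) base::bitwShiftR(x, n)
  else base::bitwShiftR(bitwAnd(x, 2147483647L), n) +
    base::bitwShiftR(1073741824L, n - 1L)  # reinsert the sign bit
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' A pixel belongs to the ROI iff its center lies inside the polygon
#' (even-odd rule). Pixel (row i, col j) has its center at ImageJ
#' coordinates (x = j - 0.5, y = i - 0.5).
#'
#' @param roi An `imagej_roi` (or list with vertex vectors `x`, `y`).
#' @param nrow,ncol Mask dimensions.
#' @return Logical matrix.
#' @export
roi_to_mask <- function(roi, nrow, ncol) {
  px <- roi$x; py <- roi$y
  j <- seq_len(ncol); i <- seq_len(nrow)
  cx <- rep(j - 0.5, each = nrow)
  cy <- rep(i - 0.5, times = ncol)
  inside <- rep(FALSE, nrow * ncol)
  n <- length(px)
  jprev <- n
  for (k in seq_len(n)) {
    x1 <- px[jprev]; y1 <- py[jprev]; x2 <- px[k]; y2 <- py[k]
    crosses <- ((y2 > cy) != (y1 > cy)) &
      (cx < (x1 - x2) * (cy - y2) / (y1 - y2) + x2)
    inside <- xor(inside, crosses & !is.na(crosses))
    jprev <- k
  }
  matrix(inside, nrow, ncol)
}
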