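# Morphometry of predicted POS masks: 26-connected labelling, isotropic
# rescaling to 0.323 um voxels, per-label size/shape/intensity features,
# pooled 5-95 percentile volume filter and per-image summaries.

#' Connected-component labelling (26-connectivity)
#'
#' Labels the foreground of a binary 3D mask under 26-connectivity. Labels
#' are 1..K ordered deterministically by each component's first voxel in
#' array scan order (z fastest).
#'
#' @param mask Logical/0-1 3D array.
#' @return Integer 3D array of labels (0 = background), with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask) {
  mask <- as.array(mask)
  stopifnot(length(dim(mask)) == 3L)
  fg <- as.logical(mask)
  d <- dim(mask)
  lab <- array(0, d)
  lab[fg] <- which(fg)   # provisional label = own linear index
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  iz <- seq_len(d[1]); iy <- seq_len(d[2]); ix <- seq_len(d[3])
  repeat {
    before <- lab
    for (k in seq_len(nrow(offs))) {
      sz <- iz + offs[k, 1]; sy <- iy + offs[k, 2]; sx <- ix + offs[k, 3]
      okz <- sz >= 1L & sz <= d[1]
      oky <- sy >= 1L & sy <= d[2]
      okx <- sx >= 1L & sx <= d[3]
      nb <- array(0, d)
      nb[iz[okz], iy[oky], ix[okx]] <- lab[sz[okz], sy[oky], sx[okx]]
      upd <- fg & nb > 0 & (lab == 0 | nb < lab)
      lab[upd] <- nb[upd]
    }
    if (identical(lab, before)) break
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  if (length(ids)) out[fg] <- match(lab[fg], ids)
  attr(out, "n_labels") <- length(ids)
  out
}

#' Resample a stack or label image to isotropic voxels
#'
#' Intensities are resampled with trilinear interpolation, label images with
#' nearest-neighbour lookup, onto a grid with `target` micrometre spacing in
#' all three axes. Physical extents are preserved to within one voxel.
#'
#' @param x An [image_stack()], or a 3D array together with `voxel_size`.
#' @param target Target isotropic voxel edge in micrometres (default 0.323).
#' @param voxel_size Required if `x` is a plain array: (z, y, x) in um.
#' @param labels If `TRUE`, use nearest-neighbour (for label/mask images).
#' @return An [image_stack()] with isotropic `voxel_size` (label output is
#'   an integer array wrapped the same way).
#' @export
rescale_isotropic <- function(x, target = 0.323, voxel_size = NULL,
                              labels = FALSE) {
  if (inherits(x, "image_stack")) {
    a <- x$voxels; vs <- x$voxel_size; ch <- x$channel
  } else {
    if (is.null(voxel_size)) stop("missing voxel-size metadata")
    a <- x; vs <- voxel_size; ch <- "resampled"
  }
  d <- dim(a)
  nd <- pmax(1L, as.integer(round(d * vs / target)))
  if (all(abs(vs - target) < 1e-12)) {
    out <- a
  } else {
    # physical center of output voxel i: (i - 0.5) * target; map into input
    # index space: idx = pos / vs + 0.5
    src <- lapply(1:3, function(ax)
      (seq_len(nd[ax]) - 0.5) * target / vs[ax] + 0.5)
    if (labels) {
      idx <- lapply(1:3, function(ax)
        pmin(pmax(as.integer(round(src[[ax]])), 1L), d[ax]))
      out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      dim(out) <- nd
    } else {
      lo <- lapply(1:3, function(ax)
        pmin(pmax(floor(src[[ax]]), 1), d[ax]))
      hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d[ax]))
      fr <- lapply(1:3, function(ax)
        pmin(pmax(src[[ax]] - lo[[ax]], 0), 1))
      out <- array(0, nd)
      gz <- list(lo[[1]], hi[[1]]); gy <- list(lo[[2]], hi[[2]])
      gx <- list(lo[[3]], hi[[3]])
      wz <- list(1 - fr[[1]], fr[[1]]); wy <- list(1 - fr[[2]], fr[[2]])
      wx <- list(1 - fr[[3]], fr[[3]])
      for (cz in 1:2) for (cy in 1:2) for (cx in 1:2) {
        w <- outer(outer(wz[[cz]], wy[[cy]]), wx[[cx]])
        dim(w) <- nd
        out <- out + w * a[gz[[cz]], gy[[cy]], gx[[cx]], drop = FALSE]
      }
    }
  }
  image_stack(out, rep(target, 3), ch)
}

# surface area of a binary label by the coarea formula on the Gaussian-
# smoothed indicator: A = sum |grad(G_sigma * chi)| * h^3. Mesh-free; makes
# sphericity -> 1 attainable for digital balls (voxel-face counting would
# overestimate by ~50%). The indicator is upsampled 2x (nearest neighbour)
# first so that opposite faces of thin labels do not cancel under the
# smoothing; sigma = 1 upsampled voxel = 0.5 original voxels.
surface_area_coarea <- function(chi, h, sigma = 1) {
  # 2x nearest-neighbour upsampling
  d0 <- dim(chi)
  chi <- chi[rep(seq_len(d0[1]), each = 2L),
             rep(seq_len(d0[2]), each = 2L),
             rep(seq_len(d0[3]), each = 2L), drop = FALSE]
  h <- h / 2
  pad <- max(4L, ceiling(4 * sigma))
  d <- dim(chi)
  a <- array(0, d + 2L * pad)
  a[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- chi
  a <- gaussian_blur3(a, sigma)
  g2 <- array(0, dim(a))
  for (ax in 1:3) {
    n <- dim(a)[ax]
    fwd <- slice_axis3(a, pmin(seq_len(n) + 1L, n), ax)
    bwd <- slice_axis3(a, pmax(seq_len(n) - 1L, 1L), ax)
    g2 <- g2 + ((fwd - bwd) / 2)^2
  }
  sum(sqrt(g2)) * h^2   # |grad| has units 1/h; * h^3 volume element
}

# max pairwise distance between surface-voxel centers; for large surfaces,
# reduce first to support points of ~200 deterministic directions
feret_diameter <- function(coords, h) {
  if (nrow(coords) < 2L) return(0)
  p <- coords
  if (nrow(p) > 3000L) {
    i <- seq_len(200L)
    phi <- acos(1 - 2 * (i - 0.5) / 200)
    lam <- pi * (1 + sqrt(5)) * i
    dirs <- cbind(cos(phi), sin(phi) * cos(lam), sin(phi) * sin(lam))
    keep <- unique(apply(p %*% t(dirs), 2L, which.max))
    p <- p[keep, , drop = FALSE]
  }
  d2 <- 0
  for (i in seq_len(nrow(p) - 1L)) {
    di <- (p[(i + 1L):nrow(p), , drop = FALSE] -
             matrix(p[i, ], nrow(p) - i, 3, byrow = TRUE))^2
    d2 <- max(d2, max(rowSums(di)))
  }
  sqrt(d2) * h
}

#' Per-label feature extraction
#'
#' Measures each label of an isotropically rescaled label image: volume
#' (voxel count times voxel volume), bounding-box height (physical extent
#' along y, the apical-basal axis as imaged), Feret diameter (max pairwise
#' distance between surface-voxel centers), sphericity
#' (`pi^(1/3) (6V)^(2/3) / A` with surface area A from the smoothed-indicator
#' coarea estimate) and intensity statistics over the normalized image.
#'
#' @param labels Integer 3D label array ([image_stack()] or array) on an
#'   isotropic grid.
#' @param intensity Matching intensity stack (same grid).
#' @param voxel_size Isotropic voxel edge in um (taken from the stack if
#'   available; default 0.323).
#' @return Data.frame with one row per label: `label_id`, `volume_um3`,
#'   `bbox_height_um`, `feret_um`, `sphericity`, `intensity_min/mean/max/sum`,
#'   `centroid_z/y/x_um`, `n_voxels`.
#' @export
extract_features <- function(labels, intensity, voxel_size = NULL) {
  if (inherits(labels, "image_stack")) {
    if (is.null(voxel_size)) voxel_size <- labels$voxel_size[1]
    labels <- labels$voxels
  }
  if (inherits(intensity, "image_stack")) intensity <- intensity$voxels
  if (is.null(voxel_size)) voxel_size <- 0.323
  h <- voxel_size
  if (!identical(dim(labels), dim(intensity)))
    stop("label/intensity shape mismatch")
  ids <- sort(unique(labels[labels > 0]))
  d <- dim(labels)
  rows <- lapply(ids, function(id) {
    lin <- which(labels == id)
    co <- arrayInd(lin, d)   # columns z, y, x
    n <- length(lin)
    vol <- n * h^3
    bbox_h <- (diff(range(co[, 2])) + 1L) * h
    # surface voxels: any 6-neighbour outside the label
    chi_dim <- apply(co, 2L, function(v) diff(range(v)) + 1L)
    off <- apply(co, 2L, min) - 1L
    chi <- array(0, chi_dim + 2L)   # 1-voxel pad
    chi[cbind(co[, 1] - off[1] + 1L, co[, 2] - off[2] + 1L,
              co[, 3] - off[3] + 1L)] <- 1
    # 6-neighbour interior; complement = surface voxels
    interior <- chi > 0
    for (ax in 1:3) {
      nn <- dim(chi)[ax]
      interior <- interior &
        slice_axis3(chi, pmin(seq_len(nn) + 1L, nn), ax) > 0 &
        slice_axis3(chi, pmax(seq_len(nn) - 1L, 1L), ax) > 0
    }
    surf <- which(chi > 0 & !interior)
    sco <- arrayInd(surf, dim(chi))
    feret <- feret_diameter(sco, h)
    area <- surface_area_coarea(chi, h)
    spher <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
    iv <- intensity[lin]
    data.frame(label_id = id, volume_um3 = vol, bbox_height_um = bbox_h,
               feret_um = feret, sphericity = spher,
               intensity_min = min(iv), intensity_mean = mean(iv),
               intensity_max = max(iv), intensity_sum = sum(iv),
               centroid_z_um = (mean(co[, 1]) - 0.5) * h,
               centroid_y_um = (mean(co[, 2]) - 0.5) * h,
               centroid_x_um = (mean(co[, 3]) - 0.5) * h,
               n_voxels = n)
  })
  if (length(rows) == 0L)
    return(data.frame(label_id = integer(), volume_um3 = numeric(),
                      bbox_height_um = numeric(), feret_um = numeric(),
                      sphericity = numeric(), intensity_min = numeric(),
                      intensity_mean = numeric(), intensity_max = numeric(),
                      intensity_sum = numeric(), centroid_z_um = numeric(),
                      centroid_y_um = numeric(), centroid_x_um = numeric(),
                      n_voxels = integer()))
  do.call(rbind, rows)
}

#' Pooled percentile volume filter
#'
#' Keeps records whose volume lies within the `[lo, hi]` percentiles of the
#' pooled volume distribution (linear-interpolation quantiles over all
#' supplied records, i.e. the whole experiment dataset, not per image).
#' Excludes segmentation clusters (above the 95th) and speckle (below the
#' 5th); the unfiltered set should be retained for summed-volume analyses.
#'
#' @param records Data.frame from [extract_features()] (possibly pooled over
#'   images) with a `volume_um3` column.
#' @param lo,hi Percentile bounds as fractions (defaults 0.05, 0.95).
#' @param pool Optional numeric vector of volumes defining the percentile
#'   pool (defaults to `records$volume_um3`); use this to filter per-image
#'   tables against experiment-wide thresholds.
#' @return The filtered data.frame (always a subset of the input), with the
#'   thresholds in attributes `lo_um3`, `hi_um3`.
#' @export
percentile_filter <- function(records, lo = 0.05, hi = 0.95, pool = NULL) {
  if (nrow(records) == 0L) stop("empty input")
  v <- records$volume_um3
  poolv <- if (is.null(pool)) v else pool
  q <- stats::quantile(poolv, c(lo, hi), type = 7, names = FALSE)
  out <- records[v >= q[1] & v <= q[2], , drop = FALSE]
  attr(out, "lo_um3") <- q[1]
  attr(out, "hi_um3") <- q[2]
  out
}

#' Per-image summary of POS records
#'
#' `n_pos` counts the filtered labels; `summed_volume_um3` sums over the
#' unfiltered records (clusters contribute to total volume even when they
#' are excluded as individual POS); feature means are over filtered records.
#'
#' @param records Filtered records of one image.
#' @param unfiltered_records All records of the same image before filtering
#'   (defaults to `records`).
#' @param image_id,replicate_id,group Metadata copied into the row.
#' @return One-row data.frame.
#' @export
summarize_image <- function(records, unfiltered_records = records,
                            image_id = "image", replicate_id = NA,
                            group = NA) {
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(image = image_id, replicate = replicate_id, group = group,
             n_pos = nrow(records),
             summed_volume_um3 = sum(unfiltered_records$volume_um3),
             mean_volume_um3 = mean_or_na(records$volume_um3),
             mean_bbox_height_um = mean_or_na(records$bbox_height_um),
             mean_feret_um = mean_or_na(records$feret_um),
             mean_sphericity = mean_or_na(records$sphericity),
             mean_intensity_min = mean_or_na(records$intensity_min),
             mean_intensity_mean = mean_or_na(records$intensity_mean),
             stringsAsFactors = FALSE)
}

#' Full LM quantification of one predicted mask
#'
#' Labels the mask, rescales labels and intensity to isotropic voxels,
#' extracts per-label features, applies the pooled percentile filter (if
#' `filter = TRUE`) and summarizes. Convenience wrapper over the individual
#' steps for single-image use.
#'
#' @param mask Binary 3D array (prediction).
#' @param stack The preprocessed intensity [image_stack()].
#' @param target Isotropic voxel edge (um).
#' @param filter Apply the 5-95 percent volume filter within this image.
#' @param image_id Identifier for the summary row.
#' @return List with `records` (filtered), `records_unfiltered`, `summary`.
#' @export
quantify_mask <- function(mask, stack, target = 0.323, filter = TRUE,
                          image_id = "image") {
  stack <- as_image_stack(stack)
  lab <- label_components(mask)
  lab_iso <- rescale_isotropic(lab, target, voxel_size = stack$voxel_size,
                               labels = TRUE)
  int_iso <- rescale_isotropic(stack, target)
  rec <- extract_features(lab_iso$voxels, int_iso$voxels, voxel_size = target)
  recf <- if (filter && nrow(rec) > 0L) percentile_filter(rec) else rec
  list(records = recf, records_unfiltered = rec,
       summary = summarize_image(recf, rec, image_id = image_id))
}
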