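# Q-tensor coherency analysis. The coherency of a weighted set of nematic
# directors is the scalar nematic order parameter: twice the larger
# eigenvalue of the weight-normalized Q-tensor, equivalently
# |sum(m * exp(2i*theta))| / sum(m), in [0, 1].

#' Q-tensor of a weighted director set
#'
#' `qxx = sum m (cos^2 theta - 1/2)`, `qxy = sum m cos theta sin theta`.
#' The tensor is symmetric and traceless, so these two entries describe it
#' fully. Members with weight 0 or undefined angle contribute nothing.
#'
#' @param theta Director angles in radians (any real; used modulo pi). `NA`
#'   allowed where `m == 0`.
#' @param m Non-negative weights, same length as `theta`.
#' @return List of class `q_tensor` with `qxx`, `qxy`, `weight_sum`.
#' @export
q_tensor <- function(theta, m = rep(1, length(theta))) {
  if (length(theta) == 0L) stop("empty neighborhood")
  stopifnot(length(m) == length(theta), all(m >= 0 | is.na(m)))
  keep <- !is.na(theta) & !is.na(m) & m > 0
  th <- theta[keep]; w <- m[keep]
  structure(list(qxx = sum(w * (cos(th)^2 - 0.5)),
                 qxy = sum(w * cos(th) * sin(th)),
                 weight_sum = sum(w)),
            class = "q_tensor")
}

#' Coherency (scalar nematic order parameter) of a Q-tensor
#'
#' Returns `2 * sqrt(qxx^2 + qxy^2) / weight_sum`, which equals twice the
#' larger eigenvalue of the normalized tensor and `|sum m e^{2 i theta}| /
#' sum m`. A zero-weight tensor has coherency 0.
#'
#' @param q A `q_tensor`.
#' @return Numeric in `[0, 1]`.
#' @export
coherency <- function(q) {
  stopifnot(inherits(q, "q_tensor"))
  if (q$weight_sum <= 0) return(0)
  2 * sqrt(q$qxx^2 + q$qxy^2) / q$weight_sum
}

#' Dominant director angle of a Q-tensor
#'
#' The orientation of the larger-eigenvalue eigenvector, obtained as the
#' four-quadrant inverse tangent of the doubled-angle vector, halved:
#' `0.5 * atan2(qxy, qxx)`, folded into `[0, 180)` degrees. Undefined (`NA`)
#' for a zero tensor.
#'
#' @param q A `q_tensor`.
#' @return Angle in degrees in `[0, 180)`, or `NA` if the tensor vanishes.
#' @export
dominant_angle <- function(q) {
  stopifnot(inherits(q, "q_tensor"))
  mag <- sqrt(q$qxx^2 + q$qxy^2)
  if (q$weight_sum <= 0 || mag <= 1e-14 * q$weight_sum) return(NA_real_)
  rad2deg(fold_pi(0.5 * atan2(q$qxy, q$qxx)))
}

#' Local coherency map over a ROI
#'
#' Slides a `(2*box_radius+1)^2` box over the orientation field and computes
#' the coherency and dominant angle of the Q-tensor of each box. A query
#' pixel is valid only if its whole box and every underlying 5x5 gradient
#' support lie inside the ROI -- equivalently, the ROI eroded by
#' `box_radius + 2` pixels (and the corresponding image-border margin).
#'
#' @param field An `orientation_field`.
#' @param roi_mask Logical matrix, same shape as the field.
#' @param box_radius Box half-width in pixels (default 12, i.e. 25x25; sized
#'   to span 2-3 membrane layers at 287.5 px/um).
#' @return List of class `coherency_map` with matrices `local_coherency`,
#'   `local_angle_deg` (NA outside `valid_mask`), logical `valid_mask`,
#'   `n_valid`, and the `box_radius` used. If no query pixel is valid the map
#'   is flagged `empty = TRUE` rather than raising an error.
#' @export
local_coherency_map <- function(field, roi_mask, box_radius = 12L) {
  stopifnot(inherits(field, "orientation_field"))
  roi_mask <- as.matrix(roi_mask)
  if (!identical(dim(roi_mask), dim(field$theta)))
    stop("roi_mask shape must match the orientation field")
  box_radius <- as.integer(box_radius)
  members <- erode_box2(roi_mask, 2L) & field$valid
  valid <- erode_box2(members, box_radius)
  w <- field$m * members
  w[is.na(field$theta)] <- 0
  th <- field$theta; th[is.na(th)] <- 0
  A <- box_sum2(w * cos(2 * th), box_radius)
  B <- box_sum2(w * sin(2 * th), box_radius)
  W <- box_sum2(w, box_radius)
  coh <- matrix(NA_real_, nrow(w), ncol(w))
  ang <- matrix(NA_real_, nrow(w), ncol(w))
  pos <- valid & W > 0
  coh[pos] <- sqrt(A[pos]^2 + B[pos]^2) / W[pos]
  coh[valid & W <= 0] <- 0
  ang[pos] <- rad2deg(fold_pi(0.5 * atan2(B[pos], A[pos])))
  structure(list(local_coherency = coh, local_angle_deg = ang,
                 valid_mask = valid, n_valid = sum(valid),
                 box_radius = box_radius, empty = sum(valid) == 0L),
            class = "coherency_map")
}

#' Global coherency and dominant angle of a ROI
#'
#' One Q-tensor over all pixels whose 5x5 gradient support is fully inside
#' the ROI (ROI eroded by 2 px, intersected with the gradient validity mask).
#'
#' @param field An `orientation_field`.
#' @param roi_mask Logical matrix.
#' @return List with `coherency`, `angle_deg` (NA if undefined) and
#'   `n_valid` (number of contributing pixels).
#' @export
global_coherency <- function(field, roi_mask) {
  stopifnot(inherits(field, "orientation_field"))
  roi_mask <- as.matrix(roi_mask)
  if (!identical(dim(roi_mask), dim(field$theta)))
    stop("roi_mask shape must match the orientation field")
  members <- erode_box2(roi_mask, 2L) & field$valid
  if (!any(members)) stop("ROI empty after erosion by the gradient support")
  q <- q_tensor(field$theta[members], field$m[members])
  list(coherency = coherency(q), angle_deg = dominant_angle(q),
       n_valid = sum(members))
}

#' Per-ROI coherency summary
#'
#' Combines a local coherency map and the global coherency of the same ROI
#' into the standard per-ROI record: mean local coherency (unweighted mean
#' over valid query pixels), global coherency and angle, and the ratio of
#' global to mean local coherency (the POS maturation index: ~1 for
#' uniformly stacked membranes, << 1 for patchwork alignment).
#'
#' @param map A `coherency_map`.
#' @param global Result of [global_coherency()].
#' @param roi_id Identifier stored in the summary.
#' @return A one-row data.frame with columns `roi_id`,
#'   `mean_local_coherency`, `global_coherency`, `global_angle_deg`,
#'   `ratio_global_to_local`, `n_valid_local`, `n_valid_global`.
#' @export
summarize_roi <- function(map, global, roi_id = "roi") {
  stopifnot(inherits(map, "coherency_map"))
  mlc <- if (map$n_valid >= 1L)
    mean(map$local_coherency[map$valid_mask]) else NA_real_
  ratio <- if (!is.na(mlc) && mlc > 0) global$coherency / mlc else NA_real_
  data.frame(roi_id = roi_id,
             mean_local_coherency = mlc,
             global_coherency = global$coherency,
             global_angle_deg = global$angle_deg,
             ratio_global_to_local = ratio,
             n_valid_local = map$n_valid,
             n_valid_global = global$n_valid,
             stringsAsFactors = FALSE)
}

#' Alignment of global-coherency angles across ROIs of one replicate
#'
#' Builds a unit-weight Q-tensor from the per-ROI global angles (respecting
#' their 180-degree periodicity); its coherency is the replicate alignment in
#' `[0, 1]` (1 iff all angles identical mod 180) and its dominant angle the
#' dominant membrane direction of the replicate.
#'
#' @param global_angles_deg Numeric vector of angles in degrees (>= 1).
#' @return List with `alignment`, `dominant_angle_deg`, `n_rois`.
#' @export
replicate_alignment <- function(global_angles_deg) {
  a <- global_angles_deg[!is.na(global_angles_deg)]
  if (length(a) == 0L) stop("need at least one global angle")
  q <- q_tensor(deg2rad(a))
  list(alignment = coherency(q), dominant_angle_deg = dominant_angle(q),
       n_rois = length(a))
}

#' Distributions of local coherency and director angles within a ROI
#'
#' Returns (a) a binned density of local coherency values on `[0, 1]` with
#' the mean local and global coherency as markers, and (b) a count histogram
#' of local directors on `[0, 180)` degrees suitable for polar display (the
#' duplication to `[180, 360)` is a rendering concern, not done here).
#'
#' @param map A `coherency_map`.
#' @param global Optional result of [global_coherency()] for the marker.
#' @param n_coh_bins,n_angle_bins Bin counts.
#' @return List with data.frames `coherency_density` (`mid`, `count`,
#'   `density`) and `angle_histogram` (`mid_deg`, `count`), plus markers
#'   `mean_local_coherency` and `global_coherency`.
#' @export
roi_distributions <- function(map, global = NULL, n_coh_bins = 25L,
                              n_angle_bins = 18L) {
  stopifnot(inherits(map, "coherency_map"))
  if (map$n_valid < 1L) stop("empty coherency map")
  coh <- map$local_coherency[map$valid_mask]
  ang <- map$local_angle_deg[map$valid_mask]
  ang <- ang[!is.na(ang)]
  cb <- seq(0, 1, length.out = n_coh_bins + 1L)
  ch <- graphics::hist(pmin(coh, 1 - 1e-12), breaks = cb, plot = FALSE)
  ab <- seq(0, 180, length.out = n_angle_bins + 1L)
  ah <- graphics::hist(ang %% 180, breaks = ab, plot = FALSE)
  list(coherency_density = data.frame(mid = ch$mids, count = ch$counts,
                                      density = ch$density),
       angle_histogram = data.frame(mid_deg = ah$mids, count = ah$counts),
       mean_local_coherency = mean(coh),
       global_coherency = if (is.null(global)) NA_real_ else global$coherency)
}

#' Full TEM coherency analysis of one image with its ROIs
#'
#' Runs gradient estimation, orientation extraction, optional grayscale- or
#' orientation-level downsampling, and per-ROI local/global coherency
#' summaries -- the complete per-image pipeline of the TEM arm.
#'
#' @param img [gray_image()] or matrix.
#' @param rois Named list of logical ROI masks (image shape), or a list of
#'   ROI polygon objects as returned by [read_imagej_roi()] /
#'   [read_roi_zip()] which are rasterized with the pixel-center rule.
#' @param box_radius Local box half-width (default 12).
#' @param downsample_gray,downsample_orient Integer factors (default 1).
#' @param image_id Identifier copied into the output table.
#' @return List with `summary` (one row per ROI, see [summarize_roi()]) and
#'   `maps` (per-ROI `coherency_map`s).
#' @export
analyze_tem_image <- function(img, rois, box_radius = 12L,
                              downsample_gray = 1L, downsample_orient = 1L,
                              image_id = "image") {
  img <- as_gray_image(img)
  img <- downsample_gray(img, downsample_gray)
  field <- gradient_to_orientation(compute_gradient(img))
  field <- downsample_orientation(field, downsample_orient)
  shape <- dim(field$theta)
  masks <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    if (is.matrix(r) || is.logical(r)) {
      m <- as.matrix(r)
    } else {
      m <- roi_to_mask(r, shape[1], shape[2])
    }
    if (!identical(dim(m), shape))
      stop("ROI mask shape does not match the (possibly downsampled) field")
    m
  })
  ids <- names(rois) %||% paste0("roi", seq_along(rois))
  if (is.null(names(rois)) || any(names(rois) == ""))
    ids <- paste0("roi", seq_along(rois))
  rows <- vector("list", length(masks))
  maps <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    map <- local_coherency_map(field, masks[[i]], box_radius)
    glob <- global_coherency(field, masks[[i]])
    rows[[i]] <- cbind(image = image_id,
                       summarize_roi(map, glob, roi_id = ids[i]))
    maps[[i]] <- map
  }
  names(maps) <- ids
  list(summary = do.call(rbind, rows), maps = maps)
}
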