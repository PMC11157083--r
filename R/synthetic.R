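# Synthetic test stimuli with exact ground truth: (a) layered sinusoidal
# "membrane" textures with controllable angular disorder for the TEM arm,
# (b) 3D volumes of elongated ellipsoidal "outer segments" over noisy
# background for the LM arm. Same seed => bit-identical output.

#' Specification of a synthetic membrane-stack image
#'
#' Defaults state the emulated world: stripes with an 8 px wavelength
#' (membrane repeat of ~0.028 um at 287.5 px/um), unit amplitude, and mild
#' detector noise. `jitter_sd_deg` bends the membranes with a smooth random
#' angle field (correlation length ~ one wavelength); `patches` replaces the
#' single director with a patchwork of internally aligned, mutually rotated
#' patches ("partly stacked"); `vesicle_density` adds isotropic ring-shaped
#' vesicles ("chaotic", use `amplitude = 0` for vesicles only).
#'
#' @param size Image side in pixels.
#' @param angle_deg Director angle of the stripes in degrees.
#' @param wavelength Stripe wavelength in pixels (>= 4; band-limited).
#' @param amplitude Stripe amplitude.
#' @param jitter_sd_deg Angular disorder (sd of the smooth jitter field).
#' @param patches Optional numeric vector of per-patch directors (degrees);
#'   patches tile the image on a near-square grid.
#' @param vesicle_density Expected vesicles per pixel (e.g. 0.002).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer; fully determines the output.
#' @return List of class `membrane_spec`.
#' @export
membrane_spec <- function(size = 192L, angle_deg = 30, wavelength = 8,
                          amplitude = 1, jitter_sd_deg = 0, patches = NULL,
                          vesicle_density = 0, noise_sd = 0.02, seed = 1L) {
  if (wavelength < 4) stop("wavelength must be >= 4 px (band-limited)")
  structure(list(size = as.integer(size), angle_deg = angle_deg,
                 wavelength = wavelength, amplitude = amplitude,
                 jitter_sd_deg = jitter_sd_deg, patches = patches,
                 vesicle_density = vesicle_density, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "membrane_spec")
}

gaussian_blur2 <- function(m, sigma) {
  k <- gaussian_kernel1(sigma)
  conv_axis2(conv_axis2(m, k, 1L), k, 2L)
}

#' Generate a synthetic membrane-stack image with ground truth
#'
#' Stripes are rendered as `amplitude * sin(phi)` where the phase field
#' `phi` combines the base director (per patch) with a smooth random phase
#' perturbation scaled so the local director deviates with the requested sd.
#' The returned ground truth is the per-pixel director computed from the
#' numerical phase gradient (exact for the rendered pattern), `NA` where no
#' stripes are rendered (vesicle-only images).
#'
#' @param spec A [membrane_spec()].
#' @return List with `image` ([gray_image()]), `truth_director_deg` (matrix,
#'   degrees in `[0, 180)` or `NA`), and `spec`.
#' @export
make_membrane_image <- function(spec = membrane_spec()) {
  stopifnot(inherits(spec, "membrane_spec"))
  set.seed(spec$seed)
  n <- spec$size
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index = x
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index = y
  k0 <- 2 * pi / spec$wavelength
  img <- matrix(0, n, n)
  truth <- matrix(NA_real_, n, n)
  if (spec$amplitude > 0) {
    # patch assignment
    if (is.null(spec$patches)) {
      patch_id <- matrix(1L, n, n)
      directors <- spec$angle_deg
    } else {
      directors <- spec$patches
      g <- ceiling(sqrt(length(directors)))
      gi <- pmin(ceiling(ys / (n / g)), g)
      gj <- pmin(ceiling(xs / (n / g)), g)
      patch_id <- ((gi - 1L) * g + gj - 1L) %% length(directors) + 1L
    }
    # smooth phase perturbation scaled to the requested angular sd
    psi <- matrix(0, n, n)
    if (spec$jitter_sd_deg > 0) {
      raw <- gaussian_blur2(matrix(stats::rnorm(n * n), n, n),
                            sigma = spec$wavelength)
      # angular deviation ~ (tangential gradient of psi) / k0
      a0 <- deg2rad(spec$angle_deg)
      gx <- conv_axis2(raw, c(-0.5, 0, 0.5), 2L)
      gy <- conv_axis2(raw, c(-0.5, 0, 0.5), 1L)
      dev_raw <- (gx * cos(a0) + gy * sin(a0)) / k0
      s <- deg2rad(spec$jitter_sd_deg) / stats::sd(dev_raw)
      psi <- raw * s
    }
    for (p in seq_along(directors)) {
      sel <- patch_id == p
      if (!any(sel)) next
      a <- deg2rad(directors[p])
      nvec <- c(-sin(a), cos(a))   # stripe normal
      phase0 <- stats::runif(1, 0, 2 * pi)
      phi <- k0 * (xs * nvec[1] + ys * nvec[2]) + psi + phase0
      img[sel] <- img[sel] + spec$amplitude * sin(phi[sel])
      # exact director of the rendered pattern from the phase gradient
      kx <- k0 * nvec[1] + conv_axis2(psi, c(-0.5, 0, 0.5), 2L)
      ky <- k0 * nvec[2] + conv_axis2(psi, c(-0.5, 0, 0.5), 1L)
      truth[sel] <- rad2deg(fold_pi(atan2(ky, kx) + pi / 2))[sel]
    }
  }
  if (spec$vesicle_density > 0) {
    n_ves <- stats::rpois(1, spec$vesicle_density * n * n)
    amp_v <- if (spec$amplitude > 0) spec$amplitude else 1
    for (v in seq_len(n_ves)) {
      cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
      r0 <- stats::runif(1, 4, 12)
      d <- sqrt((xs - cx)^2 + (ys - cy)^2)
      img <- img + amp_v * exp(-(d - r0)^2 / (2 * 1.5^2))
    }
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
  list(image = gray_image(img), truth_director_deg = truth, spec = spec)
}

#' Specification of a 3D POS phantom
#'
#' Defaults state the emulated world: a 24 x 96 x 96 voxel stack with
#' anisotropic voxels of 1 x 0.323 x 0.323 um (20x air-objective z-stack),
#' 20 ellipsoidal outer segments elongated along y (semi-axes ~0.6 x 1.8 x
#' 0.6 um, i.e. POS ~3.6 um long and ~1.2 um wide), bright objects over a
#' dim background with a shallow apical-basal gradient, and mixed
#' Poisson-Gaussian noise.
#'
#' @param shape Integer (z, y, x) dimensions.
#' @param voxel_size (z, y, x) voxel size in um.
#' @param K Number of objects.
#' @param semi_axes_um Mean semi-axes (z, y, x) in um.
#' @param size_jitter Lognormal sdlog applied per object to all semi-axes.
#' @param intensity Mean object intensity (arbitrary detector units).
#' @param background Background offset as a fraction of `intensity`.
#' @param gradient Apical-basal background slope as a fraction of
#'   `intensity` (linear along y).
#' @param photons Photon scale of the Poisson noise (larger = cleaner).
#' @param gaussian_sd Read-noise sd as a fraction of `intensity`.
#' @param min_separation_vox Minimal gap between object surfaces, voxels.
#' @param seed Integer; fully determines the output.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24L, 96L, 96L),
                         voxel_size = c(1, 0.323, 0.323), K = 20L,
                         semi_axes_um = c(0.6, 1.8, 0.6),
                         size_jitter = 0.15, intensity = 1000,
                         background = 0.06, gradient = 0.04,
                         photons = 0.05, gaussian_sd = 0.02,
                         min_separation_vox = 4, seed = 1L) {
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 K = as.integer(K), semi_axes_um = semi_axes_um,
                 size_jitter = size_jitter, intensity = intensity,
                 background = background, gradient = gradient,
                 photons = photons, gaussian_sd = gaussian_sd,
                 min_separation_vox = min_separation_vox,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a 3D POS phantom with ground truth
#'
#' Places `K` non-overlapping ellipsoids (rejection sampling; objects
#' separated by at least `min_separation_vox` voxels), renders them
#' additively over the background, applies Poisson-plus-Gaussian noise, and
#' returns the noisy stack, the exact binary mask, and a per-object truth
#' table (centroids, semi-axes, analytic and voxel volumes, bbox height).
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` ([image_stack()]), `mask` (logical array),
#'   `truth` (data.frame), and `spec`.
#' @export
make_pos_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape; vs <- spec$voxel_size
  ext <- d * vs   # physical extents (z, y, x) in um
  axes <- matrix(0, spec$K, 3)
  cen <- matrix(0, spec$K, 3)
  placed <- 0L; tries <- 0L
  # per-axis separation: objects are accepted when their bounding boxes,
  # inflated by min_separation_vox voxels of that axis, are disjoint along
  # at least one axis -- guaranteeing the stated voxel gap without the
  # gross over-rejection of a ball bound
  gap_axis <- spec$min_separation_vox * vs
  while (placed < spec$K) {
    tries <- tries + 1L
    if (tries > 4000L * spec$K)
      stop("overlap-infeasible spec: cannot place ", spec$K, " objects")
    ax <- spec$semi_axes_um * stats::rlnorm(1, 0, spec$size_jitter)
    margin <- ax + gap_axis
    if (any(ext - 2 * margin <= 0)) next
    ce <- stats::runif(3, margin, ext - margin)
    ok <- TRUE
    if (placed > 0L) {
      prev <- seq_len(placed)
      dc <- abs(cen[prev, , drop = FALSE] -
                  matrix(ce, placed, 3, byrow = TRUE))
      lim <- sweep(axes[prev, , drop = FALSE], 2, ax + gap_axis, `+`)
      ok <- all(rowSums(dc >= lim) > 0)
    }
    if (!ok) next
    placed <- placed + 1L
    axes[placed, ] <- ax
    cen[placed, ] <- ce
  }
  # voxel-center physical coordinates
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]
  Z <- array(rep(zc, times = d[2] * d[3]), d)
  Y <- array(rep(rep(yc, each = d[1]), times = d[3]), d)
  X <- array(rep(xc, each = d[1] * d[2]), d)
  mask <- array(FALSE, d)
  signal <- array(0, d)
  truth <- vector("list", spec$K)
  for (i in seq_len(spec$K)) {
    # a thin object whose z extent sits between slice centers can render
    # few or no voxels; when thinner than one slice spacing, snap its z
    # center onto the nearest slice center (<= half a slice, far below the
    # enforced separation)
    if (axes[i, 1] < vs[1]) {
      cen[i, 1] <- zc[which.min(abs(zc - cen[i, 1]))]
    }
    r2 <- ((Z - cen[i, 1]) / axes[i, 1])^2 +
      ((Y - cen[i, 2]) / axes[i, 2])^2 +
      ((X - cen[i, 3]) / axes[i, 3])^2
    inside <- r2 <= 1
    amp <- spec$intensity * stats::runif(1, 0.7, 1)
    signal[inside] <- signal[inside] + amp
    mask <- mask | inside
    truth[[i]] <- data.frame(
      object = i,
      centroid_z_um = cen[i, 1], centroid_y_um = cen[i, 2],
      centroid_x_um = cen[i, 3],
      semi_z_um = axes[i, 1], semi_y_um = axes[i, 2], semi_x_um = axes[i, 3],
      volume_analytic_um3 = 4 / 3 * pi * prod(axes[i, ]),
      volume_voxels_um3 = sum(inside) * prod(vs),
      bbox_height_um = 2 * axes[i, 2],
      intensity = amp)
  }
  bg <- spec$intensity * (spec$background + spec$gradient * Y / ext[2])
  clean <- signal + bg
  noisy <- stats::rpois(length(clean), clean * spec$photons) / spec$photons +
    stats::rnorm(length(clean), sd = spec$gaussian_sd * spec$intensity)
  noisy[noisy < 0] <- 0
  dim(noisy) <- d
  list(stack = image_stack(noisy, vs), mask = mask,
       truth = do.call(rbind, truth), spec = spec)
}

#' Sample sparse training annotations from a phantom
#'
#' Draws `n_per_class` signal and background voxels from the ground-truth
#' mask, mimicking the sparse manual annotations used to train the pixel
#' classifier. Human annotators label background both in the far field and
#' directly adjacent to the structures ("according to intensity as well as
#' the structure"); accordingly a fraction `near_fraction` of the background
#' voxels is drawn from the 2-voxel shell around the objects and the rest
#' image-wide.
#'
#' @param phantom Result of [make_pos_phantom()].
#' @param n_per_class Voxels per class (default 100).
#' @param image Image id stored in the annotation.
#' @param near_fraction Fraction of background annotations drawn from the
#'   shell around objects (default 0.5).
#' @param seed RNG seed.
#' @return A [sparse_annotation()] data.frame.
#' @export
sample_annotations <- function(phantom, n_per_class = 100L, image = "img1",
                               near_fraction = 0.5, seed = 1L) {
  set.seed(seed)
  d <- dim(phantom$mask)
  fg <- phantom$mask
  shell <- dilate_box3(fg * 1, 2L) > 0 & !fg
  sig <- sample(which(fg), min(n_per_class, sum(fg)))
  n_near <- round(n_per_class * near_fraction)
  near <- sample(which(shell), min(n_near, sum(shell)))
  far_pool <- which(!fg & !shell)
  far <- sample(far_pool, min(n_per_class - length(near), length(far_pool)))
  bgv <- c(near, far)
  co <- arrayInd(c(sig, bgv), d)
  sparse_annotation(image, co[, 1], co[, 2], co[, 3],
                    rep(c("signal", "background"),
                        c(length(sig), length(bgv))))
}
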