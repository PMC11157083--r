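# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# coherency via the complex order parameter |sum m e^{2i theta}| / sum m
oracle_coherency_complex <- function(theta, m = rep(1, length(theta))) {
  keep <- m > 0 & !is.na(theta)
  s <- sum(m[keep] * exp(2i * theta[keep]))
  Mod(s) / sum(m[keep])
}

# coherency as twice the larger eigenvalue of the normalized Q matrix,
# via base eigen() on the explicit 2x2 symmetric matrix
oracle_coherency_eigen <- function(theta, m = rep(1, length(theta))) {
  keep <- m > 0 & !is.na(theta)
  th <- theta[keep]; w <- m[keep] / sum(m[keep])
  qxx <- sum(w * (cos(th)^2 - 0.5))
  qxy <- sum(w * cos(th) * sin(th))
  2 * max(eigen(matrix(c(qxx, qxy, qxy, -qxx), 2), symmetric = TRUE)$values)
}

# dominant angle by brute-force argmax of sum cos(2(theta - phi)) on a grid
oracle_dominant_angle_deg <- function(theta_deg, m = rep(1, length(theta_deg)),
                                      step = 0.001) {
  phi <- seq(0, 180 - step, by = step)
  score <- vapply(phi, function(p)
    sum(m * cos(2 * (theta_deg - p) * pi / 180)), numeric(1))
  phi[which.max(score)]
}

# direct (non-separable) grayscale opening with a box of half-width r
oracle_opening3 <- function(a, r) {
  d <- dim(a)
  er <- array(Inf, d); di <- array(-Inf, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zi <- max(1, z - r):min(d[1], z + r)
    yi <- max(1, y - r):min(d[2], y + r)
    xi <- max(1, x - r):min(d[3], x + r)
    er[z, y, x] <- min(a[zi, yi, xi])
  }
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zi <- max(1, z - r):min(d[1], z + r)
    yi <- max(1, y - r):min(d[2], y + r)
    xi <- max(1, x - r):min(d[3], x + r)
    di[z, y, x] <- max(er[zi, yi, xi])
  }
  di
}

# direct dense gaussian convolution (replicate edges) for one voxel's value
oracle_gaussian_at <- function(a, sigma, at) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  d <- dim(a)
  val <- 0
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    z <- min(max(at[1] + dz, 1), d[1])
    y <- min(max(at[2] + dy, 1), d[2])
    x <- min(max(at[3] + dx, 1), d[3])
    val <- val + k1[dz + r + 1] * k1[dy + r + 1] * k1[dx + r + 1] * a[z, y, x]
  }
  val
}

# a synthetic grating image evaluated at pixel centers (x = col, y = row)
grating <- function(n, angle_deg, wavelength, phase = 0) {
  a <- angle_deg * pi / 180
  nv <- c(-sin(a), cos(a))
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  sin(2 * pi / wavelength * (xs * nv[1] + ys * nv[2]) + phase)
}

ordered_index <- function(at, d) at[1] + (at[2] - 1) * d[1] +
  (at[3] - 1) * d[1] * d[2]

# smallest absolute difference between two director angles in degrees
angdiff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
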