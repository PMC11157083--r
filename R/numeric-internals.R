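# Internal vectorized numerics shared by both arms.
# Edge policy for convolutions is replicate ("nearest") unless stated; the
# public gradient operator instead masks unsupported border pixels.

# correlate a matrix along one axis with a small kernel, replicate edges;
# kernel index j runs -r..r, axis 1 = rows (y), axis 2 = cols (x)
conv_axis2 <- function(m, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- dim(m)[axis]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * (if (axis == 1L) m[idx, , drop = FALSE]
                              else m[, idx, drop = FALSE])
  }
  out
}

# correlate a 3D array along one axis (1=z, 2=y, 3=x), replicate edges
conv_axis3 <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * slice_axis3(a, idx, axis)
  }
  out
}

slice_axis3 <- function(a, idx, axis) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

gaussian_kernel1 <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 2D box sums of half-width r via integral image (zero padding outside)
box_sum2 <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 1L, nc + 1L)
  p[-1L, -1L] <- m
  p <- apply(p, 2L, cumsum)
  p <- t(apply(p, 1L, cumsum))
  i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
  p[i2 + 1L, j2 + 1L, drop = FALSE] - p[i1, j2 + 1L, drop = FALSE] -
    p[i2 + 1L, j1, drop = FALSE] + p[i1, j1, drop = FALSE]
}

# erode a logical mask with a (2r+1)^2 box; pixels whose box leaves the image
# are FALSE (no padding)
erode_box2 <- function(mask, r) {
  if (r == 0L) return(mask)
  s <- box_sum2(mask * 1, r)
  nr <- nrow(mask); nc <- ncol(mask)
  full <- (2L * r + 1L)^2
  out <- s >= full - 0.5
  if (nr >= 1L) {
    border <- rep(FALSE, r)
    out[c(seq_len(min(r, nr)), seq.int(max(1L, nr - r + 1L), nr)), ] <- FALSE
    out[, c(seq_len(min(r, nc)), seq.int(max(1L, nc - r + 1L), nc))] <- FALSE
  }
  out
}

# separable running min/max over a box of half-width r along each axis of a
# 3D array, replicate edges (exact morphology for box structuring elements)
running_extreme_axis3 <- function(a, r, axis, op) {
  n <- dim(a)[axis]
  out <- slice_axis3(a, pmin(pmax(seq_len(n) - r, 1L), n), axis)
  for (off in seq.int(-r + 1L, r)) {
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- op(out, slice_axis3(a, idx, axis))
  }
  out
}

erode_box3 <- function(a, r) {
  for (ax in 1:3) a <- running_extreme_axis3(a, r, ax, pmin)
  a
}

dilate_box3 <- function(a, r) {
  for (ax in 1:3) a <- running_extreme_axis3(a, r, ax, pmax)
  a
}

# block-mean reduction of a matrix by an integer factor (truncates remainder)
block_reduce2 <- function(m, f, fun_sum = TRUE) {
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # sum over f x f blocks via two reshapes
  a <- array(m, dim = c(f, nr %/% f, nc))
  s <- colSums(a)                       # (nr/f) x nc
  a <- array(t(s), dim = c(f, nc %/% f, nr %/% f))
  s <- t(colSums(a))                    # (nr/f) x (nc/f)
  if (fun_sum) s else s / (f * f)
}

fold_pi <- function(theta) {
  out <- theta %% pi
  out[out < 0] <- out[out < 0] + pi   # guard fp edge
  out[out >= pi] <- 0
  out
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
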