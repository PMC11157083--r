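test_that("connected components use 26-connectivity with scan-order labels", {
  m <- array(0, c(5, 9, 5))
  m[2:3, 2:3, 2:3] <- 1
  m[2:3, 7:8, 2:3] <- 1
  lab <- label_components(m)
  expect_equal(attr(lab, "n_labels"), 2L)
  expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
  # scan order: the component containing the smallest linear index is 1
  expect_equal(lab[2, 2, 2], 1L)
  expect_equal(lab[2, 7, 2], 2L)

  diagm <- array(0, c(4, 4, 4))
  diagm[1, 1, 1] <- 1; diagm[2, 2, 2] <- 1   # touch only diagonally
  expect_equal(attr(label_components(diagm), "n_labels"), 1L)

  expect_equal(attr(label_components(array(0, c(3, 3, 3))), "n_labels"), 0L)
})

test_that("isotropic rescaling preserves geometry and label counts", {
  # already isotropic at target: unchanged
  a <- array(runif(4 * 5 * 6), c(4, 5, 6))
  st <- image_stack(a, rep(0.323, 3))
  expect_equal(rescale_isotropic(st)$voxels, a)

  # z twice the target: z dimension doubles, extent conserved
  st2 <- image_stack(a, c(0.646, 0.323, 0.323))
  r2 <- rescale_isotropic(st2)
  expect_equal(dim(r2$voxels)[1], 8L)
  expect_equal(dim(r2$voxels)[2:3], c(5L, 6L))

  expect_error(rescale_isotropic(a), "voxel-size")

  # label count conserved on well-separated phantoms; volume within 2%
  ph <- make_pos_phantom(phantom_spec(K = 8L, seed = 12))
  lab <- label_components(ph$mask)
  lab_iso <- rescale_isotropic(lab, voxel_size = ph$spec$voxel_size,
                               labels = TRUE)
  expect_equal(length(setdiff(unique(as.vector(lab_iso$voxels)), 0L)), 8L)
  vol_in <- sum(ph$mask) * prod(ph$spec$voxel_size)
  vol_out <- sum(lab_iso$voxels > 0) * 0.323^3
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.02)
})

test_that("shape features match closed forms on digital phantoms", {
  # digital ball r = 10 voxels
  d <- c(25, 25, 25)
  co <- arrayInd(seq_len(prod(d)), d)
  ball <- array(0L, d)
  ball[rowSums((co - 13)^2) <= 100] <- 1L
  rec <- extract_features(ball, ball * 1, voxel_size = 0.323)
  expect_gte(rec$sphericity, 0.95)
  expect_lte(rec$sphericity, 1.05)
  expect_equal(rec$feret_um, 2 * 10 * 0.323, tolerance = 0.323)
  expect_equal(rec$volume_um3, sum(ball) * 0.323^3)

  # 1 x 1 x 20 rod along y
  rod <- array(0L, c(5, 24, 5)); rod[3, 3:22, 3] <- 1L
  rr <- extract_features(rod, rod * 1, voxel_size = 0.323)
  expect_equal(rr$bbox_height_um, 20 * 0.323)
  expect_lt(rr$sphericity, rec$sphericity - 0.05)   # clearly less spherical

  # single voxel
  sv <- array(0L, c(3, 3, 3)); sv[2, 2, 2] <- 1L
  expect_equal(extract_features(sv, sv * 1, 0.323)$volume_um3, 0.323^3)

  expect_error(extract_features(rod, array(0, c(2, 2, 2))), "mismatch")
})

test_that("percentile filter reproduces explicit quantile arithmetic", {
  rec <- data.frame(volume_um3 = 1:100)
  f <- percentile_filter(rec)
  # type-7 quantiles of 1..100 at 5/95%: 5.95 and 95.05 -> keep 6..95
  expect_equal(attr(f, "lo_um3"), 5.95)
  expect_equal(attr(f, "hi_um3"), 95.05)
  expect_equal(nrow(f), 90L)
  expect_equal(range(f$volume_um3), c(6, 95))

  same <- data.frame(volume_um3 = rep(3.3, 7))
  expect_equal(nrow(percentile_filter(same)), 7L)

  set.seed(8)
  r <- data.frame(volume_um3 = rlnorm(40))
  expect_true(all(percentile_filter(r)$volume_um3 %in% r$volume_um3))
  expect_error(percentile_filter(r[0, , drop = FALSE]), "empty")

  # pooled thresholds can keep everything in a narrow per-image subset
  wide <- data.frame(volume_um3 = c(0.01, seq(1, 2, length.out = 20), 50))
  sub <- data.frame(volume_um3 = seq(1.2, 1.8, length.out = 5))
  expect_equal(nrow(percentile_filter(sub, pool = wide$volume_um3)), 5L)
})

test_that("image summaries follow the filtered/unfiltered contract", {
  s0 <- summarize_image(data.frame(volume_um3 = numeric()),
                        data.frame(volume_um3 = numeric()))
  expect_equal(s0$n_pos, 0L)
  expect_equal(s0$summed_volume_um3, 0)

  rec <- data.frame(volume_um3 = c(2, 2, 2), bbox_height_um = c(1, 2, 3),
                    feret_um = 1, sphericity = 0.9, intensity_min = 0,
                    intensity_mean = 5)
  s <- summarize_image(rec[1:2, ], rec)
  expect_equal(s$n_pos, 2L)
  expect_equal(s$summed_volume_um3, 6)   # unfiltered sum
  expect_equal(s$mean_bbox_height_um, 1.5)
})

test_that("pipeline monotonicity: larger objects, larger summed volume", {
  ph1 <- make_pos_phantom(phantom_spec(K = 6L, seed = 30))
  ph2 <- make_pos_phantom(phantom_spec(K = 6L, seed = 30,
                                       semi_axes_um = c(0.9, 2.7, 0.9)))
  q1 <- quantify_mask(ph1$mask, ph1$stack, filter = FALSE)
  q2 <- quantify_mask(ph2$mask, ph2$stack, filter = FALSE)
  expect_gt(q2$summary$summed_volume_um3, q1$summary$summed_volume_um3)
  expect_gt(q2$summary$mean_bbox_height_um, q1$summary$mean_bbox_height_um)
  # doubling semi-axes scales volume ~8x (checked loosely at voxel scale)
  ph3 <- make_pos_phantom(phantom_spec(K = 6L, seed = 30,
                                       semi_axes_um = c(1.2, 3.6, 1.2),
                                       shape = c(32L, 128L, 128L)))
  q3 <- quantify_mask(ph3$mask, ph3$stack, filter = FALSE)
  ratio <- q3$summary$summed_volume_um3 / q1$summary$summed_volume_um3
  expect_gt(ratio, 5); expect_lt(ratio, 11)
})
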