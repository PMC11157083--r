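test_that("q_tensor matches the summand formula", {
  q <- q_tensor(0, 1)
  expect_equal(q$qxx, 0.5); expect_equal(q$qxy, 0)

  q2 <- q_tensor(c(0, pi / 2), c(1, 1))
  expect_equal(q2$qxx, 0, tolerance = 1e-15)
  expect_equal(q2$qxy, 0, tolerance = 1e-15)

  q3 <- q_tensor(c(0, pi / 4), c(1, 2))   # direct evaluation: 0.5, 1.0
  expect_equal(q3$qxx, 0.5, tolerance = 1e-12)
  expect_equal(q3$qxy, 1.0, tolerance = 1e-12)

  expect_error(q_tensor(numeric(0)), "empty")
})

test_that("coherency limits and the 1/3 example hold", {
  expect_equal(coherency(q_tensor(rep(0.7, 5), runif(5, 0.5, 2))), 1)
  expect_equal(coherency(q_tensor(c(0, pi / 2), c(1, 1))), 0,
               tolerance = 1e-15)
  # {0, 90, 45} degrees: |e^0 + e^{i pi} + e^{i pi/2}| / 3 = 1/3
  expect_equal(coherency(q_tensor(c(0, 90, 45) * pi / 180)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(coherency(q_tensor(NA_real_, 0)), 0)   # zero weight
})

test_that("coherency equals complex-sum and eigen oracles on random sets", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    th <- runif(n, 0, pi)
    m <- rexp(n)
    c0 <- coherency(q_tensor(th, m))
    expect_equal(c0, oracle_coherency_complex(th, m), tolerance = 1e-12)
    expect_equal(c0, oracle_coherency_eigen(th, m), tolerance = 1e-12)
    expect_gte(c0, 0); expect_lte(c0, 1 + 1e-12)
  }
})

test_that("dominant angle folds correctly and matches the grid oracle", {
  expect_equal(dominant_angle(q_tensor(rep(0, 3))), 0)
  expect_equal(dominant_angle(q_tensor(rep(170 * pi / 180, 3))), 170,
               tolerance = 1e-9)
  a <- dominant_angle(q_tensor(c(10, 20, 30) * pi / 180))
  expect_equal(a, 20, tolerance = 1e-9)
  expect_equal(a, oracle_dominant_angle_deg(c(10, 20, 30)), tolerance = 2e-3)
  expect_true(is.na(dominant_angle(q_tensor(c(0, pi / 2), c(1, 1)))))
})

test_that("rotation invariance: coherency fixed, angles shift", {
  set.seed(7)
  th <- runif(12, 0, pi); m <- rexp(12)
  for (shift in c(0.3, 1.1, 2.9)) {
    q0 <- q_tensor(th, m); q1 <- q_tensor(th + shift, m)
    expect_equal(coherency(q0), coherency(q1), tolerance = 1e-12)
    expect_lt(angdiff_deg(dominant_angle(q0) + shift * 180 / pi,
                          dominant_angle(q1)), 1e-9)
  }
})

test_that("local coherency map: support rule, grating, noise", {
  n <- 64
  m <- grating(n, 40, 12)
  f <- gradient_to_orientation(compute_gradient(gray_image(m)))
  roi <- matrix(TRUE, n, n)
  cm <- local_coherency_map(f, roi)
  # validity: ROI eroded by box_radius + 2 = 14
  expect_equal(cm$n_valid, (n - 28)^2)
  expect_true(all(cm$local_coherency[cm$valid_mask] > 0.95))
  expect_true(all(abs(angdiff_deg(
    cm$local_angle_deg[cm$valid_mask], 40)) < 1))

  # ROI too small for any valid query pixel: flagged empty, no error
  small <- matrix(FALSE, 64, 64); small[20:39, 20:39] <- TRUE
  cme <- local_coherency_map(f, small)
  expect_true(cme$empty)
  expect_equal(cme$n_valid, 0L)

  # isotropic white noise: low local coherency (random-walk scaling)
  set.seed(5)
  vals <- replicate(5, {
    fn <- gradient_to_orientation(compute_gradient(
      gray_image(matrix(rnorm(60 * 60), 60, 60))))
    cmn <- local_coherency_map(fn, matrix(TRUE, 60, 60))
    mean(cmn$local_coherency[cmn$valid_mask])
  })
  expect_lt(mean(vals), 0.3)
})

test_that("global coherency on gratings and cancelling half-fields", {
  n <- 64
  f <- gradient_to_orientation(compute_gradient(gray_image(grating(n, 25, 10))))
  g <- global_coherency(f, matrix(TRUE, n, n))
  expect_gte(g$coherency, 0.95)
  expect_lt(angdiff_deg(g$angle_deg, 25), 1)

  # half 0-degree grating, half 90-degree grating: near cancellation
  h <- rbind(grating(64, 0, 8)[1:32, ], grating(64, 90, 8)[33:64, ])
  fh <- gradient_to_orientation(compute_gradient(gray_image(h)))
  gh <- global_coherency(fh, matrix(TRUE, 64, 64))
  expect_lt(gh$coherency, 0.1)

  expect_error(global_coherency(f, matrix(FALSE, n, n)), "empty")
})

test_that("summarize_roi arithmetic and patchwork direction", {
  fake_map <- structure(list(
    local_coherency = matrix(c(0.2, 0.4, 0.6, NA), 2, 2),
    local_angle_deg = matrix(10, 2, 2),
    valid_mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
    n_valid = 3L, box_radius = 12L, empty = FALSE),
    class = "coherency_map")
  s <- summarize_roi(fake_map, list(coherency = 0.3, angle_deg = 50,
                                    n_valid = 100L))
  expect_equal(s$mean_local_coherency, 0.4)
  expect_equal(s$ratio_global_to_local, 0.75)

  s2 <- summarize_roi(fake_map, list(coherency = 0.4, angle_deg = 1,
                                     n_valid = 1L))
  expect_equal(s2$ratio_global_to_local, 1.0)
})

test_that("replicate alignment respects 180-degree periodicity", {
  r <- replicate_alignment(rep(37, 6))
  expect_equal(r$alignment, 1)
  expect_equal(r$dominant_angle_deg, 37, tolerance = 1e-9)
  expect_equal(replicate_alignment(c(0, 90))$alignment, 0, tolerance = 1e-15)
  # {0, 0, 90}: |2 e^0 + e^{i pi}| / 3 = 1/3
  expect_equal(replicate_alignment(c(0, 0, 90))$alignment, 1 / 3,
               tolerance = 1e-12)
  # angles congruent mod 180 are identical directors
  expect_equal(replicate_alignment(c(10, 190, 10))$alignment, 1,
               tolerance = 1e-12)
  expect_error(replicate_alignment(numeric(0)), "at least one")
})

test_that("roi_distributions bins coherency and angles", {
  n <- 64
  f <- gradient_to_orientation(compute_gradient(gray_image(grating(n, 40, 12))))
  cm <- local_coherency_map(f, matrix(TRUE, n, n))
  g <- global_coherency(f, matrix(TRUE, n, n))
  d <- roi_distributions(cm, g)
  expect_equal(sum(d$coherency_density$count), cm$n_valid)
  expect_equal(sum(d$angle_histogram$count), cm$n_valid)
  # single-orientation grating: angle mass concentrated in one bin
  expect_gte(max(d$angle_histogram$count) / sum(d$angle_histogram$count), 0.99)
  # all local coherencies nearly equal: single occupied density bin
  expect_equal(sum(d$coherency_density$count > 0), 1L)
  expect_equal(d$global_coherency, g$coherency)
})

test_that("disorder monotonicity: coherency strictly decreases with jitter", {
  sds <- c(0, 10, 20, 40)
  gmeans <- lmeans <- numeric(length(sds))
  for (i in seq_along(sds)) {
    gs <- ls <- numeric(5)
    for (s in 1:5) {
      mb <- make_membrane_image(membrane_spec(size = 96, jitter_sd_deg = sds[i],
                                              seed = 100 * i + s))
      f <- gradient_to_orientation(compute_gradient(mb$image))
      roi <- matrix(TRUE, 96, 96)
      gs[s] <- global_coherency(f, roi)$coherency
      cm <- local_coherency_map(f, roi)
      ls[s] <- mean(cm$local_coherency[cm$valid_mask])
    }
    gmeans[i] <- mean(gs); lmeans[i] <- mean(ls)
  }
  expect_true(all(diff(gmeans) < 0))
  expect_true(all(diff(lmeans) < 0))
})

test_that("full image analysis returns a tidy per-ROI table", {
  mb <- make_membrane_image(membrane_spec(size = 96, angle_deg = 60, seed = 3))
  rois <- list(left = {
    m <- matrix(FALSE, 96, 96); m[, 1:48] <- TRUE; m
  }, right = {
    m <- matrix(FALSE, 96, 96); m[, 49:96] <- TRUE; m
  })
  res <- analyze_tem_image(mb$image, rois, image_id = "synthetic1")
  expect_equal(nrow(res$summary), 2L)
  expect_equal(res$summary$roi_id, c("left", "right"))
  expect_true(all(res$summary$global_coherency > 0.9))
  expect_true(all(angdiff_deg(res$summary$global_angle_deg, 60) < 1.5))
  # coherent pattern: global and mean local nearly coincide
  expect_true(all(abs(res$summary$ratio_global_to_local - 1) < 0.02))
})
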