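make_separable_stack <- function(seed, d = c(10, 30, 30), t = 100) {
  # signal voxels have intensity > t with margin; background < t
  set.seed(seed)
  a <- array(runif(prod(d), 0, 0.5 * t), d)
  mask <- array(FALSE, d)
  mask[3:8, 5:12, 5:12] <- TRUE
  mask[3:8, 18:25, 18:25] <- TRUE
  a[mask] <- runif(sum(mask), 1.5 * t, 2 * t)
  list(stack = image_stack(a, c(1, 1, 1)), mask = mask)
}

test_that("feature bank has fixed vocabulary and arity", {
  expect_error(feature_bank("not_a_filter"), "unknown filter")
  b2 <- feature_bank(c("gaussian", "mean_box"), c(1, 1))
  f <- compute_features(image_stack(array(1, c(6, 6, 6)), c(1, 1, 1)), b2)
  expect_equal(ncol(f), 2L)
  b3 <- feature_bank(c("original", "gaussian", "mean_box"), c(0, 1, 1))
  expect_equal(ncol(compute_features(
    image_stack(array(1, c(6, 6, 6)), c(1, 1, 1)), b3)), 3L)
})

test_that("filters behave on constants and point sources", {
  const <- image_stack(array(3, c(9, 9, 9)), c(1, 1, 1))
  all_f <- feature_bank(
    c("original", "gaussian", "difference_of_gaussian",
      "laplace_of_gaussian_box", "sobel_of_gaussian", "median_box",
      "mean_box", "tophat_box"),
    c(0, 1, 1, 1, 1, 1, 1, 1))
  f <- compute_features(const, all_f)
  expect_true(all(abs(f[, "gaussian_s1"] - 3) < 1e-10))
  expect_true(all(abs(f[, "difference_of_gaussian_s1"]) < 1e-10))
  expect_true(all(abs(f[, "laplace_of_gaussian_box_s1"]) < 1e-10))
  expect_true(all(abs(f[, "sobel_of_gaussian_s1"]) < 1e-10))
  expect_true(all(abs(f[, "median_box_s1"] - 3) < 1e-10))
  expect_true(all(abs(f[, "tophat_box_s1"]) < 1e-10))

  # single bright voxel: gaussian feature equals the sampled kernel
  d <- c(11, 11, 11)
  a <- array(0, d); a[6, 6, 6] <- 1
  g <- compute_features(image_stack(a, c(1, 1, 1)),
                        feature_bank("gaussian", 1))
  garr <- array(g[, 1], d)
  for (at in list(c(6, 6, 6), c(5, 6, 7), c(4, 4, 6)))
    expect_equal(garr[at[1], at[2], at[3]], oracle_gaussian_at(a, 1, at),
                 tolerance = 1e-12)
})

test_that("forest separates a margin dataset and beats 0.9 Jaccard", {
  tr <- make_separable_stack(31)
  te <- make_separable_stack(32)
  d <- dim(tr$mask)
  set.seed(33)
  sig <- sample(which(tr$mask), 100)
  bg <- sample(which(!tr$mask), 100)
  co <- arrayInd(c(sig, bg), d)
  ann <- sparse_annotation("img1", co[, 1], co[, 2], co[, 3],
                           rep(c("signal", "background"), each = 100))
  mod <- train_pos_classifier(list(img1 = tr$stack), ann, seed = 1)
  # threshold-classifier oracle on held-out image: exact by construction
  oracle_mask <- te$stack$voxels > 100
  expect_equal(oracle_mask, te$mask)
  pred <- predict_pos(mod, te$stack)
  sc <- segmentation_scores(confusion_matrix(pred, oracle_mask))
  expect_gte(sc["jaccard"], 0.9)
  # training-voxel agreement on separable data
  pred_tr <- predict_pos(mod, tr$stack)
  lin <- c(sig, bg)
  expect_gte(mean(pred_tr[lin] == rep(c(TRUE, FALSE), each = 100)), 0.99)
})

test_that("training is reproducible and serialization round-trips", {
  tr <- make_separable_stack(41)
  ann <- sample_annotations(list(mask = tr$mask), 60, "img1", seed = 5)
  m1 <- train_pos_classifier(list(img1 = tr$stack), ann, seed = 9)
  m2 <- train_pos_classifier(list(img1 = tr$stack), ann, seed = 9)
  expect_identical(m1$trees, m2$trees)

  p1 <- tempfile(fileext = ".posquant.json")
  p2 <- tempfile(fileext = ".posquant.json")
  write_pos_classifier(m1, p1)
  m3 <- read_pos_classifier(p1)
  write_pos_classifier(m3, p2)
  expect_identical(readLines(p1), readLines(p2))   # lossless round-trip
  pred1 <- predict_pos(m1, tr$stack)
  pred3 <- predict_pos(m3, tr$stack)
  expect_identical(pred1, pred3)
})

test_that("annotation hygiene: duplicates, bounds, single class", {
  tr <- make_separable_stack(51)
  ann <- sparse_annotation("img1", c(3, 3, 4), c(5, 5, 6), c(5, 5, 6),
                           c("signal", "signal", "background"))
  expect_warning(
    m <- train_pos_classifier(list(img1 = tr$stack), ann, n_trees = 5,
                              seed = 1),
    "duplicate")
  bad <- sparse_annotation("img1", c(3, 99), c(5, 5), c(5, 5),
                           c("signal", "background"))
  expect_error(train_pos_classifier(list(img1 = tr$stack), bad, seed = 1),
               "out of bounds")
  mono <- sparse_annotation("img1", c(3, 4), c(5, 6), c(5, 6),
                            c("signal", "signal"))
  expect_error(train_pos_classifier(list(img1 = tr$stack), mono, seed = 1),
               "both classes")
})

test_that("prediction edge cases: all-zero stack, tie to background", {
  tr <- make_separable_stack(61)
  ann <- sample_annotations(list(mask = tr$mask), 60, "img1", seed = 6)
  mod <- train_pos_classifier(list(img1 = tr$stack), ann, seed = 2)
  zero <- image_stack(array(0, dim(tr$mask)), c(1, 1, 1))
  expect_true(all(!predict_pos(mod, zero)))

  # exact vote tie loses to background
  leafA <- data.frame(id = 1L, feature = NA_integer_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_, pred = 1L)
  leafB <- leafA; leafB$pred <- 0L
  tie <- mod
  tie$trees <- list(leafA, leafB)
  tie$n_trees <- 2L
  expect_true(all(!predict_pos(tie, zero)))

  # feature-bank mismatch is an error
  mod2 <- mod
  mod2$feature_names <- c("bogus")
  expect_error(predict_pos(mod2, tr$stack), "mismatch")
})

test_that("monotone sanity: brightening a signal region keeps it signal", {
  tr <- make_separable_stack(71)
  ann <- sample_annotations(list(mask = tr$mask), 80, "img1", seed = 7)
  mod <- train_pos_classifier(list(img1 = tr$stack), ann, seed = 3)
  pred <- predict_pos(mod, tr$stack)
  boosted <- tr$stack
  boosted$voxels[tr$mask] <- boosted$voxels[tr$mask] * 1.5
  pred2 <- predict_pos(mod, boosted)
  core <- tr$mask & pred
  expect_true(all(pred2[core]))
})
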