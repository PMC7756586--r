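# segmentation core: centre of mass, crop/refine compositing, fusion,
# augmentation plumbing and trained-model quality on the shared cohort

test_that("center_of_mass matches direct enumeration", {
  m <- array(0L, dim = c(8, 8, 8)); m[4, 5, 6] <- 1L
  expect_equal(center_of_mass(m), c(4L, 5L, 6L))
  m2 <- array(0L, dim = c(8, 8, 8)); m2[1, 1, 1] <- 1L; m2[3, 1, 1] <- 1L
  expect_equal(center_of_mass(m2), c(2L, 1L, 1L))
  set.seed(8)
  for (i in 1:10) {
    m3 <- rand_mask(c(7, 9, 11))
    w <- which(m3 == 1, arr.ind = TRUE)
    expect_equal(center_of_mass(m3), as.integer(round(colMeans(w))))
  }
  expect_error(center_of_mass(array(0L, c(3, 3, 3))), "empty")
})

test_that("fuse_2d3d is a commutative, associative, idempotent union", {
  set.seed(9)
  dm <- c(6, 7, 8)
  a <- seg_prediction("s", rand_mask(dm), "coarse")
  b <- seg_prediction("s", rand_mask(dm), "refined")
  c3 <- seg_prediction("s", rand_mask(dm), "coarse")
  ab <- fuse_2d3d(a, b)
  expect_identical(ab$stage, "fused_2d3d")
  expect_identical(ab$mask, fuse_2d3d(b, a)$mask)
  expect_identical(fuse_2d3d(a, a)$mask, a$mask)
  expect_identical(fuse_2d3d(fuse_2d3d(a, b), c3)$mask,
                   fuse_2d3d(a, fuse_2d3d(b, c3))$mask)
  # disjoint inputs: union volume = sum of volumes
  d1 <- array(0L, dm); d1[1:2, , ] <- 1L
  d2 <- array(0L, dm); d2[5:6, , ] <- 1L
  expect_equal(sum(fuse_2d3d(seg_prediction("s", d1, "coarse"),
                             seg_prediction("s", d2, "coarse"))$mask),
               sum(d1) + sum(d2))
  expect_error(fuse_2d3d(a, seg_prediction("s", rand_mask(c(6, 7, 9)), "coarse")),
               "grid mismatch")
  expect_error(fuse_2d3d(a, seg_prediction("t", rand_mask(dm), "coarse")),
               "structure mismatch")
})

test_that("fusion never reduces recall relative to either input", {
  set.seed(10)
  for (i in 1:25) {
    dm <- c(6, 8, 8)
    gt <- rand_mask(dm)
    p2 <- seg_prediction("s", rand_mask(dm), "coarse")
    p3 <- seg_prediction("s", rand_mask(dm), "coarse")
    fu <- fuse_2d3d(p2, p3)
    recall <- function(p) sum(p$mask & gt) / sum(gt)
    expect_gte(recall(fu), max(recall(p2), recall(p3)))
  }
})

test_that("refine with an oracle model reaches DSC 1 and stays inside the crop box", {
  ph <- small_cohort()[[7]]
  gt <- ph$structures$masks$bladder
  coarse <- seg_prediction("bladder", gt, "coarse")   # anchor on truth
  crop <- derive_crop_spec(small_cohort()[1:6], "bladder")
  oracle <- function(vol, region) {
    array(gt[region$z, region$y, region$x],
          dim = c(length(region$z), length(region$y), length(region$x)))
  }
  ref <- refine_segment(coarse, ph$volume, oracle, crop)
  expect_identical(ref$stage, "refined")
  expect_equal(dice(ref$mask, gt), 1)
  # leak-free compositing: nothing outside the crop box
  ctr <- center_of_mass(gt)
  reg <- cascadeseg:::crop_ranges(ctr, crop$box_shape, dim(gt))
  outside <- array(TRUE, dim = dim(gt))
  outside[reg$z, reg$y, reg$x] <- FALSE
  expect_equal(sum(ref$mask[outside]), 0)
})

test_that("crop boxes clamp at grid edges without changing shape", {
  grid <- c(20, 30, 30)
  for (ctr in list(c(1, 1, 1), c(20, 30, 30), c(10, 15, 15))) {
    r <- cascadeseg:::crop_ranges(ctr, c(8, 10, 10), grid)
    expect_equal(lengths(r), c(z = 8, y = 10, x = 10))
    expect_true(all(unlist(r) >= 1))
    expect_true(r$z[8] <= 20 && r$y[10] <= 30 && r$x[10] <= 30)
  }
})

test_that("empty coarse prediction falls back with a warning", {
  ph <- small_cohort()[[7]]
  empty <- seg_prediction("bladder", array(0L, dim(ph$volume$data)), "coarse")
  crop <- crop_spec(c(8, 8, 8))
  expect_warning(out <- refine_segment(empty, ph$volume, function(v, r) r, crop),
                 "empty coarse")
  expect_identical(out$stage, "coarse")
  expect_equal(sum(out$mask), 0)
})

test_that("coarse_segment at native shape equals direct segmentation; errors on bad extent", {
  mods <- small_bladder_models()
  ph <- small_cohort()[[7]]
  ext <- pad_extent(mask_extent(ph$structures$masks$bladder), 1)
  native <- coarse_segment(mods$refine, ph$volume, ext, coarse_shape = NULL)
  same <- coarse_segment(mods$refine, ph$volume, ext,
                         coarse_shape = dim(ph$volume$data)[2:3])
  expect_identical(native$mask, same$mask)
  expect_error(coarse_segment(mods$coarse, ph$volume, extent = NULL), "extent_interval")
})

test_that("trained coarse model: training DSC >= 0.8, held-out centroid within 2 voxels", {
  co <- small_cohort()
  mods <- small_bladder_models()
  d_train <- sapply(co[1:6], function(s) {
    ext <- pad_extent(mask_extent(s$structures$masks$bladder), 1)
    dice(coarse_segment(mods$coarse, s$volume, ext)$mask, s$structures$masks$bladder)
  })
  expect_gte(mean(d_train), 0.8)
  for (s in co[7:8]) {
    ext <- pad_extent(mask_extent(s$structures$masks$bladder), 1)
    cm <- coarse_segment(mods$coarse, s$volume, ext)
    expect_lte(sqrt(sum((center_of_mass(cm$mask) -
                         center_of_mass(s$structures$masks$bladder))^2)), 2)
  }
})

test_that("refined predictions do not degrade the coarse result", {
  co <- small_cohort()
  mods <- small_bladder_models()
  deltas <- sapply(co[7:8], function(s) {
    ext <- pad_extent(extent_postprocess(predict_presence(mods$classifier, s$volume)), 1)
    cm <- coarse_segment(mods$coarse, s$volume, ext)
    rf <- refine_segment(cm, s$volume, mods$refine, mods$crop)
    gt <- s$structures$masks$bladder
    dice(rf$mask, gt) - dice(cm$mask, gt)
  })
  expect_gte(stats::median(deltas), -0.01)
})

test_that("multi-label training yields one channel per structure, argmax-disjoint", {
  co <- small_cohort()
  ml <- train_segmenter(co[1:6], c("l4", "l5"), mode = "volume_3d",
                        opt = adam_config(epochs = 400, seed = 5), region = "extent")
  expect_equal(ncol(ml$weights), 2)
  s <- co[[7]]
  ext <- pad_extent(mask_extent(s$structures$masks$l4 + s$structures$masks$l5), 1)
  pr <- predict_multilabel(ml, s$volume, ext)
  expect_named(pr, c("l4", "l5"))
  expect_equal(sum(pr$l4 & pr$l5), 0)
  expect_gte(dice(pr$l4, s$structures$masks$l4), 0.8)
  expect_gte(dice(pr$l5, s$structures$masks$l5), 0.8)
})

test_that("augmentation changes the training stream; fixed seeds reproduce it", {
  co <- small_cohort()[1:3]
  fast <- adam_config(epochs = 2, seed = 1)
  m_aug <- train_segmenter(co, "bladder", opt = fast, aug = augment_spec())
  m_off <- train_segmenter(co, "bladder", opt = fast, aug = no_augment())
  expect_false(identical(m_aug$train_stream, m_off$train_stream))
  expect_true(any(grepl("rotate", m_aug$train_stream)))
  expect_true(any(grepl("hflip", m_aug$train_stream)))
  m_aug2 <- train_segmenter(co, "bladder", opt = fast, aug = augment_spec())
  expect_identical(m_aug$train_stream, m_aug2$train_stream)
  expect_identical(m_aug$weights, m_aug2$weights)
})

test_that("train_segmenter preconditions", {
  co <- small_cohort()[1:3]
  expect_error(train_segmenter(co, "missing_structure"), "fewer than 2")
  expect_error(train_segmenter(co, "bladder", region = "crop"), "crop_spec")
  expect_error(seg_prediction("s", array(2, c(2, 2, 2)), "coarse"), "binary")
})
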