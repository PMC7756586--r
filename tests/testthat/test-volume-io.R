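# volume containers, NIfTI round trips, preprocessing and resampling

test_that("write/read round-trips data, spacing, origin and intensity kind", {
  set.seed(1)
  vol <- ct_volume(array(rnorm(10 * 10 * 10, 0, 300), dim = c(10, 10, 10)),
                   spacing = c(2.5, 1.17, 1.17), origin = c(-12.5, 3, -7))
  d <- withr::local_tempdir()
  for (ext in c("v.nii", "v.nii.gz")) {
    p <- file.path(d, ext)
    write_volume(vol, p)
    back <- read_volume(p)
    expect_identical(back$data, vol$data)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
    expect_identical(back$intensity_kind, "raw_hu")
  }
  pp <- clip_shift_intensity(vol)
  p2 <- file.path(d, "pp.nii.gz")
  write_volume(pp, p2)
  expect_identical(read_volume(p2)$intensity_kind, "preprocessed")
})

test_that("mask round trip preserves binarity; scan folders are self-describing", {
  ph <- small_cohort()[[1]]
  d <- withr::local_tempdir()
  write_scan(file.path(d, "s1"), ph$volume, ph$structures)
  back <- read_scan(file.path(d, "s1"))
  expect_identical(back$volume$data, ph$volume$data)
  for (nm in names(ph$structures$masks))
    expect_identical(back$structures$masks[[nm]], ph$structures$masks[[nm]])
  expect_identical(unname(back$structures$provenance[["bladder"]]), "ground_truth")
})

test_that("read_volume rejects non-NIfTI, truncated and 2D inputs", {
  d <- withr::local_tempdir()
  junk <- file.path(d, "junk.nii")
  writeBin(as.raw(rep(7, 400)), junk)
  expect_error(read_volume(junk), "not a NIfTI")
  expect_error(read_volume(file.path(d, "absent.nii")), "not found")
  # craft a 2D file by patching the dim field of a valid one
  vol <- ct_volume(array(0, dim = c(4, 5, 6)), spacing = c(1, 1, 1))
  p <- file.path(d, "v.nii")
  write_volume(vol, p)
  raw <- readBin(p, "raw", file.info(p)$size)
  raw[41:42] <- writeBin(2L, raw(), size = 2, endian = "little")
  writeBin(raw, p)
  expect_error(read_volume(p), "not a 3D image")
})

test_that("clip_shift_intensity implements the stated affine map and refuses reapplication", {
  vol <- ct_volume(array(c(3000, -1500, 0, 5000, -1000, 42),
                         dim = c(6, 1, 1)), spacing = c(1, 1, 1))
  out <- clip_shift_intensity(vol)
  expect_equal(out$data[1, 1, 1], 4000)   # 3000 HU -> top of the 0..4000 range
  expect_equal(out$data[2, 1, 1], 0)      # below -1000 HU clips to 0
  expect_equal(out$data[3, 1, 1], 1000)   # 0 HU -> 1000
  expect_equal(out$data[4, 1, 1], 4000)
  expect_equal(out$data[5, 1, 1], 0)
  expect_equal(out$data[6, 1, 1], 1042)
  expect_identical(out$intensity_kind, "preprocessed")
  expect_true(min(out$data) >= 0 && max(out$data) <= 4000)
  expect_error(clip_shift_intensity(out), "already preprocessed")
})

test_that("clip+shift is idempotent in effect on re-expressed HU", {
  set.seed(2)
  hu <- array(rnorm(125, 0, 1500), dim = c(5, 5, 5))
  once <- clip_shift_intensity(ct_volume(hu, c(1, 1, 1)))
  again <- clip_shift_intensity(ct_volume(once$data - 1000, c(1, 1, 1)))
  expect_equal(again$data, once$data)
})

test_that("preprocess_spec and ct_volume enforce their invariants", {
  expect_error(preprocess_spec(hu_low = 0, hu_high = 0), "exceed")
  expect_error(preprocess_spec(shift = 500), "equal 0")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)), "positive")
  expect_error(ct_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(ct_volume(array(-5, c(2, 2, 2)), c(1, 1, 1),
                         intensity_kind = "preprocessed"), "0, 4000")
  expect_error(structure_set("s", list(a = array(2, c(2, 2, 2)))), "binary")
})

test_that("identity resample returns voxelwise identical data; constants stay constant", {
  set.seed(3)
  vol <- ct_volume(array(rnorm(8 * 12 * 12), dim = c(8, 12, 12)),
                   spacing = c(2.5, 1.17, 1.17))
  expect_identical(resample_to_grid(vol)$data, vol$data)
  const <- ct_volume(array(7, dim = c(9, 11, 13)), spacing = c(3, 2, 2))
  out <- resample_to_grid(const)
  expect_true(all(abs(out$data - 7) < 1e-9))
  expect_equal(out$spacing, c(2.5, 1.17, 1.17))
  expect_error(resample_to_grid(ct_volume(array(0, c(1, 5, 5)), c(1, 1, 1))),
               "degenerate")
})

test_that("a downsampled delta impulse lands within one voxel of its physical position", {
  # impulse on the downsampled lattice (a point-sampling resampler misses
  # deltas that fall between output voxel centres)
  a <- array(0, dim = c(11, 11, 11))
  a[7, 7, 7] <- 1000
  vol <- ct_volume(a, spacing = c(1, 1, 1))
  out <- resample_to_grid(vol, spec = c(2, 2, 2))
  w <- which(out$data == max(out$data), arr.ind = TRUE)[1, ]
  # independent physical mapping: position (6,6,6) mm -> index 6/2 + 1 = 4
  expect_gt(max(out$data), 0)
  expect_true(all(abs(w - 4) <= 1))
})

test_that("resample there-and-back changes a band-limited phantom by < 2% RMS", {
  dm <- c(20, 24, 24)
  co <- expand.grid(z = 1:dm[1], y = 1:dm[2], x = 1:dm[3])
  f <- 1000 * exp(-((co$z - 10)^2 / 50 + (co$y - 12)^2 / 72 + (co$x - 12)^2 / 72))
  vol <- ct_volume(array(f, dim = dm), spacing = c(2.5, 1.17, 1.17))
  there <- resample_to_grid(vol, spec = c(2, 1, 1))
  back <- resample_to_grid(there, spec = c(2.5, 1.17, 1.17))
  n <- pmin(dim(back$data), dm)
  diff <- back$data[1:n[1], 1:n[2], 1:n[3]] - vol$data[1:n[1], 1:n[2], 1:n[3]]
  rms_rel <- sqrt(mean(diff^2)) / sqrt(mean(vol$data^2))
  expect_lt(rms_rel, 0.02)
})

test_that("mask resampling stays strictly binary", {
  ph <- small_cohort()[[1]]
  out <- resample_mask(ph$structures$masks$bladder, spacing = c(2.5, 1.17, 1.17),
                       spec = c(2, 1, 1))
  expect_true(all(out %in% c(0L, 1L)))
  expect_gt(sum(out), 0)
})
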