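# DSC / MSD / HD, surface extraction, evaluation-time trimming, cohort tables

test_that("dice: identities, disjoint, voxel arithmetic and empty-mask policy", {
  dm <- c(6, 6, 6)
  a <- rand_mask(dm)
  expect_equal(dice(a, a), 1)
  d1 <- array(0L, dm); d1[1:2, , ] <- 1L
  d2 <- array(0L, dm); d2[4:5, , ] <- 1L
  expect_equal(dice(d1, d2), 0)
  # 2x2x2 cube overlapping a shifted cube in 4 voxels -> 2*4/16 = 0.5
  c1 <- array(0L, dm); c1[1:2, 1:2, 1:2] <- 1L
  c2 <- array(0L, dm); c2[1:2, 1:2, 2:3] <- 1L
  expect_equal(dice(c1, c2), 0.5)
  z <- array(0L, dm)
  expect_equal(dice(z, z), 1)     # both empty
  expect_equal(dice(z, c1), 0)    # exactly one empty
  expect_equal(dice(c1, z), 0)
  expect_error(dice(c1, array(0L, c(6, 6, 7))), "grid mismatch")
  # symmetry on random masks
  set.seed(13)
  for (i in 1:10) {
    p <- rand_mask(dm, blob = FALSE, p = .4); r <- rand_mask(dm, blob = FALSE, p = .4)
    expect_equal(dice(p, r), dice(r, p))
  }
})

test_that("extract_surface: single voxel, 3x3x3 cube, slab; border counts as background", {
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  s <- extract_surface(one, c(2, 1, 1))
  expect_equal(nrow(s), 1)
  expect_equal(unname(s[1, ]), c(4, 2, 2))
  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(extract_surface(cube)), 26)  # all but the centre
  slab <- array(0L, c(1, 4, 4)); slab[1, , ] <- 1L
  expect_equal(nrow(extract_surface(slab)), 16)  # thickness 1: all surface
  full <- array(1L, c(3, 3, 3))
  expect_equal(nrow(extract_surface(full)), 26)  # border is background, centre interior
  expect_error(extract_surface(array(0L, c(2, 2, 2))), "empty")
})

test_that("MSD and HD: point pairs and identical masks", {
  dm <- c(12, 12, 12)
  a <- array(0L, dm); a[2, 2, 2] <- 1L
  b <- array(0L, dm); b[6, 2, 2] <- 1L      # 4 slices * 2.5 mm = 10 mm apart
  sp <- c(2.5, 1, 1)
  expect_equal(mean_surface_distance(a, b, sp), 1.0)
  expect_equal(hausdorff_distance(a, b, sp), 1.0)
  m <- rand_mask(dm)
  expect_equal(mean_surface_distance(m, m, sp), 0)
  expect_equal(hausdorff_distance(m, m, sp), 0)
  expect_error(mean_surface_distance(a, array(0L, dm), sp), "empty")
  expect_error(hausdorff_distance(array(0L, dm), b, sp), "empty")
})

test_that("accelerated metrics agree with O(n^2) brute-force oracles to 1e-9", {
  set.seed(14)
  sp <- c(2.5, 1.17, 1.17)
  for (i in 1:30) {
    dm <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
    p <- rand_mask(dm); r <- rand_mask(dm)
    expect_equal(dice(p, r), dice_bf(p, r), tolerance = 1e-12)
    expect_equal(mean_surface_distance(p, r, sp), msd_bf(p, r, sp), tolerance = 1e-9)
    expect_equal(hausdorff_distance(p, r, sp), hd_bf(p, r, sp), tolerance = 1e-9)
  }
})

test_that("HD >= MSD >= 0; metrics invariant to joint rigid translation", {
  set.seed(15)
  sp <- c(2, 1, 1)
  for (i in 1:15) {
    p <- rand_mask(c(10, 10, 10)); r <- rand_mask(c(10, 10, 10))
    msd <- mean_surface_distance(p, r, sp); hd <- hausdorff_distance(p, r, sp)
    expect_gte(hd, msd - 1e-12)
    expect_gte(msd, 0)
    d <- c(2, -1, 3)
    ps <- cascadeseg:::shift_array(p, d); rs <- cascadeseg:::shift_array(r, d)
    if (sum(ps) == sum(p) && sum(rs) == sum(r)) {   # nothing clipped off-grid
      expect_equal(mean_surface_distance(ps, rs, sp), msd, tolerance = 1e-9)
      expect_equal(hausdorff_distance(ps, rs, sp), hd, tolerance = 1e-9)
    }
  }
})

test_that("hausdorff percentile variant is monotone in the percentile", {
  set.seed(16)
  p <- rand_mask(c(10, 10, 10), blob = FALSE, p = .3)
  r <- rand_mask(c(10, 10, 10), blob = FALSE, p = .3)
  h95 <- hausdorff_distance(p, r, c(1, 1, 1), percentile = 95)
  h100 <- hausdorff_distance(p, r, c(1, 1, 1), percentile = 100)
  expect_lte(h95, h100)
})

test_that("trim_to_reference_extent truncates the configured end only", {
  dm <- c(40, 6, 6)
  pred <- array(0L, dm); pred[5:30, 2:4, 2:4] <- 1L
  ref <- array(0L, dm); ref[5:25, 2:4, 2:4] <- 1L
  sup <- trim_to_reference_extent(pred, ref, "superior")
  expect_equal(range(which(cascadeseg:::slice_any(sup))), c(5, 25))
  inf <- trim_to_reference_extent(pred, ref, "inferior")
  expect_identical(inf, pred)   # pred does not extend below ref
  ref2 <- array(0L, dm); ref2[10:35, 2:4, 2:4] <- 1L
  inf2 <- trim_to_reference_extent(pred, ref2, "inferior")
  expect_equal(range(which(cascadeseg:::slice_any(inf2))), c(10, 30))
  expect_error(trim_to_reference_extent(pred, array(0L, dm), "superior"), "empty")
  # voxelwise oracle on random masks
  set.seed(17)
  for (i in 1:10) {
    p <- rand_mask(c(15, 6, 6), blob = FALSE, p = .3)
    r <- rand_mask(c(15, 6, 6))
    ez <- cascadeseg:::mask_extent_z(r)
    co <- cascadeseg:::coord_arrays(dim(p))
    expect_identical(trim_to_reference_extent(p, r, "superior"),
                     array(as.integer(p == 1 & co$z <= ez[2]), dim = dim(p)))
    expect_identical(trim_to_reference_extent(p, r, "inferior"),
                     array(as.integer(p == 1 & co$z >= ez[1]), dim = dim(p)))
  }
})

test_that("evaluate_cohort: perfect predictions, empty predictions, skipped pairs,
           trims applied, aggregates match per-scan brute force", {
  set.seed(18)
  sp <- c(2.5, 1.17, 1.17)
  refs <- preds <- list()
  for (k in 1:4) {
    id <- sprintf("s%02d", k)
    gt <- list(bladder = rand_mask(c(10, 12, 12)), rectum = rand_mask(c(10, 12, 12)))
    refs[[id]] <- gt
    preds[[id]] <- list(bladder = cascadeseg:::binary_dilate(gt$bladder, 1),
                        rectum = gt$rectum)
  }
  preds$s01$cord <- rand_mask(c(10, 12, 12))        # no reference -> skipped
  preds$s02$bladder <- array(0L, c(10, 12, 12))     # empty prediction
  res <- evaluate_cohort(preds, refs, spacing = sp)
  expect_true(all(res$per_scan$dsc[res$per_scan$structure == "rectum"] == 1))
  expect_true(all(res$per_scan$msd_cm[res$per_scan$structure == "rectum"] == 0))
  skipped <- res$per_scan[res$per_scan$status == "skipped_no_reference", ]
  expect_equal(skipped$structure, "cord")
  emptyrow <- res$per_scan[res$per_scan$scan == "s02" &
                           res$per_scan$structure == "bladder", ]
  expect_equal(emptyrow$dsc, 0)
  expect_true(is.na(emptyrow$msd_cm))
  expect_identical(emptyrow$status, "missing_metric_empty_mask")
  # rectum rows are trimmed per config (inferior) - flag recorded
  expect_true(all(res$per_scan$trimmed[res$per_scan$structure == "rectum"]))
  # aggregates equal hand-computed means over the valid rows
  g <- res$per_scan[res$per_scan$structure == "bladder" & !is.na(res$per_scan$dsc), ]
  s <- res$summary[res$summary$structure == "bladder", ]
  expect_equal(s$dsc_mean, mean(g$dsc))
  expect_equal(s$n, nrow(g))
  # hand-verify one dilated row against brute force
  expect_equal(g$dsc[g$scan == "s03"],
               dice_bf(preds$s03$bladder, refs$s03$bladder))
})
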