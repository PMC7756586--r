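# Segmentation core: pluggable 2D/3D voxel segmenters trained with the soft
# Dice loss and Adam, the coarse -> crop -> refine strategy, multi-label
# heads, flip/rotation augmentation and 2D-union-3D fusion.
#
# The reference segmenter is a per-voxel logistic model on intensity features
# (raw and locally smoothed preprocessed intensity) plus normalised region
# coordinates and their squares, so a single linear head can carve an
# ellipsoidal decision surface gated by intensity. 3D mode uses a 3D
# smoothing kernel and the axial coordinate; 2D mode sees in-plane features
# only. The contract downstream stages depend on is: fit on (volume, mask)
# pairs, emit a per-voxel probability per structure channel.

#' Augmentation settings
#'
#' Horizontal (left-right) flips and in-plane rotations by random angles in
#' `rotation_range` degrees about the axial axis; images are interpolated
#' linearly, masks nearest-neighbour. `crop_center_jitter` randomises the
#' crop centre over the ground-truth bounding box when training refine
#' models.
#'
#' @param hflip enable horizontal flips.
#' @param rotation_range degrees, within `[-180, 180]`.
#' @param n_rotations rotated copies per scan per training set build.
#' @param crop_center_jitter enable random crop centres for refine training.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(hflip = TRUE, rotation_range = c(-30, 30),
                         n_rotations = 1L, crop_center_jitter = TRUE) {
  stopifnot(length(rotation_range) == 2, all(abs(rotation_range) <= 180),
            rotation_range[1] <= rotation_range[2])
  structure(list(hflip = hflip, rotation_range = rotation_range,
                 n_rotations = as.integer(n_rotations),
                 crop_center_jitter = crop_center_jitter),
            class = "augment_spec")
}

#' No-op augmentation
#' @export
no_augment <- function() augment_spec(hflip = FALSE, n_rotations = 0L,
                                      crop_center_jitter = FALSE)

#' Crop specification for the refine stage
#'
#' @param box_shape voxel triple `(dz, dy, dx)` of the crop box.
#' @param center optional voxel triple; normally the coarse centre of mass.
#' @param coarse_shape optional in-plane `(ny, nx)` used by the coarse pass.
#' @return An object of class `crop_spec`.
#' @export
crop_spec <- function(box_shape, center = NULL, coarse_shape = NULL) {
  stopifnot(length(box_shape) == 3, all(box_shape >= 1))
  structure(list(center = center, box_shape = as.integer(box_shape),
                 coarse_shape = coarse_shape),
            class = "crop_spec")
}

#' Derive a per-structure crop box from a training cohort
#'
#' The box is the tightest bounding box of the structure across the cohort,
#' dilated by `dilate` (fraction) in each axis -- large enough to enclose the
#' structure on the training data while bounding the refine model's field of
#' view.
#'
#' @param cohort list of scans.
#' @param structure structure name.
#' @param dilate fractional dilation per axis (default 0.25).
#' @return A [crop_spec()].
#' @export
derive_crop_spec <- function(cohort, structure, dilate = 0.25) {
  spans <- sapply(cohort, function(s) {
    bb <- mask_bbox(s$structures$masks[[structure]])
    bb["hi", ] - bb["lo", ] + 1
  })
  box <- ceiling(apply(spans, 1, max) * (1 + dilate))
  grid <- dim(cohort[[1]]$volume$data)
  crop_spec(pmin(box, grid))
}

# clamp a box of shape `shape` centred at `center` to the grid; returns
# list(z, y, x) index ranges whose lengths equal `shape` (when it fits)
crop_ranges <- function(center, shape, grid) {
  out <- vector("list", 3)
  for (k in 1:3) {
    half <- (shape[k] - 1) %/% 2
    lo <- center[k] - half
    hi <- lo + shape[k] - 1
    if (lo < 1) { hi <- hi - lo + 1; lo <- 1 }
    if (hi > grid[k]) { lo <- lo - (hi - grid[k]); hi <- grid[k] }
    lo <- max(1, lo)
    out[[k]] <- lo:hi
  }
  names(out) <- c("z", "y", "x")
  out
}

# voxel features inside a region (list of z/y/x index vectors) of a
# preprocessed volume; `smooth` is the matching precomputed smoothed array.
# Intensity enters as raw and smoothed linear terms plus three classic CT
# band indicators on each (soft tissue, contrast-enhanced vessel, bone) --
# cheap nonlinearities that mark tissue class without being swamped by bone
# variance; position enters as region-normalised coordinates and their
# squares, so one linear head can carve an intensity-gated ellipsoid.
voxel_features <- function(a, smooth, region, mode) {
  sub <- a[region$z, region$y, region$x, drop = FALSE]
  subs <- smooth[region$z, region$y, region$x, drop = FALSE]
  dm <- dim(sub)
  co <- coord_arrays(dm)
  nrm <- function(v, n) if (n > 1) (2 * (v - 1) / (n - 1) - 1) else v * 0
  zc <- nrm(co$z, dm[1]); yc <- nrm(co$y, dm[2]); xc <- nrm(co$x, dm[3])
  i1 <- (as.vector(sub) - 1000) / 1000
  i2 <- (as.vector(subs) - 1000) / 1000
  sv <- as.vector(sub); sm <- as.vector(subs)
  s1 <- as.numeric(sv > 1005 & sv <= 1120)
  s2 <- as.numeric(sm > 1005 & sm <= 1120)
  v1 <- as.numeric(sv > 1120 & sv <= 1320)
  v2 <- as.numeric(sm > 1120 & sm <= 1320)
  b1 <- as.numeric(sv > 1400)
  b2 <- as.numeric(sm > 1400)
  g1 <- abs(i1 - i2)   # raw/smooth divergence: large at sharp interfaces
  if (mode == "volume_3d") {
    cbind(1, i1, i2, s1, s2, v1, v2, b1, b2, g1,
          as.vector(zc), as.vector(yc), as.vector(xc),
          as.vector(zc)^2, as.vector(yc)^2, as.vector(xc)^2)
  } else {
    cbind(1, i1, i2, s1, s2, v1, v2, b1, b2, g1, as.vector(yc), as.vector(xc),
          as.vector(yc)^2, as.vector(xc)^2)
  }
}

# build one training view (possibly augmented) of a scan: returns the
# preprocessed array, its smoothed copy and the label arrays
training_view <- function(vol, masks, transform, angle, mode) {
  a <- vol$data
  ms <- masks
  if (transform == "hflip") {
    a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
    ms <- lapply(ms, function(m) m[, , rev(seq_len(dim(m)[3])), drop = FALSE])
  } else if (transform == "rotate") {
    fill <- stats::median(a)
    a <- rotate_inplane(a, angle, "linear", fill = fill)
    ms <- lapply(ms, function(m) rotate_inplane(m, angle, "nearest", fill = 0))
  }
  list(a = a, smooth = box_smooth(a, if (mode == "volume_3d") "3d" else "2d"),
       masks = ms)
}

#' Train a 2D or 3D voxel segmenter
#'
#' Fits one probability channel per structure (a single model handles the
#' multi-label pair L4/L5) by minimising the soft Dice loss with Adam over
#' voxels sampled from each scan's training region. Training is restricted to
#' the padded ground-truth extent (`region = "extent"`), to crops around the
#' structure (`region = "crop"`, with random crop centres when
#' `aug$crop_center_jitter`), or to the whole grid (`region = "full"`).
#'
#' @param cohort list of scans with `volume` and `structures`.
#' @param structures one structure name, or a character vector for a
#'   multi-label model.
#' @param mode `"volume_3d"` or `"slice_2d"`.
#' @param opt an [adam_config()].
#' @param aug an [augment_spec()].
#' @param region training field-of-view rule (see above).
#' @param crop a [crop_spec()], required for `region = "crop"`.
#' @param coarse_shape optional in-plane `(ny, nx)`: train (and later
#'   predict) on in-plane downsampled volumes.
#' @param extent_pad slices of padding around the ground-truth extent.
#' @param n_samples voxels sampled per training view.
#' @param anchor_structure optional structure whose centroid anchors the
#'   training crop (instead of the target's own bounding box), mirroring how
#'   the crop is placed at prediction time (e.g. the vessel model cropped
#'   around L4).
#' @return An object of class `voxel_segmenter`.
#' @export
train_segmenter <- function(cohort, structures,
                            mode = c("volume_3d", "slice_2d"),
                            opt = adam_config(), aug = augment_spec(),
                            region = c("extent", "crop", "full"),
                            crop = NULL, coarse_shape = NULL,
                            extent_pad = 1L, n_samples = 6000L,
                            anchor_structure = NULL) {
  mode <- match.arg(mode)
  region <- match.arg(region)
  if (region == "crop" && is.null(crop))
    stop("train_segmenter: region = 'crop' requires a crop_spec")
  wanted <- c(structures, anchor_structure)
  keep <- vapply(cohort, function(s)
    all(wanted %in% names(s$structures$masks)) &&
      all(vapply(wanted, function(nm) sum(s$structures$masks[[nm]]) > 0, logical(1))),
    logical(1))
  if (sum(keep) < 2)
    stop(sprintf("train_segmenter: structures [%s] present in fewer than 2 scans",
                 paste(structures, collapse = ", ")))
  cohort <- cohort[keep]
  set.seed(opt$seed)
  X <- NULL; Y <- NULL
  stream <- character(0)
  for (s in cohort) {
    vol <- ensure_preprocessed(s$volume)
    if (!is.null(coarse_shape)) {
      vol <- ct_volume(resize_inplane(vol$data, coarse_shape, "linear"),
                       vol$spacing, vol$origin, "preprocessed")
      masks <- lapply(s$structures$masks[wanted], resize_inplane,
                      out_yx = coarse_shape, interp = "nearest")
    } else {
      masks <- s$structures$masks[wanted]
    }
    transforms <- "identity"
    angles <- 0
    if (aug$hflip) { transforms <- c(transforms, "hflip"); angles <- c(angles, 0) }
    if (aug$n_rotations > 0) {
      th <- stats::runif(aug$n_rotations, aug$rotation_range[1], aug$rotation_range[2])
      transforms <- c(transforms, rep("rotate", aug$n_rotations))
      angles <- c(angles, th)
    }
    for (ti in seq_along(transforms)) {
      vw <- training_view(vol, masks, transforms[ti], angles[ti], mode)
      stream <- c(stream, sprintf("%s:%s:%.4f", s$id, transforms[ti], angles[ti]))
      union_mask <- Reduce(`+`, vw$masks[structures])
      grid <- dim(vw$a)
      reg <- switch(region,
        full = list(z = seq_len(grid[1]), y = seq_len(grid[2]), x = seq_len(grid[3])),
        extent = {
          ez <- mask_extent_z(union_mask)
          if (is.null(ez)) next
          lo <- max(1, ez[1] - extent_pad); hi <- min(grid[1], ez[2] + extent_pad)
          list(z = lo:hi, y = seq_len(grid[2]), x = seq_len(grid[3]))
        },
        crop = {
          bb <- mask_bbox(union_mask)
          if (is.null(bb)) next
          ctr <- if (!is.null(anchor_structure))
            center_of_mass(vw$masks[[anchor_structure]])
          else if (aug$crop_center_jitter)
            vapply(1:3, function(k) sample(bb["lo", k]:bb["hi", k], 1), numeric(1))
          else round(colMeans(which(union_mask == 1, arr.ind = TRUE)))
          crop_ranges(ctr, crop$box_shape, grid)
        })
      Xi <- voxel_features(vw$a, vw$smooth, reg, mode)
      Yi <- sapply(vw$masks[structures], function(m)
        as.vector(m[reg$z, reg$y, reg$x, drop = FALSE]))
      Yi <- as.matrix(Yi)
      # rebalanced voxel subsample: foreground capped at a quarter; half of
      # the background budget is spent on hard negatives (tissue-like voxels
      # that are not the target), which forces the head to use position, not
      # just the intensity window
      fg <- which(rowSums(Yi) > 0)
      bg <- which(rowSums(Yi) == 0)
      n_fg <- min(length(fg), floor(n_samples / 4))
      hard <- bg[Xi[bg, 2] > 0.005 | Xi[bg, 3] > 0.005]
      n_hard <- min(length(hard), floor((n_samples - n_fg) / 2))
      n_bg <- min(length(bg), n_samples - n_fg - n_hard)
      pick <- c(if (n_fg > 0) sample(fg, n_fg),
                if (n_hard > 0) sample(hard, n_hard),
                if (n_bg > 0) sample(bg, n_bg))
      X <- rbind(X, Xi[pick, , drop = FALSE])
      Y <- rbind(Y, Yi[pick, , drop = FALSE])
    }
  }
  if (is.null(X) || nrow(X) == 0)
    stop("train_segmenter: empty training set after extent restriction")
  # z-score the non-intercept features so intensity contrasts and coordinate
  # terms share a scale the optimizer can traverse quickly
  mu <- colMeans(X); mu[1] <- 0
  sdv <- apply(X, 2, stats::sd); sdv[1] <- 1; sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  fit <- fit_logistic(Xs, Y, loss = "dice", cfg = opt)
  structure(list(structures = structures, mode = mode, region = region,
                 weights = fit$weights, feat_mu = mu, feat_sd = sdv,
                 crop = crop,
                 coarse_shape = coarse_shape, threshold = 0.5,
                 train_stream = stream, loss_trace = fit$trace,
                 opt = opt),
            class = "voxel_segmenter")
}

# per-voxel probabilities of `model` inside `region` of a preprocessed array
predict_prob_region <- function(model, a, smooth, region) {
  X <- voxel_features(a, smooth, region, model$mode)
  X <- sweep(sweep(X, 2, model$feat_mu), 2, model$feat_sd, `/`)
  P <- sigmoid(X %*% model$weights)
  dims <- c(length(region$z), length(region$y), length(region$x))
  lapply(seq_len(ncol(P)), function(k) array(P[, k], dim = dims))
}

#' Segmentation prediction container
#'
#' @param structure structure name.
#' @param mask binary 3D array on the full volume grid.
#' @param stage `"coarse"`, `"refined"` or `"fused_2d3d"`.
#' @return An object of class `seg_prediction`.
#' @export
seg_prediction <- function(structure, mask, stage = c("coarse", "refined", "fused_2d3d")) {
  stage <- match.arg(stage)
  if (!all(mask %in% c(0, 1))) stop("seg_prediction: mask must be binary")
  structure(list(structure = structure, mask = mask, stage = stage),
            class = "seg_prediction")
}

#' Coarse segmentation on an in-plane downsampled volume
#'
#' Restricts to the (already padded) extent, downsamples in-plane to the
#' model's coarse shape, predicts, thresholds at 0.5, keeps the largest
#' connected component, and upsamples nearest-neighbour back to the working
#' grid. With no coarse shape (native resolution) this is direct
#' segmentation.
#'
#' @param model a `voxel_segmenter` (single-structure).
#' @param vol a `ct_volume`.
#' @param extent an [extent_interval()] restricting the slices processed.
#' @param coarse_shape in-plane `(ny, nx)` override; defaults to the shape
#'   the model was trained on.
#' @param keep_largest drop all but the largest 3D connected component.
#' @return A [seg_prediction()] with `stage = "coarse"`; the mask may be
#'   empty, which the caller handles as a failure case.
#' @export
coarse_segment <- function(model, vol, extent, coarse_shape = NULL,
                           keep_largest = TRUE) {
  if (!inherits(extent, "extent_interval"))
    stop("coarse_segment: `extent` must be an extent_interval")
  vol <- ensure_preprocessed(vol)
  grid <- dim(vol$data)
  coarse_shape <- coarse_shape %||% model$coarse_shape
  a <- vol$data
  if (!is.null(coarse_shape) && !all(coarse_shape == grid[2:3])) {
    a <- resize_inplane(a, coarse_shape, "linear")
  }
  dm <- dim(a)
  reg <- list(z = extent$lo:extent$hi, y = seq_len(dm[2]), x = seq_len(dm[3]))
  sm <- box_smooth(a, if (model$mode == "volume_3d") "3d" else "2d")
  prob <- predict_prob_region(model, a, sm, reg)[[1]]
  m_small <- array(0L, dim = dm)
  m_small[reg$z, reg$y, reg$x] <- as.integer(prob >= model$threshold)
  if (keep_largest && sum(m_small) > 0) m_small <- largest_component(m_small)
  m <- if (all(dim(m_small)[2:3] == grid[2:3])) m_small else
    array(as.integer(resize_inplane(m_small, grid[2:3], "nearest") != 0), dim = grid)
  seg_prediction(model$structures[1], m, "coarse")
}

#' Centre of mass of a binary mask
#'
#' Unweighted mean voxel coordinate of the foreground, rounded to the
#' nearest voxel.
#'
#' @param mask binary 3D array, non-empty.
#' @return Integer voxel triple `(z, y, x)`.
#' @export
center_of_mass <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(w)) stop("center_of_mass: empty mask")
  as.integer(round(colMeans(w)))
}

#' Refine a coarse prediction inside a crop at native resolution
#'
#' Crops a box of `crop$box_shape` centred on the coarse centre of mass
#' (clamped to the grid), applies the refine model at native resolution
#' inside the box, and composites the result back onto the full grid (zero
#' outside the box). An empty coarse prediction cannot anchor a crop: the
#' coarse prediction is returned unchanged with a warning and the scan is
#' recorded as a failure case.
#'
#' @param coarse a [seg_prediction()].
#' @param vol the `ct_volume`.
#' @param refine_model a `voxel_segmenter` trained on crops, or a plain
#'   function `(vol, region) -> probability array` honouring the same
#'   contract (used to plug in oracle predictors).
#' @param crop a [crop_spec()].
#' @return A [seg_prediction()] with `stage = "refined"`.
#' @export
refine_segment <- function(coarse, vol, refine_model, crop) {
  stopifnot(inherits(coarse, "seg_prediction"))
  if (sum(coarse$mask) == 0) {
    warning("refine_segment: empty coarse prediction; returning it unrefined")
    return(coarse)
  }
  vol <- ensure_preprocessed(vol)
  grid <- dim(vol$data)
  ctr <- center_of_mass(coarse$mask)
  reg <- crop_ranges(ctr, crop$box_shape, grid)
  if (is.function(refine_model)) {
    prob <- refine_model(vol, reg)
    thr <- 0.5
  } else {
    sm <- box_smooth(vol$data, if (refine_model$mode == "volume_3d") "3d" else "2d")
    prob <- predict_prob_region(refine_model, vol$data, sm, reg)[[1]]
    thr <- refine_model$threshold
  }
  m <- array(0L, dim = grid)
  m[reg$z, reg$y, reg$x] <- as.integer(prob >= thr)
  if (sum(m) > 0) m <- largest_component(m)
  seg_prediction(coarse$structure, m, "refined")
}

#' Predict every channel of a multi-label segmenter
#'
#' @param model a multi-label `voxel_segmenter`.
#' @param vol a `ct_volume`.
#' @param extent optional [extent_interval()]; defaults to the whole volume.
#' @return Named list of binary masks, one per structure channel, each
#'   restricted to the voxels where its channel wins the argmax (so adjacent
#'   multi-label structures stay disjoint).
#' @export
predict_multilabel <- function(model, vol, extent = NULL) {
  vol <- ensure_preprocessed(vol)
  grid <- dim(vol$data)
  ext <- extent %||% extent_interval(1, grid[1], grid[1])
  reg <- list(z = ext$lo:ext$hi, y = seq_len(grid[2]), x = seq_len(grid[3]))
  sm <- box_smooth(vol$data, if (model$mode == "volume_3d") "3d" else "2d")
  probs <- predict_prob_region(model, vol$data, sm, reg)
  K <- length(probs)
  win <- array(1L, dim = dim(probs[[1]]))
  best <- probs[[1]]
  for (k in seq_len(K)[-1]) {
    upd <- probs[[k]] > best
    win[upd] <- k
    best[upd] <- probs[[k]][upd]
  }
  out <- list()
  for (k in seq_len(K)) {
    m <- array(0L, dim = grid)
    m[reg$z, reg$y, reg$x] <- as.integer(probs[[k]] >= model$threshold & win == k)
    if (sum(m) > 0) m <- largest_component(m)
    out[[model$structures[k]]] <- m
  }
  out
}

#' Fuse 2D and 3D predictions by voxelwise union
#'
#' The final nodal contour is the union of the 2D and 3D model outputs, so
#' fusion can only add foreground: recall never decreases relative to either
#' input. Union is commutative, associative and idempotent.
#'
#' @param pred2d,pred3d [seg_prediction()]s on congruent grids for the same
#'   structure.
#' @return A [seg_prediction()] with `stage = "fused_2d3d"`.
#' @export
fuse_2d3d <- function(pred2d, pred3d) {
  if (!identical(dim(pred2d$mask), dim(pred3d$mask)))
    stop("fuse_2d3d: grid mismatch")
  if (!identical(pred2d$structure, pred3d$structure))
    stop("fuse_2d3d: structure mismatch")
  m <- array(as.integer(pred2d$mask | pred3d$mask), dim = dim(pred2d$mask))
  seg_prediction(pred2d$structure, m, "fused_2d3d")
}
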