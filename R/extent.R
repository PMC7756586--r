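# Per-slice organ-presence classification and cranial-caudal extent
# postprocessing. The classifier is a pluggable contract: fit on labelled
# slices, emit a per-slice presence probability. The reference implementation
# is a slice-feature logistic model (per-slice mean, spread and a 4 x 4
# mean-pool of the preprocessed slice) trained with weighted cross-entropy,
# the weight being the ratio of absent to present slices.

#' Per-slice presence probability series
#'
#' @param structure structure name.
#' @param probs numeric vector, one presence probability in `[0, 1]` per
#'   axial slice.
#' @param labels optional per-slice binary ground truth.
#' @return An object of class `slice_presence_series`.
#' @export
slice_presence_series <- function(structure, probs, labels = NULL) {
  if (length(probs) < 1 || any(probs < 0 | probs > 1))
    stop("slice_presence_series: probs must lie in [0, 1]")
  if (!is.null(labels) && length(labels) != length(probs))
    stop("slice_presence_series: labels length must equal probs length")
  structure(list(structure = structure, probs = as.numeric(probs),
                 labels = labels),
            class = "slice_presence_series")
}

#' Inclusive axial extent interval
#'
#' @param lo,hi 1-based inclusive slice indices, `1 <= lo <= hi <= n_slices`.
#' @param n_slices total slice count of the volume.
#' @return An object of class `extent_interval`.
#' @export
extent_interval <- function(lo, hi, n_slices) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo < 1L || hi < lo || hi > n_slices)
    stop("extent_interval: need 1 <= lo <= hi <= n_slices")
  structure(list(lo = lo, hi = hi, n_slices = as.integer(n_slices)),
            class = "extent_interval")
}

#' Pad an extent by `pad` slices at each end, clamped to the grid
#' @param ext an [extent_interval()].
#' @param pad slices to add at each end.
#' @return An [extent_interval()].
#' @export
pad_extent <- function(ext, pad = 1L) {
  extent_interval(max(1L, ext$lo - pad), min(ext$n_slices, ext$hi + pad),
                  ext$n_slices)
}

#' Presence-classifier configuration
#'
#' @param optimizer an [adam_config()].
#' @param loss_weight_mode `"auto_ratio"` (weight = absences / presences on
#'   the training slices) or `"fixed"`.
#' @param fixed_weight weight used when `loss_weight_mode = "fixed"`.
#' @param threshold binarisation threshold for extent postprocessing.
#' @param max_gap internal zero-gaps up to this many slices are filled.
#' @param pad slices of padding added to the extent handed downstream.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(optimizer = adam_config(lr = 0.2, epochs = 300),
                              loss_weight_mode = c("auto_ratio", "fixed"),
                              fixed_weight = 1,
                              threshold = 0.5, max_gap = 2L, pad = 1L) {
  loss_weight_mode <- match.arg(loss_weight_mode)
  stopifnot(optimizer$epochs >= 1)
  structure(list(optimizer = optimizer, loss_weight_mode = loss_weight_mode,
                 fixed_weight = fixed_weight, threshold = threshold,
                 max_gap = as.integer(max_gap), pad = as.integer(pad)),
            class = "classifier_config")
}

# per-slice features: mean, sd, a 4x4 in-plane mean-pool of the preprocessed
# volume, and a matching pool of the soft-tissue fraction (voxels within the
# 1005-1105 window, i.e. organ-like HU after the +1000 shift)
slice_features <- function(vol) {
  ap <- ensure_preprocessed(vol)$data
  a <- (ap - 1000) / 1000
  soft <- (ap > 1005 & ap <= 1120) + 0
  vess <- (ap > 1120 & ap <= 1320) + 0
  dm <- dim(a)
  nz <- dm[1]
  M <- matrix(a, nrow = nz)
  mu <- rowMeans(M)
  sd_ <- sqrt(pmax(0, rowMeans(M^2) - mu^2))
  yb <- ceiling(seq_len(dm[2]) / dm[2] * 4)
  xb <- ceiling(seq_len(dm[3]) / dm[3] * 4)
  pool <- matrix(0, nz, 48)
  k <- 0
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1
    sel_y <- yb == i; sel_x <- xb == j
    pool[, k] <- rowMeans(matrix(a[, sel_y, sel_x, drop = FALSE], nrow = nz))
    pool[, 16 + k] <- rowMeans(matrix(soft[, sel_y, sel_x, drop = FALSE], nrow = nz))
    pool[, 32 + k] <- rowMeans(matrix(vess[, sel_y, sel_x, drop = FALSE], nrow = nz))
  }
  cbind(mean = mu, sd = sd_, pool)
}

#' Train a per-slice presence classifier
#'
#' One model per structure; the per-slice label is "the structure's mask is
#' non-empty on that slice". Under `auto_ratio` the positive-class weight is
#' computed from the pooled training slices.
#'
#' @param cohort list of scans (each with `volume` and `structures`).
#' @param structure structure name, or several names: the per-slice label is
#'   then "any of the structures present" (used for multi-label models whose
#'   field of view must cover the union).
#' @param cfg a [classifier_config()].
#' @return An object of class `presence_classifier` with the trained weights,
#'   feature standardisation, the class weight used, and a training log.
#' @export
train_presence_classifier <- function(cohort, structure,
                                      cfg = classifier_config()) {
  has <- vapply(cohort, function(s)
    all(structure %in% names(s$structures$masks)) &&
      all(vapply(structure, function(nm) sum(s$structures$masks[[nm]]) > 0,
                 logical(1))),
    logical(1))
  if (sum(has) == 0)
    stop(sprintf("train_presence_classifier: structure '%s' absent from all scans", structure))
  if (sum(has) < 2)
    stop(sprintf("train_presence_classifier: structure '%s' present in fewer than 2 scans", structure))
  cohort <- cohort[has]
  X <- NULL; y <- NULL
  for (s in cohort) {
    X <- rbind(X, slice_features(s$volume))
    pres <- Reduce(`|`, lapply(structure, function(nm)
      slice_any(s$structures$masks[[nm]])))
    y <- c(y, as.integer(pres))
  }
  w <- if (cfg$loss_weight_mode == "auto_ratio") auto_class_weight(y) else cfg$fixed_weight
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-8] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, mu), 2, sdv, `/`))
  fit <- fit_logistic(Xs, y, loss = "wce", w = w, cfg = cfg$optimizer)
  structure(list(structure = paste(structure, collapse = "+"),
                 weights = drop(fit$weights),
                 feat_mu = mu, feat_sd = sdv, class_weight = w,
                 cfg = cfg, loss_trace = fit$trace),
            class = "presence_classifier")
}

#' Predict a slice-presence series for one volume
#'
#' @param model a `presence_classifier`.
#' @param vol a `ct_volume`.
#' @return A [slice_presence_series()].
#' @export
predict_presence <- function(model, vol) {
  X <- slice_features(vol)
  Xs <- cbind(1, sweep(sweep(X, 2, model$feat_mu), 2, model$feat_sd, `/`))
  slice_presence_series(model$structure, sigmoid(drop(Xs %*% model$weights)))
}

#' Postprocess a presence series to a single cranial-caudal extent
#'
#' Binarises at `threshold` (probabilities >= threshold count as present),
#' fills internal runs of absent slices no longer than `max_gap`, and returns
#' the longest remaining run as an inclusive `[lo, hi]` interval. Ties between
#' equally long runs are broken toward the run with the larger summed
#' probability. Errors when no slice reaches the threshold.
#'
#' @param series a [slice_presence_series()].
#' @param threshold probability cutoff (default 0.5).
#' @param max_gap largest internal gap to bridge, in slices (default 2).
#' @return An [extent_interval()].
#' @export
extent_postprocess <- function(series, threshold = 0.5, max_gap = 2L) {
  stopifnot(inherits(series, "slice_presence_series"))
  p <- series$probs
  b <- as.integer(p >= threshold)
  if (!any(b == 1))
    stop(sprintf("extent_postprocess: no slice above threshold for '%s'",
                 series$structure))
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # fill internal zero-gaps of length <= max_gap
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0 && k > 1 && k < length(r$values) &&
        r$lengths[k] <= max_gap)
      b[starts[k]:ends[k]] <- 1L
  }
  r2 <- rle(b)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1
  runs <- which(r2$values == 1)
  lens <- r2$lengths[runs]
  best <- runs[lens == max(lens)]
  if (length(best) > 1) {
    sums <- vapply(best, function(k) sum(p[starts2[k]:ends2[k]]), numeric(1))
    best <- best[which.max(sums)]
  }
  extent_interval(starts2[best], ends2[best], length(p))
}

#' Extent of a binary mask in the cranial-caudal direction
#'
#' @param mask binary 3D array.
#' @return An [extent_interval()], or error if the mask is empty.
#' @export
mask_extent <- function(mask) {
  ez <- mask_extent_z(mask)
  if (is.null(ez)) stop("mask_extent: empty mask")
  extent_interval(ez[1], ez[2], dim(mask)[1])
}
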