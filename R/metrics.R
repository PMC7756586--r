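# Overlap and surface-distance metrics. Surfaces are six-connected boundary
# voxels (the volume border counts as background); distances are Euclidean
# between voxel centres in physical mm and reported in cm. The Hausdorff
# distance defaults to the true maximum (100th percentile); a percentile
# parameter is exposed for HD95-style variants.

#' Sorensen-Dice similarity coefficient
#'
#' `2|P & R| / (|P| + |R|)`. Defined as 1 when both masks are empty and 0
#' when exactly one is empty.
#'
#' @param pred,ref binary masks on congruent grids.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("dice: grid mismatch")
  np <- sum(pred != 0); nr <- sum(ref != 0)
  if (np == 0 && nr == 0) return(1)
  if (np == 0 || nr == 0) return(0)
  2 * sum(pred != 0 & ref != 0) / (np + nr)
}

#' Extract surface voxels in physical coordinates
#'
#' A foreground voxel is surface if at least one of its six face neighbours
#' is background, treating everything outside the volume as background.
#' Coordinates are voxel centres in mm: `(index - 1) * spacing`.
#'
#' @param mask binary 3D array, non-empty.
#' @param spacing `(dz, dy, dx)` in mm.
#' @return An n x 3 matrix of (z, y, x) physical coordinates.
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1)) {
  if (sum(mask) == 0) stop("extract_surface: empty mask")
  fg <- mask != 0
  interior <- fg
  offs <- neighbor_offsets6()
  for (r in seq_len(nrow(offs))) {
    # neighbour shifted in; voxels whose neighbour falls outside the volume
    # see background there (shift_array zero-fills)
    interior <- interior & (shift_array(fg, offs[r, ]) != 0)
  }
  surf <- fg & !interior
  w <- which(surf, arr.ind = TRUE)
  sweep(w - 1, 2, spacing, `*`)
}

# directed nearest-surface distances from each row of A to the set B (mm);
# compiled exact per-pair scan (see src/nn_dist.cpp)
nearest_dists <- function(A, B) {
  nn_dist_cpp(A, B)
}

#' Symmetric mean surface distance
#'
#' Average of the two directed means of nearest-surface distances, Euclidean
#' in physical mm, reported in cm. Undefined (error) when either mask is
#' empty; callers report such cases as missing rather than zero.
#'
#' @param pred,ref binary masks on congruent grids, both non-empty.
#' @param spacing `(dz, dy, dx)` in mm.
#' @return MSD in cm.
#' @export
mean_surface_distance <- function(pred, ref, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(ref))) stop("mean_surface_distance: grid mismatch")
  if (sum(pred) == 0 || sum(ref) == 0)
    stop("mean_surface_distance: undefined for empty masks")
  P <- extract_surface(pred, spacing)
  R <- extract_surface(ref, spacing)
  0.5 * (mean(nearest_dists(P, R)) + mean(nearest_dists(R, P))) / 10
}

#' Hausdorff distance
#'
#' Maximum of the two directed maxima of nearest-surface distances (or a
#' percentile thereof), physical units, reported in cm.
#'
#' @param pred,ref binary masks on congruent grids, both non-empty.
#' @param spacing `(dz, dy, dx)` in mm.
#' @param percentile directed-distance percentile (default 100, the true
#'   Hausdorff distance).
#' @return HD in cm.
#' @export
hausdorff_distance <- function(pred, ref, spacing = c(1, 1, 1), percentile = 100) {
  if (!identical(dim(pred), dim(ref))) stop("hausdorff_distance: grid mismatch")
  if (sum(pred) == 0 || sum(ref) == 0)
    stop("hausdorff_distance: undefined for empty masks")
  P <- extract_surface(pred, spacing)
  R <- extract_surface(ref, spacing)
  dpr <- nearest_dists(P, R)
  drp <- nearest_dists(R, P)
  q <- function(v) if (percentile >= 100) max(v) else
    stats::quantile(v, percentile / 100, names = FALSE)
  max(q(dpr), q(drp)) / 10
}

#' Trim a prediction to the reference's axial extent
#'
#' Evaluation-time border adjustment: for `end = "superior"` all predicted
#' voxels above the reference's top occupied slice are removed (used for the
#' PAN target volume); for `end = "inferior"` all voxels below the
#' reference's bottom occupied slice are removed (rectum, spinal cord).
#'
#' @param pred predicted binary mask.
#' @param ref reference binary mask, non-empty.
#' @param end `"superior"` or `"inferior"`.
#' @return The trimmed prediction.
#' @export
trim_to_reference_extent <- function(pred, ref, end = c("superior", "inferior")) {
  end <- match.arg(end)
  if (sum(ref) == 0) stop("trim_to_reference_extent: empty reference")
  if (!identical(dim(pred), dim(ref))) stop("trim_to_reference_extent: grid mismatch")
  ez <- mask_extent_z(ref)
  out <- pred
  dm <- dim(pred)
  if (end == "superior" && ez[2] < dm[1]) out[(ez[2] + 1):dm[1], , ] <- 0L
  if (end == "inferior" && ez[1] > 1) out[1:(ez[1] - 1), , ] <- 0L
  out
}

#' Evaluation configuration
#'
#' @param trim_superior structures whose predictions are trimmed to the
#'   reference superior border before metrics (default `"pan"`).
#' @param trim_inferior structures trimmed at the inferior border
#'   (default rectum and spinal cord).
#' @param hd_percentile Hausdorff percentile (default 100).
#' @param outlier_whisker DSC whisker multiplier for outlier flagging
#'   (Q1 - k * IQR; default 1.5).
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(trim_superior = "pan",
                        trim_inferior = c("rectum", "cord"),
                        hd_percentile = 100, outlier_whisker = 1.5) {
  structure(list(trim_superior = trim_superior, trim_inferior = trim_inferior,
                 hd_percentile = hd_percentile, outlier_whisker = outlier_whisker),
            class = "eval_config")
}

#' Evaluate predicted against reference masks over a cohort
#'
#' Applies the configured border trims, computes DSC / MSD / HD per
#' (scan, structure) pair, and aggregates mean, SD and boxplot summaries per
#' structure. Predictions with no matching reference are recorded as skipped;
#' empty predictions yield DSC 0 with missing distances.
#'
#' @param predictions named list: scan id -> named list of predicted masks.
#' @param references named list: scan id -> named list of reference masks.
#' @param spacing `(dz, dy, dx)` in mm (shared working grid).
#' @param config an [eval_config()].
#' @return List with `per_scan` (one row per pair), `summary` (per-structure
#'   mean +/- SD and n), and `outliers` (rows below the DSC whisker).
#' @export
evaluate_cohort <- function(predictions, references, spacing = c(2.5, 1.17, 1.17),
                            config = eval_config()) {
  rows <- list()
  for (sid in names(predictions)) {
    preds <- predictions[[sid]]
    refs <- references[[sid]]
    for (nm in names(preds)) {
      if (is.null(refs) || is.null(refs[[nm]])) {
        rows[[length(rows) + 1]] <- data.frame(
          scan = sid, structure = nm, dsc = NA_real_, msd_cm = NA_real_,
          hd_cm = NA_real_, n_pred = sum(preds[[nm]]), n_ref = NA_integer_,
          trimmed = FALSE, status = "skipped_no_reference")
        next
      }
      p <- preds[[nm]]; r <- refs[[nm]]
      trimmed <- FALSE
      if (nm %in% config$trim_superior && sum(r) > 0) {
        p <- trim_to_reference_extent(p, r, "superior"); trimmed <- TRUE
      }
      if (nm %in% config$trim_inferior && sum(r) > 0) {
        p <- trim_to_reference_extent(p, r, "inferior"); trimmed <- TRUE
      }
      d <- dice(p, r)
      if (sum(p) > 0 && sum(r) > 0) {
        msd <- mean_surface_distance(p, r, spacing)
        hd <- hausdorff_distance(p, r, spacing, config$hd_percentile)
        status <- "ok"
      } else {
        msd <- NA_real_; hd <- NA_real_
        status <- "missing_metric_empty_mask"
      }
      rows[[length(rows) + 1]] <- data.frame(
        scan = sid, structure = nm, dsc = d, msd_cm = msd, hd_cm = hd,
        n_pred = sum(p), n_ref = sum(r), trimmed = trimmed, status = status)
    }
  }
  per_scan <- do.call(rbind, rows)
  ok <- per_scan[!is.na(per_scan$dsc), , drop = FALSE]
  summary <- do.call(rbind, lapply(split(ok, ok$structure), function(g) {
    data.frame(structure = g$structure[1], n = nrow(g),
               dsc_mean = mean(g$dsc), dsc_sd = stats::sd(g$dsc),
               msd_mean_cm = mean(g$msd_cm, na.rm = TRUE),
               msd_sd_cm = stats::sd(g$msd_cm, na.rm = TRUE),
               hd_mean_cm = mean(g$hd_cm, na.rm = TRUE),
               hd_sd_cm = stats::sd(g$hd_cm, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  out_rows <- do.call(rbind, lapply(split(ok, ok$structure), function(g) {
    q <- stats::quantile(g$dsc, c(.25, .75), names = FALSE)
    thr <- q[1] - config$outlier_whisker * (q[2] - q[1])
    g[g$dsc < thr, , drop = FALSE]
  }))
  list(per_scan = per_scan, summary = summary,
       outliers = out_rows[order(out_rows$dsc), , drop = FALSE])
}
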