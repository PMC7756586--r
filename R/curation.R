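# Semi-automatic label curation by half-split cross-training. Unreviewed
# contours are split in half; a segmenter trained on each half predicts the
# other; any (scan, structure) whose label disagrees with the cross
# prediction below a DSC threshold (0.7 for the rectum, 0.8 otherwise) is
# flagged for review, and removed if judged incorrect. The whole process is
# repeated on the refined cohort, three times by default, with a fresh
# random split each iteration.

#' Curation configuration
#'
#' @param dsc_threshold named numeric vector of per-structure thresholds;
#'   the `.default` entry covers unnamed structures. Defaults: rectum 0.7,
#'   everything else 0.8.
#' @param n_iterations number of flag-review-refine passes (default 3).
#' @param split_seed seed for the half splits; iteration `k` uses a seed
#'   derived from `split_seed + k` so each pass re-splits afresh.
#' @param reviewer verdict function `(scan_id, structure, record) ->
#'   "keep" | "remove"`, called only for flagged records. Defaults to
#'   [reviewer_keep_all()].
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(dsc_threshold = c(rectum = 0.7, .default = 0.8),
                            n_iterations = 3L, split_seed = 1L,
                            reviewer = NULL) {
  stopifnot(all(dsc_threshold > 0), all(dsc_threshold < 1), n_iterations >= 1)
  structure(list(dsc_threshold = dsc_threshold,
                 n_iterations = as.integer(n_iterations),
                 split_seed = as.integer(split_seed),
                 reviewer = reviewer %||% reviewer_keep_all()),
            class = "curation_config")
}

threshold_for <- function(cfg, structure) {
  if (structure %in% names(cfg$dsc_threshold)) cfg$dsc_threshold[[structure]]
  else if (".default" %in% names(cfg$dsc_threshold)) cfg$dsc_threshold[[".default"]]
  else 0.8
}

#' Reviewer that keeps every flagged contour
#' @return A verdict function.
#' @export
reviewer_keep_all <- function() function(scan_id, structure, record) "keep"

#' Reviewer that removes every flagged contour
#' @return A verdict function.
#' @export
reviewer_remove_flagged <- function() function(scan_id, structure, record) "remove"

#' Oracle reviewer for simulation studies
#'
#' Removes a flagged contour iff its `scan/structure` id is in the known
#' corrupted set (available only in simulations, where the corruption
#' ground truth is known).
#'
#' @param corrupted_ids character vector of `"scan_id/structure"` ids.
#' @return A verdict function.
#' @export
reviewer_oracle <- function(corrupted_ids) {
  force(corrupted_ids)
  function(scan_id, structure, record) {
    if (paste0(scan_id, "/", structure) %in% corrupted_ids) "remove" else "keep"
  }
}

#' Split scan ids into two halves
#'
#' Disjoint, exhaustive, sizes differing by at most one; deterministic under
#' `seed`.
#'
#' @param ids character vector of scan ids (>= 4).
#' @param seed RNG seed.
#' @return List with components `A` and `B`.
#' @export
split_halves <- function(ids, seed = 1L) {
  if (length(ids) < 4) stop("split_halves: need at least 4 scans")
  set.seed(seed)
  perm <- sample(ids)
  nA <- ceiling(length(ids) / 2)
  list(A = sort(perm[seq_len(nA)]), B = sort(perm[-seq_len(nA)]))
}

#' Train-on-one-half, flag-on-the-other cross-prediction pass
#'
#' Trains one model per half via `train_fn`, predicts the opposite half, and
#' computes the DSC between each scan's (possibly corrupted) label and the
#' cross prediction. Records are flagged exactly when the cross DSC falls
#' below the structure's threshold.
#'
#' @param cohort list of scans with `id`, `volume`, `structures`.
#' @param structure structure name.
#' @param cfg a [curation_config()].
#' @param train_fn training contract: `train_fn(cohort_half, structure)`
#'   returns a predictor `function(scan) -> binary mask`.
#' @param iteration iteration number recorded in the output.
#' @param seed split seed override (defaults to `cfg$split_seed`).
#' @return A data.frame of curation records (scan_id, structure, iteration,
#'   cross_dsc, flagged, verdict), verdict `"not_reviewed"` throughout.
#' @export
cross_train_flag <- function(cohort, structure, cfg, train_fn,
                             iteration = 1L, seed = NULL) {
  has <- vapply(cohort, function(s)
    structure %in% names(s$structures$masks), logical(1))
  sub <- cohort[has]
  ids <- vapply(sub, `[[`, character(1), "id")
  halves <- split_halves(ids, seed %||% cfg$split_seed)
  in_A <- ids %in% halves$A
  if (!any(in_A) || !any(!in_A))
    stop(sprintf("cross_train_flag: structure '%s' not present in both halves", structure))
  model_A <- tryCatch(train_fn(sub[in_A], structure),
                      error = function(e) stop(sprintf(
                        "cross_train_flag: training failed on half A: %s",
                        conditionMessage(e))))
  model_B <- tryCatch(train_fn(sub[!in_A], structure),
                      error = function(e) stop(sprintf(
                        "cross_train_flag: training failed on half B: %s",
                        conditionMessage(e))))
  thr <- threshold_for(cfg, structure)
  rows <- lapply(seq_along(sub), function(i) {
    model <- if (in_A[i]) model_B else model_A
    pred <- model(sub[[i]])
    d <- dice(sub[[i]]$structures$masks[[structure]], pred)
    data.frame(scan_id = ids[i], structure = structure,
               iteration = as.integer(iteration), cross_dsc = d,
               flagged = d < thr, verdict = "not_reviewed",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full semi-automatic curation loop
#'
#' Per iteration: cross-train and flag, review flagged records with
#' `cfg$reviewer`, remove contours judged incorrect (only that structure's
#' label is deleted, the scan itself stays), then repeat on the refined
#' cohort with a fresh split. Stops early with a warning if fewer than 4
#' usable scans remain for a structure.
#'
#' @param cohort list of scans.
#' @param structures structure names to curate.
#' @param cfg a [curation_config()].
#' @param train_fn training contract as in [cross_train_flag()].
#' @return List with `cohort` (refined) and `ledger` (every record of every
#'   iteration, with final verdicts).
#' @export
curation_loop <- function(cohort, structures, cfg, train_fn) {
  ledger <- list()
  for (iter in seq_len(cfg$n_iterations)) {
    for (structure in structures) {
      usable <- vapply(cohort, function(s)
        structure %in% names(s$structures$masks), logical(1))
      if (sum(usable) < 4) {
        warning(sprintf(
          "curation_loop: fewer than 4 scans with '%s' at iteration %d; stopping early",
          structure, iter))
        return(list(cohort = cohort, ledger = do.call(rbind, ledger)))
      }
      recs <- cross_train_flag(cohort, structure, cfg, train_fn,
                               iteration = iter,
                               seed = derive_seed(cfg$split_seed + iter, iter))
      for (j in seq_len(nrow(recs))) {
        if (!recs$flagged[j]) next
        verdict <- cfg$reviewer(recs$scan_id[j], structure, recs[j, ])
        recs$verdict[j] <- verdict
        if (identical(verdict, "remove")) {
          k <- which(vapply(cohort, `[[`, character(1), "id") == recs$scan_id[j])
          cohort[[k]]$structures$masks[[structure]] <- NULL
          cohort[[k]]$structures$provenance <-
            cohort[[k]]$structures$provenance[
              names(cohort[[k]]$structures$provenance) != structure]
        }
      }
      ledger[[length(ledger) + 1]] <- recs
    }
  }
  list(cohort = cohort, ledger = do.call(rbind, ledger))
}

#' Default cross-training contract backed by the package segmenter
#'
#' Trains a full-grid 3D voxel segmenter on the half-cohort's labels and
#' predicts whole volumes; used when no external trainer is supplied.
#'
#' Flagging with this trainer is sensitivity-oriented: a grossly wrong label
#' reliably lands below the threshold, but a corrupted label inside a
#' training half also degrades that half's low-capacity model, so clean
#' scans predicted by it can be flagged too. The review step (human or
#' oracle) supplies the specificity; the iterative loop then runs on the
#' cleaned cohort.
#'
#' @param opt an [adam_config()].
#' @param n_samples training voxels sampled per scan.
#' @return A `train_fn` suitable for [cross_train_flag()].
#' @export
default_curation_trainer <- function(opt = adam_config(epochs = 400), n_samples = 6000L) {
  function(cohort_half, structure) {
    model <- train_segmenter(cohort_half, structure, mode = "volume_3d",
                             opt = opt, aug = no_augment(), region = "full",
                             n_samples = n_samples)
    function(scan) {
      grid <- dim(scan$volume$data)
      ext <- extent_interval(1, grid[1], grid[1])
      coarse_segment(model, scan$volume, ext)$mask
    }
  }
}

#' Oracle training contract for simulation studies
#'
#' Returns the pristine ground-truth mask for every scan, looked up in an
#' uncorrupted reference cohort. Used to isolate the flagging logic from
#' segmenter quality in tests.
#'
#' @param truth_cohort cohort holding the clean labels.
#' @return A `train_fn`.
#' @export
oracle_trainer <- function(truth_cohort) {
  truth <- stats::setNames(truth_cohort,
                           vapply(truth_cohort, `[[`, character(1), "id"))
  function(cohort_half, structure) {
    function(scan) truth[[scan$id]]$structures$masks[[structure]]
  }
}
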