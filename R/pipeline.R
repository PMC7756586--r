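# Configuration-driven orchestration: phantom generation, per-structure
# training, cascade inference, curation and evaluation. The default registry
# reproduces the system's routing: bony structures share a 3D multi-label
# model; spinal cord and the para-aortic (PAN) volume use 2D models; the
# remaining organs use 3D models with coarse-to-fine refinement; the nodal
# volume additionally fuses 2D and 3D predictions and is truncated one slice
# below the aortic bifurcation, which is detected from a vessel segmentation
# run inside a crop anchored on L4. Execution order makes the dependency
# chain L4 -> vessel -> nodal/PAN explicit.

#' Default pipeline configuration
#'
#' @param grid_shape phantom grid `(nz, ny, nx)`.
#' @param seed global seed.
#' @param epochs training epochs for every model (scaled-down default).
#' @return A nested configuration list (serialisable to JSON).
#' @export
default_pipeline_config <- function(grid_shape = c(64, 96, 96), seed = 1L,
                                    epochs = 150L) {
  list(
    seed = as.integer(seed),
    phantom = list(grid_shape = as.integer(grid_shape),
                   spacing = c(2.5, 1.17, 1.17),
                   noise_sigma = 20, contrast_scale = 1),
    preprocess = list(hu_low = -1000, hu_high = 3000, shift = 1000,
                      target_spacing = c(2.5, 1.17, 1.17)),
    optimizer = list(lr = 0.1, epochs = as.integer(epochs),
                     beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8),
    augment = list(hflip = TRUE, rotation_range = c(-30, 30), n_rotations = 1),
    classifier = list(lr = 0.3, epochs = max(400L, 2L * as.integer(epochs)),
                      threshold = 0.5, max_gap = 2, pad = 1),
    curation = list(dsc_threshold = list(rectum = 0.7, .default = 0.8),
                    n_iterations = 3, split_seed = 1),
    registry = list(
      l4l5    = list(targets = c("l4", "l5"), mode = "volume_3d",
                     multilabel = TRUE, refine = FALSE, fusion = FALSE,
                     max_gap = 4),
      bone    = list(targets = "bone", mode = "volume_3d",
                     refine = FALSE, fusion = FALSE),
      cord    = list(targets = "cord", mode = "slice_2d",
                     refine = FALSE, fusion = FALSE),
      pan     = list(targets = "pan", mode = "slice_2d",
                     refine = FALSE, fusion = FALSE, border = "pan_inferior"),
      bladder = list(targets = "bladder", mode = "volume_3d",
                     refine = TRUE, fusion = FALSE),
      rectum  = list(targets = "rectum", mode = "volume_3d",
                     refine = TRUE, fusion = FALSE),
      kidney_l = list(targets = "kidney_l", mode = "volume_3d",
                      refine = TRUE, fusion = FALSE, hflip = FALSE),
      kidney_r = list(targets = "kidney_r", mode = "volume_3d",
                      refine = TRUE, fusion = FALSE, hflip = FALSE),
      vessel  = list(targets = "vessel", mode = "volume_3d",
                     refine = FALSE, fusion = FALSE, anchor = "l4"),
      nodal   = list(targets = "nodal", mode = "volume_3d",
                     refine = TRUE, fusion = TRUE, border = "nodal_superior")
    )
  )
}

#' Write / read a pipeline configuration (JSON)
#' @param config configuration list.
#' @param path file path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg
}

config_opt <- function(config) {
  o <- config$optimizer
  adam_config(lr = o$lr, epochs = o$epochs, beta1 = o$beta1, beta2 = o$beta2,
              epsilon = o$epsilon, seed = config$seed)
}

config_aug <- function(config) {
  a <- config$augment
  augment_spec(hflip = isTRUE(a$hflip), rotation_range = a$rotation_range,
               n_rotations = a$n_rotations %||% 1L)
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` scan folders (`volume.nii.gz`, `masks/*.nii.gz`,
#' `manifest.json`) plus a cohort manifest; optionally corrupts a fraction
#' of labels, recording the corrupted ids in a sidecar for test oracles.
#'
#' @param out_dir output directory.
#' @param n cohort size.
#' @param config pipeline configuration.
#' @param seed cohort seed (defaults to `config$seed`).
#' @param corrupt fraction of labels to corrupt covertly (0 disables).
#' @param corrupt_structures candidate structures for corruption.
#' @param force overwrite a non-empty output directory.
#' @return Invisibly, the list of scan directories.
#' @export
cmd_generate <- function(out_dir, n = 10, config = default_pipeline_config(),
                         seed = NULL, corrupt = 0,
                         corrupt_structures = NULL, force = FALSE) {
  seed <- seed %||% config$seed
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop(sprintf("cmd_generate: '%s' is not empty (use force = TRUE)", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec_args <- list(grid_shape = config$phantom$grid_shape,
                    spacing = config$phantom$spacing,
                    noise_sigma = config$phantom$noise_sigma,
                    contrast_scale = config$phantom$contrast_scale)
  if (!is.null(config$phantom$structures))
    spec_args$structures <- unlist(config$phantom$structures)
  spec <- do.call(phantom_spec, spec_args)
  cohort <- generate_cohort(spec, n = n, seed = seed)
  if (corrupt > 0) {
    cs <- corruption_spec(mode = "shift", magnitude = 5,
                          fraction_corrupted = corrupt,
                          seed = derive_seed(seed, 999L))
    cr <- corrupt_labels(cohort, cs, structures = corrupt_structures)
    cohort <- cr$cohort
    jsonlite::write_json(list(corrupted_ids = cr$corrupted_ids),
                         file.path(out_dir, "corruption.json"),
                         auto_unbox = FALSE, pretty = TRUE)
  }
  dirs <- character(0)
  for (ph in cohort) {
    d <- file.path(out_dir, ph$id)
    write_scan(d, ph$volume, ph$structures)
    dirs <- c(dirs, d)
  }
  jsonlite::write_json(list(scans = vapply(cohort, `[[`, character(1), "id"),
                            seed = seed, n = n),
                       file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dirs)
}

#' Load a cohort directory written by [cmd_generate()]
#' @param dir cohort directory.
#' @return List of scans (`id`, `volume`, `structures`).
#' @export
load_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  lapply(mf$scans, function(id) read_scan(file.path(dir, id)))
}

#' Train the models for one registry entry
#'
#' Trains the presence classifier plus the segmenters the registry routes
#' this entry to (multi-label / 2D / 3D, refine model, 2D fusion partner),
#' and stores checkpoints under `model_dir`.
#'
#' @param config pipeline configuration.
#' @param cohort training cohort (list of scans).
#' @param entry registry entry name (e.g. `"bladder"`, `"l4l5"`).
#' @param model_dir checkpoint directory.
#' @return Invisibly, the checkpoint path.
#' @export
cmd_train <- function(config, cohort, entry, model_dir) {
  reg <- config$registry[[entry]]
  if (is.null(reg)) stop(sprintf("cmd_train: no registry entry '%s'", entry))
  dir.create(model_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- config_opt(config)
  aug <- config_aug(config)
  # lateralised structures must not be flip-augmented: a mirror copy of the
  # left kidney is indistinguishable from the right one for a local model
  if (isFALSE(reg$hflip)) aug$hflip <- FALSE
  ccfg <- classifier_config(
    optimizer = adam_config(lr = config$classifier$lr,
                            epochs = config$classifier$epochs,
                            seed = config$seed),
    threshold = config$classifier$threshold,
    max_gap = config$classifier$max_gap, pad = config$classifier$pad)
  bundle <- list(entry = entry, registry = reg)
  grid <- dim(cohort[[1]]$volume$data)
  coarse_shape <- round(grid[2:3] / 2)
  if (isTRUE(reg$multilabel)) {
    bundle$segmenter <- train_segmenter(cohort, reg$targets, mode = reg$mode,
                                        opt = opt, aug = aug, region = "extent")
    bundle$classifier <- train_presence_classifier(cohort, reg$targets, ccfg)
  } else {
    target <- reg$targets
    bundle$classifier <- train_presence_classifier(cohort, target, ccfg)
    if (identical(reg$anchor, "l4")) {
      # vessel model trained inside the L4-anchored search region; the
      # bifurcation geometry is fine detail, so it gets a longer schedule
      crop <- vessel_search_region(cohort[[1]]$structures$masks$l4)
      opt_v <- adam_config(lr = opt$lr, epochs = 3L * opt$epochs,
                           beta1 = opt$beta1, beta2 = opt$beta2,
                           epsilon = opt$epsilon, seed = opt$seed)
      bundle$segmenter <- train_segmenter(cohort, target, mode = reg$mode,
                                          opt = opt_v, aug = no_augment(),
                                          region = "crop", crop = crop,
                                          anchor_structure = reg$anchor)
      bundle$crop <- crop
    } else if (reg$mode == "slice_2d") {
      bundle$segmenter <- train_segmenter(cohort, target, mode = "slice_2d",
                                          opt = opt, aug = aug, region = "extent")
    } else {
      bundle$segmenter <- train_segmenter(cohort, target, mode = "volume_3d",
                                          opt = opt, aug = aug,
                                          region = "extent",
                                          coarse_shape = coarse_shape)
    }
    if (isTRUE(reg$refine)) {
      crop <- derive_crop_spec(cohort, target)
      bundle$refiner <- train_segmenter(cohort, target, mode = "volume_3d",
                                        opt = opt, aug = aug,
                                        region = "crop", crop = crop)
      bundle$crop <- crop
    }
    if (isTRUE(reg$fusion)) {
      bundle$segmenter_2d <- train_segmenter(cohort, target, mode = "slice_2d",
                                             opt = opt, aug = aug,
                                             region = "extent")
    }
  }
  path <- file.path(model_dir, paste0(entry, ".rds"))
  saveRDS(bundle, path)
  invisible(path)
}

load_bundle <- function(model_dir, entry) {
  path <- file.path(model_dir, paste0(entry, ".rds"))
  if (!file.exists(path))
    stop(sprintf("cmd_predict: missing checkpoint for stage '%s'", entry))
  readRDS(path)
}

#' Run the full cascade on one scan
#'
#' Fig-4 order: per-structure extent classification gates every segmenter;
#' bony structures come first because the vessel search region is anchored
#' on L4; the vessel model then provides the bifurcation slice for the
#' nodal/PAN border rules; remaining structures run coarse (-> refine)
#' independently. Returns predicted masks plus an audit log of every extent,
#' crop and border decision.
#'
#' @param config pipeline configuration.
#' @param scan a scan (`id`, `volume`, `structures` optional).
#' @param entries registry entries to predict (default: all).
#' @param model_dir checkpoint directory.
#' @return List with `masks` (named list), `audit` (data.frame), and
#'   `bifurcation` (detected slice or NA).
#' @export
cmd_predict <- function(config, scan, entries = names(config$registry),
                        model_dir) {
  vol <- ensure_preprocessed(scan$volume)
  grid <- dim(vol$data)
  masks <- list()
  audit <- list()
  note <- function(stage, structure, key, value) {
    audit[[length(audit) + 1]] <<- data.frame(
      scan = scan$id, stage = stage, structure = structure,
      key = key, value = as.character(value))
  }
  needs_vessel <- any(vapply(config$registry[entries], function(r)
    !is.null(r$border), logical(1)))
  if (needs_vessel && !all(c("l4l5", "vessel") %in% entries))
    stop("cmd_predict: border rules requested without the l4l5/vessel stages they depend on")
  # dependency order: bony first, vessel second, bordered structures last
  pri <- function(e) {
    r <- config$registry[[e]]
    if (isTRUE(r$multilabel)) 1 else if (!is.null(r$anchor)) 2
    else if (!is.null(r$border)) 4 else 3
  }
  entries <- entries[order(vapply(entries, pri, numeric(1)))]
  b <- NA_integer_
  for (entry in entries) {
    reg <- config$registry[[entry]]
    bundle <- load_bundle(model_dir, entry)
    series <- predict_presence(bundle$classifier, vol)
    ext <- tryCatch(pad_extent(extent_postprocess(
      series, config$classifier$threshold,
      reg$max_gap %||% config$classifier$max_gap),
      config$classifier$pad),
      error = function(e) NULL)
    if (is.null(ext)) {
      for (t in reg$targets) masks[[t]] <- array(0L, dim = grid)
      note("classify", reg$targets[1], "extent", "empty")
      next
    }
    note("classify", reg$targets[1], "extent", sprintf("%d-%d", ext$lo, ext$hi))
    if (isTRUE(reg$multilabel)) {
      ml <- predict_multilabel(bundle$segmenter, vol, ext)
      for (t in names(ml)) masks[[t]] <- ml[[t]]
    } else if (!is.null(reg$anchor)) {
      if (is.null(masks[[reg$anchor]]) || sum(masks[[reg$anchor]]) == 0)
        stop(sprintf("cmd_predict: stage '%s' requires a non-empty '%s' prediction",
                     entry, reg$anchor))
      crop <- vessel_search_region(masks[[reg$anchor]])
      reg_rng <- crop_ranges(crop$center, crop$box_shape, grid)
      note("crop", reg$targets, "center", paste(crop$center, collapse = ","))
      sm <- box_smooth(vol$data, "3d")
      prob <- predict_prob_region(bundle$segmenter, vol$data, sm, reg_rng)[[1]]
      m <- array(0L, dim = grid)
      m[reg_rng$z, reg_rng$y, reg_rng$x] <- as.integer(prob >= 0.5)
      # opening strips thin false-positive shells (e.g. nodal sheath edges)
      # that would fake extra in-plane components; small blobs go next
      if (sum(m) > 0) m <- binary_open(m, 1)
      if (sum(m) > 0) m <- drop_small_components(m)
      masks[[reg$targets]] <- m
      b <- tryCatch(detect_bifurcation_slice(m), error = function(e) NA_integer_)
      note("bifurcation", reg$targets, "slice", b)
    } else {
      pred <- coarse_segment(bundle$segmenter, vol, ext)
      if (isTRUE(reg$refine) && sum(pred$mask) > 0) {
        pred <- refine_segment(pred, vol, bundle$refiner, bundle$crop)
        note("refine", reg$targets, "stage", pred$stage)
      }
      if (isTRUE(reg$fusion)) {
        p2 <- coarse_segment(bundle$segmenter_2d, vol, ext)
        pred <- fuse_2d3d(p2, pred)
        note("fusion", reg$targets, "stage", pred$stage)
      }
      m <- pred$mask
      if (!is.null(reg$border) && !is.na(b)) {
        res <- if (reg$border == "nodal_superior")
          apply_nodal_superior_border(m, b) else apply_pan_inferior_border(m, b)
        m <- res$mask
        note("border", reg$targets, reg$border,
             sprintf("b=%d removed=%d", b, res$result$voxels_removed))
      }
      masks[[reg$targets]] <- m
    }
  }
  list(masks = masks, audit = do.call(rbind, audit), bifurcation = b)
}

#' Curate a cohort's labels
#'
#' Non-destructive wrapper around [curation_loop()]: returns the refined
#' cohort and writes nothing back to disk.
#'
#' @param config pipeline configuration.
#' @param cohort list of scans.
#' @param structures structures to curate.
#' @param train_fn training contract; defaults to the package segmenter.
#' @param reviewer verdict function; defaults to keep-all.
#' @return As [curation_loop()].
#' @export
cmd_curate <- function(config, cohort, structures,
                       train_fn = default_curation_trainer(),
                       reviewer = NULL) {
  cc <- config$curation
  thr <- unlist(cc$dsc_threshold)
  cfg <- curation_config(dsc_threshold = thr, n_iterations = cc$n_iterations,
                         split_seed = cc$split_seed, reviewer = reviewer)
  curation_loop(cohort, structures, cfg, train_fn)
}

#' Evaluate predictions against references and write CSVs
#'
#' @param config pipeline configuration.
#' @param predictions,references named lists: scan id -> named mask lists.
#' @param out_dir optional directory for `metrics.csv` / `summary.csv`.
#' @return As [evaluate_cohort()].
#' @export
cmd_evaluate <- function(config, predictions, references, out_dir = NULL) {
  res <- evaluate_cohort(predictions, references,
                         spacing = config$preprocess$target_spacing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$per_scan, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  res
}
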