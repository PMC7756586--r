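#' CT volume container
#'
#' A `ct_volume` carries a 3D scalar array ordered (slice/z, row/y, col/x)
#' together with voxel spacing and origin in millimetres. The z axis increases
#' toward the head; every superior/inferior rule in the package refers to the
#' z index. `intensity_kind` distinguishes raw Hounsfield units from the
#' clipped-and-shifted representation used by the models.
#'
#' @param data 3D numeric array, (z, y, x).
#' @param spacing numeric triple `(dz, dy, dx)` in mm, strictly positive.
#' @param origin numeric triple `(z, y, x)` in mm.
#' @param intensity_kind `"raw_hu"` or `"preprocessed"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0),
                      intensity_kind = c("raw_hu", "preprocessed")) {
  intensity_kind <- match.arg(intensity_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("ct_volume: `data` must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be three strictly positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("ct_volume: origin must have length 3")
  if (intensity_kind == "preprocessed" &&
      (min(data) < 0 || max(data) > 4000))
    stop("ct_volume: preprocessed intensities must lie in [0, 4000]")
  structure(list(data = data, spacing = spacing, origin = origin,
                 intensity_kind = intensity_kind),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s, spacing %.3g x %.3g x %.3g mm, %s>\n",
              paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3], x$intensity_kind))
  invisible(x)
}

#' Named binary masks aligned to one volume
#'
#' @param volume_id scan identifier the masks belong to.
#' @param masks named list of binary 3D arrays, all congruent with the volume.
#' @param provenance named character vector (`ground_truth`, `predicted`,
#'   `curated`); defaults to `ground_truth` for every structure.
#' @param grid_shape optional expected array dimension used for validation.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(volume_id, masks, provenance = NULL, grid_shape = NULL) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("structure_set: masks must be a named list")
  shp <- grid_shape %||% dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), as.integer(shp)) && !identical(dim(m), shp))
      stop(sprintf("structure_set: mask '%s' shape differs from the volume grid", nm))
    if (!all(m %in% c(0, 1)))
      stop(sprintf("structure_set: mask '%s' is not strictly binary", nm))
  }
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("ground_truth", length(masks)), names(masks))
  }
  stopifnot(all(provenance %in% c("ground_truth", "predicted", "curated")))
  structure(list(volume_id = volume_id, masks = masks,
                 provenance = provenance),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set '%s': %s>\n", x$volume_id,
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Intensity and grid preprocessing parameters
#'
#' Defaults encode the working grid and HU window used throughout: resample to
#' 2.5 x 1.17 x 1.17 mm voxels, clip HU to \[-1000, 3000\] and shift by +1000
#' so intensities land in \[0, 4000\].
#'
#' @param hu_low,hu_high clip bounds in HU.
#' @param shift additive shift applied after clipping; must satisfy
#'   `hu_low + shift == 0` so the output range starts at zero.
#' @param target_spacing working-grid voxel size `(dz, dy, dx)` in mm.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(hu_low = -1000, hu_high = 3000, shift = 1000,
                            target_spacing = c(2.5, 1.17, 1.17)) {
  if (hu_high <= hu_low) stop("preprocess_spec: hu_high must exceed hu_low")
  if (abs(hu_low + shift) > 1e-9)
    stop("preprocess_spec: hu_low + shift must equal 0")
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("preprocess_spec: target_spacing must be three positive numbers")
  structure(list(hu_low = hu_low, hu_high = hu_high, shift = shift,
                 target_spacing = target_spacing),
            class = "preprocess_spec")
}

#' Clip and shift CT intensities
#'
#' Clamps raw HU to `[hu_low, hu_high]` and adds `shift`, producing the
#' non-negative intensity range the models are trained on (0-4000 with the
#' defaults). Refuses volumes that were already preprocessed so the shift is
#' never applied twice.
#'
#' @param vol a `ct_volume` with `intensity_kind == "raw_hu"`.
#' @param spec a [preprocess_spec()].
#' @return A `ct_volume` with `intensity_kind == "preprocessed"`.
#' @export
clip_shift_intensity <- function(vol, spec = preprocess_spec()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(spec, "preprocess_spec"))
  if (vol$intensity_kind != "raw_hu")
    stop("clip_shift_intensity: volume is already preprocessed")
  out <- clamp(vol$data, spec$hu_low, spec$hu_high) + spec$shift
  ct_volume(out, vol$spacing, vol$origin, intensity_kind = "preprocessed")
}

ensure_preprocessed <- function(vol, spec = preprocess_spec()) {
  if (vol$intensity_kind == "preprocessed") vol else clip_shift_intensity(vol, spec)
}

# trilinear (or nearest) sampling of `a` at fractional (z,y,x) index triples
sample_at <- function(a, iz, iy, ix, interp) {
  dm <- dim(a)
  iz <- clamp(iz, 1, dm[1]); iy <- clamp(iy, 1, dm[2]); ix <- clamp(ix, 1, dm[3])
  if (interp == "nearest") {
    return(a[cbind(round(iz), round(iy), round(ix))])
  }
  z0 <- clamp(floor(iz), 1, dm[1]); z1 <- clamp(z0 + 1, 1, dm[1]); fz <- iz - z0
  y0 <- clamp(floor(iy), 1, dm[2]); y1 <- clamp(y0 + 1, 1, dm[2]); fy <- iy - y0
  x0 <- clamp(floor(ix), 1, dm[3]); x1 <- clamp(x0 + 1, 1, dm[3]); fx <- ix - x0
  a[cbind(z0, y0, x0)] * (1 - fz) * (1 - fy) * (1 - fx) +
    a[cbind(z1, y0, x0)] * fz * (1 - fy) * (1 - fx) +
    a[cbind(z0, y1, x0)] * (1 - fz) * fy * (1 - fx) +
    a[cbind(z0, y0, x1)] * (1 - fz) * (1 - fy) * fx +
    a[cbind(z1, y1, x0)] * fz * fy * (1 - fx) +
    a[cbind(z1, y0, x1)] * fz * (1 - fy) * fx +
    a[cbind(z0, y1, x1)] * (1 - fz) * fy * fx +
    a[cbind(z1, y1, x1)] * fz * fy * fx
}

#' Resample a volume to the working grid
#'
#' Maps voxel centres of the output grid into the input grid through physical
#' coordinates and interpolates. Images should use `interp = "linear"`, binary
#' masks `interp = "nearest"` (the caller states which); nearest-neighbour
#' sampling preserves mask binarity.
#'
#' @param vol a `ct_volume`.
#' @param spec a [preprocess_spec()] supplying `target_spacing`, or a numeric
#'   spacing triple.
#' @param interp `"linear"` or `"nearest"`.
#' @return A `ct_volume` on the target grid with the physical extent preserved
#'   to within one voxel.
#' @export
resample_to_grid <- function(vol, spec = preprocess_spec(),
                             interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(vol, "ct_volume"))
  target <- if (inherits(spec, "preprocess_spec")) spec$target_spacing else as.numeric(spec)
  dm <- dim(vol$data)
  if (dm[1] < 2L)
    stop("resample_to_grid: degenerate single-slice volume")
  n_out <- pmax(1L, as.integer(round(dm * vol$spacing / target)))
  if (all(n_out == dm) && all(abs(vol$spacing - target) < 1e-5 * target)) {
    out <- vol$data
  } else {
    # physical coordinate of output voxel i along axis k:
    #   origin_k + (i-1) * target_k  ->  input index (phys - origin)/spacing + 1
    gi <- lapply(1:3, function(k) ((seq_len(n_out[k]) - 1) * target[k]) / vol$spacing[k] + 1)
    IZ <- rep(gi[[1]], times = n_out[2] * n_out[3])
    IY <- rep(rep(gi[[2]], each = n_out[1]), times = n_out[3])
    IX <- rep(gi[[3]], each = n_out[1] * n_out[2])
    out <- array(sample_at(vol$data, IZ, IY, IX, interp), dim = n_out)
  }
  ct_volume(out, target, vol$origin, intensity_kind = vol$intensity_kind)
}

#' Resample a binary mask with nearest-neighbour interpolation
#'
#' @param mask binary 3D array on the source grid.
#' @param spacing source spacing `(dz, dy, dx)` in mm.
#' @param spec target grid description as in [resample_to_grid()].
#' @return Binary array on the target grid.
#' @export
resample_mask <- function(mask, spacing, spec = preprocess_spec()) {
  v <- ct_volume(mask, spacing, intensity_kind = "raw_hu")
  out <- resample_to_grid(v, spec, interp = "nearest")
  array(as.integer(out$data != 0), dim = dim(out$data))
}
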