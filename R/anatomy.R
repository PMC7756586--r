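# Anatomical border logic. The nodal target volume's superior border sits
# one slice below the bifurcation of the common iliac artery; the
# para-aortic (PAN) target volume reaches from the renal-vein level down to
# one slice above the nodal superior border. The bifurcation is read off a
# vessel mask by axial connected-component counting: a single aorta above
# the bifurcation slice, two iliac branches below it. The vessel segmenter
# runs inside a crop anchored on the L4 vertebral body.

#' Border rule audit record
#'
#' @param structure structure the rule was applied to.
#' @param rule `"nodal_superior"` or `"pan_inferior"`.
#' @param anchor_slice the bifurcation slice the rule was anchored on.
#' @param applied whether any voxel was removed.
#' @param voxels_removed count of removed voxels.
#' @return An object of class `border_rule_result`.
#' @export
border_rule_result <- function(structure, rule, anchor_slice, applied,
                               voxels_removed = 0L) {
  structure(list(structure = structure, rule = rule,
                 anchor_slice = as.integer(anchor_slice),
                 applied = applied, voxels_removed = as.integer(voxels_removed)),
            class = "border_rule_result")
}

#' Crop region around the L4 vertebral body for the vessel segmenter
#'
#' The crop is centred on the L4 centroid with a box equal to the L4
#' bounding box dilated by `margin` voxels on each side (default 8 slices
#' axially, 12 voxels in-plane).
#'
#' @param l4_mask binary L4 mask, non-empty.
#' @param margin voxel triple `(z, y, x)` of one-sided margins.
#' @return A [crop_spec()] with `center` set to the L4 centroid.
#' @export
vessel_search_region <- function(l4_mask, margin = c(8, 12, 12)) {
  if (sum(l4_mask) == 0)
    stop("vessel_search_region: empty L4 mask")
  bb <- mask_bbox(l4_mask)
  box <- (bb["hi", ] - bb["lo", ] + 1) + 2 * margin
  crop_spec(pmin(box, dim(l4_mask)), center = center_of_mass(l4_mask))
}

#' Detect the aortic bifurcation slice from a vessel mask
#'
#' Returns the smallest slice index `b` such that every occupied slice at or
#' above `b` has exactly one in-plane connected component and slice `b - 1`
#' has at least two (single aorta superiorly, iliac branches inferiorly).
#' In-plane components smaller than `min_size` voxels are discarded first so
#' isolated prediction specks cannot fake a branch.
#'
#' @param vessel_mask binary 3D array with at least 3 occupied slices.
#' @param min_size speck filter, voxels (default 3).
#' @return The bifurcation slice index (1-based).
#' @export
detect_bifurcation_slice <- function(vessel_mask, min_size = 3) {
  if (sum(vessel_mask) == 0)
    stop("detect_bifurcation_slice: empty vessel mask")
  if (length(which(slice_any(vessel_mask))) < 3)
    stop("detect_bifurcation_slice: vessel occupies fewer than 3 slices")
  counts <- count_slice_components(vessel_mask, min_size = min_size)
  # occupancy after the speck filter: slices holding nothing but specks do
  # not count as vessel
  occ <- which(counts >= 1)
  if (length(occ) < 3)
    stop("detect_bifurcation_slice: vessel occupies fewer than 3 slices")
  cts <- counts[occ]
  if (mean(cts >= 3) > 0.5)
    stop("detect_bifurcation_slice: fragmented vessel mask (>= 3 components on most slices)")
  if (all(cts <= 1))
    stop("detect_bifurcation_slice: vessel never splits (no bifurcation)")
  # smallest b with all occupied z >= b single-component and >= 2 at b - 1
  multi <- occ[cts >= 2]
  b <- max(multi) + 1L
  above <- occ[occ >= b]
  if (!length(above) || any(counts[above] != 1))
    stop("detect_bifurcation_slice: no single-trunk region above the split")
  b
}

#' Truncate a nodal mask at the bifurcation-derived superior border
#'
#' Removes all nodal voxels on slices at or above the bifurcation slice `b`,
#' so the superior-most allowed slice is `b - 1` (one slice below the
#' bifurcation).
#'
#' @param nodal_mask binary 3D array.
#' @param b bifurcation slice index.
#' @return List with the truncated `mask` and a [border_rule_result()].
#' @export
apply_nodal_superior_border <- function(nodal_mask, b) {
  dm <- dim(nodal_mask)
  b <- as.integer(b)
  if (b <= 1L || b > dm[1])
    stop("apply_nodal_superior_border: degenerate border (b must be in 2..n_slices)")
  out <- nodal_mask
  removed <- sum(out[b:dm[1], , ])
  out[b:dm[1], , ] <- 0L
  list(mask = out,
       result = border_rule_result("nodal", "nodal_superior", b,
                                   applied = removed > 0, voxels_removed = removed))
}

#' Truncate a PAN mask at its bifurcation-derived inferior border
#'
#' Removes all PAN voxels on slices below `b`; the inferior-most allowed
#' slice is `b`, i.e. one slice above the nodal superior border `b - 1`, so
#' nodal and PAN end up axially adjacent and disjoint.
#'
#' @param pan_mask binary 3D array.
#' @param b bifurcation slice index.
#' @return List with the truncated `mask` and a [border_rule_result()].
#' @export
apply_pan_inferior_border <- function(pan_mask, b) {
  dm <- dim(pan_mask)
  b <- as.integer(b)
  if (b <= 1L || b > dm[1])
    stop("apply_pan_inferior_border: degenerate border (b must be in 2..n_slices)")
  out <- pan_mask
  removed <- sum(out[1:(b - 1), , ])
  out[1:(b - 1), , ] <- 0L
  list(mask = out,
       result = border_rule_result("pan", "pan_inferior", b,
                                   applied = removed > 0, voxels_removed = removed))
}
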