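# Synthetic pelvic phantoms. Geometry is parameterised as fractions of the
# grid so the same anatomy scales from the default 64 x 96 x 96 grid down to
# the 48 x 64 x 64 grids used in the fast test runs. The layout emulates a
# female pelvic CT: an anterior ellipsoidal bladder, a gently bent rectal
# tube and a thin spinal cord posteriorly, two kidneys superiorly-laterally,
# a pelvic bone ring plus L4/L5 vertebral blocks, and a Y-shaped vessel
# (aorta splitting into the common iliac branches) whose bifurcation slice is
# known exactly. Thin nodal / para-aortic sheaths wrap the vessel so the
# border rules can be exercised end to end. All masks are exact and pairwise
# disjoint.

#' Phantom specification
#'
#' Builds the per-structure geometry (in voxel units) for a pelvic phantom.
#' Structure intensities are plausible CT means: background -50 HU, soft
#' organs 30-110 HU, vessel 150 HU, bone 700 HU; additive Gaussian noise has
#' `noise_sigma = 20` HU by default. `contrast_scale` multiplies every
#' organ-minus-background difference to emulate low-contrast scans.
#'
#' @param grid_shape voxel triple `(nz, ny, nx)`.
#' @param spacing mm triple `(dz, dy, dx)`.
#' @param structures which structures to include.
#' @param bifurcation_frac axial position of the vessel bifurcation as a
#'   fraction of `nz`.
#' @param noise_sigma Gaussian image noise, HU.
#' @param contrast_scale multiplier in `(0, 1]` for organ contrast.
#' @param seed integer RNG seed; identical `(spec, seed)` pairs reproduce
#'   identical phantoms voxelwise.
#' @return An object of class `phantom_spec` with `organ_params` in voxels.
#' @export
phantom_spec <- function(grid_shape = c(64, 96, 96),
                         spacing = c(2.5, 1.17, 1.17),
                         structures = c("bladder", "rectum", "cord",
                                        "kidney_l", "kidney_r", "bone",
                                        "l4", "l5", "vessel", "nodal", "pan"),
                         bifurcation_frac = 0.55,
                         noise_sigma = 20,
                         contrast_scale = 1,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            contrast_scale > 0, contrast_scale <= 1, noise_sigma >= 0)
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  f <- function(frac, n) frac * n
  b <- round(bifurcation_frac * nz)
  organ_params <- list(
    bladder  = list(kind = "ellipsoid",
                    center = c(f(.26, nz), f(.25, ny), f(.50, nx)),
                    radii  = c(f(.09, nz), f(.08, ny), f(.13, nx))),
    rectum   = list(kind = "bent_tube",
                    z_range = c(f(.08, nz), f(.42, nz)),
                    center_yx = c(f(.68, ny), f(.50, nx)),
                    bend_amp = f(.03, ny), radius = f(.055, ny)),
    cord     = list(kind = "cylinder",
                    z_range = c(f(.40, nz), nz),
                    center_yx = c(f(.84, ny), f(.50, nx)),
                    radius = max(1.6, f(.025, ny))),
    kidney_l = list(kind = "ellipsoid",
                    center = c(f(.82, nz), f(.55, ny), f(.28, nx)),
                    radii  = c(f(.09, nz), f(.09, ny), f(.08, nx))),
    kidney_r = list(kind = "ellipsoid",
                    center = c(f(.82, nz), f(.55, ny), f(.72, nx)),
                    radii  = c(f(.09, nz), f(.09, ny), f(.08, nx))),
    bone     = list(kind = "ring",
                    z_range = c(f(.05, nz), f(.40, nz)),
                    center_yx = c(f(.52, ny), f(.50, nx)),
                    r_outer = .46 * min(ny, nx), r_inner = .40 * min(ny, nx)),
    l5       = list(kind = "block",
                    z_range = c(f(.44, nz), f(.56, nz)),
                    y_range = c(f(.64, ny), f(.76, ny)),
                    x_range = c(f(.42, nx), f(.58, nx))),
    l4       = list(kind = "block",
                    z_range = c(f(.585, nz), f(.69, nz)),
                    y_range = c(f(.64, ny), f(.76, ny)),
                    x_range = c(f(.42, nx), f(.58, nx))),
    vessel   = list(kind = "y_tube",
                    z_range = c(f(.46, nz), f(.80, nz)),
                    bifurcation = b,
                    center_yx = c(f(.56, ny), f(.50, nx)),
                    radius = max(2.5, f(.045, ny)),
                    branch_slope = 1),
    nodal    = list(kind = "vessel_sheath", region = "inferior",
                    thickness = 2),
    pan      = list(kind = "vessel_sheath", region = "superior",
                    thickness = 2, z_top = f(.85, nz))
  )
  organ_params <- organ_params[intersect(names(organ_params), structures)]
  intensity_map <- c(background = -50, bladder = 30, rectum = 60, cord = 80,
                     kidney_l = 45, kidney_r = 45, bone = 700, l4 = 700,
                     l5 = 700, vessel = 150, nodal = 90, pan = 100)
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 organ_params = organ_params, intensity_map = intensity_map,
                 noise_sigma = noise_sigma, contrast_scale = contrast_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# rasterise one structure of a phantom_spec to a binary mask
rasterize_structure <- function(spec, name, vessel_mask = NULL) {
  p <- spec$organ_params[[name]]
  dm <- spec$grid_shape
  co <- coord_arrays(dm)
  m <- switch(p$kind,
    ellipsoid = {
      d2 <- ((co$z - p$center[1]) / p$radii[1])^2 +
        ((co$y - p$center[2]) / p$radii[2])^2 +
        ((co$x - p$center[3]) / p$radii[3])^2
      d2 <= 1
    },
    cylinder = {
      inz <- co$z >= p$z_range[1] & co$z <= p$z_range[2]
      d2 <- (co$y - p$center_yx[1])^2 + (co$x - p$center_yx[2])^2
      inz & d2 <= p$radius^2
    },
    bent_tube = {
      z0 <- p$z_range[1]; z1 <- p$z_range[2]
      cy_vec <- p$center_yx[1] +
        p$bend_amp * sin(2 * pi * (seq_len(dm[1]) - z0) / max(1, z1 - z0))
      CY <- array(cy_vec[co$z], dim = dm)
      inz <- co$z >= z0 & co$z <= z1
      inz & ((co$y - CY)^2 + (co$x - p$center_yx[2])^2 <= p$radius^2)
    },
    ring = {
      inz <- co$z >= p$z_range[1] & co$z <= p$z_range[2]
      d2 <- (co$y - p$center_yx[1])^2 + (co$x - p$center_yx[2])^2
      inz & d2 <= p$r_outer^2 & d2 >= p$r_inner^2
    },
    block = {
      co$z >= p$z_range[1] & co$z <= p$z_range[2] &
        co$y >= p$y_range[1] & co$y <= p$y_range[2] &
        co$x >= p$x_range[1] & co$x <= p$x_range[2]
    },
    y_tube = {
      b <- p$bifurcation
      z0 <- ceiling(p$z_range[1]); z1 <- floor(p$z_range[2])
      if (b <= z0 || b >= z1)
        stop("phantom_spec: bifurcation slice must lie strictly inside the vessel extent")
      r <- p$radius
      # single aorta for z >= b, two iliac branches for z < b. At slice b-1
      # the branch centres sit r+1 from the midline (a 2-voxel gap between
      # the circles, so the slice has two in-plane components) while each
      # branch footprint still overlaps the aorta's, keeping the tree
      # 6-connected; the offset then grows inferiorly.
      off_vec <- numeric(dm[1])
      below <- seq_len(dm[1]) < b
      off_vec[below] <- r + 1 + p$branch_slope * (b - 1 - seq_len(dm[1])[below])
      OFF <- array(off_vec[co$z], dim = dm)
      inz <- co$z >= z0 & co$z <= z1
      dy2 <- (co$y - p$center_yx[1])^2
      single <- inz & co$z >= b & dy2 + (co$x - p$center_yx[2])^2 <= r^2
      left  <- inz & co$z < b & dy2 + (co$x - (p$center_yx[2] - OFF))^2 <= r^2
      right <- inz & co$z < b & dy2 + (co$x - (p$center_yx[2] + OFF))^2 <= r^2
      single | left | right
    },
    vessel_sheath = {
      stopifnot(!is.null(vessel_mask))
      vp <- spec$organ_params$vessel
      b <- vp$bifurcation
      grown <- binary_dilate(vessel_mask, iter = ceiling(p$thickness))
      shell <- grown == 1 & vessel_mask == 0
      if (p$region == "inferior") {
        shell & co$z >= ceiling(vp$z_range[1]) & co$z < b
      } else {
        shell & co$z >= b & co$z <= p$z_top
      }
    },
    stop(sprintf("unknown structure kind '%s'", p$kind))
  )
  array(as.integer(m), dim = dm)
}

#' Generate one phantom
#'
#' Produces a raw-HU volume with additive Gaussian noise and a
#' `structure_set` of exact, pairwise-disjoint binary masks (provenance
#' `ground_truth`). The vessel mask has exactly one in-plane connected
#' component at and above the bifurcation slice and exactly two below it.
#'
#' @param spec a [phantom_spec()].
#' @param id scan identifier for the structure set.
#' @return A list with elements `id`, `volume`, `structures`, and
#'   `bifurcation` (the true bifurcation slice index).
#' @export
generate_phantom <- function(spec, id = "phantom_001") {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  order_names <- names(spec$organ_params)
  masks <- list()
  vessel_mask <- NULL
  # vessel first so the sheaths can be carved from its dilation
  for (nm in c(intersect("vessel", order_names), setdiff(order_names, "vessel"))) {
    masks[[nm]] <- rasterize_structure(spec, nm, vessel_mask = vessel_mask)
    if (nm == "vessel") vessel_mask <- masks[[nm]]
    if (!sum(masks[[nm]]))
      stop(sprintf("phantom_spec: structure '%s' is empty on this grid", nm))
    bb <- mask_bbox(masks[[nm]])
    if (any(bb["lo", ] < 1) || any(bb["hi", ] > dm))
      stop(sprintf("phantom_spec: structure '%s' does not fit inside the grid", nm))
  }
  masks <- masks[order_names]
  # enforce pairwise disjointness (the stated-world contract); any overlap,
  # including overlap with bone, is a spec error
  occ <- Reduce(`+`, masks)
  if (max(occ) > 1) {
    bad <- names(masks)[vapply(masks, function(m) any(m[occ > 1] == 1), logical(1))]
    stop(sprintf("phantom_spec: structures overlap (%s)", paste(bad, collapse = ", ")))
  }
  bg <- spec$intensity_map[["background"]]
  img <- array(bg, dim = dm)
  for (nm in names(masks)) {
    hu <- bg + spec$contrast_scale * (spec$intensity_map[[nm]] - bg)
    img[masks[[nm]] == 1] <- hu
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- img + array(stats::rnorm(prod(dm), sd = spec$noise_sigma), dim = dm)
  }
  vol <- ct_volume(img, spec$spacing, intensity_kind = "raw_hu")
  ss <- structure_set(id, masks)
  list(id = id, volume = vol, structures = ss,
       bifurcation = if ("vessel" %in% names(masks))
         spec$organ_params$vessel$bifurcation else NA_integer_)
}

#' Default per-parameter jitter ranges for cohort generation
#'
#' Half-widths of uniform jitter: organ centres move up to 2 slices axially
#' and 3 voxels in-plane, radii scale by up to 10%, and the vessel
#' bifurcation moves up to 3 slices.
#'
#' @return A list of jitter half-widths.
#' @export
default_jitter <- function() {
  list(center_z = 2, center_yx = 2, radius_scale = 0.08, bifurcation = 3)
}

#' Zero jitter (identical geometry across a cohort)
#' @export
zero_jitter <- function() {
  list(center_z = 0, center_yx = 0, radius_scale = 0, bifurcation = 0)
}

jitter_spec <- function(spec, jitter, seed) {
  set.seed(seed)
  sp <- spec
  sp$seed <- derive_seed(seed, 1L)
  j <- jitter
  for (nm in names(sp$organ_params)) {
    p <- sp$organ_params[[nm]]
    if (p$kind == "ellipsoid") {
      p$center <- p$center + c(stats::runif(1, -j$center_z, j$center_z),
                               stats::runif(2, -j$center_yx, j$center_yx))
      p$radii <- p$radii * stats::runif(3, 1 - j$radius_scale, 1 + j$radius_scale)
    } else if (p$kind %in% c("cylinder", "bent_tube")) {
      p$center_yx <- p$center_yx + stats::runif(2, -j$center_yx / 2, j$center_yx / 2)
      p$radius <- p$radius * stats::runif(1, 1 - j$radius_scale, 1 + j$radius_scale)
    } else if (p$kind == "y_tube") {
      db <- round(stats::runif(1, -j$bifurcation, j$bifurcation))
      p$bifurcation <- as.integer(clamp(p$bifurcation + db,
                                        ceiling(p$z_range[1]) + 2,
                                        floor(p$z_range[2]) - 2))
      p$center_yx <- p$center_yx + stats::runif(2, -j$center_yx / 2, j$center_yx / 2)
    } else if (p$kind == "block") {
      dz <- round(stats::runif(1, -j$center_z, j$center_z) / 2)
      p$z_range <- p$z_range + dz
    }
    sp$organ_params[[nm]] <- p
  }
  sp
}

#' Generate a cohort of jittered phantoms
#'
#' @param spec_template a [phantom_spec()].
#' @param n number of phantoms (>= 2).
#' @param jitter per-parameter jitter half-widths, see [default_jitter()];
#'   use zero entries for identical geometry.
#' @param seed master seed; the cohort is deterministic given `(spec, seed)`.
#' @return List of phantoms as returned by [generate_phantom()].
#' @export
generate_cohort <- function(spec_template = phantom_spec(), n = 10,
                            jitter = default_jitter(), seed = 1L) {
  stopifnot(n >= 2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- jitter_spec(spec_template, jitter, derive_seed(seed, i))
    ph <- tryCatch(generate_phantom(sp, id = sprintf("phantom_%03d", i)),
                   error = function(e)
                     stop(sprintf("generate_cohort: phantom %d invalid: %s",
                                  i, conditionMessage(e))))
    out[[i]] <- ph
  }
  out
}

#' Label corruption specification
#'
#' Models the incorrect clinical contours the curation loop must catch:
#' dilation/erosion by `magnitude` voxels, an in-plane shift by `magnitude`
#' voxels, or `wrong_level` (the mask moved axially by its own height,
#' emulating a vertebral mislevel).
#'
#' @param mode one of `dilate`, `erode`, `shift`, `wrong_level`.
#' @param magnitude voxels (>= 1).
#' @param fraction_corrupted proportion of the cohort in `(0, 1)`.
#' @param seed RNG seed.
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(mode = c("shift", "dilate", "erode", "wrong_level"),
                            magnitude = 5, fraction_corrupted = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(magnitude >= 1, fraction_corrupted > 0, fraction_corrupted < 1)
  structure(list(mode = mode, magnitude = as.integer(magnitude),
                 fraction_corrupted = fraction_corrupted, seed = as.integer(seed)),
            class = "corruption_spec")
}

corrupt_one_mask <- function(mask, mode, magnitude, rng_dir) {
  out <- switch(mode,
    dilate = binary_dilate(mask, magnitude),
    erode  = binary_erode(mask, magnitude),
    shift  = {
      dirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
      shift_array(mask, dirs[rng_dir, ] * magnitude)
    },
    wrong_level = {
      ez <- mask_extent_z(mask)
      shift_array(mask, c(ez[2] - ez[1] + 1, 0, 0))
    })
  if (!sum(out))
    stop("corrupt_labels: magnitude exceeds the structure extent")
  array(as.integer(out != 0), dim = dim(mask))
}

#' Covertly corrupt a fraction of cohort labels
#'
#' `ceiling(fraction * n)` scans are chosen at random; in each, one structure
#' (uniform among `structures`) has its label perturbed. Provenance is left
#' as `ground_truth` -- corruption is covert -- and the corrupted
#' `scan/structure` ids are returned for test oracles only.
#'
#' @param cohort list of phantoms (as from [generate_cohort()]).
#' @param spec a [corruption_spec()].
#' @param structures candidate structure names (default: all in the first scan).
#' @return List with `cohort` (labels perturbed in place) and
#'   `corrupted_ids` (character vector `"scan_id/structure"`).
#' @export
corrupt_labels <- function(cohort, spec, structures = NULL) {
  stopifnot(length(cohort) >= 1, inherits(spec, "corruption_spec"))
  structures <- structures %||% names(cohort[[1]]$structures$masks)
  n <- length(cohort)
  k <- ceiling(spec$fraction_corrupted * n)
  set.seed(spec$seed)
  chosen <- sample.int(n, k)
  ids <- character(0)
  for (i in chosen) {
    nm <- structures[sample.int(length(structures), 1)]
    rng_dir <- sample.int(4L, 1)
    m <- cohort[[i]]$structures$masks[[nm]]
    cohort[[i]]$structures$masks[[nm]] <-
      corrupt_one_mask(m, spec$mode, spec$magnitude, rng_dir)
    ids <- c(ids, paste0(cohort[[i]]$id, "/", nm))
  }
  list(cohort = cohort, corrupted_ids = ids)
}
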