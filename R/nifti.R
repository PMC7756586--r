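# Minimal NIfTI-1 reader/writer. No NIfTI-capable R package is available in
# the runtime image, so the single-file (.nii / .nii.gz) variant of the format
# is implemented here directly: 348-byte header, vox_offset 352, little- or
# big-endian, datatypes uint8 / int16 / int32 / float32 / float64. Arrays are
# stored on disk x-fastest (the NIfTI convention) and presented in R as
# (z, y, x); spacing maps to pixdim (dx, dy, dz) reversed, the origin to the
# qform offset. The volume's intensity_kind is round-tripped through the
# header `descrip` field.

nifti_open <- function(path, mode) {
  if (mode == "rb") gzfile(path, "rb") else if (grepl("\\.gz$", path))
    gzfile(path, "wb") else file(path, "wb")
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol a `ct_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype on-disk type: `"float32"` (default for images) or
#'   `"uint8"` (masks).
#' @return `path`, invisibly. Re-reading the file reproduces `data`,
#'   `spacing` and `origin` exactly (up to float32 rounding of the header
#'   fields, which is exact for the spacings used here).
#' @export
write_volume <- function(vol, path, datatype = c("float64", "float32", "uint8")) {
  stopifnot(inherits(vol, "ct_volume"))
  datatype <- match.arg(datatype)
  if (!dir.exists(dirname(path)))
    stop(sprintf("write_volume: parent directory of '%s' does not exist", path))
  dm <- dim(vol$data)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_chr <- function(s, n) {
    b <- charToRaw(s)
    if (length(b) > n) b <- b[seq_len(n)]
    writeBin(c(b, raw(n - length(b))), con)
  }
  w_i32(348)                                   # sizeof_hdr
  w_raw(36)                                    # data_type..dim_info
  w_i16(c(3, dm[3], dm[2], dm[1], 1, 1, 1, 1)) # dim: x, y, z
  w_f32(c(0, 0, 0)); w_i16(0)                  # intent
  dt_code <- switch(datatype, float64 = 64L, float32 = 16L, uint8 = 2L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L, uint8 = 8L)
  w_i16(dt_code); w_i16(bitpix); w_i16(0)      # datatype, bitpix, slice_start
  w_f32(c(1, vol$spacing[3], vol$spacing[2], vol$spacing[1], 0, 0, 0, 0)) # pixdim
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_i16(0); w_raw(1)                           # slice_end, slice_code
  writeBin(as.raw(2L), con)                    # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i32(c(0, 0))                               # glmax, glmin
  w_chr(paste0("cascadeseg:", vol$intensity_kind), 80)  # descrip
  w_raw(24)                                    # aux_file
  w_i16(1); w_i16(0)                           # qform_code, sform_code
  w_f32(c(0, 0, 0))                            # quatern b, c, d
  w_f32(c(vol$origin[3], vol$origin[2], vol$origin[1]))  # qoffset x, y, z
  w_f32(rep(0, 12))                            # srow
  w_raw(16)                                    # intent_name
  w_chr("n+1", 4)                              # magic
  w_raw(4)                                     # extension flag
  vals <- as.vector(aperm(vol$data, c(3, 2, 1)))  # x fastest on disk
  if (datatype == "float64") {
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  } else if (datatype == "float32") {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  } else {
    if (any(vals < 0 | vals > 255)) stop("write_volume: uint8 overflow")
    writeBin(as.raw(as.integer(vals)), con)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a readable `.nii` or `.nii.gz` file containing a 3D image.
#' @param intensity_kind override for the intensity kind; by default it is
#'   recovered from the header `descrip` field when present, else `"raw_hu"`.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path, intensity_kind = NULL) {
  if (!file.exists(path))
    stop(sprintf("read_volume: file '%s' not found", path))
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 352)
    stop(sprintf("read_volume: '%s' is not a NIfTI-1 file (truncated header)", path))
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  }
  if (sz != 348L)
    stop(sprintf("read_volume: '%s' is not a NIfTI-1 file", path))
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("read_volume: '%s' has no NIfTI magic string", path))
  dim_field <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim_field[1]
  extra_ok <- ndim <= 3L || all(dim_field[seq(5, 1 + ndim)] == 1L)
  if (ndim < 3L || !extra_ok)
    stop(sprintf("read_volume: '%s' is not a 3D image (dim = %d)", path, ndim))
  nx <- dim_field[2]; ny <- dim_field[3]; nz <- dim_field[4]
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "numeric", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4, endian = endian)
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  qoffset <- readBin(hdr[269:280], "numeric", n = 3, size = 4, endian = endian)
  n <- nx * ny * nz
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop(sprintf("read_volume: unsupported NIfTI datatype %d in '%s'", datatype, path))
  )
  if (length(vals) < n)
    stop(sprintf("read_volume: '%s' is truncated", path))
  a <- aperm(array(vals, dim = c(nx, ny, nz)), c(3, 2, 1))
  kind <- intensity_kind %||%
    (if (identical(descrip, "cascadeseg:preprocessed")) "preprocessed" else "raw_hu")
  ct_volume(a, spacing = c(pixdim[4], pixdim[3], pixdim[2]),
            origin = c(qoffset[3], qoffset[2], qoffset[1]),
            intensity_kind = kind)
}

#' Write a scan folder: volume, masks and a JSON manifest
#'
#' The manifest maps structure names to mask files and provenance so a scan
#' directory is self-describing.
#'
#' @param dir scan directory (created if missing).
#' @param vol the `ct_volume`.
#' @param structures a `structure_set` (optional).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(dir, vol, structures = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(vol, file.path(dir, "volume.nii.gz"))
  manifest <- list(volume = "volume.nii.gz",
                   spacing = vol$spacing,
                   structures = list())
  if (!is.null(structures)) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (nm in names(structures$masks)) {
      rel <- file.path("masks", paste0(nm, ".nii.gz"))
      mvol <- ct_volume(structures$masks[[nm]], vol$spacing, vol$origin)
      write_volume(mvol, file.path(dir, rel), datatype = "uint8")
      manifest$structures[[nm]] <- list(file = rel,
                                        provenance = unname(structures$provenance[nm]))
    }
    manifest$volume_id <- structures$volume_id
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scan folder written by [write_scan()]
#'
#' @param dir scan directory containing `manifest.json`.
#' @return A list with elements `id`, `volume` (`ct_volume`) and `structures`
#'   (`structure_set`, possibly with no masks).
#' @export
read_scan <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("read_scan: no manifest.json in '%s'", dir))
  mf <- jsonlite::read_json(mf_path)
  vol <- read_volume(file.path(dir, mf$volume))
  id <- mf$volume_id %||% basename(dir)
  masks <- list(); prov <- character(0)
  for (nm in names(mf$structures)) {
    mv <- read_volume(file.path(dir, mf$structures[[nm]]$file))
    masks[[nm]] <- array(as.integer(mv$data != 0), dim = dim(mv$data))
    prov[nm] <- mf$structures[[nm]]$provenance
  }
  ss <- if (length(masks)) structure_set(id, masks, prov) else
    structure(list(volume_id = id, masks = list(), provenance = character(0)),
              class = "structure_set")
  list(id = id, volume = vol, structures = ss)
}
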