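# Low-level array helpers shared across modules. Arrays are always ordered
# (slice/z, row/y, col/x) with z increasing toward the head; slice indices are
# 1-based throughout the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(z) 1 / (1 + exp(-z))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
coord_arrays <- function(dm) {
  nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
  list(
    z = array(rep(seq_len(nz), times = ny * nx), dim = dm),
    y = array(rep(rep(seq_len(ny), each = nz), times = nx), dim = dm),
    x = array(rep(seq_len(nx), each = nz * ny), dim = dm)
  )
}

# integer shift with zero fill; d = c(dz, dy, dx)
shift_array <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dim = dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    n <- dm[k]
    if (abs(d[k]) >= n) return(out)
    if (d[k] >= 0) {
      dst[[k]] <- (1 + d[k]):n
      src[[k]] <- 1:(n - d[k])
    } else {
      dst[[k]] <- 1:(n + d[k])
      src[[k]] <- (1 - d[k]):n
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_offsets6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

binary_dilate <- function(mask, iter = 1) {
  m <- mask != 0
  offs <- neighbor_offsets6()
  for (i in seq_len(iter)) {
    acc <- m
    for (r in seq_len(nrow(offs))) acc <- acc | (shift_array(m, offs[r, ]) != 0)
    m <- acc
  }
  array(as.integer(m), dim = dim(mask))
}

binary_erode <- function(mask, iter = 1) {
  m <- mask != 0
  offs <- neighbor_offsets6()
  for (i in seq_len(iter)) {
    acc <- m
    for (r in seq_len(nrow(offs))) acc <- acc & (shift_array(m, offs[r, ]) != 0)
    m <- acc
  }
  array(as.integer(m), dim = dim(mask))
}

# morphological opening (erosion then dilation): removes structures thinner
# than ~2*iter voxels while preserving blobby ones
binary_open <- function(mask, iter = 1) {
  binary_dilate(binary_erode(mask, iter), iter)
}

# logical per-slice "any foreground"
slice_any <- function(mask) {
  dm <- dim(mask)
  rowSums(matrix(mask != 0, nrow = dm[1])) > 0
}

mask_extent_z <- function(mask) {
  s <- which(slice_any(mask))
  if (!length(s)) return(NULL)
  c(min(s), max(s))
}

mask_bbox <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

# connected components of a 2D logical/0-1 matrix, 4-connectivity
label_components_2d <- function(m) {
  idx <- which(m != 0)
  if (!length(idx)) return(list(n = 0L, sizes = integer(0), labels = NULL))
  nr <- nrow(m); nc <- ncol(m)
  fg <- m != 0
  # vertical edges (r, r+1) and horizontal edges (c, c+1)
  ev <- which(fg[-nr, , drop = FALSE] & fg[-1, , drop = FALSE])
  eh <- which(fg[, -nc, drop = FALSE] & fg[, -1, drop = FALSE])
  # map sub-matrix linear indices back to full-matrix linear indices
  v_a <- ((ev - 1) %/% (nr - 1)) * nr + ((ev - 1) %% (nr - 1)) + 1
  v_b <- v_a + 1
  h_a <- eh
  h_b <- eh + nr
  vid <- match(c(v_a, h_a), idx)
  wid <- match(c(v_b, h_b), idx)
  g <- igraph::make_graph(rbind(vid, wid), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab <- matrix(0L, nr, nc)
  lab[idx] <- comp$membership
  list(n = comp$no, sizes = as.integer(comp$csize), labels = lab)
}

# connected components of a 3D 0-1 array, 6-connectivity
label_components_3d <- function(mask) {
  idx <- which(mask != 0)
  if (!length(idx)) return(list(n = 0L, sizes = integer(0), labels = NULL))
  dm <- dim(mask)
  fg <- mask != 0
  pairs_a <- integer(0); pairs_b <- integer(0)
  strides <- c(1L, dm[1], dm[1] * dm[2])
  for (k in 1:3) {
    keep <- slice.index(fg, k) < dm[k]
    both <- fg & keep & (shift_array(fg, -{d <- c(0, 0, 0); d[k] <- 1; d}) != 0)
    a <- which(both)
    pairs_a <- c(pairs_a, a)
    pairs_b <- c(pairs_b, a + strides[k])
  }
  vid <- match(pairs_a, idx)
  wid <- match(pairs_b, idx)
  g <- igraph::make_graph(rbind(vid, wid), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab <- array(0L, dim = dm)
  lab[idx] <- comp$membership
  list(n = comp$no, sizes = as.integer(comp$csize), labels = lab)
}

# drop connected components smaller than min_size voxels (6-connectivity)
drop_small_components <- function(mask, min_size = 9) {
  cc <- label_components_3d(mask)
  if (cc$n <= 1L) return(array(as.integer(mask != 0), dim = dim(mask)))
  keep <- which(cc$sizes >= min_size)
  if (!length(keep)) keep <- which.max(cc$sizes)
  array(as.integer(cc$labels %in% keep), dim = dim(mask))
}

largest_component <- function(mask) {
  cc <- label_components_3d(mask)
  if (cc$n <= 1L) return(array(as.integer(mask != 0), dim = dim(mask)))
  keep <- which.max(cc$sizes)
  array(as.integer(cc$labels == keep), dim = dim(mask))
}

# per-slice in-plane component counts after dropping specks smaller than
# min_size voxels; returns an integer vector of length nz
count_slice_components <- function(mask, min_size = 3) {
  dm <- dim(mask)
  counts <- integer(dm[1])
  occ <- which(slice_any(mask))
  for (z in occ) {
    cc <- label_components_2d(matrix(mask[z, , ], dm[2], dm[3]))
    counts[z] <- sum(cc$sizes >= min_size)
  }
  counts
}

# mean filter with radius 1 and edge replication; mode "2d" smooths in-plane only
box_smooth <- function(a, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  dm <- dim(a)
  offs <- expand.grid(dz = if (mode == "3d") -1:1 else 0, dy = -1:1, dx = -1:1)
  acc <- array(0, dim = dm)
  iz <- seq_len(dm[1]); iy <- seq_len(dm[2]); ix <- seq_len(dm[3])
  for (r in seq_len(nrow(offs))) {
    acc <- acc + a[clamp(iz + offs$dz[r], 1, dm[1]),
                   clamp(iy + offs$dy[r], 1, dm[2]),
                   clamp(ix + offs$dx[r], 1, dm[3])]
  }
  acc / nrow(offs)
}

# in-plane bilinear/nearest resize of a (z,y,x) array to (ny2, nx2)
resize_inplane <- function(a, out_yx, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  dm <- dim(a)
  ny2 <- out_yx[1]; nx2 <- out_yx[2]
  if (ny2 == dm[2] && nx2 == dm[3]) return(a)
  sy <- (seq_len(ny2) - 0.5) * dm[2] / ny2 + 0.5
  sx <- (seq_len(nx2) - 0.5) * dm[3] / nx2 + 0.5
  sy <- clamp(sy, 1, dm[2]); sx <- clamp(sx, 1, dm[3])
  M <- matrix(a, nrow = dm[1])
  col_of <- function(y, x) (x - 1L) * dm[2] + y
  if (interp == "nearest") {
    yi <- round(sy); xi <- round(sx)
    cols <- col_of(rep(yi, times = nx2), rep(xi, each = ny2))
    out <- M[, cols, drop = FALSE]
  } else {
    y0 <- clamp(floor(sy), 1, dm[2]); y1 <- clamp(y0 + 1, 1, dm[2]); fy <- sy - y0
    x0 <- clamp(floor(sx), 1, dm[3]); x1 <- clamp(x0 + 1, 1, dm[3]); fx <- sx - x0
    Y0 <- rep(y0, times = nx2); Y1 <- rep(y1, times = nx2); FY <- rep(fy, times = nx2)
    X0 <- rep(x0, each = ny2); X1 <- rep(x1, each = ny2); FX <- rep(fx, each = ny2)
    w00 <- (1 - FY) * (1 - FX); w10 <- FY * (1 - FX); w01 <- (1 - FY) * FX; w11 <- FY * FX
    out <- sweep(M[, col_of(Y0, X0), drop = FALSE], 2, w00, `*`) +
      sweep(M[, col_of(Y1, X0), drop = FALSE], 2, w10, `*`) +
      sweep(M[, col_of(Y0, X1), drop = FALSE], 2, w01, `*`) +
      sweep(M[, col_of(Y1, X1), drop = FALSE], 2, w11, `*`)
  }
  array(out, dim = c(dm[1], ny2, nx2))
}

# in-plane rotation about the slice centre; same angle for every slice.
# Linear interpolation for images, nearest for masks; out-of-frame samples
# take `fill`.
rotate_inplane <- function(a, theta_deg, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  if (abs(theta_deg) < 1e-12) return(a)
  dm <- dim(a)
  th <- theta_deg * pi / 180
  cy <- (dm[2] + 1) / 2; cx <- (dm[3] + 1) / 2
  gy <- rep(seq_len(dm[2]), times = dm[3]) - cy
  gx <- rep(seq_len(dm[3]), each = dm[2]) - cx
  sy <- cy + cos(th) * gy - sin(th) * gx
  sx <- cx + sin(th) * gy + cos(th) * gx
  M <- matrix(a, nrow = dm[1])
  col_of <- function(y, x) (x - 1L) * dm[2] + y
  inside <- sy >= 1 & sy <= dm[2] & sx >= 1 & sx <= dm[3]
  if (interp == "nearest") {
    yi <- clamp(round(sy), 1, dm[2]); xi <- clamp(round(sx), 1, dm[3])
    out <- M[, col_of(yi, xi), drop = FALSE]
  } else {
    y0 <- clamp(floor(sy), 1, dm[2]); y1 <- clamp(y0 + 1, 1, dm[2]); fy <- sy - y0
    x0 <- clamp(floor(sx), 1, dm[3]); x1 <- clamp(x0 + 1, 1, dm[3]); fx <- sx - x0
    out <- sweep(M[, col_of(y0, x0), drop = FALSE], 2, (1 - fy) * (1 - fx), `*`) +
      sweep(M[, col_of(y1, x0), drop = FALSE], 2, fy * (1 - fx), `*`) +
      sweep(M[, col_of(y0, x1), drop = FALSE], 2, (1 - fy) * fx, `*`) +
      sweep(M[, col_of(y1, x1), drop = FALSE], 2, fx * fy, `*`)
  }
  if (any(!inside)) out[, !inside] <- fill
  array(out, dim = dm)
}

# deterministic child seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
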