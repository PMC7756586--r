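# Independent brute-force oracles and random-mask generators for the metric
# and geometry tests. These deliberately share no code with the package's
# accelerated implementations: surfaces are found by explicit neighbour
# checks, distances by per-point enumeration.

rand_mask <- function(dm, p = 0.5, blob = TRUE) {
  if (blob) {
    # a random box plus salt, guaranteed non-empty
    lo <- sapply(dm, function(n) sample.int(max(1, n - 2), 1))
    hi <- pmin(dm, lo + sapply(dm, function(n) sample.int(max(1, n %/% 2), 1)))
    m <- array(0L, dim = dm)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
    m
  } else {
    array(as.integer(stats::runif(prod(dm)) < p), dim = dm)
  }
}

dice_bf <- function(a, b) {
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  inter <- 0
  for (i in which(a != 0)) if (b[i] != 0) inter <- inter + 1
  2 * inter / (na + nb)
}

# surface voxels by explicit 6-neighbour enumeration
surface_bf <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  w <- which(mask != 0, arr.ind = TRUE)
  keep <- logical(nrow(w))
  for (r in seq_len(nrow(w))) {
    z <- w[r, 1]; y <- w[r, 2]; x <- w[r, 3]
    nb <- rbind(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
                c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))
    for (q in seq_len(6)) {
      zz <- nb[q, 1]; yy <- nb[q, 2]; xx <- nb[q, 3]
      outside <- zz < 1 || zz > dm[1] || yy < 1 || yy > dm[2] || xx < 1 || xx > dm[3]
      if (outside || mask[zz, yy, xx] == 0) { keep[r] <- TRUE; break }
    }
  }
  sweep(w[keep, , drop = FALSE] - 1, 2, spacing, `*`)
}

# O(n^2) directed nearest distances: per-point loop
nearest_bf <- function(A, B) {
  out <- numeric(nrow(A))
  for (r in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[r, 1])^2 + (B[, 2] - A[r, 2])^2 + (B[, 3] - A[r, 3])^2
    out[r] <- sqrt(min(d2))
  }
  out
}

msd_bf <- function(pred, ref, spacing) {
  P <- surface_bf(pred, spacing); R <- surface_bf(ref, spacing)
  0.5 * (mean(nearest_bf(P, R)) + mean(nearest_bf(R, P))) / 10
}

hd_bf <- function(pred, ref, spacing) {
  P <- surface_bf(pred, spacing); R <- surface_bf(ref, spacing)
  max(max(nearest_bf(P, R)), max(nearest_bf(R, P))) / 10
}
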