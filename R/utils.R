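# Internal grid helpers shared by all model layers. Activity fields are plain
# numeric matrices/arrays indexed [row, col, ...]; row increases downward so a
# clockwise 90-degree image rotation adds +90 degrees to angles measured in
# (x = col, y = row) coordinates.

# out[i, j] = M[i + dy, j + dx]; reads outside the grid give `fill`
fetch_shift <- function(M, dy, dx, fill = 0) {
  n <- nrow(M); m <- ncol(M)
  r0 <- max(1L, 1L - dy); r1 <- min(n, n - dy)
  c0 <- max(1L, 1L - dx); c1 <- min(m, m - dx)
  out <- matrix(fill, n, m)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- M[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx)]
  }
  out
}

# Chebyshev (3x3 structuring element applied `r` times) binary dilation.
dilate_mask <- function(mask, r = 1L) {
  stopifnot(is.matrix(mask))
  if (r <= 0) return(mask & TRUE)
  acc <- matrix(0, nrow(mask), ncol(mask))
  num <- mask * 1
  for (dy in -r:r) for (dx in -r:r) {
    acc <- acc + fetch_shift(num, dy, dx)
  }
  acc > 0
}

# Figure pixels with a 4-neighbour outside the mask (inner boundary).
inner_boundary <- function(mask) {
  num <- mask * 1
  nb <- fetch_shift(num, 1L, 0L) * fetch_shift(num, -1L, 0L) *
    fetch_shift(num, 0L, 1L) * fetch_shift(num, 0L, -1L)
  mask & (nb == 0)
}

# column-wise cumulative sums computed with a single cumsum() pass
col_cumsum <- function(M) {
  n <- nrow(M); m <- ncol(M)
  cs <- cumsum(M)
  if (m > 1L) {
    off <- c(0, cs[seq_len(m - 1L) * n])
    cs <- cs - rep(off, each = n)
  }
  matrix(cs, n, m)
}

# Mean over a centered (2r+1)^2 box via integral images; out-of-grid treated
# as zero activity but the normalisation stays constant so pooled responses
# near the canvas edge are not inflated.
box_pool <- function(M, r) {
  r <- as.integer(round(r))
  if (r <= 0) return(M)
  n <- nrow(M); m <- ncol(M)
  P <- matrix(0, n + 2L * r, m + 2L * r)
  P[(r + 1L):(r + n), (r + 1L):(r + m)] <- M
  cs <- t(col_cumsum(t(col_cumsum(P))))
  cs <- rbind(0, cbind(0, cs))
  w <- 2L * r + 1L
  i1 <- (1:n) + 2L * r; j1 <- (1:m) + 2L * r
  i0 <- 1:n; j0 <- 1:m
  (cs[i1 + 1L, j1 + 1L, drop = FALSE] - cs[i0, j1 + 1L, drop = FALSE] -
      cs[i1 + 1L, j0, drop = FALSE] + cs[i0, j0, drop = FALSE]) / (w * w)
}

# Clockwise 90-degree rotation of an image matrix (row = y down).
rot90cw <- function(M) {
  t(M)[, nrow(M):1, drop = FALSE]
}

# Rotate a (dy, dx) offset the same way rot90cw rotates the raster.
rot_offset_cw <- function(dy, dx) c(dx, -dy)

relu <- function(x) pmax(x, 0)

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Symmetric rounding (round-half-away-from-zero) so that rounded offsets
# commute with exact 90-degree rotations.
sym_round <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_if_not_mask <- function(x, what = "mask") {
  if (!is.matrix(x) || !is.logical(x)) {
    stop(what, " must be a logical matrix", call. = FALSE)
  }
  invisible(x)
}
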