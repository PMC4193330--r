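# Brute-force oracles, independent of the package implementation paths.

# Euclidean distance transform by direct enumeration: for every figure pixel,
# the minimum distance over all background pixels bordering the figure (the
# nearest background pixel always borders the figure); the canvas border
# counts as background.
brute_edt <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  bgc <- which(!pad)
  br <- (bgc - 1L) %% (n + 2L) + 1L
  bc <- (bgc - 1L) %/% (n + 2L) + 1L
  keep <- rep(FALSE, length(bgc))
  for (dy in -1:1) for (dx in -1:1) {
    rr <- br + dy; cc <- bc + dx
    ok <- rr >= 1 & rr <= n + 2 & cc >= 1 & cc <= m + 2
    v <- rep(FALSE, length(bgc))
    v[ok] <- pad[cbind(rr[ok], cc[ok])]
    keep <- keep | v
  }
  br <- br[keep] - 1L; bc <- bc[keep] - 1L
  d <- matrix(0, n, m)
  fig <- which(mask)
  fr <- (fig - 1L) %% n + 1L
  fc <- (fig - 1L) %/% n + 1L
  for (i in seq_along(fig)) {
    d[fig[i]] <- sqrt(min((fr[i] - br)^2 + (fc[i] - bc)^2))
  }
  d
}

shift0 <- function(M, dy, dx) {
  out <- matrix(0, nrow(M), ncol(M))
  r0 <- max(1, 1 - dy); r1 <- min(nrow(M), nrow(M) - dy)
  c0 <- max(1, 1 - dx); c1 <- min(ncol(M), ncol(M) - dx)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- M[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx)]
  }
  out
}

# ridge of the brute-force distance transform: distance >= both neighbours
# along some opposing direction, strictly greater than at least one
oracle_medial_ridge <- function(mask) {
  d <- brute_edt(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (p in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    a <- shift0(d, p[1], p[2]); b <- shift0(d, -p[1], -p[2])
    out <- out | (d >= a & d >= b & (d > a | d > b))
  }
  out & mask
}

dilate1 <- function(mask) {
  acc <- mask * 1
  for (dy in -1:1) for (dx in -1:1) acc <- acc + shift0(mask * 1, dy, dx)
  acc > 0
}

# pixels of each skeleton farther than one pixel from the other
skeleton_mismatch <- function(a, b) {
  sum(a & !dilate1(b)) + sum(b & !dilate1(a))
}

# direct mask-mean contrast, the definition of the figure-ground indices
oracle_index <- function(map, mask_a, mask_b) {
  a <- mean(map[mask_a]); b <- mean(map[mask_b])
  if (a + b == 0) 0 else (a - b) / (a + b)
}

rot_cw <- function(M) t(M)[, nrow(M):1, drop = FALSE]
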