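#' Oriented, polarity-insensitive edge map of a display
#'
#' Lumped early-vision stage: boundary contours of the figure are converted
#' into oriented edge energy approximating rectified complex-cell output.
#' Energy is the Sobel gradient magnitude of the figure mask, restricted to
#' within one pixel of the figure boundary and normalised to a maximum of 1;
#' each pixel's energy is distributed over `n_orient` orientation channels
#' (spanning 180 degrees, contrast-polarity insensitive) by a squared-cosine
#' tuning curve centered on the local boundary tangent. Working from the
#' figure mask rather than raw pixels means texture-defined figures produce
#' energy on their orientation-contrast outline, not on individual strokes —
#' and a background-only control display produces an empty edge map.
#'
#' @param display a `visual_display`.
#' @param n_orient number of orientation channels over 180 degrees
#'   (default 8, i.e. 22.5-degree spacing).
#' @return an `edge_map`: list with `energy` (array position x position x
#'   orientation, nonnegative) and `n_orient`.
#' @export
compute_edge_map <- function(display, n_orient = 8L) {
  stopifnot(inherits(display, "visual_display"), n_orient >= 2)
  mask <- display$figure_mask * 1
  n <- nrow(mask); m <- ncol(mask)
  gx <- sobel_gradient(mask, axis = "x")
  gy <- sobel_gradient(mask, axis = "y")
  mag <- sqrt(gx^2 + gy^2)
  band <- dilate_mask(display$boundary_mask, 1L)
  mag[!band] <- 0
  energy <- array(0, c(n, m, n_orient))
  if (max(mag) > 0) {
    mag <- mag / max(mag)
    tang <- (atan2(gy, gx) * 180 / pi + 90) %% 180
    phis <- (seq_len(n_orient) - 1) * 180 / n_orient
    w <- array(0, c(n, m, n_orient))
    for (k in seq_len(n_orient)) {
      w[, , k] <- relu(cos(2 * (tang - phis[k]) * pi / 180))^2
    }
    tot <- apply(w, c(1, 2), sum)
    tot[tot == 0] <- 1
    for (k in seq_len(n_orient)) {
      energy[, , k] <- mag * w[, , k] / tot
    }
  }
  structure(list(energy = energy, n_orient = as.integer(n_orient)),
            class = "edge_map")
}

sobel_gradient <- function(M, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    # d/dx: column differences, rows smoothed 1-2-1
    (fetch_shift(M, -1L, 1L) + 2 * fetch_shift(M, 0L, 1L) + fetch_shift(M, 1L, 1L) -
       fetch_shift(M, -1L, -1L) - 2 * fetch_shift(M, 0L, -1L) - fetch_shift(M, 1L, -1L))
  } else {
    (fetch_shift(M, 1L, -1L) + 2 * fetch_shift(M, 1L, 0L) + fetch_shift(M, 1L, 1L) -
       fetch_shift(M, -1L, -1L) - 2 * fetch_shift(M, -1L, 0L) - fetch_shift(M, -1L, 1L))
  }
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map: %dx%d px, %d orientation channels, total energy %.3f>\n",
              dim(x$energy)[1], dim(x$energy)[2], x$n_orient, sum(x$energy)))
  invisible(x)
}
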