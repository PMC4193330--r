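#' Default annular RF radii
#'
#' Seven scales in geometric progression from 3 to 24 px, shared by the
#' curved-contour, convex, and teardrop stages.
#'
#' @return numeric vector of 7 radii (pixels).
#' @export
default_radii <- function() {
  3 * 8^((0:6) / 6)
}

#' Bank of curvature-tuned arc templates (model V4)
#'
#' Curved-contour cells are tuned to one of `n_arcs` arcs of a circle
#' (45-degree arcs for the default 8) at one of `length(radii)` scales. The
#' template for arc `k` at scale `s` samples the arc of the circle of radius
#' `radii[s]` centered on the cell's position at roughly 1-px spacing; each
#' sample carries the circle's tangent orientation at that point and the
#' template's total weight mass is 1, so responses are comparable across
#' scales. Arcs `k + n_arcs/4` are exact 90-degree rotations of arc `k`,
#' which makes the whole bank exactly equivariant to quarter-turn rotations
#' of the input raster.
#'
#' @param radii strictly increasing scale radii in pixels (all >= 2).
#' @param n_arcs number of arcs tiling the circle (multiple of 4).
#' @param orient_tol orientation tuning half-width in degrees (the tuning
#'   curve falls to half its peak at this angular offset); default 22.5.
#' @param ring_width radial thickness of the annulus in pixels: each arc
#'   sample is replicated at `ring_width` radii straddling the nominal
#'   radius, giving the RF a graded radial profile (default 2).
#' @return an `arc_bank` object.
#' @export
build_arc_bank <- function(radii = default_radii(), n_arcs = 8L, orient_tol = 22.5,
                           ring_width = 2L) {
  stopifnot(length(radii) >= 1, all(diff(radii) > 0), n_arcs %% 4 == 0,
            orient_tol > 0, orient_tol < 45, ring_width >= 1)
  if (any(radii < 2)) stop("arc radii must be >= 2 px", call. = FALSE)
  alpha <- 360 / n_arcs
  base_arcs <- n_arcs %/% 4L
  dr <- seq_len(ring_width) - (ring_width + 1) / 2
  templates <- vector("list", length(radii))
  for (s in seq_along(radii)) {
    r <- radii[s]
    n_samp <- max(3L, ceiling(2 * pi * r / n_arcs))
    arcs <- vector("list", n_arcs)
    for (k in seq_len(base_arcs)) {
      th_deg <- ((k - 1) + (seq_len(n_samp) - 0.5) / n_samp) * alpha
      th_deg <- rep(th_deg, each = length(dr))
      rr <- pmax(rep(r + dr, n_samp), 1)
      th <- th_deg * pi / 180
      arcs[[k]] <- data.frame(
        dy = sym_round(rr * sin(th)),
        dx = sym_round(rr * cos(th)),
        w = 1 / (n_samp * length(dr)),
        orient = (th_deg + 90) %% 180
      )
    }
    for (k in (base_arcs + 1L):n_arcs) {
      prev <- arcs[[k - base_arcs]]
      arcs[[k]] <- data.frame(
        dy = prev$dx, dx = -prev$dy,   # exact 90-degree raster rotation
        w = prev$w,
        orient = (prev$orient + 90) %% 180
      )
    }
    templates[[s]] <- arcs
  }
  structure(list(radii = radii, n_arcs = as.integer(n_arcs),
                 orient_tol = orient_tol, ring_width = as.integer(ring_width),
                 templates = templates),
            class = "arc_bank")
}

# orientation tuning of a template sample across the edge-map channels,
# normalised to unit mass per sample
orientation_weights <- function(orient, phis, orient_tol) {
  p <- log(0.5) / log(cos(2 * orient_tol * pi / 180))
  w <- relu(cos(2 * (orient - phis) * pi / 180))^p
  s <- sum(w)
  if (s > 0) w / s else w
}

#' Curved-contour cell responses (model V4)
#'
#' Rectified template match of the arc bank against an oriented edge map:
#' the response of the cell at position p, arc k, scale s is the
#' orientation-weighted sum of edge energy over the template samples (read
#' at p + offset), minus the contrast threshold `theta_c`, rectified at
#' zero. Corners drive two adjacent arcs partially; a circle of radius
#' `radii[s]` drives all arcs of scale s at its center.
#'
#' @param edge_map an [compute_edge_map()] result.
#' @param bank an [build_arc_bank()] object.
#' @param theta_c rectification threshold (default 0).
#' @return `curved_field`: array position x position x arc x scale, >= 0.
#' @export
curved_response <- function(edge_map, bank, theta_c = 0) {
  stopifnot(inherits(edge_map, "edge_map"), inherits(bank, "arc_bank"))
  E <- edge_map$energy
  n <- dim(E)[1]; m <- dim(E)[2]; n_or <- dim(E)[3]
  phis <- (seq_len(n_or) - 1) * 180 / n_or
  S <- length(bank$radii)
  out <- array(0, c(n, m, bank$n_arcs, S))
  for (s in seq_len(S)) {
    for (k in seq_len(bank$n_arcs)) {
      tpl <- bank$templates[[s]][[k]]
      # aggregate duplicate (offset, channel) reads before shifting
      rows <- do.call(rbind, lapply(seq_len(nrow(tpl)), function(j) {
        wc <- tpl$w[j] * orientation_weights(tpl$orient[j], phis, bank$orient_tol)
        ch <- which(wc > 1e-10)
        data.frame(dy = tpl$dy[j], dx = tpl$dx[j], c = ch, w = wc[ch])
      }))
      agg <- stats::aggregate(w ~ dy + dx + c, data = rows, FUN = sum)
      acc <- matrix(0, n, m)
      for (j in seq_len(nrow(agg))) {
        acc <- acc + agg$w[j] * fetch_shift(E[, , agg$c[j]], agg$dy[j], agg$dx[j])
      }
      out[, , k, s] <- relu(acc - theta_c)
    }
  }
  class(out) <- c("curved_field", class(out))
  out
}
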