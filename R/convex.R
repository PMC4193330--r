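#' Annular RF parameters for convex cells (model PIT)
#'
#' @param radii the scale radii shared with the arc bank.
#' @param opposing_gate minimum number of active arc pairs separated by at
#'   least a quarter circle that a convex cell needs to receive feedforward
#'   drive (default 2). Cells without boundary contours on opposing sides of
#'   the RF are suppressed; a quarter-circle separation (rather than strict
#'   antipodality) admits medial points of corner wedges, where the two
#'   boundary contacts are orthogonal.
#' @param gate_eps activity level above which an arc counts as active.
#' @return an `annulus_params` object.
#' @export
annulus_params <- function(radii = default_radii(), opposing_gate = 2L,
                           gate_eps = 0.01) {
  stopifnot(all(diff(radii) > 0), opposing_gate >= 0, gate_eps >= 0)
  structure(list(radii = radii, opposing_gate = as.integer(opposing_gate),
                 gate_eps = gate_eps),
            class = "annulus_params")
}

#' Feedforward drive to convex cells
#'
#' A convex cell at position p and scale s integrates, over the eight arc
#' sectors, the curved-contour activity of scale s centered at p — i.e. the
#' boundary-contour evidence lying on the annulus of radius `radii[s]`
#' around p. The drive is gated to zero unless at least `opposing_gate`
#' active arc pairs lie at least a quarter circle apart, so isolated contour
#' fragments on one side of the RF cannot drive the cell.
#'
#' @param curved a `curved_field` (position x position x arc x scale).
#' @param params an [annulus_params()] object.
#' @return array position x position x scale of nonnegative drives, with the
#'   per-position count of active opposing arc pairs in attribute `npairs`.
#' @export
annulus_drive <- function(curved, params = annulus_params()) {
  d <- dim(curved)
  n_arcs <- d[3]; S <- d[4]
  stopifnot(n_arcs %% 4 == 0, S == length(params$radii))
  quarter <- n_arcs %/% 4L
  half <- n_arcs %/% 2L
  # unordered arc pairs separated by >= a quarter circle (circular distance)
  pair_idx <- which(outer(seq_len(n_arcs), seq_len(n_arcs), function(i, j) {
    sep <- pmin((i - j) %% n_arcs, (j - i) %% n_arcs)
    i < j & sep >= quarter & sep <= half
  }), arr.ind = TRUE)
  drive <- array(0, c(d[1], d[2], S))
  npairs <- array(0L, c(d[1], d[2], S))
  for (s in seq_len(S)) {
    tot <- matrix(0, d[1], d[2])
    for (k in seq_len(n_arcs)) tot <- tot + curved[, , k, s]
    active <- curved[, , , s] > params$gate_eps
    np <- matrix(0L, d[1], d[2])
    for (r in seq_len(nrow(pair_idx))) {
      np <- np + (active[, , pair_idx[r, 1]] & active[, , pair_idx[r, 2]])
    }
    drive[, , s] <- tot * (np >= params$opposing_gate)
    npairs[, , s] <- np
  }
  attr(drive, "npairs") <- npairs
  drive
}

# per-(position, scale) curved energy summed over arcs (ungated); used for
# the cancellation branch of the recurrent circuit
curved_scale_energy <- function(curved) {
  d <- dim(curved)
  out <- array(0, c(d[1], d[2], d[4]))
  for (s in seq_len(d[4])) {
    acc <- matrix(0, d[1], d[2])
    for (k in seq_len(d[3])) acc <- acc + curved[, , k, s]
    out[, , s] <- acc
  }
  out
}

#' Coarse-to-fine recurrent inhibition between convex cells
#'
#' Convex cells receive inhibition only from convex cells with larger RFs
#' (uniform weights over larger scales). In the underlying circuit, the
#' curved-contour cells that drive a large convex cell also drive an
#' inhibitory interneuron, so the two inhibitory signals cancel whenever
#' the large cell's activity is fully accounted for by its bottom-up curved
#' input; only its activity *excess* over that feedforward expectation —
#' the part sustained by closure feedback, as happens over a concave
#' "negative part" spanned by a false medial axis — is passed on as
#' suppression. The suppression is delivered around the large cell's RF
#' center (spatial pooling over a fraction `rec_pool` of its radius), which
#' for a figure with a large concavity is precisely where the spurious
#' small-scale medial responses sit.
#'
#' @param convex array position x position x scale of convex activities.
#' @param expected per-(position, scale) feedforward expectation: the
#'   shunting equilibrium each cell would reach from its bottom-up drive
#'   alone (precomputed in the model context).
#' @param radii scale radii.
#' @param kappa cancellation gain on the feedforward expectation (values
#'   slightly above 1 leave headroom so purely feedforward states generate
#'   no recurrent suppression).
#' @param rec_pool footprint of the delivered inhibition as a fraction of
#'   the inhibiting cell's radius (default 0.3).
#' @return array of nonnegative inhibition, zero at the largest scale.
#' @export
convex_recurrent_inhibition <- function(convex, expected,
                                        radii = default_radii(), kappa = 1.1,
                                        rec_pool = 0.3) {
  d <- dim(convex)
  S <- d[3]
  out <- array(0, d)
  if (S < 2) return(out)
  pooled <- vector("list", S)
  for (s in 2:S) {
    excess <- relu(convex[, , s] - kappa * expected[, , s])
    pooled[[s]] <- box_pool(excess, rec_pool * radii[s])
  }
  for (s in seq_len(S - 1L)) {
    acc <- matrix(0, d[1], d[2])
    for (sp in (s + 1L):S) acc <- acc + pooled[[sp]]
    out[, , s] <- acc / (S - s)
  }
  out
}

#' Cross-scale competition among convex cells sharing an RF center
#'
#' Convex cells with different RF sizes at the same position compete in a
#' contrast-enhancing recurrent network: scale s receives inhibition equal
#' to the sum of a faster-than-linear (quadratic) signal of the activity of
#' all other scales at that position. A uniform scale profile inhibits
#' itself symmetrically; a non-uniform one is sharpened toward the winning
#' scale as the network settles.
#'
#' @param convex array position x position x scale.
#' @return array of the same shape: competitive inhibition per cell.
#' @export
cross_scale_competition <- function(convex) {
  d <- dim(convex)
  sq <- convex^2
  tot <- array(0, c(d[1], d[2]))
  for (s in seq_len(d[3])) tot <- tot + sq[, , s]
  out <- array(0, d)
  for (s in seq_len(d[3])) out[, , s] <- tot - sq[, , s]
  out
}
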