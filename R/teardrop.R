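#' Teardrop-cell sampling geometry (model AIT)
#'
#' A teardrop cell at position p with integration direction d and size
#' sigma groups convex cells whose RF sizes increase linearly along d
#' toward p: sample i (i = 0 .. sigma-1) reads the convex cell of scale
#' sigma - i at p - offset_i * u_d, with equally spaced offsets
#' offset_i = i * Delta_sigma and Delta_sigma = lambda * (radii[sigma] -
#' radii[1]) / (sigma - 1). The offset-0 sample — the largest convex cell,
#' which defines the teardrop's RF position — is shared by all integration
#' directions at p. Directions are spaced 45 degrees apart (default 8) and
#' directions d + n_dir/4 are exact 90-degree rotations of direction d.
#'
#' Teardrop cells exist at every size sigma = 1 .. length(radii); the size
#' axis is what lets the closure evidence follow a figure's own scale, and
#' the per-size populations are what the activity panels of the worked
#' analyses display.
#'
#' @param radii scale radii shared with the other stages.
#' @param n_dir number of integration directions (multiple of 4).
#' @param lambda spacing slope: how far apart, relative to the RF-size ramp,
#'   the sampled convex cells sit (default 1.5, approximating the medial
#'   wedge of a right-angle corner).
#' @param min_size smallest teardrop size simulated (default 2): a
#'   "teardrop" of size 1 would consist of the shared offset-0 sample alone
#'   and carry no directional information, so closure evidence starts at
#'   groups of two cells.
#' @return a `teardrop_geometry` object with per-(size, direction) sample
#'   tables of fetch offsets and scales.
#' @export
teardrop_geometry <- function(radii = default_radii(), n_dir = 8L, lambda = 1.5,
                              min_size = 2L) {
  stopifnot(n_dir %% 4 == 0, lambda > 0, all(diff(radii) > 0),
            min_size >= 1)
  S <- length(radii)
  base_dirs <- n_dir %/% 4L
  samples <- vector("list", S)
  for (sigma in seq_len(S)) {
    delta <- if (sigma > 1) lambda * (radii[sigma] - radii[1]) / (sigma - 1) else 0
    offs <- (seq_len(sigma) - 1L) * delta
    dirs <- vector("list", n_dir)
    for (d in seq_len(base_dirs)) {
      th <- (d - 1) * (360 / n_dir) * pi / 180
      # drive(p) samples convex at p - off * u_d  =>  fetch shift is -off * u_d
      dirs[[d]] <- data.frame(
        sdy = -sym_round(offs * sin(th)),
        sdx = -sym_round(offs * cos(th)),
        scale = sigma - (seq_len(sigma) - 1L)
      )
    }
    for (d in (base_dirs + 1L):n_dir) {
      prev <- dirs[[d - base_dirs]]
      dirs[[d]] <- data.frame(sdy = prev$sdx, sdx = -prev$sdy, scale = prev$scale)
    }
    samples[[sigma]] <- dirs
  }
  structure(list(radii = radii, n_dir = as.integer(n_dir), lambda = lambda,
                 min_size = as.integer(min_size), n_scales = S,
                 samples = samples),
            class = "teardrop_geometry")
}

# number of in-grid samples per position, per (size, direction); used to
# renormalise drives near the canvas border
teardrop_sample_counts <- function(geom, n, m) {
  ones <- matrix(1, n, m)
  counts <- vector("list", geom$n_scales)
  for (sigma in seq_len(geom$n_scales)) {
    counts[[sigma]] <- vector("list", geom$n_dir)
    for (d in seq_len(geom$n_dir)) {
      tab <- geom$samples[[sigma]][[d]]
      acc <- matrix(0, n, m)
      for (j in seq_len(nrow(tab))) {
        acc <- acc + fetch_shift(ones, tab$sdy[j], tab$sdx[j])
      }
      counts[[sigma]][[d]] <- pmax(acc, 1)
    }
  }
  counts
}

#' Feedforward drive to teardrop cells
#'
#' A teardrop cell responds to an ordered collection of convex cells along a
#' medial-axis segment, so its drive is conjunctive over the whole chain:
#' the geometric mean of the sampled convex activities (floored at a small
#' `eps`, which is subtracted again so a silent chain yields exactly zero),
#' taken over the in-grid samples and rectified against `theta_t`. A single
#' silent cell in the chain collapses
#' the evidence, which keeps closure signals off the background and off
#' positions whose chains only graze active regions. With `direction` and
#' `size` both `NULL` the full position x direction array, maximum-pooled
#' over sizes, is returned — the directional closure evidence used by the
#' feedback stage.
#'
#' @param convex array position x position x scale.
#' @param geom a [teardrop_geometry()].
#' @param direction integer in 1..n_dir, or `NULL` for all directions.
#' @param size teardrop size in 1..n_scales, or `NULL` to pool (max) over sizes.
#' @param theta_t rectification threshold.
#' @param eps activity floor inside the geometric mean.
#' @return matrix (single direction) or array position x position x direction.
#' @export
teardrop_drive <- function(convex, geom, direction = NULL, size = NULL,
                           theta_t = 0, eps = 0.01) {
  all4 <- teardrop_drive_sizes(convex, geom, theta_t, eps)
  d <- dim(all4)
  pooled <- if (is.null(size)) {
    out <- array(0, d[1:3])
    for (sigma in seq_len(d[4])) out <- pmax(out, all4[, , , sigma])
    out
  } else {
    all4[, , , size]
  }
  if (is.null(direction)) pooled else pooled[, , direction]
}

#' Per-size teardrop drives
#'
#' @inheritParams teardrop_drive
#' @return array position x position x direction x size.
#' @export
teardrop_drive_sizes <- function(convex, geom, theta_t = 0, eps = 0.01) {
  n <- dim(convex)[1]; m <- dim(convex)[2]
  stopifnot(dim(convex)[3] == geom$n_scales)
  out <- array(0, c(n, m, geom$n_dir, geom$n_scales))
  ones <- matrix(1, n, m)
  logc <- log(pmax(convex, eps))
  for (sigma in seq(geom$min_size, geom$n_scales)) {
    for (d in seq_len(geom$n_dir)) {
      tab <- geom$samples[[sigma]][[d]]
      acc <- matrix(0, n, m)
      cnt <- matrix(0, n, m)
      for (j in seq_len(nrow(tab))) {
        acc <- acc + fetch_shift(logc[, , tab$scale[j]], tab$sdy[j], tab$sdx[j])
        cnt <- cnt + fetch_shift(ones, tab$sdy[j], tab$sdx[j])
      }
      out[, , d, sigma] <- relu(exp(acc / pmax(cnt, 1)) - eps - theta_t)
    }
  }
  out
}

# sigmoidal closure signal of one teardrop cell: a steep (Hill-4) sigmoid,
# so a direction only counts toward closure when its teardrop is strongly
# active — partial chains contribute little
closure_signal <- function(x, sigma_g) {
  x^4 / (x^4 + sigma_g^4)
}

# Precomputed linear-index plan for the teardrop sampling lattice: for each
# (size, direction) the destination pixels and source indices into the
# flattened convex array, plus in-grid sample counts. Semantically identical
# to teardrop_drive_sizes(), just faster inside the simulation loop.
teardrop_shift_plan <- function(geom, n, m) {
  idx <- matrix(seq_len(n * m), n, m)
  nm <- n * m
  plans <- vector("list", geom$n_scales)
  for (sigma in seq(geom$min_size, geom$n_scales)) {
    plans[[sigma]] <- vector("list", geom$n_dir)
    for (d in seq_len(geom$n_dir)) {
      tab <- geom$samples[[sigma]][[d]]
      dst <- src <- vector("list", nrow(tab))
      counts <- numeric(nm)
      for (j in seq_len(nrow(tab))) {
        dy <- tab$sdy[j]; dx <- tab$sdx[j]
        r0 <- max(1L, 1L - dy); r1 <- min(n, n - dy)
        c0 <- max(1L, 1L - dx); c1 <- min(m, m - dx)
        if (r0 <= r1 && c0 <= c1) {
          dst[[j]] <- as.vector(idx[r0:r1, c0:c1])
          src[[j]] <- as.vector(idx[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx)]) +
            (tab$scale[j] - 1L) * nm
          counts[dst[[j]]] <- counts[dst[[j]]] + 1
        } else {
          dst[[j]] <- integer(0); src[[j]] <- integer(0)
        }
      }
      plans[[sigma]][[d]] <- list(dst = dst, src = src, counts = pmax(counts, 1))
    }
  }
  list(n = n, m = m, S = geom$n_scales, D = geom$n_dir,
       min_size = geom$min_size, samples = plans)
}

td_drive_fast <- function(convex, plan, theta_t, eps = 0.01) {
  nm <- plan$n * plan$m
  logc <- log(pmax(convex, eps))
  out <- array(0, c(plan$n, plan$m, plan$D, plan$S))
  for (sigma in seq(plan$min_size, plan$S)) {
    for (d in seq_len(plan$D)) {
      p <- plan$samples[[sigma]][[d]]
      acc <- numeric(nm)
      for (j in seq_along(p$dst)) {
        acc[p$dst[[j]]] <- acc[p$dst[[j]]] + logc[p$src[[j]]]
      }
      out[, , d, sigma] <- relu(exp(acc / p$counts) - eps - theta_t)
    }
  }
  out
}

#' Signed closure feedback from teardrop cells to convex cells
#'
#' At each position the closure evidence for scale s is the sum over
#' integration directions of a sigmoidal signal of the strongest teardrop
#' activity of size >= s in that direction, minus the agreement threshold
#' `theta_F`: positive when sufficiently many directions agree (the RF is on
#' a figure's medial axis), negative otherwise. Because the feedback is
#' carried by the teardrop cells themselves, the signed evidence is
#' delivered in proportion to how active the local teardrop population is
#' (`ramp`, saturating at 1): a silent teardrop layer sends no feedback at
#' all, while an active layer with poor directional agreement delivers
#' suppression approaching `-theta_F`. Positive feedback enhances and
#' negative feedback suppresses the convex cells of the same or smaller RF
#' size; the signal is spread over part of the teardrop's spatial extent (a
#' box pool of half-width `spread * radii[s]`) so interior convex cells —
#' not only the peak — are modulated.
#'
#' @param teardrop array position x position x direction (single-size
#'   evidence applied to every scale) or position x position x direction x
#'   size as produced by [teardrop_drive_sizes()].
#' @param geom a [teardrop_geometry()].
#' @param theta_F agreement threshold: with the sigmoid saturating at 1,
#'   `theta_F = 2` means at least three strongly (or four moderately) active
#'   directions are needed for net excitation.
#' @param sigma_g half-saturation activity of the sigmoid.
#' @param alpha weight of the unspread (RF-position) component vs the
#'   spatially spread component.
#' @param spread spatial extent of the spread component, as a fraction of
#'   the scale radius (default 0.5).
#' @param ramp_c half-saturation total evidence of the delivery ramp.
#' @return array position x position x scale of signed feedback; zero
#'   teardrop activity gives zero feedback.
#' @export
teardrop_feedback <- function(teardrop, geom, theta_F = 2, sigma_g = 0.25,
                              alpha = 0.5, spread = 0.5, ramp_c = 0.5) {
  dims <- dim(teardrop)
  n <- dims[1]; m <- dims[2]; n_dir <- dims[3]
  S <- geom$n_scales
  per_size <- length(dims) == 4
  out <- array(0, c(n, m, S))
  if (per_size) {
    G <- closure_signal(teardrop, sigma_g)
    # per-direction running max of the closure signal over sizes >= s
    gmax <- lapply(seq_len(n_dir), function(d) matrix(0, n, m))
    for (s in S:1) {
      tot <- matrix(0, n, m)
      for (d in seq_len(n_dir)) {
        gmax[[d]] <- pmax(gmax[[d]], G[, , d, s])
        tot <- tot + gmax[[d]]
      }
      F_s <- (tot - theta_F) * tot / (tot + ramp_c)
      out[, , s] <- alpha * F_s + (1 - alpha) * box_pool(F_s, spread * geom$radii[s])
    }
  } else {
    tot <- matrix(0, n, m)
    for (d in seq_len(n_dir)) {
      tot <- tot + closure_signal(teardrop[, , d], sigma_g)
    }
    F_all <- (tot - theta_F) * tot / (tot + ramp_c)
    for (s in seq_len(S)) {
      out[, , s] <- alpha * F_all + (1 - alpha) * box_pool(F_all, spread * geom$radii[s])
    }
  }
  out
}

#' Size-invariance probe
#'
#' Runs the full model on a family of scaled versions of a figure and
#' reports the maximum teardrop activity for each, flagging figures whose
#' inscribed radius exceeds the largest convex RF (where the closure
#' machinery necessarily collapses).
#'
#' @param displays list of `visual_display` objects (one figure family at
#'   increasing sizes).
#' @param lesion a [lesion_config()]; default intact.
#' @param params a [sim_params()].
#' @return data frame with columns `name`, `inscribed_radius`,
#'   `max_teardrop`, `excluded`.
#' @export
size_invariance_probe <- function(displays, lesion = lesion_config("intact"),
                                  params = sim_params()) {
  rows <- lapply(displays, function(dsp) {
    rin <- max(distance_transform(dsp$figure_mask))
    excl <- rin > max(params$radii)
    mt <- NA_real_
    if (!excl) {
      run <- run_model(dsp, lesion = lesion, params = params)
      mt <- max(teardrop_field(run))
    }
    data.frame(name = dsp$name, inscribed_radius = rin,
               max_teardrop = mt, excluded = excl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
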