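#' Simulation parameters
#'
#' All dynamical constants of the model in one place. Every layer obeys
#' shunting (membrane) dynamics dx/dt = -A x + (B - x) E - (D + x) I, so
#' activities stay in \[-D, B\]; with the defaults A = B = 1, D = 0 all
#' activities live in \[0, 1\]. Integration uses the exponential-Euler
#' update, which is exact for inputs held constant over a step and
#' unconditionally respects the shunting bounds.
#'
#' Pathway gains and thresholds are model design constants; the defaults
#' were calibrated once so that (i) a 60/40 two-scale contrast is sharpened
#' by cross-scale competition within 100 steps, (ii) closure feedback turns
#' excitatory when at least half of the integration directions are
#' moderately active, and (iii) the exemplar figures reproduce the expected
#' interior-enhancement behaviour (see the package vignette).
#'
#' @param A,B,D decay, excitatory ceiling, inhibitory floor.
#' @param dt integration step.
#' @param n_steps maximum number of steps.
#' @param convergence_tol stop when the largest per-step activity change
#'   falls below this value.
#' @param radii the 7 scale radii (px).
#' @param n_arcs,n_orient,orient_tol,ring_width arc bank geometry (see
#'   [build_arc_bank()]).
#' @param theta_c curved-contour rectification threshold.
#' @param g_ff,ff_expn feedforward gain onto convex cells and the
#'   expansive exponent applied to the gated annular drive (sharpens the
#'   spatial tuning of medial-axis responses).
#' @param opposing_gate,gate_eps annulus gating (see [annulus_params()]).
#' @param g_comp cross-scale competition gain.
#' @param g_rec,kappa,rec_pool coarse-to-fine recurrent inhibition gain,
#'   local curved-input cancellation gain, and inhibition footprint (see
#'   [convex_recurrent_inhibition()]).
#' @param g_td,theta_t teardrop drive gain and threshold.
#' @param n_dir,lambda teardrop geometry (see [teardrop_geometry()]).
#' @param theta_F,sigma_g,alpha_spread,fb_spread,ramp_c closure feedback
#'   constants (see [teardrop_feedback()]).
#' @param g_fb_e,g_fb_i gains of the excitatory/inhibitory halves of the
#'   teardrop feedback; the excitatory half acts as a multiplicative gain on
#'   the feedforward drive, the inhibitory half adds to the shunting
#'   inhibition.
#' @param rho_readout fraction of the dominant-scale peak kept by
#'   [readout_medial()].
#' @param seed optional integer seed recorded with runs.
#' @param ... override any field by name.
#' @return a `sim_params` list.
#' @export
sim_params <- function(A = 1, B = 1, D = 0, dt = 0.25, n_steps = 400L,
                       convergence_tol = 2e-4,
                       radii = default_radii(),
                       n_arcs = 8L, n_orient = 8L, orient_tol = 22.5,
                       ring_width = 3L, theta_c = 0.02, g_ff = 12, ff_expn = 4,
                       opposing_gate = 2L,
                       gate_eps = 0.01, g_comp = 8, g_rec = 6, kappa = 1.1,
                       rec_pool = 0.5,
                       g_td = 6, theta_t = 0.02, n_dir = 8L, lambda = 1.5,
                       theta_F = 1.9, sigma_g = 0.45, alpha_spread = 0.6,
                       fb_spread = 0.3, ramp_c = 0.5, g_fb_e = 3, g_fb_i = 3,
                       rho_readout = 0.8, seed = NULL, ...) {
  p <- list(A = A, B = B, D = D, dt = dt, n_steps = as.integer(n_steps),
            convergence_tol = convergence_tol, radii = radii,
            n_arcs = as.integer(n_arcs), n_orient = as.integer(n_orient),
            orient_tol = orient_tol, ring_width = as.integer(ring_width),
            theta_c = theta_c, g_ff = g_ff, ff_expn = ff_expn,
            opposing_gate = as.integer(opposing_gate), gate_eps = gate_eps,
            g_comp = g_comp, g_rec = g_rec, kappa = kappa, rec_pool = rec_pool,
            g_td = g_td,
            theta_t = theta_t, n_dir = as.integer(n_dir), lambda = lambda,
            theta_F = theta_F, sigma_g = sigma_g, alpha_spread = alpha_spread,
            fb_spread = fb_spread, ramp_c = ramp_c, g_fb_e = g_fb_e, g_fb_i = g_fb_i,
            rho_readout = rho_readout, seed = seed)
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  stopifnot(p$A > 0, p$B > 0, p$dt > 0, p$n_steps >= 1)
  structure(p, class = "sim_params")
}

#' Lesion configuration for the two feedback pathways
#'
#' The four combinations name the standard experimental conditions:
#' `"intact"` (both pathways on), `"convex_only"` (only the convex-cell
#' recurrent circuit), `"teardrop_only"` (only the teardrop feedback
#' circuit), and `"none"` (no feedback).
#'
#' @param condition one of `"intact"`, `"convex_only"`, `"teardrop_only"`,
#'   `"none"`; or supply the booleans directly.
#' @param convex_recurrent_on,teardrop_feedback_on explicit switches.
#' @return a `lesion_config` list.
#' @export
lesion_config <- function(condition = NULL, convex_recurrent_on = TRUE,
                          teardrop_feedback_on = TRUE) {
  if (!is.null(condition)) {
    condition <- match.arg(condition,
                           c("intact", "convex_only", "teardrop_only", "none"))
    convex_recurrent_on <- condition %in% c("intact", "convex_only")
    teardrop_feedback_on <- condition %in% c("intact", "teardrop_only")
  } else {
    condition <- if (convex_recurrent_on && teardrop_feedback_on) "intact"
    else if (convex_recurrent_on) "convex_only"
    else if (teardrop_feedback_on) "teardrop_only"
    else "none"
  }
  structure(list(condition = condition,
                 convex_recurrent_on = convex_recurrent_on,
                 teardrop_feedback_on = teardrop_feedback_on),
            class = "lesion_config")
}

#' Precomputed per-display model context
#'
#' The curved-contour layer is a static function of the display, so the edge
#' map, arc bank responses, gated feedforward drive, curved cancellation
#' energy, and teardrop sampling caches are computed once and shared by all
#' simulations (e.g. across lesion conditions) of the same display.
#'
#' @param display a `visual_display`.
#' @param params a [sim_params()].
#' @return a `model_context` list.
#' @export
build_model_context <- function(display, params = sim_params()) {
  stopifnot(inherits(display, "visual_display"))
  edge <- compute_edge_map(display, params$n_orient)
  bank <- build_arc_bank(params$radii, params$n_arcs, params$orient_tol,
                         params$ring_width)
  curved <- curved_response(edge, bank, params$theta_c)
  ap <- annulus_params(params$radii, params$opposing_gate, params$gate_eps)
  drive <- annulus_drive(curved, ap)
  geom <- teardrop_geometry(params$radii, params$n_dir, params$lambda)
  n <- nrow(display$image); m <- ncol(display$image)
  E_ff <- params$g_ff * drive^params$ff_expn
  structure(list(display = display, edge_map = edge, bank = bank,
                 curved = curved, drive_ff = drive, E_ff = E_ff,
                 ff_expect = params$B * E_ff / (params$A + E_ff),
                 curved_energy = curved_scale_energy(curved),
                 geom = geom,
                 td_plan = teardrop_shift_plan(geom, n, m),
                 dims = c(n, m)),
            class = "model_context")
}

new_model_state <- function(ctx, params) {
  n <- ctx$dims[1]; m <- ctx$dims[2]
  S <- length(params$radii)
  list(convex = array(0, c(n, m, S)),
       teardrop = array(0, c(n, m, params$n_dir, S)),
       t = 0L)
}

#' Exponential-Euler shunting update
#'
#' Advances dx/dt = -A x + (B - x) E - (D + x) I by one step of `params$dt`
#' using the exact solution for excitation and inhibition held constant over
#' the step, so activities remain in \[-D, B\] for any nonnegative E and I
#' and the fixed point `(B E - D I) / (A + E + I)` is reached without
#' overshoot.
#'
#' @param x current activity (any numeric array).
#' @param E,I nonnegative excitatory/inhibitory inputs (scalar or same shape).
#' @param params a [sim_params()] (fields `A`, `B`, `D`, `dt`).
#' @return updated activity, same shape as `x`.
#' @export
shunt_update <- function(x, E, I, params) {
  rate <- params$A + E + I
  xinf <- (params$B * E - params$D * I) / rate
  xinf + (x - xinf) * exp(-params$dt * rate)
}

#' One synchronous model step
#'
#' Updates the convex and teardrop layers by one shunting step. All drives
#' are evaluated on the incoming state, so the update order is immaterial.
#' Excitation to a convex cell is the gated annular feedforward drive, with
#' the positive half of the teardrop feedback acting as a multiplicative
#' gain on it (closure feedback enhances the cells it received feedforward
#' input from — it cannot create activity where there is no boundary
#' evidence); inhibition collects cross-scale competition, coarse-to-fine
#' recurrent inhibition, and the negative half of the teardrop feedback.
#' Lesioned pathways contribute nothing. The curved layer is static per
#' display and lives in the context.
#'
#' @param state list with `convex`, `teardrop`, `t` (see
#'   [build_model_context()] / [run_model()]).
#' @param ctx a [build_model_context()] result.
#' @param lesion a [lesion_config()].
#' @param params a [sim_params()].
#' @return the updated state, with the largest absolute activity change in
#'   attribute `delta`.
#' @export
step_model <- function(state, ctx, lesion = lesion_config("intact"),
                       params = sim_params()) {
  E_cvx <- ctx$E_ff
  I_cvx <- params$g_comp * cross_scale_competition(state$convex)
  if (lesion$convex_recurrent_on) {
    I_cvx <- I_cvx + params$g_rec *
      convex_recurrent_inhibition(state$convex, ctx$ff_expect,
                                  params$radii, params$kappa, params$rec_pool)
  }
  if (lesion$teardrop_feedback_on) {
    fb <- teardrop_feedback(state$teardrop, ctx$geom, params$theta_F,
                            params$sigma_g, params$alpha_spread,
                            params$fb_spread, params$ramp_c)
    E_cvx <- E_cvx * (1 + params$g_fb_e * relu(fb))
    I_cvx <- I_cvx + params$g_fb_i * relu(-fb)
  }
  convex_new <- shunt_update(state$convex, E_cvx, I_cvx, params)

  E_td <- params$g_td *
    td_drive_fast(state$convex, ctx$td_plan, params$theta_t)
  teardrop_new <- shunt_update(state$teardrop, E_td, 0, params)

  bad <- !is.finite(convex_new) | convex_new < -params$D - 1e-6 |
    convex_new > params$B + 1e-6
  if (any(bad)) {
    stop(sprintf("numerical divergence at step %d: %d convex activities left [%g, %g]",
                 state$t + 1L, sum(bad), -params$D, params$B), call. = FALSE)
  }
  delta <- max(max(abs(convex_new - state$convex)),
               max(abs(teardrop_new - state$teardrop)))
  out <- list(convex = convex_new, teardrop = teardrop_new, t = state$t + 1L)
  attr(out, "delta") <- delta
  out
}

#' Run the model on a display
#'
#' Integrates the recurrent network from rest until the largest per-step
#' activity change falls below `convergence_tol` or `n_steps` is reached
#' (the latter sets `converged = FALSE` with a warning). Runs are
#' deterministic functions of the display, lesion, and parameters.
#'
#' @param x a `visual_display` or a prebuilt [build_model_context()] (to
#'   share the static feedforward stage across lesion conditions).
#' @param lesion a [lesion_config()].
#' @param params a [sim_params()].
#' @param probes optional data frame with columns `row`, `col`, `scale`:
#'   convex-cell activities at these cells are recorded at every step.
#' @param record_stride if > 0, keep a snapshot of the full state every
#'   `record_stride` steps (plus the final state) in `$trajectory`.
#' @return a `model_run`: final `state`, `converged`, `steps`, `delta`,
#'   per-step `scale_max` matrix (steps x scales), probe `traces`,
#'   optional `trajectory`, plus the `ctx`, `lesion`, `params` used.
#' @export
run_model <- function(x, lesion = lesion_config("intact"),
                      params = sim_params(), probes = NULL,
                      record_stride = 0L) {
  ctx <- if (inherits(x, "model_context")) x else build_model_context(x, params)
  state <- new_model_state(ctx, params)
  S <- length(params$radii)
  scale_max <- matrix(NA_real_, params$n_steps, S)
  traces <- NULL
  if (!is.null(probes)) {
    stopifnot(all(c("row", "col", "scale") %in% names(probes)))
    traces <- matrix(NA_real_, params$n_steps, nrow(probes))
  }
  trajectory <- if (record_stride > 0) list() else NULL
  steps <- 0L
  delta <- Inf
  for (it in seq_len(params$n_steps)) {
    state <- step_model(state, ctx, lesion, params)
    delta <- attr(state, "delta")
    steps <- it
    for (s in seq_len(S)) scale_max[it, s] <- max(state$convex[, , s])
    if (!is.null(traces)) {
      traces[it, ] <- state$convex[cbind(probes$row, probes$col, probes$scale)]
    }
    if (record_stride > 0 && (it %% record_stride == 0L)) {
      trajectory[[length(trajectory) + 1L]] <- state
    }
    if (delta < params$convergence_tol) break
  }
  converged <- delta < params$convergence_tol
  if (!converged) {
    warning(sprintf("model did not converge within %d steps (delta = %.3g)",
                    params$n_steps, delta))
  }
  if (record_stride > 0 &&
      (length(trajectory) == 0L || trajectory[[length(trajectory)]]$t != state$t)) {
    trajectory[[length(trajectory) + 1L]] <- state
  }
  structure(list(state = state, converged = converged, steps = steps,
                 delta = delta,
                 scale_max = scale_max[seq_len(steps), , drop = FALSE],
                 traces = if (is.null(traces)) NULL else
                   traces[seq_len(steps), , drop = FALSE],
                 probes = probes, trajectory = trajectory,
                 ctx = ctx, lesion = lesion, params = params),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run '%s' [%s]: %d steps, %sconverged, peak convex %.3f>\n",
              x$ctx$display$name, x$lesion$condition, x$steps,
              if (x$converged) "" else "NOT ", max(x$state$convex)))
  invisible(x)
}

#' Convex activity of a run
#' @param run a `model_run`.
#' @return array position x position x scale.
#' @export
convex_field <- function(run) run$state$convex

#' Teardrop activity of a run (pooled over sizes)
#' @param run a `model_run`.
#' @param per_size if `TRUE` return the position x position x direction x
#'   size array instead of the size-pooled field.
#' @return array position x position x direction (default).
#' @export
teardrop_field <- function(run, per_size = FALSE) {
  if (per_size) return(run$state$teardrop)
  d <- dim(run$state$teardrop)
  out <- array(0, d[1:3])
  for (sigma in seq_len(d[4])) out <- pmax(out, run$state$teardrop[, , , sigma])
  out
}

#' Activity time course of one convex cell
#'
#' Returns the per-step activity of the probed convex cell; the cell must
#' have been listed in `probes` when the run was created.
#'
#' @param run a `model_run` created with `probes`.
#' @param row,col,scale the probed cell.
#' @return numeric vector with one entry per recorded step.
#' @export
time_course <- function(run, row, col, scale) {
  if (is.null(run$traces)) {
    stop("run was created without probes; pass `probes` to run_model()",
         call. = FALSE)
  }
  hit <- which(run$probes$row == row & run$probes$col == col &
                 run$probes$scale == scale)
  if (!length(hit)) stop("no probe was recorded at that cell", call. = FALSE)
  run$traces[, hit[1]]
}
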