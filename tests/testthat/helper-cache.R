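# Session-level cache of expensive simulations so several test files can
# share one equilibrium run per (exemplar, lesion) pair.
.run_cache <- new.env(parent = emptyenv())

cached_exemplars <- function() {
  if (is.null(.run_cache$exemplars)) .run_cache$exemplars <- make_exemplars()
  .run_cache$exemplars
}

cached_params <- function() {
  if (is.null(.run_cache$params)) .run_cache$params <- sim_params()
  .run_cache$params
}

cached_ctx <- function(name) {
  key <- paste0("ctx_", name)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- build_model_context(cached_exemplars()[[name]],
                                             cached_params())
  }
  .run_cache[[key]]
}

cached_run <- function(name, lesion = "intact", probes = NULL) {
  key <- paste0("run_", name, "_", lesion, "_",
                if (is.null(probes)) "np" else paste(unlist(probes), collapse = "_"))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- suppressWarnings(
      run_model(cached_ctx(name), lesion_config(lesion), cached_params(),
                probes = probes)
    )
  }
  .run_cache[[key]]
}

# canonical medial-axis / concavity probes for the C-shape exemplar:
# the spine midline cell at the arm's fitting scale, and the concavity cell
# with the strongest feedforward drive at its own best scale
c_shape_probes <- function() {
  if (!is.null(.run_cache$c_probes)) return(.run_cache$c_probes)
  cs <- cached_exemplars()$c_shape
  ctx <- cached_ctx("c_shape")
  mrow <- as.integer(round(nrow(cs$image) / 2))
  mcol <- min(which(cs$medial_mask[mrow, ]))
  mscale <- which.max(ctx$drive_ff[mrow, mcol, ])
  rows_fig <- range(which(rowSums(cs$figure_mask) > 0))
  inside <- matrix(FALSE, nrow(cs$image), ncol(cs$image))
  inside[(rows_fig[1] + 1):(rows_fig[2] - 1), ] <- TRUE
  concav <- inside & !cs$figure_mask
  dmax <- apply(ctx$drive_ff, c(1, 2), max)
  dmax[!concav] <- -1
  ij <- which(dmax == max(dmax), arr.ind = TRUE)[1, ]
  cscale <- which.max(ctx$drive_ff[ij[1], ij[2], ])
  .run_cache$c_probes <- data.frame(
    row = c(mrow, ij[1]), col = c(mcol, ij[2]), scale = c(mscale, cscale),
    role = c("medial", "concavity")
  )
  .run_cache$c_probes
}
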