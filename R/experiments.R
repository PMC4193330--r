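#' Experiment specification
#'
#' Describes a reproducible sweep: which display set, which lesion
#' conditions, which parameters, and where to write artifacts. Stochastic
#' sets (the random-block classes) derive per-display seeds from `seed`, and
#' subsampling of parametric sets is itself seeded, so a spec regenerates
#' its outputs byte-identically.
#'
#' @param displays a set name (`"exemplars"`, `"rectangles"`, `"c_shapes"`,
#'   `"crosses"`, `"square_textures"`, `"blocks_lc"`, `"blocks_mc"`,
#'   `"blocks_hc"`) or a list of `visual_display` objects.
#' @param lesions character vector of [lesion_config()] condition names.
#' @param params a [sim_params()].
#' @param out_dir directory for artifacts (CSV, manifest), or `NULL`.
#' @param seed integer seed for display generation/subsampling.
#' @param subsample for large sets, the number of displays actually run
#'   (`NULL` = all; the block classes default to their full 500).
#' @param name experiment label.
#' @return an `experiment_spec` list.
#' @export
experiment_spec <- function(displays, lesions = c("intact", "convex_only",
                                                  "teardrop_only", "none"),
                            params = sim_params(), out_dir = NULL, seed = 1L,
                            subsample = NULL, name = "experiment") {
  structure(list(displays = displays, lesions = lesions, params = params,
                 out_dir = out_dir, seed = as.integer(seed),
                 subsample = subsample, name = name),
            class = "experiment_spec")
}

#' Materialise the displays of an experiment
#' @param spec an [experiment_spec()].
#' @return list of `visual_display` objects.
#' @export
materialize_displays <- function(spec) {
  d <- spec$displays
  if (is.list(d) && !is.null(d[[1]]) && inherits(d[[1]], "visual_display")) {
    return(d)
  }
  stopifnot(is.character(d), length(d) == 1)
  set <- switch(
    d,
    exemplars = make_exemplars(),
    rectangles = make_rectangle_set(),
    c_shapes = make_c_shape_set(),
    crosses = make_cross_set(),
    square_textures = make_square_texture_set(),
    blocks_lc = make_block_set(4L, n = spec$subsample %||% 500L, seed = spec$seed),
    blocks_mc = make_block_set(16L, n = spec$subsample %||% 500L, seed = spec$seed),
    blocks_hc = make_block_set(32L, n = spec$subsample %||% 500L, seed = spec$seed),
    stop("unknown display set: ", d, call. = FALSE)
  )
  if (!is.null(spec$subsample) && !startsWith(d, "blocks") &&
      spec$subsample < length(set)) {
    idx <- with_seed(spec$seed, sample.int(length(set), spec$subsample))
    set <- set[sort(idx)]
  }
  set
}

#' Run an experiment: all displays under all lesion conditions
#'
#' The static feedforward context of each display is built once and shared
#' across lesion conditions. Per-display failures are caught and recorded
#' (column `error`); if `out_dir` is set, the metrics table, a per-lesion
#' summary, and a JSON manifest (parameters, seeds, package version, config
#' hash) are written there.
#'
#' @param spec an [experiment_spec()].
#' @return data frame with one row per display x lesion.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  displays <- materialize_displays(spec)
  rows <- list()
  for (dsp in displays) {
    res <- tryCatch({
      ctx <- build_model_context(dsp, spec$params)
      lapply(spec$lesions, function(cond) {
        run <- run_model(ctx, lesion_config(cond), spec$params)
        df <- as.data.frame(metrics_report(run))
        df$error <- NA_character_
        df
      })
    }, error = function(e) {
      list(data.frame(display = dsp$name, lesion = NA_character_,
                      ioi = NA_real_, mai = NA_real_, bi = NA_real_,
                      mai_dominant = NA_real_, kurtosis = NA_real_,
                      peak_scale = NA_integer_, peak_row = NA_integer_,
                      peak_col = NA_integer_, converged = NA, steps = NA_integer_,
                      error = conditionMessage(e), stringsAsFactors = FALSE))
    })
    rows <- c(rows, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(spec$out_dir)) {
    write_experiment_artifacts(spec, out)
  }
  out
}

write_experiment_artifacts <- function(spec, out) {
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(spec$out_dir, paste0(spec$name, "_metrics.csv"))
  utils::write.csv(out, csv, row.names = FALSE)
  summ <- summarize_experiment(out)
  utils::write.csv(summ, file.path(spec$out_dir, paste0(spec$name, "_summary.csv")),
                   row.names = FALSE)
  cfg <- list(
    name = spec$name,
    displays = if (is.character(spec$displays)) spec$displays else "custom list",
    lesions = spec$lesions, seed = spec$seed, subsample = spec$subsample,
    params = unclass(spec$params),
    package_version = as.character(utils::packageVersion("teardrop"))
  )
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null", digits = NA)
  cfg_file <- file.path(spec$out_dir, paste0(spec$name, "_manifest.json"))
  writeLines(cfg_json, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  manifest <- c(as.list(jsonlite::fromJSON(cfg_json, simplifyVector = FALSE)),
                list(config_md5 = hash))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), cfg_file)
  invisible(csv)
}

#' Per-lesion summary of an experiment table
#'
#' Mean and standard deviation of each index per lesion condition, plus each
#' index mean min-max normalised across the conditions present (1 = best,
#' 0 = worst).
#'
#' @param df a [run_experiment()] result.
#' @return data frame with one row per lesion condition.
#' @export
summarize_experiment <- function(df) {
  df <- df[is.na(df$error) & !is.na(df$lesion), , drop = FALSE]
  conds <- unique(df$lesion)
  rows <- lapply(conds, function(cond) {
    d <- df[df$lesion == cond, ]
    data.frame(lesion = cond, n = nrow(d),
               ioi_mean = mean(d$ioi, na.rm = TRUE),
               ioi_sd = stats::sd(d$ioi, na.rm = TRUE),
               mai_mean = mean(d$mai, na.rm = TRUE),
               mai_sd = stats::sd(d$mai, na.rm = TRUE),
               bi_mean = mean(d$bi, na.rm = TRUE),
               bi_sd = stats::sd(d$bi, na.rm = TRUE),
               kurtosis_mean = mean(d$kurtosis[is.finite(d$kurtosis)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ioi_norm <- normalize_indices(out$ioi_mean)
  out$mai_norm <- normalize_indices(out$mai_mean)
  out$bi_norm <- normalize_indices(out$bi_mean)
  out
}

#' Render figure-style panels for one run
#'
#' Writes one PNG per scale of the convex activity, one per scale of the
#' signed teardrop feedback (blue = suppression, warm = enhancement), the
#' display itself, and (when probes were recorded) a time-course plot.
#'
#' @param run a `model_run`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
render_panels <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dsp <- run$ctx$display
  files <- character()
  files <- c(files, write_gray_png(dsp$image,
                                   file.path(out_dir, "display.png")))
  S <- dim(run$state$convex)[3]
  peak <- max(run$state$convex, 1e-12)
  fb <- teardrop_feedback(run$state$teardrop, run$ctx$geom,
                          run$params$theta_F, run$params$sigma_g,
                          run$params$alpha_spread, run$params$fb_spread,
                          run$params$ramp_c)
  for (s in seq_len(S)) {
    f1 <- file.path(out_dir, sprintf("convex_scale%d.png", s))
    files <- c(files, write_gray_png(run$state$convex[, , s] / peak, f1))
    f2 <- file.path(out_dir, sprintf("feedback_scale%d.png", s))
    files <- c(files, write_signed_png(fb[, , s], f2))
  }
  if (!is.null(run$traces)) {
    f <- file.path(out_dir, "time_course.png")
    grDevices::png(f, width = 640, height = 480)
    graphics::matplot(run$traces, type = "l", lty = 1,
                      xlab = "step", ylab = "convex activity",
                      main = dsp$name)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

#' Bar chart of normalised indices across lesion conditions
#' @param summary a [summarize_experiment()] table.
#' @param file output PNG path.
#' @return the file path, invisibly.
#' @export
render_index_bars <- function(summary, file) {
  grDevices::png(file, width = 720, height = 420)
  on.exit(grDevices::dev.off())
  m <- t(as.matrix(summary[, c("ioi_norm", "mai_norm", "bi_norm")]))
  colnames(m) <- summary$lesion
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                    legend.text = c("IOI", "MAI", "BI"),
                    ylab = "normalised index (1 = best)")
  invisible(file)
}
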