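# Figure-ground indices. Each index is a normalised contrast
# (a - b) / (a + b) of mean activities over two complementary regions, so
# all indices live in [-1, 1] for nonnegative activity and are invariant to
# rescaling the activity map by any positive constant.

index_contrast <- function(a, b) {
  if (a + b == 0) {
    warning("0/0 index contrast; returning 0")
    return(0)
  }
  (a - b) / (a + b)
}

mask_mean <- function(map, mask, what) {
  if (!any(mask)) stop("empty ", what, " mask", call. = FALSE)
  mean(map[mask])
}

#' In-Out Index: activity inside vs outside the figure
#'
#' `(A_fig - A_gnd) / (A_fig + A_gnd)` with `A` the mean activity over the
#' figure and ground masks. 1 means all activity is on the figure interior.
#'
#' @param map nonnegative activity matrix.
#' @param masks [region_masks()] of the display.
#' @return scalar in \[-1, 1\].
#' @export
ioi <- function(map, masks) {
  index_contrast(mask_mean(map, masks$figure, "figure"),
                 mask_mean(map, masks$ground, "ground"))
}

#' Medial Axis Index: activity on vs off the skeleton band
#'
#' `(A_med - A_int) / (A_med + A_int)`, comparing mean activity within one
#' pixel of the medial axis against the complementary portion of the figure
#' interior. Larger values mean activation is concentrated on the skeleton.
#'
#' @inheritParams ioi
#' @return scalar in \[-1, 1\].
#' @export
mai <- function(map, masks) {
  index_contrast(mask_mean(map, masks$medial_band, "medial band"),
                 mask_mean(map, masks$interior_rest, "interior"))
}

#' Boundary Index: activity near the boundary vs everywhere else
#'
#' `(A_bnd - A_else) / (A_bnd + A_else)`, comparing mean activity within one
#' pixel of the figure boundary against the rest of the canvas.
#'
#' @inheritParams ioi
#' @return scalar in \[-1, 1\].
#' @export
bi <- function(map, masks) {
  index_contrast(mask_mean(map, masks$boundary_band, "boundary band"),
                 mask_mean(map, masks$elsewhere, "elsewhere"))
}

#' Activity map of a convex field
#'
#' @param convex array position x position x scale.
#' @param scale a scale index for a single-scale map, or `NULL` for the
#'   per-position maximum over scales.
#' @return activity matrix.
#' @export
activity_map <- function(convex, scale = NULL) {
  if (!is.null(scale)) return(convex[, , scale])
  d <- dim(convex)
  out <- matrix(0, d[1], d[2])
  for (s in seq_len(d[3])) out <- pmax(out, convex[, , s])
  out
}

#' Kurtosis of the scale profile of maximal convex activity
#'
#' The per-scale maxima of convex activity, normalised to unit sum, are
#' treated as a probability mass over the scale index, and the Pearson
#' kurtosis mu4 / mu2^2 of that mass is returned. A large kurtosis means
#' most active convex cells share a common RF size (high confidence in the
#' medial-axis scale); mass split evenly over the two extreme scales gives
#' exactly 1, and a profile concentrated on a single scale gives `Inf`.
#'
#' @param x a convex field array or the numeric vector of per-scale maxima.
#' @return Pearson (non-excess) kurtosis.
#' @export
scale_profile_kurtosis <- function(x) {
  v <- if (is.array(x) && length(dim(x)) == 3) {
    apply(x, 3, max)
  } else {
    as.numeric(x)
  }
  if (all(v == 0)) stop("all-zero scale profile", call. = FALSE)
  if (any(v < 0)) stop("scale profile must be nonnegative", call. = FALSE)
  w <- v / sum(v)
  s <- seq_along(w)
  mu <- sum(w * s)
  mu2 <- sum(w * (s - mu)^2)
  if (mu2 == 0) return(Inf)
  sum(w * (s - mu)^4) / mu2^2
}

#' Medial-axis readout from convex activity
#'
#' The dominant scale is the one whose maximal activity is largest (ties
#' broken toward the smaller scale); the readout positions are the pixels of
#' that scale within a fraction `rho` of its peak. This is a plain
#' peak-picking summary of the population activity, not a probabilistic
#' decode.
#'
#' @param convex array position x position x scale, not all zero.
#' @param rho peak fraction retained (default 0.8).
#' @return list with `scale`, `peak` (row, col of the first maximal pixel),
#'   and `positions` (matrix of row/col readout pixels).
#' @export
readout_medial <- function(convex, rho = 0.8) {
  per_scale <- apply(convex, 3, max)
  if (max(per_scale) == 0) stop("cannot read out an all-zero field", call. = FALSE)
  s <- which.max(per_scale)
  slice <- convex[, , s]
  pk <- which(slice == max(slice), arr.ind = TRUE)[1, ]
  pos <- which(slice >= rho * max(slice), arr.ind = TRUE)
  list(scale = as.integer(s), peak = as.integer(pk), positions = pos)
}

#' Full metrics report for one simulation
#'
#' Indices are computed on the per-position maximum of convex activity over
#' scales; the medial-axis index is additionally reported at the dominant RF
#' size (`mai_dominant`), matching how single-figure analyses quote it.
#'
#' @param run a `model_run` (or a convex field array, with `display` given).
#' @param display the simulated `visual_display` (defaults to the run's).
#' @param tol index band half-width in pixels.
#' @return a `metrics_report` (also a one-row data frame via
#'   [as.data.frame.metrics_report()]).
#' @export
metrics_report <- function(run, display = NULL, tol = 1L) {
  if (inherits(run, "model_run")) {
    convex <- run$state$convex
    display <- display %||% run$ctx$display
    lesion <- run$lesion$condition
    converged <- run$converged
    steps <- run$steps
  } else {
    convex <- run
    stopifnot(!is.null(display))
    lesion <- NA_character_
    converged <- NA
    steps <- NA_integer_
  }
  masks <- region_masks(display, tol)
  map_full <- activity_map(convex)
  per_scale <- apply(convex, 3, max)
  ro <- readout_medial(convex)
  map_dom <- activity_map(convex, ro$scale)
  # degenerate regions (e.g. a skeleton band that swallows the whole interior
  # of a very thin figure) yield NA rather than aborting a sweep
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  structure(list(
    display = display$name,
    lesion = lesion,
    ioi = safely(ioi(map_full, masks)),
    mai = safely(mai(map_full, masks)),
    bi = safely(bi(map_full, masks)),
    mai_dominant = safely(mai(map_dom, masks)),
    kurtosis = safely(scale_profile_kurtosis(per_scale)),
    peak_scale = ro$scale,
    peak_row = ro$peak[1],
    peak_col = ro$peak[2],
    per_scale_max = per_scale,
    converged = converged,
    steps = steps
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics '%s' [%s]: IOI %.3f, MAI %.3f (dominant-scale %.3f), BI %.3f,\n  kurtosis %.2f, peak scale %d at (%d, %d)>\n",
              x$display, x$lesion, x$ioi, x$mai, x$mai_dominant, x$bi,
              x$kurtosis, x$peak_scale, x$peak_row, x$peak_col))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(display = x$display, lesion = x$lesion, ioi = x$ioi, mai = x$mai,
             bi = x$bi, mai_dominant = x$mai_dominant, kurtosis = x$kurtosis,
             peak_scale = x$peak_scale, peak_row = x$peak_row,
             peak_col = x$peak_col, converged = x$converged, steps = x$steps,
             stringsAsFactors = FALSE)
}

#' Min-max normalisation of an index across lesion conditions
#'
#' Rescales a vector of index values (one per lesion condition) so that 1 is
#' the best and 0 the worst performance; a constant vector maps to 0.5.
#'
#' @param x numeric vector.
#' @return values in \[0, 1\].
#' @export
normalize_indices <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (x - rng[1]) / diff(rng)
}
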