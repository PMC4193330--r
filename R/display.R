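#' Visual display objects
#'
#' A `visual_display` bundles a raster image (values in \[0, 1\]) with the
#' ground-truth masks the figure-ground indices need: the figure interior
#' (including its boundary), the one-pixel inner boundary, and the figure's
#' medial-axis skeleton. All generators return this class.
#'
#' @param image numeric matrix in \[0, 1\] (row = y, growing downward).
#' @param figure_mask logical matrix, `TRUE` on the figure (interior plus
#'   boundary). Must be nonempty unless `allow_empty = TRUE` (used only for
#'   background-only control displays in the interior-enhancement paradigm).
#' @param name display identifier.
#' @param params named list of generator parameters (provenance).
#' @param seed integer seed used by stochastic generators, or `NULL`.
#' @param allow_empty permit an empty figure mask (control displays).
#' @return an object of class `visual_display` with fields `image`,
#'   `figure_mask`, `boundary_mask`, `medial_mask`, `name`, `params`, `seed`.
#' @export
new_visual_display <- function(image, figure_mask, name, params = list(),
                               seed = NULL, allow_empty = FALSE) {
  stop_if_not_mask(figure_mask, "figure_mask")
  stopifnot(is.matrix(image), all(dim(image) == dim(figure_mask)))
  if (any(image < -1e-9 | image > 1 + 1e-9)) {
    stop("image values must lie in [0, 1]", call. = FALSE)
  }
  if (!any(figure_mask) && !allow_empty) {
    stop("figure_mask is empty; generated displays must contain a figure",
         call. = FALSE)
  }
  if (any(figure_mask)) {
    boundary <- inner_boundary(figure_mask)
    medial <- compute_medial_axis(figure_mask)
  } else {
    boundary <- medial <- figure_mask
  }
  structure(
    list(image = image, figure_mask = figure_mask, boundary_mask = boundary,
         medial_mask = medial, name = name, params = params, seed = seed),
    class = "visual_display"
  )
}

#' @export
print.visual_display <- function(x, ...) {
  cat(sprintf("<visual_display '%s': %dx%d px, figure %d px, skeleton %d px>\n",
              x$name, nrow(x$image), ncol(x$image),
              sum(x$figure_mask), sum(x$medial_mask)))
  invisible(x)
}

#' Check the structural invariants of a display
#'
#' Errors unless the boundary and medial masks are subsets of the figure
#' mask, all masks share the image's shape, and (unless the display was built
#' with `allow_empty`) the figure is nonempty.
#'
#' @param display a `visual_display`.
#' @return the display, invisibly.
#' @export
validate_display <- function(display) {
  stopifnot(inherits(display, "visual_display"))
  d <- dim(display$image)
  for (f in c("figure_mask", "boundary_mask", "medial_mask")) {
    stopifnot(is.logical(display[[f]]), all(dim(display[[f]]) == d))
  }
  if (any(display$boundary_mask & !display$figure_mask)) {
    stop("boundary_mask is not a subset of figure_mask", call. = FALSE)
  }
  if (any(display$medial_mask & !display$figure_mask)) {
    stop("medial_mask is not a subset of figure_mask", call. = FALSE)
  }
  invisible(display)
}

#' Region masks for the figure-ground indices
#'
#' Splits the canvas into the regions over which mean activity is compared:
#' figure vs ground (in-out index), the band within `tol` pixels of the
#' medial axis vs the complementary interior (medial-axis index), and the
#' band within `tol` pixels of the boundary vs everything else (boundary
#' index). Bands use Chebyshev dilation, so "within 1 pixel" includes
#' diagonal neighbours.
#'
#' @param display a `visual_display`.
#' @param tol band half-width in pixels (default 1; `tol = 0` leaves the
#'   masks undilated).
#' @return named list of logical matrices: `figure`, `ground`,
#'   `medial_band`, `interior_rest`, `boundary_band`, `elsewhere`.
#' @export
region_masks <- function(display, tol = 1L) {
  stopifnot(inherits(display, "visual_display"), tol >= 0)
  fig <- display$figure_mask
  medial_band <- dilate_mask(display$medial_mask, tol)
  boundary_band <- dilate_mask(display$boundary_mask, tol)
  list(
    figure = fig,
    ground = !fig,
    medial_band = medial_band,
    interior_rest = fig & !medial_band,
    boundary_band = boundary_band,
    elsewhere = !boundary_band
  )
}
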