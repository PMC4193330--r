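# Parametric visual displays. All generators draw a white figure (1) on a
# black background (0) on a square canvas (default 64 x 64 px), centered, and
# attach ground-truth figure / boundary / skeleton masks. Figures are sized
# so that the annular receptive fields of the model (radii ~3-24 px) bracket
# the figure's inscribed radius, mirroring the proportions used in the
# simulations the model was designed around.

DEFAULT_CANVAS <- 64L

blank_canvas <- function(canvas = DEFAULT_CANVAS) {
  matrix(FALSE, canvas, canvas)
}

# centered run of `len` pixels on an axis of length `canvas`
centered_span <- function(canvas, len) {
  start <- floor((canvas - len) / 2) + 1L
  start:(start + len - 1L)
}

mask_display <- function(mask, name, params = list(), seed = NULL) {
  new_visual_display(mask * 1, mask, name = name, params = params, seed = seed)
}

#' Axis-aligned rectangle display
#'
#' Builds a filled rectangle centered on the canvas. The height is set from
#' `area_scale` (the side of the equal-area square) and the width is
#' `round(aspect_ratio * height)`, so an aspect ratio of 2 yields a width of
#' exactly twice the rounded height.
#'
#' @param aspect_ratio width/height in \[1/8, 8\].
#' @param area_scale side (px) of the equal-area square; default 17.
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_rectangle <- function(aspect_ratio, area_scale = 17L, canvas = DEFAULT_CANVAS) {
  stopifnot(aspect_ratio >= 1 / 8, aspect_ratio <= 8)
  h <- as.integer(sym_round(area_scale / sqrt(aspect_ratio)))
  w <- as.integer(sym_round(aspect_ratio * h))
  rect_display(w, h, canvas,
               name = sprintf("rectangle_a%.3g", aspect_ratio),
               params = list(aspect_ratio = aspect_ratio, area_scale = area_scale))
}

rect_display <- function(w, h, canvas = DEFAULT_CANVAS, name = NULL, params = list()) {
  if (w < 3 || h < 3) {
    stop(sprintf("degenerate rectangle (%d x %d px); sides must be >= 3 px", w, h),
         call. = FALSE)
  }
  if (w > canvas - 2 || h > canvas - 2) {
    stop("rectangle does not fit the canvas", call. = FALSE)
  }
  mask <- blank_canvas(canvas)
  mask[centered_span(canvas, h), centered_span(canvas, w)] <- TRUE
  mask_display(mask, name %||% sprintf("rectangle_%dx%d", w, h),
               c(params, list(width = w, height = h)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 64-rectangle display set
#'
#' An 8 x 8 grid of widths and heights whose extreme side ratio spans
#' aspect ratios 1/8 to 8, giving 64 distinct rectangles.
#'
#' @param sides the 8 side lengths (px) crossed as widths x heights.
#' @param canvas canvas side in pixels.
#' @return list of 64 displays.
#' @export
make_rectangle_set <- function(sides = c(5L, 7L, 9L, 12L, 16L, 22L, 29L, 40L),
                               canvas = DEFAULT_CANVAS) {
  stopifnot(length(sides) == 8)
  out <- list()
  for (w in sides) for (h in sides) {
    out[[length(out) + 1L]] <- rect_display(w, h, canvas)
  }
  out
}

#' C-shape display
#'
#' A three-sided figure: an outer rectangle with a rectangular concavity
#' opening to the right. The wall and both arms are `thickness` pixels thick.
#' Concavity pixels belong to the background.
#'
#' @param aspect_ratio outer width/height in \[1/4, 4\].
#' @param thickness arm thickness, 1-6 px.
#' @param outer_scale side (px) of the equal-area outer square; default 30.
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_c_shape <- function(aspect_ratio, thickness, outer_scale = 30L,
                         canvas = DEFAULT_CANVAS) {
  stopifnot(aspect_ratio >= 1 / 4, aspect_ratio <= 4,
            thickness >= 1, thickness <= 6)
  t <- as.integer(thickness)
  w <- as.integer(sym_round(outer_scale * sqrt(aspect_ratio)))
  h <- as.integer(sym_round(outer_scale / sqrt(aspect_ratio)))
  if (h - 2L * t < 1L || w - t < 1L) {
    stop("thickness too large: the concavity vanishes", call. = FALSE)
  }
  if (w > canvas - 2 || h > canvas - 2) stop("C-shape does not fit the canvas", call. = FALSE)
  rows <- centered_span(canvas, h)
  cols <- centered_span(canvas, w)
  mask <- blank_canvas(canvas)
  mask[rows, cols] <- TRUE
  conc_rows <- rows[(t + 1L):(h - t)]
  conc_cols <- cols[(t + 1L):w]
  mask[conc_rows, conc_cols] <- FALSE
  mask_display(mask, sprintf("c_shape_a%.3g_t%d", aspect_ratio, t),
               list(aspect_ratio = aspect_ratio, thickness = t,
                    outer_scale = outer_scale, width = w, height = h))
}

#' The 96-C-shape display set (16 aspect ratios x 6 thicknesses)
#'
#' @param n_aspects number of equally spaced aspect ratios over \[1/4, 4\].
#' @param thicknesses arm thicknesses in pixels.
#' @param canvas canvas side in pixels.
#' @return list of 96 displays.
#' @export
make_c_shape_set <- function(n_aspects = 16L, thicknesses = 1:6,
                             canvas = DEFAULT_CANVAS) {
  aspects <- seq(1 / 4, 4, length.out = n_aspects)
  out <- list()
  for (a in aspects) for (t in thicknesses) {
    out[[length(out) + 1L]] <- make_c_shape(a, t, canvas = canvas)
  }
  out
}

#' Cross (plus-sign) display
#'
#' Union of a horizontal and a vertical bar of the given thickness and
#' length, centered. With odd `thickness` and `size` the figure is exactly
#' 4-fold rotationally symmetric about its own center, and its area is
#' `2 * thickness * size - thickness^2`.
#'
#' @param thickness bar thickness (px), strictly less than `size`.
#' @param size bar length (px).
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_cross <- function(thickness, size, canvas = DEFAULT_CANVAS) {
  if (thickness >= size) stop("cross thickness must be < size", call. = FALSE)
  if (size > canvas - 2) stop("cross does not fit the canvas", call. = FALSE)
  tr <- centered_span(canvas, thickness)
  sr <- centered_span(canvas, size)
  mask <- blank_canvas(canvas)
  mask[tr, sr] <- TRUE
  mask[sr, tr] <- TRUE
  mask_display(mask, sprintf("cross_t%d_s%d", thickness, size),
               list(thickness = thickness, size = size))
}

#' The 36-cross display set (6 thicknesses x 6 sizes)
#' @param thicknesses,sizes odd pixel values crossed into the grid.
#' @param canvas canvas side in pixels.
#' @return list of 36 displays.
#' @export
make_cross_set <- function(thicknesses = c(3L, 5L, 7L, 9L, 11L, 13L),
                           sizes = c(15L, 19L, 23L, 27L, 31L, 35L),
                           canvas = DEFAULT_CANVAS) {
  out <- list()
  for (t in thicknesses) for (s in sizes) {
    out[[length(out) + 1L]] <- make_cross(t, s, canvas)
  }
  out
}

#' Square-texture display (2 x 2 arrangement of square elements)
#'
#' Four filled square elements of side `element_size`, separated by a
#' background gap of `displacement` pixels, centered on the canvas. Element
#' centers form a square lattice of pitch `element_size + displacement`. The
#' skeleton mask is the union of the per-element skeletons.
#'
#' @param element_size element side (px).
#' @param displacement gap between elements (px, >= 1).
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_square_texture <- function(element_size, displacement, canvas = DEFAULT_CANVAS) {
  stopifnot(displacement >= 1, element_size >= 3)
  total <- 2L * element_size + displacement
  if (total > canvas - 2) stop("square texture does not fit the canvas", call. = FALSE)
  rows <- centered_span(canvas, total)
  mask <- blank_canvas(canvas)
  e <- element_size
  starts <- c(rows[1], rows[1] + e + displacement)
  for (r0 in starts) for (c0 in starts) {
    mask[r0:(r0 + e - 1L), c0:(c0 + e - 1L)] <- TRUE
  }
  mask_display(mask, sprintf("square_texture_e%d_d%d", element_size, displacement),
               list(element_size = element_size, displacement = displacement))
}

#' The 36-square-texture display set (6 displacements x 6 element sizes)
#' @param element_sizes,displacements pixel grids crossed into the set.
#' @param canvas canvas side in pixels.
#' @return list of 36 displays.
#' @export
make_square_texture_set <- function(element_sizes = c(5L, 7L, 9L, 11L, 13L, 15L),
                                    displacements = c(3L, 5L, 7L, 9L, 11L, 13L),
                                    canvas = DEFAULT_CANVAS) {
  out <- list()
  for (e in element_sizes) for (d in displacements) {
    out[[length(out) + 1L]] <- make_square_texture(e, d, canvas)
  }
  out
}

#' Parameters for the seeded random-block figure generator
#'
#' @param n_blocks number of blocks appended to the base rectangle
#'   (4, 16 and 32 define the low/medium/high complexity classes).
#' @param base_size side of the square base rectangle (px).
#' @param block_size_range inclusive range of block sides (px).
#' @param seed integer RNG seed; the generated figure is a deterministic
#'   function of the parameters and seed.
#' @param canvas canvas side in pixels.
#' @param margin pixels kept clear around the canvas border.
#' @return a `block_shape_params` list.
#' @export
block_shape_params <- function(n_blocks, base_size = 9L,
                               block_size_range = c(3L, 7L), seed = 1L,
                               canvas = DEFAULT_CANVAS, margin = 4L) {
  stopifnot(n_blocks >= 0, base_size >= 3,
            length(block_size_range) == 2,
            block_size_range[1] >= 1,
            block_size_range[2] >= block_size_range[1])
  structure(list(n_blocks = as.integer(n_blocks), base_size = as.integer(base_size),
                 block_size_range = as.integer(block_size_range),
                 seed = as.integer(seed), canvas = as.integer(canvas),
                 margin = as.integer(margin)),
            class = "block_shape_params")
}

#' Random-block figure
#'
#' Grows a figure from a base rectangle by iteratively attaching square
#' blocks: at each step a background pixel 4-adjacent to the shape grown so
#' far is chosen uniformly at random, a block side is drawn uniformly from
#' `block_size_range`, and the block is placed (uniformly over alignments)
#' so that it covers the chosen site. Every added block is therefore
#' edge-adjacent to the current shape and the figure stays 4-connected.
#'
#' @param params a [block_shape_params()] object.
#' @return a [new_visual_display()] object; bit-identical for equal
#'   parameters and seed.
#' @export
make_random_blocks <- function(params) {
  stopifnot(inherits(params, "block_shape_params"))
  with_seed(params$seed, {
    canvas <- params$canvas
    lo <- params$margin + 1L
    hi <- canvas - params$margin
    mask <- blank_canvas(canvas)
    mask[centered_span(canvas, params$base_size),
         centered_span(canvas, params$base_size)] <- TRUE
    n_added <- 0L
    tries <- 0L
    while (n_added < params$n_blocks) {
      tries <- tries + 1L
      if (tries > 200L * (params$n_blocks + 1L)) {
        stop("random block generator found no legal placement", call. = FALSE)
      }
      adj <- dilate4(mask) & !mask
      cand <- which(adj)
      if (!length(cand)) stop("no adjacent sites available", call. = FALSE)
      site <- cand[sample.int(length(cand), 1L)]
      sr <- ((site - 1L) %% canvas) + 1L
      sc <- ((site - 1L) %/% canvas) + 1L
      b <- sample(params$block_size_range[1]:params$block_size_range[2], 1L)
      r0 <- sr - sample.int(b, 1L) + 1L
      c0 <- sc - sample.int(b, 1L) + 1L
      if (r0 < lo || c0 < lo || r0 + b - 1L > hi || c0 + b - 1L > hi) next
      mask[r0:(r0 + b - 1L), c0:(c0 + b - 1L)] <- TRUE
      n_added <- n_added + 1L
    }
    mask_display(mask,
                 sprintf("blocks_n%d_seed%d", params$n_blocks, params$seed),
                 unclass(params), seed = params$seed)
  })
}

# 4-neighbour dilation
dilate4 <- function(mask) {
  num <- mask * 1
  (num + fetch_shift(num, 1L, 0L) + fetch_shift(num, -1L, 0L) +
      fetch_shift(num, 0L, 1L) + fetch_shift(num, 0L, -1L)) > 0
}

#' A random-block display set of one complexity class
#'
#' @param n_blocks blocks per figure (4 = low, 16 = medium, 32 = high
#'   complexity).
#' @param n number of displays.
#' @param seed base seed; display `i` uses `seed + i - 1`.
#' @param ... forwarded to [block_shape_params()].
#' @return list of `n` displays.
#' @export
make_block_set <- function(n_blocks, n = 500L, seed = 1L, ...) {
  lapply(seq_len(n), function(i) {
    make_random_blocks(block_shape_params(n_blocks, seed = seed + i - 1L, ...))
  })
}

#' Filled disk display (circle figure)
#' @param radius disk radius in px.
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_disk <- function(radius, canvas = DEFAULT_CANVAS) {
  stopifnot(radius >= 1.5, 2 * radius < canvas - 2)
  ctr <- (canvas + 1) / 2
  dy <- matrix(seq_len(canvas) - ctr, canvas, canvas)
  dx <- t(dy)
  mask <- (dy^2 + dx^2) <= radius^2
  mask_display(mask, sprintf("disk_r%.3g", radius), list(radius = radius))
}

#' Thin bar display (narrower than the smallest annular RF)
#' @param width,length bar dimensions (px).
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_thin_bar <- function(width = 4L, length = 40L, canvas = DEFAULT_CANVAS) {
  mask <- blank_canvas(canvas)
  mask[centered_span(canvas, width), centered_span(canvas, length)] <- TRUE
  mask_display(mask, sprintf("thin_bar_w%d_l%d", width, length),
               list(width = width, length = length))
}

#' Crescent display (curved counterpart of the C-shape)
#'
#' An annular sector of outer radius `r_outer` and inner radius `r_inner`
#' whose angular opening (toward +x) plays the role of the C-shape's
#' concavity; the boundaries are circular arcs instead of right angles.
#'
#' @param r_outer,r_inner outer/inner arc radii (px).
#' @param opening_deg half-angle of the opening, degrees.
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_crescent <- function(r_outer = 15, r_inner = 9, opening_deg = 55,
                          canvas = DEFAULT_CANVAS) {
  stopifnot(r_outer > r_inner, r_inner >= 1)
  ctr <- (canvas + 1) / 2
  dy <- matrix(seq_len(canvas) - ctr, canvas, canvas)
  dx <- t(dy)
  rr <- sqrt(dy^2 + dx^2)
  ang <- abs(atan2(dy, dx)) * 180 / pi
  mask <- rr <= r_outer & rr >= r_inner & ang >= opening_deg
  mask_display(mask, "crescent",
               list(r_outer = r_outer, r_inner = r_inner, opening_deg = opening_deg))
}

#' Filled triangle display
#' @param side approximate side length (px).
#' @param canvas canvas side in pixels.
#' @return a [new_visual_display()] object.
#' @export
make_triangle <- function(side = 30, canvas = DEFAULT_CANVAS) {
  ctr <- (canvas + 1) / 2
  hgt <- side * sqrt(3) / 2
  v <- rbind(c(ctr - 2 * hgt / 3, ctr),              # apex (top)
             c(ctr + hgt / 3, ctr - side / 2),       # base left
             c(ctr + hgt / 3, ctr + side / 2))       # base right
  ys <- matrix(seq_len(canvas), canvas, canvas)
  xs <- t(ys)
  sgn <- function(p1, p2) {
    (xs - p2[2]) * (p1[1] - p2[1]) - (p1[2] - p2[2]) * (ys - p2[1])
  }
  d1 <- sgn(v[1, ], v[2, ]); d2 <- sgn(v[2, ], v[3, ]); d3 <- sgn(v[3, ], v[1, ])
  mask <- !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
  mask_display(mask, "triangle", list(side = side))
}

#' Texture-defined square and its background-only control
#'
#' Emulates the classic interior-enhancement paradigm: a square region is
#' defined purely by orientation contrast between oblique line textures. The
#' control display carries the figure's texture everywhere, so the pixels
#' inside the square region are identical in the two displays while only the
#' figure display contains an orientation-contrast boundary. The lumped
#' early-vision stage places edge energy on that contrast boundary (the
#' square outline), so the control display produces an empty edge map.
#'
#' @param side square side (px).
#' @param pitch stroke spacing (px).
#' @param canvas canvas side in pixels.
#' @return list with elements `figure` and `background` (the control display,
#'   built with an empty figure mask).
#' @export
make_texture_pair <- function(side = 17L, pitch = 4L, canvas = DEFAULT_CANVAS) {
  rows <- matrix(seq_len(canvas), canvas, canvas)
  cols <- t(rows)
  tex_a <- ((rows + cols) %% pitch == 0) * 1    # figure-orientation strokes
  tex_b <- ((rows - cols) %% pitch == 0) * 1    # background-orientation strokes
  sq <- blank_canvas(canvas)
  sq[centered_span(canvas, side), centered_span(canvas, side)] <- TRUE
  img_fig <- ifelse(sq, tex_a, tex_b)
  img_bg <- tex_a
  list(
    figure = new_visual_display(img_fig, sq, name = "texture_square",
                                params = list(side = side, pitch = pitch)),
    background = new_visual_display(img_bg, blank_canvas(canvas),
                                    name = "texture_background",
                                    params = list(side = side, pitch = pitch),
                                    allow_empty = TRUE)
  )
}

#' Named exemplar displays
#'
#' The eight exemplar figures used throughout the worked analyses: a square,
#' a C-shape, a cross, a 2 x 2 square texture, a bar thinner than the
#' smallest annular RF, a crescent matching the C-shape footprint, a
#' triangle, and a texture-defined square (whose background-only control is
#' available from [make_texture_pair()]).
#'
#' @param canvas canvas side in pixels.
#' @return named list of eight displays.
#' @export
make_exemplars <- function(canvas = DEFAULT_CANVAS) {
  list(
    square = make_rectangle(1, 17L, canvas),
    c_shape = make_c_shape(1, 6L, canvas = canvas),
    cross = make_cross(9L, 33L, canvas),
    square_texture = make_square_texture(13L, 7L, canvas),
    thin_bar = make_thin_bar(4L, 40L, canvas),
    crescent = make_crescent(canvas = canvas),
    triangle = make_triangle(canvas = canvas),
    texture_square = make_texture_pair(canvas = canvas)$figure
  )
}
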