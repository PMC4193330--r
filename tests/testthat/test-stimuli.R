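test_that("rectangle generator respects aspect and rejects degenerate sizes", {
  sq <- make_rectangle(1, 17)
  expect_equal(sq$params$width, sq$params$height)
  h <- make_rectangle(2, 17)$params$height
  expect_equal(make_rectangle(2, 17)$params$width, round(2 * h))
  expect_error(make_rectangle(1, 2), "degenerate")
  expect_error(make_rectangle(10, 17))
  validate_display(sq)
})

test_that("C-shape concavity belongs to the background", {
  cs <- make_c_shape(1, 4)
  rect <- make_rectangle(1, cs$params$outer_scale)
  # C-shape figure is a subset of the same-size outer rectangle
  outer <- matrix(FALSE, 64, 64)
  rows <- teardrop:::centered_span(64L, cs$params$height)
  cols <- teardrop:::centered_span(64L, cs$params$width)
  outer[rows, cols] <- TRUE
  expect_true(all(!cs$figure_mask | outer))
  # concavity pixels (outer minus figure) are in neither figure nor boundary
  conc <- outer & !cs$figure_mask
  expect_gt(sum(conc), 0)
  expect_false(any(conc & cs$figure_mask))
  expect_false(any(conc & cs$boundary_mask))
  expect_error(make_c_shape(4, 8), "thickness|concavity")
})

test_that("crosses are 4-fold symmetric with closed-form area", {
  for (t in c(3L, 7L)) for (s in c(15L, 27L)) {
    cr <- make_cross(t, s)
    expect_equal(sum(cr$figure_mask), 2 * t * s - t^2)
    bb <- which(cr$figure_mask, arr.ind = TRUE)
    sub <- cr$figure_mask[min(bb[, 1]):max(bb[, 1]), min(bb[, 2]):max(bb[, 2])]
    expect_identical(rot_cw(sub), sub)
  }
  expect_error(make_cross(9, 9))
})

test_that("square-texture elements form a lattice of pitch size + displacement", {
  tx <- make_square_texture(9, 5)
  lab <- which(tx$figure_mask, arr.ind = TRUE)
  expect_equal(sum(tx$figure_mask), 4 * 81)
  # element centers via quadrant means
  mid <- mean(range(lab[, 1]))
  tl <- lab[lab[, 1] < mid & lab[, 2] < mid, ]
  tr <- lab[lab[, 1] < mid & lab[, 2] > mid, ]
  expect_equal(mean(tr[, 2]) - mean(tl[, 2]), 9 + 5)
})

test_that("random block figures are seeded, connected, and diverse", {
  p <- block_shape_params(0, seed = 7)
  base <- make_random_blocks(p)
  expect_equal(sum(base$figure_mask), p$base_size^2)

  p4 <- block_shape_params(4, seed = 11)
  a <- make_random_blocks(p4)
  b <- make_random_blocks(p4)
  expect_identical(a$figure_mask, b$figure_mask)

  # 4-connectivity: one connected component
  lab <- EBImage::bwlabel(a$figure_mask * 1)
  expect_equal(max(lab), 1)

  keys <- vapply(seq_len(500), function(i) {
    m <- make_random_blocks(block_shape_params(32, seed = i))$figure_mask
    paste(which(m), collapse = ",")
  }, character(1))
  expect_gte(length(unique(keys)), 495)
})

test_that("display generators are deterministic and masks satisfy invariants", {
  gens <- list(make_rectangle(1.7, 17), make_c_shape(0.8, 3), make_cross(5, 23),
               make_square_texture(7, 5), make_thin_bar(), make_crescent(),
               make_triangle())
  for (d in gens) {
    validate_display(d)
    expect_gt(sum(d$figure_mask), 0)
    expect_true(all(!d$boundary_mask | d$figure_mask))
    expect_true(all(!d$medial_mask | d$figure_mask))
  }
  expect_identical(make_c_shape(0.8, 3), make_c_shape(0.8, 3))
})

test_that("exemplars match their defining constraints", {
  ex <- cached_exemplars()
  expect_named(ex, c("square", "c_shape", "cross", "square_texture", "thin_bar",
                     "crescent", "triangle", "texture_square"))
  # thin bar narrower than the smallest annular RF diameter
  expect_lt(ex$thin_bar$params$width, 2 * default_radii()[1])
  # crescent is an annular band as thick as the C-shape's arms
  expect_equal(ex$crescent$params$r_outer - ex$crescent$params$r_inner,
               ex$c_shape$params$thickness)
  # texture pair: identical pixels inside the square region
  pair <- make_texture_pair()
  sq <- pair$figure$figure_mask
  expect_identical(pair$figure$image[sq], pair$background$image[sq])
  expect_equal(sum(pair$background$figure_mask), 0)
})

test_that("region masks partition as documented", {
  d <- make_rectangle(1.5, 15)
  m0 <- region_masks(d, tol = 0)
  expect_identical(m0$medial_band, d$medial_mask)
  m1 <- region_masks(d, tol = 1)
  expect_gte(sum(m1$boundary_band), sum(d$boundary_mask))
  expect_false(any(m1$medial_band & m1$interior_rest))
  expect_identical(m1$figure | m1$ground, matrix(TRUE, 64, 64))
  # medial band stays inside the figure for convex figures
  for (a in c(0.5, 1, 3)) {
    mm <- region_masks(make_rectangle(a, 16))
    expect_false(any(mm$medial_band & mm$ground))
  }
})
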