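test_that("teardrop geometry: equal spacing, largest scale at the RF position", {
  geom <- teardrop_geometry()
  for (sigma in 2:7) {
    tab <- geom$samples[[sigma]][[1]]
    expect_equal(tab$scale[1], sigma)
    expect_equal(tab$scale, sigma:(sigma - nrow(tab) + 1L))
    offs <- sqrt(tab$sdy^2 + tab$sdx^2)
    if (nrow(tab) > 2) expect_lt(max(abs(diff(diff(offs)))), 1.5)  # ~equal spacing
    # directions d and d+2 are exact 90-degree rotations
    t2 <- geom$samples[[sigma]][[3]]
    expect_equal(t2$sdy, tab$sdx)
    expect_equal(t2$sdx, -tab$sdy)
  }
})

test_that("teardrop drive is conjunctive and shares the offset-0 input", {
  geom <- teardrop_geometry()
  conv <- array(0, c(70, 70, 7))
  expect_equal(sum(teardrop_drive(conv, geom)), 0)

  # activity only at the shared offset-0 cell: identical drive in all
  # directions (every chain fits the grid, so no border renormalisation)
  conv[35, 35, 7] <- 0.9
  dr <- teardrop_drive_sizes(conv, geom)
  for (sigma in 2:7) {
    per_dir <- dr[35, 35, , sigma]
    expect_equal(max(per_dir) - min(per_dir), 0)
  }
  # a silent chain keeps the evidence near zero despite the strong shared cell
  expect_lt(max(dr[35, 35, , ]), 0.05)
})

test_that("teardrop drive points along a corner's medial bisector", {
  ctx <- cached_ctx("square")
  dr <- teardrop_drive(ctx$ff_expect, ctx$geom)
  # top-left corner wedge: the bisector direction (45 deg, d = 2) dominates
  expect_gt(dr[29, 29, 2], dr[29, 29, 4] + 0.1)
  expect_gt(dr[29, 29, 2], dr[29, 29, 8] + 0.1)
})

test_that("closure feedback switches sign with directional agreement", {
  geom <- teardrop_geometry()
  p <- cached_params()
  n <- 20
  all_on <- array(0.9, c(n, n, 8))
  fb <- teardrop_feedback(all_on, geom, p$theta_F, p$sigma_g, p$alpha_spread,
                          p$fb_spread, p$ramp_c)
  expect_true(all(fb > 0))

  one_on <- array(0, c(n, n, 8)); one_on[, , 1] <- 0.9
  fb1 <- teardrop_feedback(one_on, geom, p$theta_F, p$sigma_g, p$alpha_spread,
                           p$fb_spread, p$ramp_c)
  expect_true(all(fb1 < 0))

  # a silent teardrop layer delivers no feedback at all
  silent <- array(0, c(n, n, 8))
  fb0 <- teardrop_feedback(silent, geom, p$theta_F, p$sigma_g, p$alpha_spread,
                           p$fb_spread, p$ramp_c)
  expect_true(all(fb0 <= 0))
  expect_equal(sum(abs(fb0)), 0)
})

test_that("positive feedback implies multi-directional support", {
  run <- cached_run("square", "intact")
  p <- cached_params()
  fb <- teardrop_feedback(run$state$teardrop, run$ctx$geom, p$theta_F,
                          p$sigma_g, alpha = 1, spread = p$fb_spread, p$ramp_c)
  td <- teardrop_field(run)
  ndir <- apply(td > 0.05, c(1, 2), sum)
  pos <- fb[, , 1] > 0   # unspread component at the smallest scale
  expect_true(all(ndir[pos] >= 2))
})

test_that("triangle medial positions out-support positions outside the figure", {
  run <- cached_run("triangle", "intact")
  tri <- cached_exemplars()$triangle
  td <- teardrop_field(run)
  ndir <- apply(td > 0.1, c(1, 2), sum)
  outside <- teardrop:::dilate_mask(tri$figure_mask, 2) & !tri$figure_mask
  expect_gt(mean(ndir[tri$medial_mask]), mean(ndir[outside]))
})

test_that("teardrop activity is more punctate for squares than elongated rectangles", {
  # isotropic integration directions concentrate teardrop activity at a
  # square's center; an equal-area elongated rectangle spreads it along the
  # long midline, so far less of the total mass sits near the centroid
  p <- cached_params()
  central_share <- function(run) {
    td <- apply(teardrop_field(run), c(1, 2), max)
    ctr <- (nrow(td) + 1) / 2
    dy <- matrix(seq_len(nrow(td)) - ctr, nrow(td), ncol(td))
    near <- (dy^2 + t(dy)^2) <= 16
    sum(td[near]) / sum(td)
  }
  r1 <- suppressWarnings(run_model(make_rectangle(1, 17),
                                   lesion_config("intact"), p))
  r4 <- suppressWarnings(run_model(make_rectangle(4, 17),
                                   lesion_config("intact"), p))
  expect_gt(central_share(r1), 2 * central_share(r4))
})

test_that("teardrop responses are size invariant within the RF range", {
  p <- cached_params()
  fam <- list(make_rectangle(1, 17), make_rectangle(1, 26))
  pr <- size_invariance_probe(fam, params = p)
  expect_false(any(pr$excluded))
  expect_lt(abs(pr$max_teardrop[2] - pr$max_teardrop[1]) / pr$max_teardrop[1],
            0.25)

  # a figure whose inscribed radius exceeds the largest RF is flagged
  big <- make_rectangle(1, 52)
  expect_true(size_invariance_probe(list(big), params = p)$excluded)

  # a degenerate few-pixel figure yields almost no closure evidence
  tiny_mask <- matrix(FALSE, 64, 64); tiny_mask[32, 32] <- TRUE
  tiny <- new_visual_display(tiny_mask * 1, tiny_mask, name = "dot")
  rt <- suppressWarnings(run_model(tiny, lesion_config("intact"), p))
  expect_lt(max(teardrop_field(rt)), 0.05)
})
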