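test_that("annular drive peaks at a circle's center at the matching scale", {
  params <- cached_params()
  bank <- build_arc_bank(ring_width = params$ring_width)
  ap <- annulus_params()
  for (s in 3:5) {
    em <- compute_edge_map(make_disk(default_radii()[s]))
    dr <- annulus_drive(curved_response(em, bank, params$theta_c), ap)
    ctr <- function(ss) max(dr[31:34, 31:34, ss])
    expect_equal(which.max(sapply(1:7, ctr)), s)
    if (s > 1) expect_lt(ctr(s - 1), ctr(s))
    expect_lt(ctr(s + 1), ctr(s))
    # the drive peak over the whole field sits at the center
    pk <- which(dr[, , s] == max(dr[, , s]), arr.ind = TRUE)[1, ]
    expect_true(all(abs(pk - 32.5) <= 1.5))
  }
})

test_that("the opposing gate silences one-sided contour evidence", {
  params <- cached_params()
  bank <- build_arc_bank(ring_width = params$ring_width)
  tb <- make_thin_bar(4, 40)
  dr <- annulus_drive(curved_response(compute_edge_map(tb), bank,
                                      params$theta_c), annulus_params())
  top <- min(which(rowSums(tb$figure_mask) > 0))
  # a cell whose annulus is tangent to the bar from one side only
  expect_equal(sum(dr[top - 3, 32, ]), 0)
})

test_that("wide texture gaps are not bridged by small-scale annuli", {
  params <- cached_params()
  bank <- build_arc_bank(ring_width = params$ring_width)
  tx <- make_square_texture(13, 13)  # displacement > any small-RF diameter
  dr <- annulus_drive(curved_response(compute_edge_map(tx), bank,
                                      params$theta_c), annulus_params())
  gap <- region_masks(tx)$ground &
    teardrop:::dilate_mask(tx$figure_mask, 4) # gap corridor near the elements
  expect_equal(sum(dr[, , 1][gap]), 0)
  expect_equal(sum(dr[, , 2][gap]), 0)
})

test_that("cross-scale competition sharpens non-uniform profiles", {
  u <- array(0.3, c(2, 2, 7))
  comp <- cross_scale_competition(u)
  expect_equal(max(comp) - min(comp), 0)   # symmetric under a uniform profile

  single <- array(0, c(1, 1, 7)); single[1, 1, 3] <- 0.8
  expect_equal(cross_scale_competition(single)[1, 1, 3], 0)

  # 60/40 drive profile: the winner's share grows past its feedforward share
  x <- rep(0, 7); E <- c(0.6, 0.4, rep(0, 5))
  p <- cached_params()
  for (i in 1:100) {
    comp <- p$g_comp * (sum(x^2) - x^2)
    rate <- p$A + E + comp
    xinf <- p$B * E / rate
    x <- xinf + (x - xinf) * exp(-p$dt * rate)
  }
  expect_gt(x[1] / (x[1] + x[2]), 0.6)
})

test_that("recurrent inhibition passes on only feedback-driven excess", {
  S <- 7
  conv <- array(0.4, c(8, 8, S))
  # fully accounted-for activity: no suppression anywhere
  expect_equal(sum(convex_recurrent_inhibition(conv, conv)), 0)
  # unexplained large-scale activity suppresses smaller scales at its center
  expected <- array(0, c(8, 8, S))
  i2 <- convex_recurrent_inhibition(conv, expected)
  expect_true(all(i2[, , 1:(S - 1)] > 0))
  expect_equal(sum(i2[, , S]), 0)  # the largest scale receives none
})

test_that("concavity cells attract more recurrent suppression than medial cells", {
  params <- cached_params()
  cs <- cached_exemplars()$c_shape
  ctx <- cached_ctx("c_shape")
  # static pass: closure feedback has boosted the mid-scale cells that span
  # the concavity beyond their feedforward expectation
  conv <- ctx$ff_expect
  rows_fig <- range(which(rowSums(cs$figure_mask) > 0))
  inside <- matrix(FALSE, 64, 64)
  inside[(rows_fig[1] + 1):(rows_fig[2] - 1), ] <- TRUE
  concav <- inside & !cs$figure_mask
  for (s in 3:6) conv[, , s][concav] <- pmin(1, conv[, , s][concav] * 1.5 + 0.2)
  i2 <- convex_recurrent_inhibition(conv, ctx$ff_expect, params$radii,
                                    params$kappa, params$rec_pool)
  small_concav <- mean(i2[, , 1][concav]) + mean(i2[, , 2][concav])
  mb <- region_masks(cs)$medial_band
  small_medial <- mean(i2[, , 1][mb]) + mean(i2[, , 2][mb])
  expect_gt(small_concav, small_medial)
})

test_that("square equilibrium peaks at the center at the best-fitting scale", {
  run <- cached_run("square", "intact")
  rep <- metrics_report(run)
  half <- cached_exemplars()$square$params$width / 2
  best <- which.min(abs(cached_params()$radii - half))
  expect_equal(rep$peak_scale, best)
  expect_true(all(abs(c(rep$peak_row, rep$peak_col) - 32.5) <= 1.5))
})

test_that("a bar thinner than the smallest RF activates only nearby small cells", {
  run <- cached_run("thin_bar", "intact")
  cv <- convex_field(run)
  expect_equal(max(cv[, , 3:7]), 0, tolerance = 1e-6)
  act <- which(activity_map(cv) > 0.01, arr.ind = TRUE)
  fig <- which(cached_exemplars()$thin_bar$figure_mask, arr.ind = TRUE)
  dists <- vapply(seq_len(nrow(act)), function(i) {
    sqrt(min((act[i, 1] - fig[, 1])^2 + (act[i, 2] - fig[, 2])^2))
  }, numeric(1))
  expect_lt(max(dists), 2 * cached_params()$radii[1])
})
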